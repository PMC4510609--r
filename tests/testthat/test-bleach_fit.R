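test_that("energy matches hand evaluation and the log-shift identity", {
  # model-consistent curve has zero energy
  tt <- seq(0, 10, by = 0.5)
  f <- exp(1.2 - 0.6 * exp(-0.3 * tt))
  expect_lt(bleach_energy(f, tt, p = 1.2, b = 0.3, c = 0.6), 1e-24)
  # two samples f = (e^1, e^2) at t = (0, 1), p = c = 0: (1 + 4) * dt, dt = 1
  expect_equal(bleach_energy(exp(c(1, 2)), c(0, 1), 0, 0.5, 0), 5)
  # multiplying f by e^delta and shifting p leaves E unchanged
  set.seed(1)
  f2 <- exp(rnorm(21, 1, 0.1))
  e1 <- bleach_energy(f2, tt, 0.8, 0.3, 0.4)
  e2 <- bleach_energy(f2 * exp(0.37), tt, 0.8 + 0.37, 0.3, 0.4)
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_error(bleach_energy(c(1, -1, 2), 0:2, 0, 1, 0), "masked")
})

test_that("update step is a fixed point at the minimizer and matches hand evaluation", {
  tt <- seq(0, 20, by = 0.25)
  f <- exp(2 - 0.5 * exp(-0.4 * tt))
  up <- update_step(2, 0.4, 0.5, f, tt, fit_config(fix_b = FALSE))
  expect_equal(unname(up), c(2, 0.4, 0.5), tolerance = 1e-12)
  # one step from (p, c) = (0, 0) on a 3-sample curve, hand-evaluated closed
  # forms (the b-gradient vanishes when c = 0)
  t3 <- c(0, 1, 2); f3 <- c(2, 3, 4)
  cfg <- fit_config(tau_p = 0.1, tau_b = 0.01, tau_c = 0.1, fix_b = FALSE)
  w <- c(1, 1, 1)  # uniform grid, dt = 1
  b0 <- 0.3
  eb <- exp(-b0 * t3)
  p_exp <- (0 + 2 * 0.1 * (sum(w * log(f3)) + 0)) / (1 + 2 * 0.1 * sum(w))
  c_exp <- (0 - 2 * 0.1 * sum(w * log(f3) * eb)) /
    (1 + 2 * 0.1 * sum(w * eb^2))
  up2 <- update_step(0, b0, 0, f3, t3, cfg)
  expect_equal(unname(up2), c(p_exp, b0, c_exp), tolerance = 1e-12)
})

test_that("energy is non-increasing along the scheme on random curves", {
  set.seed(99)
  cfg <- fit_config(tau_p = 0.05, tau_b = 1e-3, tau_c = 0.05, fix_b = FALSE)
  for (i in 1:100) {
    tt <- seq(0, 15, length.out = 30)
    p0 <- runif(1, 1, 4); b0 <- runif(1, 0.1, 0.6); c0 <- runif(1, 0.1, 1)
    f <- exp(p0 - c0 * exp(-b0 * tt)) + abs(rnorm(30, 0, 0.05)) + 0.01
    start <- c(p0 + rnorm(1, 0, 0.3), b0 * runif(1, 0.7, 1.3),
               c0 + rnorm(1, 0, 0.2))
    e0 <- bleach_energy(f, tt, start[1], start[2], start[3])
    up <- update_step(start[1], start[2], start[3], f, tt, cfg)
    e1 <- bleach_energy(f, tt, up[1], up[2], up[3])
    expect_lte(e1, e0 + 1e-12)
  }
})

test_that("pixel fit recovers generating parameters on noiseless curves", {
  # constant curve: no bleaching signal, c -> 0, a -> the constant
  tt <- seq(0, 20, by = 0.25)
  fit0 <- fit_pixel(rep(50, length(tt)), tt, c(log(40), 0.3, 0.4),
                    fit_config())
  expect_true(fit0$converged)
  expect_equal(fit0$c_hat, 0, tolerance = 1e-5)
  expect_equal(fit0$a_hat, 50, tolerance = 1e-3)
  # 480 samples over 60 s, fixed b at the generating value
  t480 <- seq(0, 60, length.out = 480)
  f <- forward_af(t480, pixel_params(100, 0.04, 0.7))
  fit <- fit_pixel(f, t480, c(log(80), 0.04, 0.3), fit_config())
  expect_true(fit$converged)
  expect_lt(abs(fit$a_hat - 100) / 100, 1e-3)
  expect_lt(abs(fit$c_hat - 0.7) / 0.7, 1e-3)
  expect_equal(fit$b_hat, 0.04)  # fix_b
})

test_that("fixed-b fit lands on the brute-force global minimizer (noisy instances)", {
  set.seed(7)
  for (i in 1:20) {
    m <- sample(40:120, 1)
    tt <- seq(0, runif(1, 20, 60), length.out = m)
    a <- runif(1, 50, 150); b <- runif(1, 0.1, 0.5); g <- runif(1, 0.2, 1)
    f <- pmax(forward_af(tt, pixel_params(a, b, g)) + rnorm(m, 0, 2), 1)
    fit <- fit_pixel(f, tt, c(log(a) + 0.3, b, 0.1),
                     fit_config(tol = 1e-10, max_iters = 20000))
    gs <- grid_search_energy(f, tt, b, log(a) + c(-0.5, 0.5),
                             g + c(-0.5, 0.5), n = 200L)
    # the discrete argmin can slide a cell or two along the tilted valley of
    # the quadratic, so proximity is a few cells and the energy must be at
    # least as low as the best grid point
    expect_lt(abs(fit$p_hat - gs$p), 3 * gs$dp)
    expect_lt(abs(fit$c_hat - gs$c), 3 * gs$dc)
    expect_lte(bleach_energy(f, tt, fit$p_hat, b, fit$c_hat), gs$E + 1e-9)
  }
})

test_that("Hessian closed forms match finite differences; determinant 0 iff b = 0", {
  tt <- seq(0, 60, length.out = 120)
  H <- energy_hessian(0.04, tt)
  # finite differences of the energy around an arbitrary point
  f <- forward_af(tt, pixel_params(100, 0.04, 0.7)) + 1
  h <- 1e-4
  E <- function(p, c) bleach_energy(f, tt, p, 0.04, c)
  p0 <- 4; c0 <- 0.5
  d2p <- (E(p0 + h, c0) - 2 * E(p0, c0) + E(p0 - h, c0)) / h^2
  d2c <- (E(p0, c0 + h) - 2 * E(p0, c0) + E(p0, c0 - h)) / h^2
  dpc <- (E(p0 + h, c0 + h) - E(p0 + h, c0 - h) -
            E(p0 - h, c0 + h) + E(p0 - h, c0 - h)) / (4 * h^2)
  expect_equal(H[1, 1], d2p, tolerance = 1e-5)
  expect_equal(H[2, 2], d2c, tolerance = 1e-5)
  expect_equal(H[1, 2], dpc, tolerance = 1e-5)
  expect_gt(det(H), 0)
  expect_equal(det(energy_hessian(0, tt)), 0, tolerance = 1e-9)
  # positive-definiteness for a range of rates
  for (b in c(0.01, 0.04, 0.32, 1)) {
    Hb <- energy_hessian(b, tt)
    expect_gt(Hb[1, 1], 0)
    expect_gt(det(Hb), 0)
  }
})

test_that("block averaging has the right impulse response and fixed points", {
  geo <- movie_geometry(10, c(9, 9), 1.6)
  fr <- array(3, dim = c(16, 16, 3))
  mov <- af_movie(fr, 0:2, geometry = geo)
  expect_equal(block_average(mov, 8)$frames, fr)
  # single bright pixel of 64 spreads to 1 over the covering 8x8 window
  fr2 <- array(0, dim = c(16, 16, 3)); fr2[8, 8, ] <- 64
  avg <- block_average(af_movie(fr2, 0:2, geometry = geo), 8)$frames[, , 1]
  expect_equal(sum(avg), 64, tolerance = 1e-9)
  expect_equal(max(avg), 1)
  expect_equal(avg[8, 8], 1)
  # linear ramp unchanged away from borders (odd window: symmetric support)
  ramp <- array(rep(1:16, each = 16), dim = c(16, 16, 3)) * 1.0
  ar <- block_average(af_movie(ramp, 0:2, geometry = geo), 5)$frames[, , 2]
  expect_equal(ar[4:13, 4:13], ramp[4:13, 4:13, 2], tolerance = 1e-9)
  expect_error(block_average(mov, 20), "larger")
})

test_that("initialization recovers the generating rate from the b histogram", {
  sp <- clean_spec(rod_topology = list(gamma_max = 0.7, scale_sup_deg = 1),
                   seed = 13)
  ph <- generate_movie(sp)
  init <- initialize_fit(ph$movie)
  # within one histogram bin of the true 0.32 1/s
  binw <- if (!is.null(init$b_histogram))
    diff(init$b_histogram$breaks[1:2]) else 0.01
  # noiseless fits cluster so tightly that the bins become microscopic;
  # one bin width, floored at a third of a percent of the rate
  expect_lt(abs(init$b0 - sp$beta), max(binw, 1e-3))
  # p0 field constant without a macular pigment map
  expect_equal(diff(range(init$p0_field)), 0)
  # annulus-average initialization beats a naive start in energy
  e_init <- bleach_energy(init$annulus_curve, ph$movie$times,
                          init$annulus_fit$p_hat, init$annulus_fit$b_hat,
                          init$annulus_fit$c_hat)
  e_naive <- bleach_energy(init$annulus_curve, ph$movie$times, 0, 0.01, 0)
  expect_lt(e_init, e_naive)
})

test_that("macular pigment map modulates the initial amplitude spatially", {
  co <- default_optical_coeffs()
  band <- spectral_band(488, 620)
  sp <- clean_spec(seed = 21)
  ph <- generate_movie(sp)
  init0 <- initialize_fit(ph$movie)
  init1 <- initialize_fit(ph$movie, mp_map = ph$truth$d_mp_map,
                          coeffs = co, band = band)
  ksum <- extinction(co, 488, "mp") + extinction(co, 620, "mp")
  expect_equal(init1$p0_field, init0$p0_field - ph$truth$d_mp_map * ksum,
               tolerance = 1e-12)
  expect_error(initialize_fit(ph$movie, mp_map = ph$truth$d_mp_map),
               "coeffs")
})

test_that("image fit recovers the gamma field and is deterministic and scale-equivariant", {
  # flat rod topology (gamma saturated everywhere outside a tiny center):
  # median relative error of c_hat vs true gamma < 0.5%
  sp <- clean_spec(rod_topology = list(gamma_max = 0.7, scale_sup_deg = 0.05),
                   mp = list(peak = 0), seed = 17)
  ph <- generate_movie(sp)
  init <- initialize_fit(ph$movie)
  fit <- fit_image(ph$movie, init)
  rel <- abs(fit$c_hat - ph$truth$gamma_map) / ph$truth$gamma_map
  expect_lt(median(rel, na.rm = TRUE), 0.005)
  expect_lt(median(abs(fit$a_hat - ph$truth$alpha_map) /
                     ph$truth$alpha_map, na.rm = TRUE), 0.005)
  # constant frames give c ~ 0
  geo <- movie_geometry(10, c(12.5, 12.5), 2.4)
  const <- af_movie(array(80, dim = c(24, 24, 10)), seq(0, 9), geometry = geo)
  cinit <- list(p0_field = matrix(log(70), 24, 24), b0 = 0.3, c0 = 0.2)
  cfit <- fit_image(const, cinit, fit_config())
  expect_lt(max(abs(cfit$c_hat)), 1e-5)
  # determinism: identical runs are bit-identical
  fit2 <- fit_image(ph$movie, init)
  expect_identical(fit$c_hat, fit2$c_hat)
  expect_identical(fit$n_iters, fit2$n_iters)
  # scale equivariance: movie * s scales a_hat by s, leaves b, c unchanged
  s <- 2.5
  mov_s <- af_movie(ph$movie$frames * s, ph$movie$times,
                    geometry = ph$movie$geometry)
  init_s <- init
  init_s$p0_field <- init$p0_field + log(s)
  fit_s <- fit_image(mov_s, init_s)
  expect_equal(fit_s$a_hat, fit$a_hat * s, tolerance = 1e-6)
  expect_equal(fit_s$c_hat, fit$c_hat, tolerance = 1e-6)
})

test_that("vectorized image fit agrees with the scalar pixel fit", {
  sp <- clean_spec(shape = c(24, 24), fov_deg = 8, seed = 23)
  ph <- generate_movie(sp)
  init <- initialize_fit(ph$movie, annulus_deg = c(2, 3.5))
  cfg <- fit_config(block_size = 1L)
  fit <- fit_image(ph$movie, init, cfg)
  for (ij in list(c(3, 20), c(12, 12), c(20, 5))) {
    px <- fit_pixel(ph$movie$frames[ij[1], ij[2], ], ph$movie$times,
                    c(init$p0_field[ij[1], ij[2]], init$b0, init$c0), cfg)
    expect_lt(abs(fit$c_hat[ij[1], ij[2]] - px$c_hat), 1e-12)
    expect_equal(fit$n_iters[ij[1], ij[2]], px$n_iters)
  }
})

test_that("noisy-phantom gamma field correlates with the truth at r > 0.95", {
  sp <- small_spec(vessels = list(n_trunks = 0), seed = 29)  # 2% noise
  ph <- generate_movie(sp)
  init <- initialize_fit(block_average(ph$movie, 8),
                         mp_map = ph$truth$d_mp_map,
                         coeffs = default_optical_coeffs(),
                         band = spectral_band(488, 620))
  fit <- fit_image(ph$movie, init)
  sel <- is.finite(fit$c_hat)
  expect_gt(cor(fit$c_hat[sel], ph$truth$gamma_map[sel]), 0.95)
})
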