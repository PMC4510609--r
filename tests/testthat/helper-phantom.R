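# small phantoms shared across tests: quick to simulate, same structure as
# the full-scale defaults

small_spec <- function(..., shape = c(64, 64), fov_deg = 20, frame_rate = 4,
                       duration = 20, seed = 3L) {
  phantom_spec(shape = shape, fov_deg = fov_deg, frame_rate = frame_rate,
               duration = duration, seed = seed, ...)
}

clean_spec <- function(..., seed = 7L) {
  small_spec(vessels = list(n_trunks = 0), noise = list(sigma_frac = 0),
             seed = seed, ...)
}

mp_bands4 <- function() {
  list(spectral_band(460, 620), spectral_band(488, 640),
       spectral_band(520, 660), spectral_band(550, 680))
}

# brute-force minimizer of the fixed-b energy over a (p, c) grid
grid_search_energy <- function(f, times, b, p_range, c_range, n = 200L) {
  w <- rhodomap:::.quad_weights(times)
  logf <- log(f)
  eb <- exp(-b * times)
  ps <- seq(p_range[1], p_range[2], length.out = n)
  cs <- seq(c_range[1], c_range[2], length.out = n)
  # E(p,c) expands into moments, quadratic in (p, c)
  S0 <- sum(w); S1 <- sum(w * eb); S2 <- sum(w * eb^2)
  F0 <- sum(w * logf); F1 <- sum(w * logf * eb); FF <- sum(w * logf^2)
  E <- outer(ps, cs, function(p, c)
    FF + p^2 * S0 + c^2 * S2 - 2 * p * F0 + 2 * c * F1 - 2 * p * c * S1)
  ij <- which(E == min(E), arr.ind = TRUE)[1, ]
  list(p = ps[ij[1]], c = cs[ij[2]], dp = diff(p_range) / (n - 1),
       dc = diff(c_range) / (n - 1), E = min(E))
}
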