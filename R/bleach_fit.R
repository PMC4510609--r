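#' Configuration of the per-pixel variational fit
#'
#' Controls the semi-explicit gradient descent that minimizes the
#' mean-square-log energy of each pixel's brightening curve. `tau_p`,
#' `tau_b`, `tau_c` are the artificial-time step widths of the three
#' parameter updates; the `p` and `c` updates are implicit (closed form) and
#' tolerate large steps, while the explicit `b` update needs the smallest
#' step. With `fix_b = TRUE` (the default) the rate `b` is held at its
#' initial value, which is estimated once per image: the bleaching rate is
#' the ratio of retinal illuminance to the rhodopsin photosensitivity
#' constant and is therefore spatially invariant.
#'
#' @param tau_p,tau_b,tau_c Positive step widths. Defaults 0.1, 0.01, 0.1.
#' @param max_iters Maximum iterations per pixel (default 5000).
#' @param tol Convergence threshold on the maximum parameter change
#'   (default 1e-7).
#' @param fix_b Hold `b` fixed at its initial value (default `TRUE`).
#' @param block_size Side of the sliding spatial averaging window applied
#'   before fitting (default 8).
#' @param t_start Start of the fitting window `T0` in seconds (default 0);
#'   samples earlier than `t_start` are ignored.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(tau_p = 0.1, tau_b = 0.01, tau_c = 0.1,
                       max_iters = 5000L, tol = 1e-7, fix_b = TRUE,
                       block_size = 8L, t_start = 0) {
  stopifnot(tau_p > 0, tau_b > 0, tau_c > 0, max_iters >= 1, tol > 0,
            is.logical(fix_b), block_size >= 1)
  structure(list(tau_p = tau_p, tau_b = tau_b, tau_c = tau_c,
                 max_iters = as.integer(max_iters), tol = tol,
                 fix_b = fix_b, block_size = as.integer(block_size),
                 t_start = t_start),
            class = "fit_config")
}

# left-Riemann quadrature weights on the timestamp grid (uniform dt for a
# constant frame rate; the final sample reuses the last interval)
.quad_weights <- function(times) {
  if (length(times) < 2L) stop("need at least 2 time points")
  dt <- diff(times)
  c(dt, dt[length(dt)])
}

# restrict a curve to the fitting window t >= t_start
.fit_window <- function(times, t_start) which(times >= t_start)

#' Mean-square-log fitting energy
#'
#' Discrete quadrature of the log-domain misfit
#' \deqn{E(p, b, c) = \sum_i |\ln f(t_i) - p + c\, e^{-b t_i}|^2 \,\Delta t_i}
#' between a measured brightening curve `f` and the forward model
#' `exp(p - c exp(-b t))`, with `p = ln(a)`. Quadrature weights come from the
#' timestamp grid (left-Riemann).
#'
#' @param f Positive samples of the curve at `times`.
#' @param times Strictly increasing timestamps, seconds.
#' @param p,b,c Model parameters (`p = ln a`).
#' @param t0 Start of the integration window (default 0).
#' @return Nonnegative scalar energy.
#' @export
bleach_energy <- function(f, times, p, b, c, t0 = 0) {
  sel <- .fit_window(times, t0)
  f <- f[sel]; times <- times[sel]
  if (any(!is.finite(f)) || any(f <= 0))
    stop("curve has nonpositive samples; pixel must be masked")
  w <- .quad_weights(times)
  r <- log(f) - p + c * exp(-b * times)
  sum(w * r^2)
}

#' One sweep of the semi-explicit parameter update
#'
#' Applies the three closed-form updates of the semi-explicit scheme: the
#' implicit `p` update, the explicit `b` update (skipped when
#' `config$fix_b`), and the implicit `c` update. Within one sweep the `b` and
#' `c` updates use the *current* `p_n`, `b_n` on their right-hand sides,
#' exactly as the scheme is defined; integrals are replaced by weighted sums
#' over the sampled time points.
#'
#' @param p,b,c Current parameter values.
#' @param f Positive curve samples.
#' @param times Timestamps, seconds.
#' @param config A [fit_config()].
#' @return Named numeric vector `c(p, b, c)` of updated values.
#' @export
update_step <- function(p, b, c, f, times, config = fit_config()) {
  sel <- .fit_window(times, config$t_start)
  f <- f[sel]; times <- times[sel]
  if (any(!is.finite(f)) || any(f <= 0))
    stop("curve has nonpositive samples; pixel must be masked")
  w <- .quad_weights(times)
  logf <- log(f)
  eb <- exp(-b * times)
  if (any(!is.finite(eb)))
    stop("overflow in exp(-b t): b-update diverged")
  W <- sum(w)
  F_ <- sum(w * logf)
  Eb <- sum(w * eb)
  E2b <- sum(w * eb^2)
  Fb <- sum(w * logf * eb)
  p_new <- (p + 2 * config$tau_p * (F_ + c * Eb)) / (1 + 2 * config$tau_p * W)
  b_new <- if (config$fix_b) b else
    b + 2 * config$tau_b * c * sum(w * (logf - p + c * eb) * times * eb)
  c_new <- (c - 2 * config$tau_c * (Fb - p * Eb)) / (1 + 2 * config$tau_c * E2b)
  c(p = p_new, b = b_new, c = c_new)
}

#' Fit the brightening model to one pixel curve
#'
#' Iterates [update_step()] from the initial values until the maximum
#' parameter change falls below `config$tol` or `config$max_iters` is
#' reached. For fixed `b > 0` the energy has a positive-definite Hessian, so
#' the unique critical point reached is the global minimizer. When `b` is
#' free (3-parameter mode, used during initialization), a nonpositive or
#' non-finite `b` step is rejected and retried with a locally halved `tau_b`,
#' since the explicit update's stability bound depends on `b` itself.
#'
#' @param f Positive curve samples.
#' @param times Timestamps, seconds.
#' @param init Numeric vector `c(p0, b0, c0)`.
#' @param config A [fit_config()].
#' @return List with `a_hat`, `b_hat`, `c_hat`, `p_hat`, `n_iters`,
#'   `converged`, `energy`.
#' @export
fit_pixel <- function(f, times, init, config = fit_config()) {
  stopifnot(length(init) == 3L, all(is.finite(init)))
  sel <- .fit_window(times, config$t_start)
  fs <- f[sel]; ts <- times[sel]
  if (any(!is.finite(fs)) || any(fs <= 0))
    stop("curve has nonpositive samples; pixel must be masked")
  w <- .quad_weights(ts)
  logf <- log(fs)
  W <- sum(w)
  F_ <- sum(w * logf)
  p <- init[1]; b <- init[2]; c <- init[3]
  tau_b <- config$tau_b
  eb <- exp(-b * ts)
  Eb <- sum(w * eb); E2b <- sum(w * eb^2); Fb <- sum(w * logf * eb)
  converged <- FALSE
  n <- 0L
  while (n < config$max_iters) {
    n <- n + 1L
    p_new <- (p + 2 * config$tau_p * (F_ + c * Eb)) / (1 + 2 * config$tau_p * W)
    if (config$fix_b) {
      b_new <- b
    } else {
      repeat {
        b_new <- b + 2 * tau_b * c * sum(w * (logf - p + c * eb) * ts * eb)
        if (is.finite(b_new) && b_new > 0) break
        tau_b <- tau_b / 2
        if (tau_b < 1e-300) stop("b-update diverged")
      }
    }
    c_new <- (c - 2 * config$tau_c * (Fb - p * Eb)) / (1 + 2 * config$tau_c * E2b)
    delta <- max(abs(p_new - p), abs(b_new - b), abs(c_new - c))
    p <- p_new; c <- c_new
    if (!config$fix_b && b_new != b) {
      b <- b_new
      eb <- exp(-b * ts)
      Eb <- sum(w * eb); E2b <- sum(w * eb^2); Fb <- sum(w * logf * eb)
    }
    if (delta < config$tol) { converged <- TRUE; break }
  }
  list(a_hat = exp(p), b_hat = b, c_hat = c, p_hat = p,
       n_iters = n, converged = converged,
       energy = sum(w * (logf - p + c * eb)^2))
}

# sliding k x k box mean of a matrix, borders by symmetric reflection
.box_mean <- function(mat, k) {
  if (k == 1L) return(mat)
  H <- nrow(mat); W <- ncol(mat)
  if (k > min(H, W)) stop("averaging window larger than the image")
  lo <- floor((k - 1) / 2); hi <- k - 1 - lo
  ridx <- c(rev(seq_len(lo)), seq_len(H), H + 1 - seq_len(hi))
  cidx <- c(rev(seq_len(lo)), seq_len(W), W + 1 - seq_len(hi))
  pad <- mat[ridx, cidx, drop = FALSE]
  # 2-D integral image with a zero first row/column
  S <- matrix(0, nrow(pad) + 1, ncol(pad) + 1)
  S[-1, -1] <- apply(apply(pad, 2, cumsum), 1, cumsum) |> t()
  r1 <- seq_len(H); c1 <- seq_len(W)
  (S[r1 + k, c1 + k] - S[r1, c1 + k] - S[r1 + k, c1] + S[r1, c1]) / (k * k)
}

#' Spatial sliding-window averaging of a movie
#'
#' Averages every pixel of every frame over its surrounding `k x k`
#' neighborhood (sliding window, same output shape, borders by reflection).
#' This is the noise-suppression step applied before per-pixel fitting; it
#' also damps residual registration jitter.
#'
#' @param movie An [af_movie()].
#' @param k Window side in pixels (default 8).
#' @return An [af_movie()] of the same shape.
#' @export
block_average <- function(movie, k = 8L) {
  stopifnot(inherits(movie, "af_movie"))
  k <- as.integer(k)
  out <- movie$frames
  for (i in seq_len(dim(out)[3]))
    out[, , i] <- .box_mean(movie$frames[, , i], k)
  af_movie(out, movie$times, movie$t0, movie$geometry)
}

#' Closed-form Hessian of the energy in (p, c)
#'
#' For fixed `b` the mean-square-log energy is quadratic in `(p, c)` with
#' constant Hessian
#' \deqn{\partial_p^2 E = 2\sum \Delta t, \quad
#'   \partial_c^2 E = 2\sum e^{-2 b t}\Delta t, \quad
#'   \partial_p\partial_c E = -2\sum e^{-b t}\Delta t.}
#' By Cauchy-Schwarz its determinant is nonnegative and vanishes only when
#' `b = 0` (when `exp(-bt)` and 1 become linearly dependent), so for any
#' `b > 0` the energy is strictly convex and has a unique global minimizer.
#'
#' @param b Nonnegative rate.
#' @param times Timestamps, seconds.
#' @param t0 Start of the fitting window (default 0).
#' @return A symmetric 2x2 matrix, rows/cols ordered `(p, c)`.
#' @export
energy_hessian <- function(b, times, t0 = 0) {
  stopifnot(b >= 0)
  sel <- .fit_window(times, t0)
  times <- times[sel]
  w <- .quad_weights(times)
  eb <- exp(-b * times)
  matrix(c(2 * sum(w), -2 * sum(w * eb),
           -2 * sum(w * eb), 2 * sum(w * eb^2)), 2, 2)
}

#' Initial values from a spatially averaged bleaching curve
#'
#' Produces the initial values used by the per-pixel fit: (i) the movie is
#' averaged over a perifoveal annulus (default 5-8 degrees, away from the
#' fovea, major vessels and optic disc) and a full 3-parameter fit of that
#' single low-noise curve gives order-of-magnitude values `(p0, b0, c0)`;
#' (ii) 3-parameter fits on a deterministic subsample of annulus pixels are
#' histogrammed (Freedman-Diaconis bins) and `b0` is set to the mode — the
#' tight concentration of recovered `b` values is what justifies holding `b`
#' spatially constant; (iii) if a macular pigment map is supplied, `p0` is
#' spatially modulated as `p0(x,y) = p0 - D_MP(x,y) (k_MP(Lambda) +
#' k_MP(lambda))`, which places the amplitude initialization on the right
#' footing inside the fovea and speeds convergence there.
#'
#' @param movie An [af_movie()] (typically already block-averaged).
#' @param config A [fit_config()].
#' @param mp_map Optional [mp_density()] result (or a plain matrix of
#'   `D_MP(460)` values).
#' @param coeffs,band Required with `mp_map`: an [optical_coeffs()] and the
#'   movie's [spectral_band()], to convert `D_MP(460)` into the band's
#'   double-path attenuation.
#' @param annulus_deg Inner/outer annulus radii in degrees (default `c(5, 8)`).
#' @param n_subsample Target number of subsampled annulus pixels for the `b`
#'   histogram (default 256; subsampling is a deterministic stride).
#' @return List with `p0_field` (matrix), `b0`, `c0`, `b_histogram`
#'   (a `hist` object), `b_values`, `annulus_fit`, `annulus_curve`.
#' @export
initialize_fit <- function(movie, config = fit_config(), mp_map = NULL,
                           coeffs = NULL, band = NULL,
                           annulus_deg = c(5, 8), n_subsample = 256L) {
  stopifnot(inherits(movie, "af_movie"), length(annulus_deg) == 2L,
            annulus_deg[1] < annulus_deg[2])
  shp <- dim(movie$frames)[1:2]
  m <- dim(movie$frames)[3]
  r <- .radius_deg(shp, movie$geometry)
  sel <- r >= annulus_deg[1] & r <= annulus_deg[2]
  if (!any(sel)) stop("annulus contains no pixels")
  fm <- matrix(movie$frames, prod(shp), m)
  curve <- colMeans(fm[sel, , drop = FALSE])
  if (any(curve <= 0)) stop("annulus-averaged curve has nonpositive samples")
  # crude seeds from the shape of the averaged curve
  logc <- log(curve)
  ntail <- max(3L, m %/% 10L)
  p_seed <- mean(logc[(m - ntail + 1L):m])
  rise <- p_seed - mean(logc[1:min(3L, m)])
  c_seed <- max(rise, 1e-3)
  half <- which(logc - logc[1] >= rise / 2)
  b_seed <- if (rise > 0 && length(half) > 0 && movie$times[half[1]] > 0)
    log(2) / movie$times[half[1]] else 4 / max(movie$times)
  cfg3 <- config; cfg3$fix_b <- FALSE
  ann_fit <- fit_pixel(curve, movie$times, c(p_seed, b_seed, c_seed), cfg3)
  # subsampled per-pixel 3-parameter fits for the b histogram
  idx <- which(sel)
  stride <- max(1L, length(idx) %/% as.integer(n_subsample))
  idx <- idx[seq(1L, length(idx), by = stride)]
  cfg3s <- cfg3; cfg3s$max_iters <- min(cfg3$max_iters, 2000L)
  b_vals <- rep(NA_real_, length(idx))
  for (i in seq_along(idx)) {
    fi <- fm[idx[i], ]
    if (any(fi <= 0)) next
    ft <- tryCatch(
      fit_pixel(fi, movie$times,
                c(ann_fit$p_hat, ann_fit$b_hat, ann_fit$c_hat), cfg3s),
      error = function(e) NULL)
    if (!is.null(ft) && ft$converged && ft$b_hat > 0) b_vals[i] <- ft$b_hat
  }
  b_vals <- b_vals[is.finite(b_vals)]
  if (length(b_vals) == 0L) {
    b0 <- ann_fit$b_hat
    b_hist <- NULL
  } else if (diff(range(b_vals)) == 0) {
    b0 <- b_vals[1]
    b_hist <- graphics::hist(b_vals, breaks = 1L, plot = FALSE)
  } else {
    b_hist <- graphics::hist(b_vals, breaks = "FD", plot = FALSE)
    b0 <- b_hist$mids[which.max(b_hist$counts)]
  }
  # spatial modulation of p0 by macular pigment
  p0 <- matrix(ann_fit$p_hat, shp[1], shp[2])
  if (!is.null(mp_map)) {
    if (is.null(coeffs) || is.null(band))
      stop("coeffs and band are required when mp_map is given")
    d <- if (inherits(mp_map, "mp_density_map")) mp_map$d_mp else mp_map
    if (!identical(dim(d), shp)) stop("mp_map shape does not match the movie")
    ksum <- extinction(coeffs, band$excitation_nm, "mp") +
      extinction(coeffs, band$emission_nm, "mp")
    mod <- d * ksum
    mod[!is.finite(mod)] <- 0
    p0 <- p0 - mod
  }
  list(p0_field = p0, b0 = b0, c0 = ann_fit$c_hat,
       b_histogram = b_hist, b_values = b_vals,
       annulus_fit = ann_fit, annulus_curve = curve, annulus = sel)
}

#' Fit the brightening model at every pixel
#'
#' Block-averages the movie (unless `averaged = TRUE`), then runs the
#' semi-explicit descent at every pixel with `b` fixed at `init$b0`,
#' recording per-pixel iteration counts and convergence flags. The fixed-`b`
#' iteration is fully vectorized across pixels and is arithmetically
#' identical to [fit_pixel()]. Pixels with any nonpositive sample after
#' averaging are masked (`NA` estimates, `converged = FALSE`) and are natural
#' vessel-occlusion candidates. The `c_hat` field is the (preliminary)
#' rhodopsin optical density map.
#'
#' @param movie An [af_movie()].
#' @param init Initialization as returned by [initialize_fit()] (or a list
#'   with `p0_field`, `b0`, `c0`).
#' @param config A [fit_config()].
#' @param averaged Set `TRUE` if `movie` is already block-averaged.
#' @return An object of class `fit_result` with matrix fields `a_hat`,
#'   `b_hat`, `c_hat`, `p_hat`, `n_iters`, `converged`, `masked`, plus
#'   `times`, `config` and the block-averaged movie in `movie_avg`.
#' @export
fit_image <- function(movie, init, config = fit_config(), averaged = FALSE) {
  stopifnot(inherits(movie, "af_movie"))
  avg <- if (averaged || config$block_size == 1L) movie
         else block_average(movie, config$block_size)
  shp <- dim(avg$frames)[1:2]
  m <- dim(avg$frames)[3]
  sel_t <- .fit_window(avg$times, config$t_start)
  ts <- avg$times[sel_t]
  w <- .quad_weights(ts)
  fm <- matrix(avg$frames, prod(shp), m)[, sel_t, drop = FALSE]
  npix <- nrow(fm)
  masked <- apply(fm <= 0, 1, any)
  logf <- matrix(NA_real_, npix, length(sel_t))
  logf[!masked, ] <- log(fm[!masked, , drop = FALSE])

  p0 <- init$p0_field
  if (is.null(dim(p0))) p0 <- matrix(p0, shp[1], shp[2])
  stopifnot(identical(dim(p0), shp))
  b0 <- init$b0; c0 <- init$c0
  if (!config$fix_b)
    stop("fit_image supports the fixed-b production mode; use fit_pixel for 3-parameter fits")
  if (!is.finite(b0) || b0 <= 0) stop("b0 must be positive")

  eb <- exp(-b0 * ts)
  W <- sum(w); Eb <- sum(w * eb); E2b <- sum(w * eb^2)
  F_ <- as.numeric(logf %*% w)
  Fb <- as.numeric(logf %*% (w * eb))

  p <- as.numeric(p0)
  cc <- rep(c0, npix)
  niter <- rep(config$max_iters, npix)
  conv <- rep(FALSE, npix)
  active <- !masked
  tp2 <- 2 * config$tau_p; tc2 <- 2 * config$tau_c
  for (n in seq_len(config$max_iters)) {
    ia <- which(active)
    if (length(ia) == 0L) break
    pa <- p[ia]; ca <- cc[ia]
    p_new <- (pa + tp2 * (F_[ia] + ca * Eb)) / (1 + tp2 * W)
    c_new <- (ca - tc2 * (Fb[ia] - pa * Eb)) / (1 + tc2 * E2b)
    delta <- pmax(abs(p_new - pa), abs(c_new - ca))
    p[ia] <- p_new; cc[ia] <- c_new
    done <- delta < config$tol
    if (any(done)) {
      idone <- ia[done]
      niter[idone] <- n
      conv[idone] <- TRUE
      active[idone] <- FALSE
    }
  }
  p[masked] <- NA_real_; cc[masked] <- NA_real_
  res <- list(
    a_hat = matrix(exp(p), shp[1], shp[2]),
    b_hat = matrix(b0, shp[1], shp[2]),
    c_hat = matrix(cc, shp[1], shp[2]),
    p_hat = matrix(p, shp[1], shp[2]),
    n_iters = matrix(niter, shp[1], shp[2]),
    converged = matrix(conv, shp[1], shp[2]),
    masked = matrix(masked, shp[1], shp[2]),
    b0 = b0, times = avg$times, config = config, movie_avg = avg)
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %d x %d pixels, b0 = %.4g/s, %.1f%% converged, median N = %d\n",
              nrow(x$c_hat), ncol(x$c_hat), x$b0,
              100 * mean(x$converged), stats::median(x$n_iters)))
  invisible(x)
}
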