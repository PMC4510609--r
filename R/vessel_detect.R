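#' L1 model-residual map
#'
#' Per-pixel total L1 deviation between the measured curves and the fitted
#' double-exponential model,
#' \deqn{\Delta AF(x,y) = \sum_i |f(x,y,t_i) -
#'   \hat a\, e^{-\hat c e^{-\hat b t_i}}|.}
#' Vessel pixels, whose signal is largely dark noise that does not follow the
#' bleaching model, stand out with large residuals. Masked pixels yield `NA`.
#'
#' @param movie The (block-averaged) [af_movie()] the fit was run on; if
#'   omitted, the movie stored in `fit` is used.
#' @param fit A `fit_result` from [fit_image()].
#' @return Matrix of nonnegative residuals (`NA` at masked pixels).
#' @export
residual_map <- function(movie = NULL, fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (is.null(movie)) movie <- fit$movie_avg
  shp <- dim(fit$c_hat)
  if (!identical(dim(movie$frames)[1:2], shp))
    stop("movie and fit shapes differ")
  sel_t <- .fit_window(movie$times, fit$config$t_start)
  ts <- movie$times[sel_t]
  fm <- matrix(movie$frames, prod(shp), dim(movie$frames)[3])[, sel_t, drop = FALSE]
  a <- as.numeric(fit$a_hat); cc <- as.numeric(fit$c_hat); b <- fit$b0
  res <- rep(NA_real_, nrow(fm))
  ok <- is.finite(a) & is.finite(cc)
  eb <- exp(-b * ts)
  pred <- a[ok] * exp(-outer(cc[ok], eb))
  res[ok] <- rowSums(abs(fm[ok, , drop = FALSE] - pred))
  matrix(res, shp[1], shp[2])
}

#' Vessel candidates from the fitter's convergence map
#'
#' The iteration-count image `N(x, y)` carries edge information: the descent
#' converges markedly slower where the data contradict the model and the
#' initialization (vessels, fovea rim, registration artifacts). Pixels above
#' a configured percentile of `N`, plus all non-converged or masked pixels,
#' become vessel candidates.
#'
#' @param n_iters Integer matrix of per-pixel iteration counts.
#' @param converged Optional logical matrix; non-converged pixels are always
#'   included.
#' @param percentile Threshold percentile of `N` (default 95).
#' @return Logical candidate matrix.
#' @export
detect_from_iterations <- function(n_iters, converged = NULL, percentile = 95) {
  stopifnot(is.matrix(n_iters), percentile > 0, percentile < 100)
  if (diff(range(n_iters)) == 0) {
    warning("iteration-count field is constant; no vessels detected")
    mask <- matrix(FALSE, nrow(n_iters), ncol(n_iters))
  } else {
    thr <- stats::quantile(n_iters, percentile / 100, names = FALSE)
    mask <- n_iters > thr
  }
  if (!is.null(converged)) mask <- mask | !converged
  mask
}

#' Vessel candidates from the L1 residual map
#'
#' Marks pixels whose model residual falls within a percentile band
#' (rank-based, hence invariant to global intensity scaling).
#'
#' @param delta_af Residual matrix from [residual_map()].
#' @param lower_pct,upper_pct Percentile band, `0 <= lower < upper <= 100`
#'   (defaults 95 and 100).
#' @return Logical candidate matrix (`NA` residuals are not marked here;
#'   masked pixels are picked up by [detect_from_iterations()]).
#' @export
detect_from_residual <- function(delta_af, lower_pct = 95, upper_pct = 100) {
  stopifnot(is.matrix(delta_af))
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100))
    stop("need 0 <= lower_pct < upper_pct <= 100")
  q <- stats::quantile(delta_af, c(lower_pct, upper_pct) / 100,
                       na.rm = TRUE, names = FALSE)
  mask <- delta_af >= q[1] & delta_af <= q[2]
  mask[is.na(mask)] <- FALSE
  mask
}

#' Final vessel occlusion set and smooth mask
#'
#' Unions the candidate masks, dilates the union by `dilation_px` (a
#' morphological disc; simple thresholding alone under-covers vessel borders
#' blurred by eye movement and registration), and builds the smooth relaxed
#' mask `chi` as a clipped linear ramp of the Euclidean distance to the
#' occlusion set: `chi = 0` inside the set, rising to exactly 1 at distance
#' `transition_px` and beyond. `chi` down-weights the inpainting fidelity
#' term near the uncertain vessel borders.
#'
#' @param candidates A logical matrix or list of logical matrices.
#' @param dilation_px Dilation radius in pixels (default 2; 0 disables).
#' @param transition_px Ramp width in pixels (default 3).
#' @return An object of class `vessel_mask` with `omega` (logical matrix),
#'   `chi` (numeric in \[0,1\]) and `provenance`.
#' @export
finalize_mask <- function(candidates, dilation_px = 2L, transition_px = 3) {
  if (is.matrix(candidates)) candidates <- list(candidates)
  stopifnot(length(candidates) >= 1L, transition_px > 0, dilation_px >= 0)
  shp <- dim(candidates[[1]])
  omega <- matrix(FALSE, shp[1], shp[2])
  for (cm in candidates) {
    if (!identical(dim(cm), shp)) stop("candidate masks differ in shape")
    omega <- omega | cm
  }
  if (any(omega) && dilation_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilation_px) + 1L, "disc")
    omega <- EBImage::dilate(omega * 1, brush) > 0.5
  }
  if (mean(omega) > 0.5)
    stop("occlusion set covers more than half the image; detector misconfigured")
  chi <- .smooth_chi(omega, transition_px)
  structure(list(omega = omega, chi = chi,
                 provenance = list(n_candidates = length(candidates),
                                   dilation_px = dilation_px,
                                   transition_px = transition_px)),
            class = "vessel_mask")
}

# clipped-linear smooth relaxation of an occlusion indicator
.smooth_chi <- function(omega, transition_px) {
  if (!any(omega)) return(matrix(1, nrow(omega), ncol(omega)))
  d <- as.matrix(EBImage::distmap(1 - omega))
  chi <- d / transition_px
  chi[chi > 1] <- 1
  chi[omega] <- 0
  chi
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("vessel_mask: %d x %d, %.2f%% occluded\n",
              nrow(x$omega), ncol(x$omega), 100 * mean(x$omega)))
  invisible(x)
}
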