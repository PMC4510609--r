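#' Multi-spectral autofluorescence image set
#'
#' A set of `n >= 2` co-registered autofluorescence images, each tagged with
#' its excitation/emission band, together with zero-sum weights. The zero-sum
#' condition is what cancels the (band-dependent but space-invariant)
#' lipofuscin fluorescence-efficiency ratio in the macular pigment formula.
#'
#' @param images List of `n` nonnegative 2-D matrices, all the same shape.
#' @param bands List of `n` [spectral_band()] objects.
#' @param weights Numeric vector of length `n` summing to zero (to 1e-12).
#' @return An object of class `mp_image_set`.
#' @seealso [mp_density()]
#' @export
mp_image_set <- function(images, bands, weights) {
  n <- length(images)
  if (n < 2L) stop("at least 2 bands are required")
  if (length(bands) != n || length(weights) != n)
    stop("images, bands and weights must have equal length")
  if (!all(vapply(bands, inherits, logical(1), "spectral_band")))
    stop("bands must be spectral_band objects")
  shp <- dim(images[[1]])
  for (im in images) {
    if (!is.matrix(im) || !identical(dim(im), shp))
      stop("all images must be matrices of identical shape")
    if (any(!is.finite(im)) || any(im < 0))
      stop("image intensities must be finite and nonnegative")
  }
  if (abs(sum(weights)) > 1e-12)
    stop("weights must sum to zero (|sum| <= 1e-12)")
  structure(list(images = images, bands = bands, weights = as.numeric(weights)),
            class = "mp_image_set")
}

# sum_j w_j (k_MP(Lambda_j) + k_MP(lambda_j))
.mp_denominator <- function(bands, weights, coeffs) {
  ks <- vapply(bands, function(b)
    extinction(coeffs, b$excitation_nm, "mp") +
      extinction(coeffs, b$emission_nm, "mp"), numeric(1))
  sum(weights * ks)
}

#' Perifoveal reference intensity
#'
#' Mean intensity over an annulus centered on the fovea, the conventional
#' stand-in for the perifoveal autofluorescence `AF_p` (a circular average at
#' 6 degrees). The annulus spans radii
#' `[radius_deg - width_deg/2, radius_deg + width_deg/2]`.
#'
#' @param image 2-D intensity matrix.
#' @param center Fovea center `(row, col)`.
#' @param radius_deg Annulus central radius, degrees.
#' @param width_deg Annulus width, degrees.
#' @param geometry A [movie_geometry()] (only `px_per_deg` is used).
#' @return Scalar mean intensity over the annulus.
#' @export
perifoveal_reference <- function(image, center, radius_deg = 6, width_deg = 1,
                                 geometry) {
  stopifnot(is.matrix(image), inherits(geometry, "movie_geometry"),
            radius_deg > 0, width_deg > 0)
  geo <- movie_geometry(geometry$fov_deg, center, geometry$px_per_deg)
  r <- .radius_deg(dim(image), geo)
  outer_px <- (radius_deg + width_deg / 2) * geometry$px_per_deg
  if (center[1] - outer_px < 1 || center[1] + outer_px > nrow(image) ||
      center[2] - outer_px < 1 || center[2] + outer_px > ncol(image))
    stop("annulus exceeds image bounds")
  sel <- r >= radius_deg - width_deg / 2 & r <= radius_deg + width_deg / 2
  if (!any(sel)) stop("annulus contains no pixels")
  mean(image[sel])
}

#' Macular pigment optical density map
#'
#' Per-pixel macular pigment optical density at 460 nm from a multi-spectral
#' image set:
#' \deqn{D_{MP}(460) = \frac{\sum_j \omega_j \ln(AF_p^{(j)} / AF_f^{(j)})}
#'   {\sum_j \omega_j (k_{MP}(\Lambda_j) + k_{MP}(\lambda_j))}.}
#' The zero-sum weights cancel the band-dependent fluorescence-efficiency
#' ratio, so only extinction coefficients and the measured ratios enter.
#' Pixels with nonpositive intensity in any band are masked (`NA` in the map,
#' `FALSE` in `valid`), never clamped. Negative densities under noise are
#' retained.
#'
#' @param mpset An [mp_image_set()].
#' @param coeffs An [optical_coeffs()] object.
#' @param reference Numeric vector of per-band perifoveal reference values
#'   `AF_p` (positive), typically from [perifoveal_reference()].
#' @return An object of class `mp_density_map` with fields `d_mp` (matrix,
#'   `NA` at invalid pixels), `valid` (logical matrix), `reference`,
#'   `weights`, `denominator`.
#' @export
mp_density <- function(mpset, coeffs, reference) {
  stopifnot(inherits(mpset, "mp_image_set"), inherits(coeffs, "optical_coeffs"))
  n <- length(mpset$images)
  if (length(reference) != n || any(!is.finite(reference)) || any(reference <= 0))
    stop("reference must be one positive value per band")
  denom <- .mp_denominator(mpset$bands, mpset$weights, coeffs)
  if (abs(denom) < 1e-12)
    stop("weight/extinction denominator is zero; choose different weights")
  shp <- dim(mpset$images[[1]])
  valid <- matrix(TRUE, shp[1], shp[2])
  for (im in mpset$images) valid <- valid & im > 0
  num <- matrix(0, shp[1], shp[2])
  for (j in seq_len(n)) {
    lg <- matrix(NA_real_, shp[1], shp[2])
    lg[valid] <- log(reference[j] / mpset$images[[j]][valid])
    num <- num + mpset$weights[j] * lg
  }
  d <- num / denom
  d[!valid] <- NA_real_
  structure(list(d_mp = d, valid = valid, reference = reference,
                 weights = mpset$weights, denominator = denom),
            class = "mp_density_map")
}

#' @export
print.mp_density_map <- function(x, ...) {
  cat(sprintf("mp_density_map: %d x %d, D_MP range [%.3g, %.3g], %d masked pixels\n",
              nrow(x$d_mp), ncol(x$d_mp),
              min(x$d_mp, na.rm = TRUE), max(x$d_mp, na.rm = TRUE),
              sum(!x$valid)))
  invisible(x)
}

#' Self-consistency of macular pigment maps across weight choices
#'
#' Recomputes the density map for several zero-sum weight vectors and
#' summarizes their agreement: the per-pixel standard deviation across maps,
#' the per-pixel maximum pairwise absolute difference, a total spread per
#' weight set (sum of squared deviation from the cross-set mean map), and the
#' weight set minimizing that spread.
#'
#' @param mpset An [mp_image_set()] (its own weights are ignored).
#' @param weight_sets List of `>= 2` zero-sum weight vectors.
#' @param coeffs An [optical_coeffs()] object.
#' @param reference Per-band perifoveal reference values.
#' @return A list with `maps` (list of `mp_density_map`), `sd_map`,
#'   `max_abs_diff_map`, `total_spread` (per weight set), `best` (index of the
#'   minimizing set).
#' @export
mp_self_consistency <- function(mpset, weight_sets, coeffs, reference) {
  if (length(weight_sets) < 2L) stop("need at least 2 weight sets")
  maps <- lapply(weight_sets, function(w) {
    ms <- mp_image_set(mpset$images, mpset$bands, w)
    mp_density(ms, coeffs, reference)
  })
  stack <- simplify2array(lapply(maps, `[[`, "d_mp"))  # H x W x nsets
  mean_map <- apply(stack, c(1, 2), mean)
  sd_map <- apply(stack, c(1, 2), stats::sd)
  rng <- apply(stack, c(1, 2), function(v) diff(range(v)))
  spread <- vapply(seq_along(maps), function(i)
    sum((stack[, , i] - mean_map)^2, na.rm = TRUE), numeric(1))
  list(maps = maps, sd_map = sd_map, max_abs_diff_map = rng,
       total_spread = spread, best = which.min(spread))
}

#' Default zero-sum weight sets over a band list
#'
#' The classic two-wavelength pair `(1, -1)` over the first two bands plus
#' all distinct zero-sum patterns with entries in `{-1, 0, 1}` whose
#' weight/extinction denominator is nonzero, deduplicated up to scale.
#'
#' @param bands List of [spectral_band()] objects.
#' @param coeffs An [optical_coeffs()] object (to drop zero-denominator sets).
#' @return List of numeric weight vectors.
#' @export
default_weight_sets <- function(bands, coeffs) {
  n <- length(bands)
  grids <- rep(list(c(-1, 0, 1)), n)
  all_w <- as.matrix(expand.grid(grids))
  keep <- rowSums(all_w) == 0 & rowSums(abs(all_w)) > 0
  all_w <- all_w[keep, , drop = FALSE]
  # deduplicate sign flips
  first_nz_pos <- apply(all_w, 1, function(w) w[which(w != 0)[1]] > 0)
  all_w <- all_w[first_nz_pos, , drop = FALSE]
  sets <- lapply(seq_len(nrow(all_w)), function(i) as.numeric(all_w[i, ]))
  sets <- Filter(function(w)
    abs(.mp_denominator(bands, w, coeffs)) > 1e-9, sets)
  sets
}
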