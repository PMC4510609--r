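#' Run the five-step rhodopsin mapping pipeline
#'
#' Orchestrates the full procedure on a registered autofluorescence movie:
#' (1) macular pigment map from a multi-spectral image set, if one is given
#' (otherwise the amplitude initialization is spatially constant — a
#' documented fallback); (2) initial values from the annulus-averaged curve
#' and the `b` histogram; (3) preliminary rhodopsin map by the per-pixel
#' fixed-`b` fit on the block-averaged movie; (4) vessel detection from the
#' iteration-count and L1-residual maps; (5) wavelet Ginzburg-Landau
#' inpainting of the vessel occlusions. Every intermediate is returned (and
#' optionally persisted); the run is deterministic given its inputs.
#'
#' @param movie An [af_movie()].
#' @param mp_set Optional [mp_image_set()] for step 1.
#' @param mp_reference Optional per-band perifoveal reference values; when
#'   omitted they are computed with [perifoveal_reference()] at 6 degrees.
#' @param coeffs An [optical_coeffs()] table.
#' @param band The movie's [spectral_band()] (default 488/620 nm).
#' @param config A [fit_config()].
#' @param vessel List of detection options: `iter_pct`, `res_lower`,
#'   `res_upper`, `dilation_px`, `transition_px`.
#' @param wgl List of [wgl_config()] variants (default [wgl_variants()]).
#' @param annulus_deg Initialization annulus, degrees (default `c(5, 8)`).
#' @param out_dir Optional directory; intermediates are persisted there as
#'   normalized float TIFFs with YAML sidecars.
#' @param verbose Print stage progress (default `FALSE`).
#' @return An object of class `rhodopsin_map`: `gamma` (the final inpainted
#'   map, relative units), plus `mp_map`, `init`, `fit`, `delta_af`, `mask`,
#'   `inpaint`, `profiles` and provenance.
#' @export
run_pipeline <- function(movie, mp_set = NULL, mp_reference = NULL,
                         coeffs = default_optical_coeffs(),
                         band = spectral_band(488, 620),
                         config = fit_config(),
                         vessel = list(), wgl = wgl_variants(),
                         annulus_deg = c(5, 8),
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(movie, "af_movie"))
  # default dilation: half the averaging window — every pixel that close to
  # a vessel has contaminated (mixed) curves after the block average
  ves <- utils::modifyList(list(iter_pct = 95, res_lower = 95, res_upper = 100,
                                dilation_px = ceiling(config$block_size / 2),
                                transition_px = 3), vessel)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("step 1/5: macular pigment map")
  mp_map <- NULL
  if (!is.null(mp_set)) {
    mp_map <- stage("macular pigment", {
      ref <- mp_reference
      if (is.null(ref))
        ref <- vapply(mp_set$images, perifoveal_reference,
                      numeric(1), center = movie$geometry$center,
                      radius_deg = 6, width_deg = 1,
                      geometry = movie$geometry)
      mp_density(mp_set, coeffs, ref)
    })
  }

  say("step 2/5: initialization (block average + annulus fit + b histogram)")
  avg <- stage("block averaging", block_average(movie, config$block_size))
  init <- stage("initialization",
                initialize_fit(avg, config, mp_map = mp_map, coeffs = coeffs,
                               band = band, annulus_deg = annulus_deg))
  say("  b0 = %.4g /s", init$b0)

  say("step 3/5: preliminary rhodopsin map (fixed-b fit)")
  fit <- stage("fitting", fit_image(avg, init, config, averaged = TRUE))

  say("step 4/5: vessel detection")
  mask <- stage("vessel detection", {
    delta_af <- residual_map(avg, fit)
    cand_iter <- detect_from_iterations(fit$n_iters, fit$converged,
                                        ves$iter_pct)
    cand_res <- detect_from_residual(delta_af, ves$res_lower, ves$res_upper)
    msk <- finalize_mask(list(cand_iter, cand_res),
                         dilation_px = ves$dilation_px,
                         transition_px = ves$transition_px)
    attr(msk, "delta_af") <- delta_af
    msk
  })
  delta_af <- attr(mask, "delta_af")

  say("step 5/5: inpainting (%d variants)", length(wgl))
  inp <- stage("inpainting", inpaint_map(fit$c_hat, mask, wgl))

  profiles <- radial_profiles(inp$filled, movie$geometry$center,
                              stripe_width_px = 5L)
  res <- structure(list(gamma = inp$filled, mp_map = mp_map, init = init,
                        fit = fit, delta_af = delta_af, mask = mask,
                        inpaint = inp, profiles = profiles,
                        band = band, geometry = movie$geometry,
                        units = "relative"),
                   class = "rhodopsin_map")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_map_tiff(fit$c_hat, file.path(out_dir, "gamma_preliminary.tif"))
    write_map_tiff(fit$a_hat, file.path(out_dir, "a_hat.tif"))
    write_map_tiff(fit$n_iters + 0, file.path(out_dir, "n_iters.tif"))
    write_map_tiff(delta_af, file.path(out_dir, "delta_af.tif"))
    write_map_tiff(mask$omega + 0, file.path(out_dir, "vessel_omega.tif"))
    write_map_tiff(mask$chi, file.path(out_dir, "vessel_chi.tif"))
    write_map_tiff(inp$filled, file.path(out_dir, "gamma_inpainted.tif"))
    if (!is.null(mp_map))
      write_map_tiff(mp_map$d_mp, file.path(out_dir, "d_mp.tif"))
    utils::write.csv(profiles, file.path(out_dir, "profiles.csv"),
                     row.names = FALSE)
  }
  res
}

#' @export
print.rhodopsin_map <- function(x, ...) {
  cat(sprintf(paste0("rhodopsin_map: %d x %d, gamma in [%.3g, %.3g] ",
                     "(relative units), %.2f%% inpainted\n"),
              nrow(x$gamma), ncol(x$gamma), min(x$gamma), max(x$gamma),
              100 * mean(x$mask$omega)))
  invisible(x)
}

#' Horizontal and vertical profiles through the fovea
#'
#' Averages a map over a stripe of `stripe_width_px` rows (columns) centered
#' on the fovea row (column), yielding the horizontal and vertical profiles
#' plus the four half-profiles running outward from the center.
#'
#' @param map Numeric matrix.
#' @param center `(row, col)` of the fovea.
#' @param stripe_width_px Odd stripe width in pixels (default 5; 1 gives the
#'   raw center row/column).
#' @return A data frame with columns `offset_px` (signed offset from the
#'   center), `horizontal`, `vertical` (`NA` where the offset leaves the
#'   image). Half-profiles are the nonnegative/negative offset halves.
#' @export
radial_profiles <- function(map, center, stripe_width_px = 5L) {
  stopifnot(is.matrix(map), length(center) == 2L, stripe_width_px >= 1)
  hw <- (as.integer(stripe_width_px) - 1L) %/% 2L
  rc <- round(center[1]); cc <- round(center[2])
  rows <- (rc - hw):(rc + hw)
  cols <- (cc - hw):(cc + hw)
  if (any(rows < 1) || any(rows > nrow(map)) ||
      any(cols < 1) || any(cols > ncol(map)))
    stop("stripe exceeds the image")
  horiz <- colMeans(map[rows, , drop = FALSE])
  vert <- rowMeans(map[, cols, drop = FALSE])
  off <- seq(-max(rc, cc) + 1L,
             max(nrow(map) - rc, ncol(map) - cc))
  data.frame(
    offset_px = off,
    horizontal = horiz[match(off + cc, seq_len(ncol(map)))],
    vertical = vert[match(off + rc, seq_len(nrow(map)))])
}

# ---- persistence helpers (float TIFF + YAML sidecar with the scale) ----

#' Write a real-valued map as a normalized float TIFF
#'
#' TIFF float samples are stored in \[0, 1\]; the original range is recorded
#' in a YAML sidecar (`<path>.yml`) so [read_map_tiff()] restores the
#' original units (up to float32 rounding).
#'
#' @param map Numeric matrix (`NA` stored as the minimum and flagged in the
#'   sidecar).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path) {
  stopifnot(is.matrix(map))
  finite <- is.finite(map)
  lo <- min(map[finite]); hi <- max(map[finite])
  span <- if (hi > lo) hi - lo else 1
  norm <- (map - lo) / span
  norm[!finite] <- 0
  tiff::writeTIFF(norm, path, bits.per.sample = 32L)
  yaml::write_yaml(list(min = lo, max = hi, na_pixels = sum(!finite)),
                   paste0(path, ".yml"))
  invisible(path)
}

#' Read a map written by [write_map_tiff()]
#'
#' @param path TIFF path (expects the YAML sidecar next to it).
#' @return Numeric matrix in original units.
#' @export
read_map_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  norm <- tiff::readTIFF(path)
  meta$min + norm * (meta$max - meta$min)
}

#' Write an autofluorescence movie as a multi-page TIFF with a manifest
#'
#' @param movie An [af_movie()].
#' @param path Output TIFF path; a YAML manifest (`<path>.yml`) stores the
#'   timestamps, intensity scale and geometry.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "af_movie"))
  hi <- max(movie$frames)
  if (hi <= 0) hi <- 1
  pages <- lapply(seq_len(dim(movie$frames)[3]),
                  function(i) movie$frames[, , i] / hi)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(times = as.list(movie$times), t0 = movie$t0,
                        scale = hi,
                        geometry = list(fov_deg = movie$geometry$fov_deg,
                                        center = as.list(movie$geometry$center),
                                        px_per_deg = movie$geometry$px_per_deg)),
                   paste0(path, ".yml"))
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path Multi-page TIFF path (expects the YAML manifest sidecar).
#' @return An [af_movie()].
#' @export
read_movie_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]] * meta$scale
  geo <- movie_geometry(meta$geometry$fov_deg,
                        unlist(meta$geometry$center),
                        meta$geometry$px_per_deg)
  af_movie(frames, unlist(meta$times), meta$t0, geo)
}
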