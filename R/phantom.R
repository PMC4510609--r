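#' Specification of a synthetic retinal phantom
#'
#' Describes a simulated registered autofluorescence acquisition: geometry,
#' bleaching kinetics, rod-topology gamma field, foveal macular pigment
#' peak, a random vessel tree and sensor noise. Defaults reproduce the
#' standard acquisition: a 30-degree field recorded at 8 frames/s for 60 s
#' with a bleaching rate of 0.04 per frame (0.32 1/s on the seconds grid),
#' a perifoveal double-path rhodopsin optical density around 0.7 (the
#' roughly 50% attenuation of a dark-adapted retina), and additive Gaussian
#' noise at 2% of the fully-bleached amplitude, reflecting the low
#' signal-to-noise of cSLO measurements.
#'
#' The rod-topology field is
#' \deqn{\gamma(r, \theta) = \gamma_{max} (1 - e^{-r / s(\theta)}),}
#' zero at the fovea center, with a direction-dependent rise scale
#' `s(theta)` smallest on the superior vertical meridian (fastest rise) and
#' largest on the nasal horizontal meridian, with the inferior retina
#' between the two — the qualitative human rod topology.
#'
#' @param shape `(H, W)` in pixels (default `c(256, 256)`).
#' @param fov_deg Field of view, degrees (default 30).
#' @param center Fovea center `(row, col)`; defaults to the image center.
#' @param frame_rate Frames per second (default 8).
#' @param duration Movie length, seconds (default 60).
#' @param beta True bleaching rate, 1/s (default 0.32 = 0.04/frame at 8 fps).
#' @param alpha Fully-bleached base amplitude, intensity units (default 100).
#' @param rod_topology List: `gamma_max` (default 0.7), `scale_sup_deg`
#'   (rise scale on the superior meridian, default 6), `meridian_factor`
#'   (extra relative scale on the horizontal meridians, default 1) and
#'   `inferior_factor` (extra relative scale inferiorly, default 0.4).
#' @param mp List: `peak` macular pigment density at 460 nm (default 0.5)
#'   and Gaussian `sigma_deg` (default 1).
#' @param vessels List: `n_trunks` (default 3), `width_px` (default 5 — the
#'   major arcade vessels that actually occlude the autofluorescence span
#'   roughly 0.5-0.7 degrees, 5-8 px at the default sampling), `attenuation`
#'   residual intensity fraction inside vessels (default 0.05), `pulsation`
#'   relative amplitude of the coherent slow blood-flow modulation of the
#'   vessel signal (default 0.3) and `pulse_hz` its frequency (default 1.2,
#'   a cardiac rate); the modulation is what makes vessel pixels genuinely
#'   violate the monotone bleaching model rather than look like a constant.
#'   Set `n_trunks = 0` for a vessel-free phantom.
#' @param noise List: `sigma_frac`, Gaussian noise s.d. as a fraction of
#'   `alpha` (default 0.02).
#' @param seed Integer RNG seed; a fixed seed gives bit-reproducible output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(256, 256), fov_deg = 30, center = NULL,
                         frame_rate = 8, duration = 60,
                         beta = 0.32, alpha = 100,
                         rod_topology = list(), mp = list(), vessels = list(),
                         noise = list(), seed = 1L) {
  rod <- utils::modifyList(list(gamma_max = 0.7, scale_sup_deg = 6,
                                meridian_factor = 1, inferior_factor = 0.4),
                           rod_topology)
  mp <- utils::modifyList(list(peak = 0.5, sigma_deg = 1), mp)
  ves <- utils::modifyList(list(n_trunks = 3L, width_px = 5, attenuation = 0.05,
                                pulsation = 0.3, pulse_hz = 1.2),
                           vessels)
  noi <- utils::modifyList(list(sigma_frac = 0.02), noise)
  if (is.null(center)) center <- floor((shape + 1) / 2)  # an exact pixel
  stopifnot(length(shape) == 2L, all(shape >= 8), fov_deg > 0,
            frame_rate > 0, duration > 0, beta > 0, alpha > 0,
            rod$gamma_max >= 0, rod$scale_sup_deg > 0,
            mp$peak >= 0, mp$sigma_deg > 0,
            ves$n_trunks >= 0, ves$attenuation >= 0, noi$sigma_frac >= 0)
  structure(list(shape = as.integer(shape), fov_deg = fov_deg,
                 center = as.numeric(center), frame_rate = frame_rate,
                 duration = duration, beta = beta, alpha = alpha,
                 rod_topology = rod, mp = mp, vessels = ves, noise = noi,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# direction-dependent rise scale (degrees) of the rod topology
.rod_scale_deg <- function(theta, rod) {
  rod$scale_sup_deg * (1 + rod$meridian_factor * cos(theta)^2 +
                         rod$inferior_factor * (1 - sin(theta)) / 2)
}

# ground-truth fields of a phantom
.phantom_fields <- function(spec) {
  geo <- movie_geometry(spec$fov_deg, spec$center,
                        min(spec$shape) / spec$fov_deg)
  r <- .radius_deg(spec$shape, geo)
  th <- .theta(spec$shape, geo)
  gamma <- spec$rod_topology$gamma_max *
    (1 - exp(-r / .rod_scale_deg(th, spec$rod_topology)))
  d_mp <- spec$mp$peak * exp(-r^2 / (2 * spec$mp$sigma_deg^2))
  list(geometry = geo, radius_deg = r, gamma = gamma, d_mp = d_mp)
}

# stamp a disc of given radius onto a logical matrix
.stamp_disc <- function(mask, row, col, radius) {
  H <- nrow(mask); W <- ncol(mask)
  ir <- max(1, floor(row - radius)):min(H, ceiling(row + radius))
  ic <- max(1, floor(col - radius)):min(W, ceiling(col + radius))
  for (i in ir) for (j in ic)
    if ((i - row)^2 + (j - col)^2 <= radius^2) mask[i, j] <- TRUE
  mask
}

# random vessel tree: trunks entering from the left edge, meandering
# across the field, occasionally branching, width tapering outward
.vessel_tree <- function(shape, n_trunks, width_px) {
  mask <- matrix(FALSE, shape[1], shape[2])
  if (n_trunks < 1) return(mask)
  queue <- list()
  for (k in seq_len(n_trunks)) {
    queue[[length(queue) + 1L]] <- list(
      row = stats::runif(1, 0.15, 0.85) * shape[1], col = 1,
      angle = stats::runif(1, -pi / 5, pi / 5),
      width = width_px, steps = round(1.1 * shape[2]))
  }
  while (length(queue) > 0L) {
    seg <- queue[[1L]]; queue[[1L]] <- NULL
    row <- seg$row; col <- seg$col; ang <- seg$angle
    for (s in seq_len(seg$steps)) {
      ang <- ang + stats::rnorm(1, 0, 0.08)
      ang <- max(min(ang, pi / 2.2), -pi / 2.2)
      row <- row + sin(ang); col <- col + cos(ang)
      if (row < 1 || row > shape[1] || col < 1 || col > shape[2]) break
      w <- seg$width * (1 - 0.5 * s / seg$steps)
      mask <- .stamp_disc(mask, row, col, max(w / 2, 0.5))
      if (seg$width > 1 && stats::runif(1) < 0.006 && length(queue) < 32) {
        queue[[length(queue) + 1L]] <- list(
          row = row, col = col,
          angle = ang + sample(c(-1, 1), 1) * stats::runif(1, pi / 6, pi / 3),
          width = seg$width - 1, steps = round(seg$steps / 2))
      }
    }
  }
  mask
}

#' Generate a synthetic autofluorescence movie with ground truth
#'
#' Builds the per-pixel forward model: the amplitude is the base level
#' attenuated by the double-path macular pigment absorption of the
#' acquisition band, the rhodopsin field follows the rod topology (zero at
#' the fovea center), and every non-vessel pixel brightens as
#' `alpha exp(-gamma exp(-beta t))`. Vessel pixels carry low-level dark
#' noise that does not follow the bleaching model. Additive Gaussian sensor
#' noise is applied to every pixel of every frame (clipped at zero); the
#' same seed yields a bit-identical stack.
#'
#' @param spec A [phantom_spec()].
#' @param band The acquisition [spectral_band()] (default 488/620 nm).
#' @param coeffs An [optical_coeffs()] table (default packaged templates).
#' @return List with `movie` (an [af_movie()]) and `truth` (class
#'   `phantom_truth`: `alpha_map`, `beta`, `gamma_map`, `d_mp_map`,
#'   `vessel_field`, `geometry`).
#' @export
generate_movie <- function(spec, band = spectral_band(488, 620),
                           coeffs = default_optical_coeffs()) {
  stopifnot(inherits(spec, "phantom_spec"))
  fld <- .phantom_fields(spec)
  ksum <- extinction(coeffs, band$excitation_nm, "mp") +
    extinction(coeffs, band$emission_nm, "mp")
  alpha_map <- spec$alpha * exp(-fld$d_mp * ksum)
  m <- max(3L, round(spec$frame_rate * spec$duration))
  times <- (seq_len(m) - 1L) / spec$frame_rate
  H <- spec$shape[1]; W <- spec$shape[2]
  .with_seed(spec$seed, {
    vessels <- .vessel_tree(spec$shape, spec$vessels$n_trunks,
                            spec$vessels$width_px)
    frames <- array(0, dim = c(H, W, m))
    decay <- exp(-spec$beta * times)
    dark <- spec$vessels$attenuation * spec$alpha
    sigma <- spec$noise$sigma_frac * spec$alpha
    phase <- stats::runif(1, 0, 2 * pi)
    pulse <- 1 + spec$vessels$pulsation *
      sin(2 * pi * spec$vessels$pulse_hz * times + phase)
    for (i in seq_len(m)) {
      fr <- alpha_map * exp(-fld$gamma * decay[i])
      fr[vessels] <- dark * pulse[i]
      if (sigma > 0) fr <- fr + matrix(stats::rnorm(H * W, 0, sigma), H, W)
      frames[, , i] <- pmax(fr, 0)
    }
  })
  truth <- structure(list(alpha_map = alpha_map, beta = spec$beta,
                          gamma_map = fld$gamma, d_mp_map = fld$d_mp,
                          vessel_field = vessels, geometry = fld$geometry),
                     class = "phantom_truth")
  list(movie = af_movie(frames, times, t0 = 0, geometry = fld$geometry),
       truth = truth)
}

#' Generate a synthetic multi-spectral macular pigment image set
#'
#' Forward-simulates one image per band from a common perifoveal base level:
#' `AF_f = AF_p exp(-D (k_MP(Lambda_j) + k_MP(lambda_j)))` with the
#' phantom's Gaussian foveal density field `D`, plus optional Gaussian
#' noise, using the phantom seed.
#'
#' @param spec A [phantom_spec()].
#' @param bands List of [spectral_band()] objects.
#' @param weights Zero-sum weights, one per band.
#' @param coeffs An [optical_coeffs()] table.
#' @param noise_sd Additive Gaussian noise s.d. in intensity units
#'   (default 0).
#' @return List with `mpset` (an [mp_image_set()]), `d_mp` (truth matrix),
#'   `reference` (true per-band `AF_p`), `geometry`.
#' @export
generate_mp_set <- function(spec, bands, weights,
                            coeffs = default_optical_coeffs(), noise_sd = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  fld <- .phantom_fields(spec)
  base <- spec$alpha
  images <- .with_seed(spec$seed + 1L, lapply(bands, function(b) {
    ksum <- extinction(coeffs, b$excitation_nm, "mp") +
      extinction(coeffs, b$emission_nm, "mp")
    im <- base * exp(-fld$d_mp * ksum)
    if (noise_sd > 0)
      im <- pmax(im + matrix(stats::rnorm(length(im), 0, noise_sd),
                             nrow(im), ncol(im)), 0)
    im
  }))
  list(mpset = mp_image_set(images, bands, weights),
       d_mp = fld$d_mp,
       reference = rep(base, length(bands)),
       geometry = fld$geometry)
}
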