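#' Spectral band of an autofluorescence acquisition
#'
#' A pair of excitation and emission wavelengths. Lipofuscin autofluorescence
#' is excited in the blue-green and detected at longer wavelengths, so the
#' Stokes shift `emission_nm > excitation_nm` is enforced.
#'
#' @param excitation_nm Excitation wavelength in nm, in \[400, 800\].
#' @param emission_nm Emission wavelength in nm, in \[400, 800\], strictly
#'   larger than `excitation_nm`.
#' @return An object of class `spectral_band`.
#' @examples
#' spectral_band(488, 620)
#' @export
spectral_band <- function(excitation_nm, emission_nm) {
  stopifnot(is.numeric(excitation_nm), length(excitation_nm) == 1L,
            is.numeric(emission_nm), length(emission_nm) == 1L,
            is.finite(excitation_nm), is.finite(emission_nm))
  if (excitation_nm < 400 || excitation_nm > 800 ||
      emission_nm < 400 || emission_nm > 800)
    stop("wavelengths must lie in [400, 800] nm")
  if (emission_nm <= excitation_nm)
    stop("emission wavelength must exceed excitation wavelength (Stokes shift)")
  structure(list(excitation_nm = excitation_nm, emission_nm = emission_nm),
            class = "spectral_band")
}

#' Rhodopsin bleaching/regeneration kinetics
#'
#' Parameters of the first-order bleaching/regeneration balance
#' \deqn{dR/dt = -I R / L + (1 - R)/K,}
#' where `R` is the fraction of unbleached rhodopsin, `I` the steady retinal
#' illuminance (relative radiant-power units), `L` the bleaching constant
#' (reciprocal photosensitivity, same units times seconds) and `K` the
#' visual-cycle regeneration time constant in seconds (roughly 700 s in young
#' eyes, rising to 1000 s with age).
#'
#' @param illuminance Positive scalar `I`.
#' @param bleach_constant Positive scalar `L`.
#' @param regen_time_constant Positive scalar `K`, seconds.
#' @return An object of class `bleach_kinetics`.
#' @seealso [bleach_rate()], [regeneration_fraction()]
#' @export
bleach_kinetics <- function(illuminance, bleach_constant, regen_time_constant) {
  for (v in list(illuminance, bleach_constant, regen_time_constant))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("illuminance, bleach_constant and regen_time_constant must be positive finite scalars")
  structure(list(illuminance = illuminance,
                 bleach_constant = bleach_constant,
                 regen_time_constant = regen_time_constant),
            class = "bleach_kinetics")
}

#' @describeIn bleach_kinetics Derived bleaching rate `beta = I / L` (1/s).
#' @param kinetics A `bleach_kinetics` object.
#' @export
bleach_rate <- function(kinetics) {
  stopifnot(inherits(kinetics, "bleach_kinetics"))
  kinetics$illuminance / kinetics$bleach_constant
}

#' Fraction of unbleached rhodopsin under steady illumination
#'
#' Closed-form solution of the bleaching/regeneration balance with `R(0) = 1`
#' (dark-adapted retina):
#' \deqn{R(t) = \frac{L}{KI + L} + \frac{KI}{KI + L}
#'   e^{-(1 + KI/L)\, t/K}.}
#' `R` decreases monotonically from 1 to the steady state `L/(KI + L)`; in
#' the cSLO regime (`KI >> L`, `t << K`) it reduces to the simplified law
#' `exp(-(I/L) t)`.
#'
#' @param t Nonnegative time(s), seconds. Vectorized.
#' @param kinetics A [bleach_kinetics()] object.
#' @return `R(t)` in (0, 1\], same shape as `t`.
#' @export
regeneration_fraction <- function(t, kinetics) {
  stopifnot(inherits(kinetics, "bleach_kinetics"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and nonnegative")
  I <- kinetics$illuminance
  L <- kinetics$bleach_constant
  K <- kinetics$regen_time_constant
  KI <- K * I
  L / (KI + L) + KI / (KI + L) * exp(-(1 + KI / L) * t / K)
}

#' Simplified exponential bleaching law
#'
#' When the retinal illuminance dominates regeneration (`I >> LK`) and the
#' movie is much shorter than the regeneration time constant (`t << K`), the
#' closed-form regeneration fraction reduces to
#' \deqn{R(t) \approx e^{-\beta t}, \qquad \beta = I/L.}
#' This is the law the per-pixel fitter assumes.
#'
#' @param t Nonnegative time(s), seconds. Vectorized.
#' @param beta Positive bleaching rate, 1/s.
#' @return `exp(-beta * t)`.
#' @export
simplified_fraction <- function(t, beta) {
  stopifnot(is.numeric(t), is.numeric(beta), length(beta) == 1L)
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and nonnegative")
  if (!is.finite(beta) || beta <= 0) stop("beta must be a positive finite scalar")
  exp(-beta * t)
}

#' Per-pixel forward-model parameters
#'
#' The triple `(alpha, beta, gamma)` of the double-exponential brightening
#' law [forward_af()]: `alpha` is the fully-bleached autofluorescence
#' amplitude (camera intensity units, already attenuated by macular pigment),
#' `beta` the bleaching rate (1/s), and `gamma` the double-path rhodopsin
#' optical density at time zero (dimensionless; excitation plus emission
#' pass).
#'
#' @param alpha Positive amplitude.
#' @param beta Positive rate, 1/s.
#' @param gamma Nonnegative optical density.
#' @return An object of class `pixel_params`.
#' @export
pixel_params <- function(alpha, beta, gamma) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (alpha <= 0) stop("alpha must be positive")
  if (beta <= 0) stop("beta must be positive")
  if (gamma < 0) stop("gamma must be nonnegative")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "pixel_params")
}

#' Forward autofluorescence brightening model
#'
#' Detected lipofuscin autofluorescence of one pixel under steady 488 nm
#' scanning, as the overlying rhodopsin bleaches:
#' \deqn{AF(t) = \alpha\, e^{-\gamma e^{-\beta t}}.}
#' At `t = 0` the unbleached rhodopsin attenuates the signal by a factor
#' `exp(-gamma)`; as `t` grows the signal brightens monotonically toward the
#' fully-bleached level `alpha`.
#'
#' @param t Time(s) in seconds, nonnegative. Vectorized.
#' @param params A [pixel_params()] object.
#' @return Intensities, same shape as `t`.
#' @export
forward_af <- function(t, params) {
  stopifnot(inherits(params, "pixel_params"), is.numeric(t))
  params$alpha * exp(-params$gamma * exp(-params$beta * t))
}

#' Relative extinction coefficient tables
#'
#' Wavelength-resolved relative extinction of macular pigment (`k_mp`,
#' normalized so that `k_mp(460 nm) = 1` exactly) and of rhodopsin (`k_rh`,
#' normalized at its 500 nm absorption peak). Lookups between tabulated
#' wavelengths are linearly interpolated; lookups outside the tabulated range
#' are an error.
#'
#' @param k_mp,k_rh Two-column data frames `(wavelength_nm, k)` with
#'   nonnegative `k` and strictly increasing wavelengths.
#' @return An object of class `optical_coeffs`.
#' @seealso [default_optical_coeffs()], [read_coeff_table()], [extinction()]
#' @export
optical_coeffs <- function(k_mp, k_rh) {
  check_tab <- function(tab, nm) {
    if (!is.data.frame(tab) || !all(c("wavelength_nm", "k") %in% names(tab)))
      stop(nm, " must be a data frame with columns wavelength_nm, k")
    if (any(!is.finite(tab$wavelength_nm)) || any(!is.finite(tab$k)))
      stop(nm, " table contains non-finite entries")
    if (is.unsorted(tab$wavelength_nm, strictly = TRUE))
      stop(nm, " wavelengths must be strictly increasing")
    if (any(tab$k < 0)) stop(nm, " entries must be nonnegative")
    tab[, c("wavelength_nm", "k")]
  }
  k_mp <- check_tab(k_mp, "k_mp")
  k_rh <- check_tab(k_rh, "k_rh")
  k460 <- stats::approx(k_mp$wavelength_nm, k_mp$k, xout = 460)$y
  if (is.na(k460) || abs(k460 - 1) > 1e-9)
    stop("k_mp must be normalized so that k_mp(460 nm) = 1")
  structure(list(k_mp = k_mp, k_rh = k_rh), class = "optical_coeffs")
}

#' Read a two-column extinction table from CSV
#'
#' @param path CSV file with columns `wavelength_nm, k`.
#' @return A data frame suitable for [optical_coeffs()].
#' @export
read_coeff_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("wavelength_nm", "k") %in% names(tab)))
    stop("coefficient table must have columns wavelength_nm, k: ", path)
  tab
}

#' Packaged default extinction templates
#'
#' Smooth literature-style templates shipped with the package: a macular
#' pigment absorbance template peaking at 460 nm (normalized to 1 there) and
#' a rhodopsin absorbance template peaking at 500 nm, set to zero at and
#' beyond 590 nm where rhodopsin absorbance of the emission band is
#' negligible. Both are editable CSVs under `inst/extdata/` and can be
#' replaced by user-supplied tables via [read_coeff_table()].
#'
#' @return An [optical_coeffs()] object.
#' @export
default_optical_coeffs <- function() {
  optical_coeffs(
    k_mp = read_coeff_table(system.file("extdata", "k_mp.csv",
                                        package = "rhodomap", mustWork = TRUE)),
    k_rh = read_coeff_table(system.file("extdata", "k_rh.csv",
                                        package = "rhodomap", mustWork = TRUE)))
}

#' Look up a relative extinction coefficient
#'
#' @param coeffs An [optical_coeffs()] object.
#' @param wavelength_nm Wavelength(s), nm. Must lie within the tabulated
#'   range; extrapolation is an error.
#' @param pigment `"mp"` (macular pigment) or `"rh"` (rhodopsin).
#' @return Interpolated coefficient(s).
#' @export
extinction <- function(coeffs, wavelength_nm, pigment = c("mp", "rh")) {
  stopifnot(inherits(coeffs, "optical_coeffs"))
  pigment <- match.arg(pigment)
  tab <- if (pigment == "mp") coeffs$k_mp else coeffs$k_rh
  out <- stats::approx(tab$wavelength_nm, tab$k, xout = wavelength_nm)$y
  if (any(is.na(out)))
    stop("wavelength outside the tabulated range for k_", pigment, ": ",
         paste(wavelength_nm[is.na(out)], collapse = ", "), " nm")
  out
}

#' Macular-pigment-attenuated amplitude
#'
#' Composes the fully-bleached amplitude of one pixel from the source term
#' `I(Lambda) * Phi(Lambda, lambda)` and the double-path macular pigment
#' attenuation:
#' \deqn{\alpha = I\Phi\, e^{-D_{MP}(460)\,(k_{MP}(\Lambda) + k_{MP}(\lambda))}.}
#'
#' @param source_product Positive product of excitation radiant power and
#'   lipofuscin fluorescence efficiency (intensity units).
#' @param d_mp_460 Nonnegative macular pigment optical density at 460 nm.
#' @param band A [spectral_band()].
#' @param coeffs An [optical_coeffs()] object covering both wavelengths.
#' @return The attenuated amplitude.
#' @export
compose_alpha <- function(source_product, d_mp_460, band, coeffs) {
  stopifnot(is.numeric(source_product), all(source_product > 0),
            is.numeric(d_mp_460), all(d_mp_460 >= 0),
            inherits(band, "spectral_band"))
  ksum <- extinction(coeffs, band$excitation_nm, "mp") +
    extinction(coeffs, band$emission_nm, "mp")
  source_product * exp(-d_mp_460 * ksum)
}

#' Acquisition geometry of a fundus image
#'
#' @param fov_deg Field of view in degrees (full width).
#' @param center Fovea center `(row, col)`, 1-based pixel coordinates.
#' @param px_per_deg Pixels per degree of visual angle.
#' @return An object of class `movie_geometry`.
#' @export
movie_geometry <- function(fov_deg, center, px_per_deg) {
  stopifnot(is.numeric(fov_deg), fov_deg > 0,
            is.numeric(center), length(center) == 2L, all(is.finite(center)),
            is.numeric(px_per_deg), px_per_deg > 0)
  structure(list(fov_deg = fov_deg, center = as.numeric(center),
                 px_per_deg = px_per_deg),
            class = "movie_geometry")
}

#' Registered autofluorescence movie
#'
#' A registered 3-D intensity stack with its time grid. Frames are stored as
#' an `H x W x m` array (`m` frames); timestamps are strictly increasing and
#' in seconds.
#'
#' @param frames `H x W x m` array of finite, nonnegative intensities,
#'   `m >= 3`.
#' @param times Strictly increasing numeric vector of length `m`, seconds.
#' @param t0 Acquisition start (time of first light exposure), `>= 0`.
#' @param geometry A [movie_geometry()] object.
#' @return An object of class `af_movie`.
#' @export
af_movie <- function(frames, times, t0 = 0, geometry) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            inherits(geometry, "movie_geometry"))
  m <- dim(frames)[3]
  if (m < 3L) stop("a movie needs at least 3 frames")
  if (length(times) != m) stop("length(times) must equal the number of frames")
  if (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE))
    stop("times must be finite and strictly increasing")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 < 0)
    stop("t0 must be a nonnegative scalar")
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("frame intensities must be finite and nonnegative")
  structure(list(frames = frames, times = as.numeric(times), t0 = t0,
                 geometry = geometry),
            class = "af_movie")
}

#' @export
print.af_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("af_movie: %d x %d pixels, %d frames, t = [%.3g, %.3g] s, fov %.3g deg\n",
              d[1], d[2], d[3], x$times[1], x$times[d[3]], x$geometry$fov_deg))
  invisible(x)
}

# radial distance (deg) of every pixel from the fovea center
.radius_deg <- function(shape, geometry) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  sqrt((rows - geometry$center[1])^2 + (cols - geometry$center[2])^2) /
    geometry$px_per_deg
}

# polar angle of every pixel: 0 = +col direction, pi/2 = -row direction (up)
.theta <- function(shape, geometry) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  atan2(-(rows - geometry$center[1]), cols - geometry$center[2])
}
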