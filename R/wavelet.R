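# Periodic orthogonal 2-D discrete wavelet transform and the Besov 1-2-2
# seminorm built on it. Implemented in-package: the inpainting energy needs
# the transform, its adjoint (equal to the inverse, orthonormality) and a
# level-weighted coefficient norm, all under periodic boundary handling.

.wavelet_filters <- function(name = c("d4", "haar")) {
  name <- match.arg(name)
  h <- switch(name,
    haar = c(1, 1) / sqrt(2),
    d4 = {
      s3 <- sqrt(3)
      c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
    })
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror filter
  list(h = h, g = g)
}

# one analysis step down the columns of X (periodic); returns approx/detail
.dwt_cols <- function(X, h, g) {
  n <- nrow(X)
  L <- length(h)
  k <- seq(0L, n - 2L, by = 2L)
  A <- matrix(0, n / 2L, ncol(X))
  D <- A
  for (m in seq_len(L)) {
    rows <- (k + (m - 1L)) %% n + 1L
    A <- A + h[m] * X[rows, , drop = FALSE]
    D <- D + g[m] * X[rows, , drop = FALSE]
  }
  list(A = A, D = D)
}

# one synthesis step up the columns (periodic); adjoint of .dwt_cols
.idwt_cols <- function(A, D, h, g) {
  n <- 2L * nrow(A)
  L <- length(h)
  k <- seq(0L, n - 2L, by = 2L)
  X <- matrix(0, n, ncol(A))
  for (m in seq_len(L)) {
    rows <- (k + (m - 1L)) %% n + 1L
    X[rows, ] <- X[rows, ] + h[m] * A + g[m] * D
  }
  X
}

# largest usable decomposition depth for a given shape
.effective_levels <- function(shape, levels, filter_len) {
  lv <- 0L
  H <- shape[1]; W <- shape[2]
  while (lv < levels && H %% 2L == 0L && W %% 2L == 0L &&
         min(H, W) >= filter_len) {
    H <- H %/% 2L; W <- W %/% 2L
    lv <- lv + 1L
  }
  if (lv == 0L) stop("image dimensions admit no wavelet level")
  lv
}

#' Periodic orthogonal 2-D wavelet decomposition
#'
#' Separable multi-level DWT with periodic boundary handling and an
#' orthonormal filter pair (Haar or Daubechies-4). Level 1 holds the finest
#' detail bands.
#'
#' @param x Numeric matrix; both dimensions must be divisible by
#'   `2^levels` (the depth is reduced automatically otherwise).
#' @param wavelet `"d4"` (default) or `"haar"`.
#' @param levels Requested decomposition depth (default 4).
#' @return An object of class `dwt2` with per-level detail blocks
#'   `lh, hl, hh`, the final approximation `ll`, and metadata.
#' @seealso [idwt2()], [besov_seminorm_sq()]
#' @export
dwt2 <- function(x, wavelet = "d4", levels = 4L) {
  stopifnot(is.matrix(x))
  flt <- .wavelet_filters(wavelet)
  levels <- .effective_levels(dim(x), as.integer(levels), length(flt$h))
  detail <- vector("list", levels)
  cur <- x
  for (lv in seq_len(levels)) {
    cs <- .dwt_cols(cur, flt$h, flt$g)
    rA <- .dwt_cols(t(cs$A), flt$h, flt$g)
    rD <- .dwt_cols(t(cs$D), flt$h, flt$g)
    detail[[lv]] <- list(lh = t(rD$A), hl = t(rA$D), hh = t(rD$D))
    cur <- t(rA$A)
  }
  structure(list(detail = detail, ll = cur, wavelet = wavelet,
                 levels = levels, dims = dim(x)),
            class = "dwt2")
}

#' Inverse of [dwt2()]
#'
#' @param w A `dwt2` object.
#' @return The reconstructed matrix (exact up to float rounding).
#' @export
idwt2 <- function(w) {
  stopifnot(inherits(w, "dwt2"))
  flt <- .wavelet_filters(w$wavelet)
  cur <- w$ll
  for (lv in rev(seq_len(w$levels))) {
    d <- w$detail[[lv]]
    A <- t(.idwt_cols(t(cur), t(d$hl), flt$h, flt$g))
    D <- t(.idwt_cols(t(d$lh), t(d$hh), flt$h, flt$g))
    cur <- .idwt_cols(A, D, flt$h, flt$g)
  }
  cur
}

#' Besov 1-2-2 seminorm (squared) of an image
#'
#' Level-weighted detail energy of the orthonormal wavelet expansion,
#' \deqn{|u|_B^2 = \sum_j 2^{2j} \sum_{\text{details at } j} d^2,}
#' with the dyadic scale index `j = 0` at the coarsest detail level and
#' increasing toward fine scales, so the seminorm penalizes fine-scale
#' oscillation most — the H1-like convention.
#'
#' @param x Matrix, or a precomputed `dwt2` object.
#' @param wavelet,levels Passed to [dwt2()] when `x` is a matrix.
#' @return Nonnegative scalar.
#' @export
besov_seminorm_sq <- function(x, wavelet = "d4", levels = 4L) {
  w <- if (inherits(x, "dwt2")) x else dwt2(x, wavelet, levels)
  tot <- 0
  for (lv in seq_len(w$levels)) {
    wt <- 4^(w$levels - lv)  # lv = 1 is finest
    d <- w$detail[[lv]]
    tot <- tot + wt * (sum(d$lh^2) + sum(d$hl^2) + sum(d$hh^2))
  }
  tot
}

# gradient of besov_seminorm_sq wrt the image: inverse transform of the
# level-scaled detail coefficients (orthonormal transform => adjoint = inverse)
.besov_grad <- function(w) {
  g <- w
  g$ll <- matrix(0, nrow(w$ll), ncol(w$ll))
  for (lv in seq_len(w$levels)) {
    wt <- 2 * 4^(w$levels - lv)
    g$detail[[lv]] <- lapply(w$detail[[lv]], function(d) wt * d)
  }
  idwt2(g)
}

# soft-threshold all detail coefficients of a dwt2 object
.soft_threshold <- function(w, thr) {
  if (thr <= 0) return(w)
  shrink <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  for (lv in seq_len(w$levels))
    w$detail[[lv]] <- lapply(w$detail[[lv]], shrink)
  w
}
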