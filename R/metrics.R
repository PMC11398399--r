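# Image similarity terms and their gradients with respect to the warped
# image. All metrics are written as losses (lower is better) so the
# registration engine can minimise them uniformly.

#' Global normalised cross-correlation
#' @param a,b numeric arrays or vectors of equal length.
#' @param mask optional logical vector restricting the support.
#' @return NCC in `[-1, 1]`; errors if either input is constant.
#' @export
ncc <- function(a, b, mask = NULL) {
  a <- as.vector(a); b <- as.vector(b)
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) stop("NCC undefined: constant image")
  stats::cor(a, b)
}

# Local statistics for LNCC with a Gaussian window (separable, row-normalised
# at borders). Returns a list used by both the value and the gradient.
lncc_stats <- function(I, J, sigma, eps = 1e-5) {
  mI <- smooth_gauss(I, sigma)
  mJ <- smooth_gauss(J, sigma)
  sII <- smooth_gauss(I * I, sigma) - mI^2
  sJJ <- smooth_gauss(J * J, sigma) - mJ^2
  sIJ <- smooth_gauss(I * J, sigma) - mI * mJ
  D <- (pmax(sII, 0) + eps) * (pmax(sJJ, 0) + eps)
  list(mI = mI, mJ = mJ, sII = sII, sJJ = sJJ, sIJ = sIJ, D = D, eps = eps,
       sigma = sigma)
}

#' Local normalised cross-correlation
#'
#' Mean over voxels of the squared local correlation coefficient computed in
#' Gaussian windows; equals 1 (up to the stabilising epsilon) when the images
#' agree locally up to affine intensity changes.
#'
#' @param fixed,moving numeric arrays on the same grid.
#' @param sigma Gaussian window standard deviation in voxels.
#' @param eps variance stabiliser.
#' @return scalar in `[0, 1]`.
#' @export
lncc <- function(fixed, moving, sigma = 2, eps = 1e-5) {
  s <- lncc_stats(fixed, moving, sigma, eps)
  mean(s$sIJ^2 / s$D)
}

# Transposed Gaussian smoothing (exact adjoint of smooth_gauss).
smooth_gauss_t <- function(vol, sigma) {
  shape <- dim(vol)
  sigma <- rep(sigma, length.out = length(shape))
  for (a in seq_along(shape)) {
    if (sigma[a] > 0) vol <- mode_mult(vol, t(gauss_matrix(shape[a], sigma[a])), a)
  }
  vol
}

# d mean(LNCC) / d moving-image values (array shaped like the image).
lncc_grad_moving <- function(fixed, moving, sigma = 2, eps = 1e-5) {
  s <- lncc_stats(fixed, moving, sigma, eps)
  n <- length(fixed)
  r <- s$sIJ / s$D                       # sIJ / ((sII+e)(sJJ+e))
  q <- s$sIJ^2 / (s$D * (pmax(s$sJJ, 0) + eps))
  g <- fixed * smooth_gauss_t(2 * r, sigma) -
       smooth_gauss_t(2 * r * s$mI, sigma) -
       moving * smooth_gauss_t(2 * q, sigma) +
       smooth_gauss_t(2 * q * s$mJ, sigma)
  g / n
}

#' Monotone histogram matching
#'
#' Remaps `moving` intensities so their empirical distribution matches that of
#' `fixed`, via the rank-to-quantile transform. Used to normalise stain
#' contrast before cross-modality local NCC registration.
#'
#' @param moving,fixed numeric arrays/vectors.
#' @return array shaped like `moving` with remapped intensities.
#' @export
match_histogram <- function(moving, fixed) {
  mv <- as.vector(moving)
  r <- rank(mv, ties.method = "average") / (length(mv) + 1)
  out <- stats::quantile(as.vector(fixed), probs = r, names = FALSE, type = 7)
  array(out, dim(moving) %||% length(mv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
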