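# Shared fixtures built in code. Heavier objects are created lazily and
# cached for the session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# Textured-body volume: an ellipsoidal "brain" with smooth random texture,
# suitable for intensity-based (NCC) registration tests.
textured_body <- function(shape = c(24, 24, 24), seed = 11) {
  body <- histatlas:::ellipsoid_mask(shape, (shape + 1) / 2, 0.42 * shape)
  set.seed(seed)
  tex <- histatlas:::smooth_gauss(array(stats::rnorm(prod(shape)), shape),
                                  1.5)
  (5 + 10 * tex) * body
}

# Small smooth 2D image for registration tests.
smooth_image_2d <- function(n = 48, seed = 5, sigma = 2) {
  set.seed(seed)
  histatlas:::smooth_gauss(array(stats::rnorm(n * n), c(n, n)), sigma)
}

# Independent RK4 integrator of the SVF flow (its own bilinear interpolation,
# not the package's): oracle for exp_svf.
rk4_flow <- function(v, pts, n_steps = 256) {
  shape <- dim(v$disp)[1:2]
  vx <- v$disp[, , 1]
  vy <- v$disp[, , 2]
  bilerp <- function(img, x, y) {
    x <- pmin(pmax(x, 1), shape[1])
    y <- pmin(pmax(y, 1), shape[2])
    x0 <- pmin(floor(x), shape[1] - 1); y0 <- pmin(floor(y), shape[2] - 1)
    fx <- x - x0; fy <- y - y0
    img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
      img[cbind(x0 + 1, y0)] * fx * (1 - fy) +
      img[cbind(x0, y0 + 1)] * (1 - fx) * fy +
      img[cbind(x0 + 1, y0 + 1)] * fx * fy
  }
  h <- 1 / n_steps
  x <- pts[, 1]; y <- pts[, 2]
  for (i in seq_len(n_steps)) {
    k1x <- bilerp(vx, x, y);                 k1y <- bilerp(vy, x, y)
    k2x <- bilerp(vx, x + h / 2 * k1x, y + h / 2 * k1y)
    k2y <- bilerp(vy, x + h / 2 * k1x, y + h / 2 * k1y)
    k3x <- bilerp(vx, x + h / 2 * k2x, y + h / 2 * k2y)
    k3y <- bilerp(vy, x + h / 2 * k2x, y + h / 2 * k2y)
    k4x <- bilerp(vx, x + h * k3x, y + h * k3y)
    k4y <- bilerp(vy, x + h * k3x, y + h * k3y)
    x <- x + h / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
    y <- y + h / 6 * (k1y + 2 * k2y + 2 * k3y + k4y)
  }
  cbind(x, y)
}

# Default tiny clustering: identity map label -> class.
identity_clustering <- function(labels) {
  tissue_clustering(stats::setNames(seq_along(labels), as.character(labels)))
}
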