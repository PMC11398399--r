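# Low-level array numerics shared by the deformation, registration and
# segmentation code. All coordinates are 1-based voxel indices at voxel
# centres; displacements are in voxel units of the fixed grid.

#' Voxel-centre coordinate matrix for a grid
#'
#' @param shape integer vector of voxel counts per axis (length 2 or 3).
#' @return numeric matrix with `prod(shape)` rows and `length(shape)` columns,
#'   column-major (first axis fastest), holding 1-based voxel coordinates.
#' @keywords internal
voxel_coords <- function(shape) {
  d <- length(shape)
  n <- prod(shape)
  out <- matrix(0, n, d)
  rep_each <- 1L
  for (a in seq_len(d)) {
    out[, a] <- rep(rep(seq_len(shape[a]), each = rep_each),
                    length.out = n)
    rep_each <- rep_each * shape[a]
  }
  out
}

# Clamp coordinates into [1, n] per axis.
clamp_coords <- function(pts, shape) {
  for (a in seq_along(shape)) {
    pts[, a] <- pmin.int(pmax.int(pts[, a], 1), shape[a])
  }
  pts
}

#' Multilinear interpolation of a 2D/3D array at arbitrary points
#'
#' @param vol numeric array (2D or 3D).
#' @param pts matrix of coordinates (rows = points, cols = axes), 1-based.
#' @param fill value for points outside the grid (ignored when `clamp`).
#' @param clamp if `TRUE`, coordinates are clamped to the grid (border
#'   replication) instead of filled.
#' @return numeric vector of interpolated values.
#' @keywords internal
interp_linear <- function(vol, pts, fill = 0, clamp = FALSE) {
  shape <- dim(vol)
  d <- length(shape)
  stopifnot(ncol(pts) == d)
  if (!clamp) {
    inside <- rep(TRUE, nrow(pts))
    for (a in seq_len(d)) {
      inside <- inside & pts[, a] >= 1 & pts[, a] <= shape[a]
    }
  }
  pts <- clamp_coords(pts, shape)
  v <- as.vector(vol)
  i0 <- floor(pts)
  # keep the base corner so that i0 + 1 stays in range
  for (a in seq_len(d)) i0[, a] <- pmin.int(i0[, a], shape[a] - 1L)
  f <- pts - i0
  if (d == 2L) {
    n1 <- shape[1]
    base <- i0[, 1] + (i0[, 2] - 1) * n1
    v00 <- v[base];          v10 <- v[base + 1]
    v01 <- v[base + n1];     v11 <- v[base + n1 + 1]
    fx <- f[, 1]; fy <- f[, 2]
    out <- (1 - fy) * ((1 - fx) * v00 + fx * v10) +
           fy * ((1 - fx) * v01 + fx * v11)
  } else if (d == 3L) {
    n1 <- shape[1]; n12 <- shape[1] * shape[2]
    base <- i0[, 1] + (i0[, 2] - 1) * n1 + (i0[, 3] - 1) * n12
    fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
    c00 <- (1 - fx) * v[base]             + fx * v[base + 1]
    c10 <- (1 - fx) * v[base + n1]        + fx * v[base + n1 + 1]
    c01 <- (1 - fx) * v[base + n12]       + fx * v[base + n12 + 1]
    c11 <- (1 - fx) * v[base + n1 + n12]  + fx * v[base + n1 + n12 + 1]
    out <- (1 - fz) * ((1 - fy) * c00 + fy * c10) +
           fz * ((1 - fy) * c01 + fy * c11)
  } else {
    stop("interp_linear supports 2D and 3D arrays")
  }
  if (!clamp && !all(inside)) out[!inside] <- fill
  out
}

#' Nearest-neighbour lookup at arbitrary points
#' @inheritParams interp_linear
#' @keywords internal
interp_nearest <- function(vol, pts, fill = 0) {
  shape <- dim(vol)
  d <- length(shape)
  inside <- rep(TRUE, nrow(pts))
  ip <- matrix(0L, nrow(pts), d)
  for (a in seq_len(d)) {
    ip[, a] <- as.integer(round(pts[, a]))
    inside <- inside & ip[, a] >= 1L & ip[, a] <= shape[a]
    ip[, a] <- pmin.int(pmax.int(ip[, a], 1L), shape[a])
  }
  if (d == 2L) {
    idx <- ip[, 1] + (ip[, 2] - 1L) * shape[1]
  } else if (d == 3L) {
    idx <- ip[, 1] + (ip[, 2] - 1L) * shape[1] +
      (ip[, 3] - 1L) * shape[1] * shape[2]
  } else stop("interp_nearest supports 2D and 3D arrays")
  out <- as.vector(vol)[idx]
  # preserve integer storage (labels) so identity warps are bit-identical
  out[!inside] <- if (is.integer(out)) as.integer(fill) else fill
  out
}

#' Spatial gradient of the multilinear interpolant
#'
#' Returns the exact derivative of the piecewise-multilinear interpolant with
#' respect to each coordinate, evaluated at the given points (coordinates are
#' clamped to the grid).
#' @inheritParams interp_linear
#' @return matrix (points x axes) of partial derivatives.
#' @keywords internal
interp_grad <- function(vol, pts) {
  shape <- dim(vol)
  d <- length(shape)
  pts <- clamp_coords(pts, shape)
  v <- as.vector(vol)
  i0 <- floor(pts)
  for (a in seq_len(d)) i0[, a] <- pmin.int(i0[, a], shape[a] - 1L)
  f <- pts - i0
  g <- matrix(0, nrow(pts), d)
  if (d == 2L) {
    n1 <- shape[1]
    base <- i0[, 1] + (i0[, 2] - 1) * n1
    v00 <- v[base];      v10 <- v[base + 1]
    v01 <- v[base + n1]; v11 <- v[base + n1 + 1]
    fx <- f[, 1]; fy <- f[, 2]
    g[, 1] <- (1 - fy) * (v10 - v00) + fy * (v11 - v01)
    g[, 2] <- (1 - fx) * (v01 - v00) + fx * (v11 - v10)
  } else if (d == 3L) {
    n1 <- shape[1]; n12 <- shape[1] * shape[2]
    base <- i0[, 1] + (i0[, 2] - 1) * n1 + (i0[, 3] - 1) * n12
    v000 <- v[base];            v100 <- v[base + 1]
    v010 <- v[base + n1];       v110 <- v[base + n1 + 1]
    v001 <- v[base + n12];      v101 <- v[base + n12 + 1]
    v011 <- v[base + n1 + n12]; v111 <- v[base + n1 + n12 + 1]
    fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
    g[, 1] <- (1 - fz) * ((1 - fy) * (v100 - v000) + fy * (v110 - v010)) +
              fz * ((1 - fy) * (v101 - v001) + fy * (v111 - v011))
    g[, 2] <- (1 - fz) * ((1 - fx) * (v010 - v000) + fx * (v110 - v100)) +
              fz * ((1 - fx) * (v011 - v001) + fx * (v111 - v101))
    g[, 3] <- (1 - fy) * ((1 - fx) * (v001 - v000) + fx * (v101 - v100)) +
              fy * ((1 - fx) * (v011 - v010) + fx * (v111 - v110))
  } else stop("interp_grad supports 2D and 3D arrays")
  g
}

# Shared-point interpolation: compute corner indices and weights once, then
# apply them to any number of arrays on the same grid (the hot path in SVF
# exponentiation and multi-channel registration).
interp_prep <- function(shape, pts, clamp = FALSE) {
  d <- length(shape)
  inside <- NULL
  if (!clamp) {
    inside <- rep(TRUE, nrow(pts))
    for (a in seq_len(d)) {
      inside <- inside & pts[, a] >= 1 & pts[, a] <= shape[a]
    }
    if (all(inside)) inside <- NULL
  }
  pts <- clamp_coords(pts, shape)
  i0 <- floor(pts)
  for (a in seq_len(d)) i0[, a] <- pmin.int(i0[, a], shape[a] - 1L)
  f <- pts - i0
  if (d == 2L) {
    n1 <- shape[1]
    base <- i0[, 1] + (i0[, 2] - 1) * n1
    fx <- f[, 1]; fy <- f[, 2]
    w <- list((1 - fx) * (1 - fy), fx * (1 - fy),
              (1 - fx) * fy, fx * fy)
    off <- c(0, 1, n1, n1 + 1)
  } else {
    n1 <- shape[1]; n12 <- shape[1] * shape[2]
    base <- i0[, 1] + (i0[, 2] - 1) * n1 + (i0[, 3] - 1) * n12
    fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
    w <- list((1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
              (1 - fx) * fy * (1 - fz),       fx * fy * (1 - fz),
              (1 - fx) * (1 - fy) * fz,       fx * (1 - fy) * fz,
              (1 - fx) * fy * fz,             fx * fy * fz)
    off <- c(0, 1, n1, n1 + 1, n12, n12 + 1, n12 + n1, n12 + n1 + 1)
  }
  list(base = base, w = w, off = off, inside = inside)
}

prep_subset <- function(prep, idx) {
  list(base = prep$base[idx], w = lapply(prep$w, `[`, idx),
       off = prep$off,
       inside = if (!is.null(prep$inside)) prep$inside[idx])
}

interp_apply <- function(prep, vol, fill = 0) {
  v <- as.vector(vol)
  out <- prep$w[[1]] * v[prep$base]
  for (i in 2:length(prep$off)) {
    out <- out + prep$w[[i]] * v[prep$base + prep$off[i]]
  }
  if (!is.null(prep$inside)) out[!prep$inside] <- fill
  out
}

# Central-difference spatial gradient of an array (one-sided at borders).
img_gradient <- function(f) {
  d <- length(dim(f))
  lapply(seq_len(d), function(a) {
    n <- dim(f)[a]
    g <- (shift_axis(f, a, -1) - shift_axis(f, a, 1)) / 2
    # one-sided at the two boundary slices
    idx <- lapply(dim(f), seq_len)
    for (b in c(1L, n)) {
      i1 <- idx; i1[[a]] <- b
      i2 <- idx; i2[[a]] <- if (b == 1L) 2L else n - 1L
      v <- do.call(`[`, c(list(f), i2)) - do.call(`[`, c(list(f), i1))
      if (b == n) v <- -v
      g <- do.call(`[<-`, c(list(g), i1, list(v)))
    }
    g
  })
}

# Tensor mode-n product: multiply array X (dims shape) along `mode` by matrix
# M (nrow(M) x shape[mode]), returning an array with shape[mode] -> nrow(M).
mode_mult <- function(X, M, mode) {
  shape <- dim(X)
  d <- length(shape)
  perm <- c(mode, seq_len(d)[-mode])
  Xp <- aperm(X, perm)
  mat <- matrix(Xp, nrow = shape[mode])
  out <- M %*% mat
  new_shape <- c(nrow(M), shape[-mode])
  out <- array(out, new_shape)
  aperm(out, order(perm))
}

# Dense 1D Gaussian smoothing matrix with row renormalisation at borders.
gauss_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  x <- seq_len(n)
  W <- exp(-outer(x, x, "-")^2 / (2 * sigma^2))
  W[W < 1e-12] <- 0
  W / rowSums(W)
}

# Separable Gaussian smoothing of a 2D/3D array.
smooth_gauss <- function(vol, sigma) {
  if (all(sigma <= 0)) return(vol)
  shape <- dim(vol)
  sigma <- rep(sigma, length.out = length(shape))
  for (a in seq_along(shape)) {
    if (sigma[a] > 0) vol <- mode_mult(vol, gauss_matrix(shape[a], sigma[a]), a)
  }
  vol
}

# Shift an array along an axis with zero fill (by = +1 pulls from lower
# index). Reshapes to (pre, n, post) so the slicing runs at native speed.
shift_axis <- function(x, axis, by) {
  if (by == 0) return(x)
  shape <- dim(x)
  n <- shape[axis]
  pre <- prod(shape[seq_len(axis - 1L)])
  post <- prod(shape) / (pre * n)
  x3 <- x
  dim(x3) <- c(pre, n, post)
  out <- array(0, c(pre, n, post))
  if (by > 0) out[, (1 + by):n, ] <- x3[, 1:(n - by), , drop = FALSE]
  else out[, 1:(n + by), ] <- x3[, (1 - by):n, , drop = FALSE]
  dim(out) <- shape
  out
}

# Run expr with a temporary RNG state seeded by `seed`; restores global state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
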