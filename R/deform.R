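# Deformation engine: stationary velocity fields (SVFs), their exponentials,
# composition and resampling. Displacements are stored in voxel units of the
# fixed grid; world-space conversion happens only at I/O via the affine.

#' Construct a velocity field
#'
#' A stationary velocity field (SVF) parameterises a diffeomorphism through
#' its flow: the time-1 solution of dx/dt = v(x). Values are voxel
#' displacement rates on a dense grid; dimensionality (2D or 3D) is inferred
#' from the array.
#'
#' @param disp numeric array with dimensions `c(shape, d)` where `d` is 2 or 3
#'   and equals `length(shape)`.
#' @param voxel_size physical voxel size per axis (mm), recycled.
#' @return object of class `velocity_field`.
#' @export
velocity_field <- function(disp, voxel_size = 1) {
  dm <- dim(disp)
  d <- dm[length(dm)]
  if (length(dm) != d + 1L || !(d %in% c(2L, 3L)))
    stop("disp must have dimensions c(shape, d) with d = 2 or 3")
  if (!all(is.finite(disp))) stop("velocity field contains non-finite values")
  structure(list(disp = disp, voxel_size = rep(voxel_size, length.out = d)),
            class = "velocity_field")
}

#' Construct a deformation (displacement) field
#'
#' Per-voxel displacement vectors in voxel units: a warped image is
#' `I(x + d(x))`.
#' @inheritParams velocity_field
#' @return object of class `deformation_field`.
#' @export
deformation_field <- function(disp, voxel_size = 1) {
  f <- velocity_field(disp, voxel_size)
  class(f) <- "deformation_field"
  f
}

field_shape <- function(f) {
  dm <- dim(f$disp)
  dm[-length(dm)]
}

field_ndim <- function(f) {
  dm <- dim(f$disp)
  dm[length(dm)]
}

# Displacement components as a (nvoxel x d) matrix.
disp_matrix <- function(f) {
  d <- field_ndim(f)
  matrix(f$disp, ncol = d)
}

# Sample a displacement field at arbitrary points (border replication), as
# required when composing maps that leave the grid.
sample_disp <- function(f, pts) {
  d <- field_ndim(f)
  shape <- field_shape(f)
  n <- prod(shape)
  prep <- interp_prep(shape, pts, clamp = TRUE)
  out <- matrix(0, nrow(pts), d)
  for (a in seq_len(d)) {
    out[, a] <- interp_apply(prep, f$disp[(a - 1) * n + seq_len(n)])
  }
  out
}

# Extract one component as an array.
field_comp <- function(f, a) {
  shape <- field_shape(f)
  idx <- slice.index(f$disp, length(shape) + 1L)
  array(f$disp[idx == a], shape)
}

zero_field <- function(shape, voxel_size = 1) {
  d <- length(shape)
  deformation_field(array(0, c(shape, d)), voxel_size)
}

# Core of compose(): displacement arithmetic on matching grids.
compose_disp <- function(outer, inner, base = NULL) {
  shape <- field_shape(inner)
  if (is.null(base)) base <- voxel_coords(shape)
  pts <- base + disp_matrix(inner)
  add <- sample_disp(outer, pts)
  deformation_field(array(disp_matrix(inner) + add,
                          dim(inner$disp)), inner$voxel_size)
}

# Warp a multi-channel stack c(shape, L) with shared interpolation weights.
warp_channels <- function(stack, d, fills = 0) {
  dm <- dim(stack)
  L <- dm[length(dm)]
  shape <- dm[-length(dm)]
  n <- prod(shape)
  fills <- rep(fills, length.out = L)
  pts <- voxel_coords(shape) + disp_matrix(d)
  prep <- interp_prep(shape, pts)
  out <- stack
  for (l in seq_len(L)) {
    out[(l - 1) * n + seq_len(n)] <-
      interp_apply(prep, stack[(l - 1) * n + seq_len(n)], fill = fills[l])
  }
  out
}

#' Exponentiate a stationary velocity field
#'
#' Computes the time-1 flow of `v` by scaling and squaring: the field is
#' divided by `2^n_steps` and the resulting small displacement is composed
#' with itself `n_steps` times. A zero field maps to the identity; a spatially
#' constant field maps to an exact translation.
#'
#' @param v a [velocity_field()].
#' @param n_steps number of squarings (default 8).
#' @return a [deformation_field()].
#' @export
exp_svf <- function(v, n_steps = 8) {
  stopifnot(inherits(v, "velocity_field") || inherits(v, "deformation_field"))
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (!all(is.finite(v$disp))) stop("non-finite velocity field")
  d <- deformation_field(v$disp / 2^n_steps, v$voxel_size)
  base <- voxel_coords(field_shape(d))
  for (i in seq_len(n_steps)) d <- compose_disp(d, d, base)
  d
}

#' Compose two deformation fields
#'
#' Returns the field whose action equals applying `inner` then `outer`:
#' `d(x) = inner(x) + outer(x + inner(x))`, with `outer` sampled by linear
#' interpolation (border replication).
#'
#' @param outer,inner [deformation_field()] objects on the same grid.
#' @return a [deformation_field()].
#' @export
compose <- function(outer, inner) {
  if (!identical(field_shape(outer), field_shape(inner)))
    stop("deformation fields live on different grids")
  compose_disp(outer, inner)
}

#' Inverse deformation of a velocity field
#'
#' The inverse of `exp(v)` is `exp(-v)`; composing the two approximates the
#' identity for safe-amplitude smooth fields.
#' @inheritParams exp_svf
#' @return a [deformation_field()].
#' @export
invert <- function(v, n_steps = 8) {
  exp_svf(velocity_field(-v$disp, v$voxel_size), n_steps)
}

#' Warp a volume by a deformation field
#'
#' Resamples `volume` at `x + d(x)`. Modes: `"linear"` interpolation for
#' intensities, `"nearest"` for labels, and `"onehot_linear"` which linearly
#' interpolates one-hot label encodings and takes the per-voxel argmax (ties
#' broken towards the lowest label id).
#'
#' @param volume numeric or integer array matching the grid of `d`.
#' @param d a [deformation_field()].
#' @param mode one of `"linear"`, `"nearest"`, `"onehot_linear"`.
#' @param fill value assigned outside the field of view.
#' @return array of the same shape as `volume`.
#' @export
warp <- function(volume, d, mode = c("linear", "nearest", "onehot_linear"),
                 fill = 0) {
  mode <- match.arg(mode)
  shape <- field_shape(d)
  if (!identical(as.integer(dim(volume)), as.integer(shape)))
    stop("volume and deformation field grids differ")
  pts <- voxel_coords(shape) + disp_matrix(d)
  if (mode == "linear") {
    out <- interp_linear(volume, pts, fill = fill)
  } else if (mode == "nearest") {
    out <- interp_nearest(volume, pts, fill = fill)
  } else {
    labs <- sort(unique(as.vector(volume)))
    best <- rep(-Inf, nrow(pts))
    lab <- rep(labs[1], nrow(pts))
    for (l in labs) {
      p <- interp_linear((volume == l) * 1, pts,
                         fill = if (l == fill) 1 else 0)
      sel <- p > best + 1e-12   # strict: ties keep the lower label id
      lab[sel] <- l
      best[sel] <- p[sel]
    }
    out <- lab
  }
  array(out, dim(volume))
}

#' Jacobian determinant of a deformation
#'
#' Finite-difference Jacobian determinant of the map `x + d(x)`, evaluated on
#' the interior of the grid; positive values everywhere indicate the
#' deformation preserves topology.
#'
#' @param d a [deformation_field()].
#' @return array of shape `shape - 2` (interior voxels).
#' @export
jacobian_det <- function(d) {
  shape <- field_shape(d)
  nd <- field_ndim(d)
  # central differences of phi = x + d(x)
  J <- vector("list", nd * nd)
  for (a in seq_len(nd)) {
    comp <- field_comp(d, a)
    for (b in seq_len(nd)) {
      der <- (shift_axis(comp, b, -1) - shift_axis(comp, b, 1)) / 2
      if (a == b) der <- der + 1
      J[[(a - 1) * nd + b]] <- crop_interior(der)
    }
  }
  if (nd == 2L) {
    J[[1]] * J[[4]] - J[[2]] * J[[3]]
  } else {
    J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
    J[[4]] * (J[[2]] * J[[9]] - J[[3]] * J[[8]]) +
    J[[7]] * (J[[2]] * J[[6]] - J[[3]] * J[[5]])
  }
}

crop_interior <- function(x) {
  shape <- dim(x)
  idx <- lapply(shape, function(n) 2:(n - 1))
  do.call(`[`, c(list(x), idx))
}
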