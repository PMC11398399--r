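# Cubic B-spline fields on regular control grids. Control points are placed
# at voxel positions 1 + (j - 2) * spacing, extending one control beyond each
# end of the grid so the basis forms a partition of unity over the volume.

#' Cubic B-spline kernel
#'
#' The standard centred cubic B-spline, support `|t| < 2`.
#' @param t numeric vector of offsets in units of the control spacing.
#' @return kernel values.
#' @export
bspline3 <- function(t) {
  at <- abs(t)
  out <- numeric(length(t))
  i1 <- at < 1
  i2 <- !i1 & at < 2
  out[i1] <- (4 - 6 * at[i1]^2 + 3 * at[i1]^3) / 6
  out[i2] <- (2 - at[i2])^3 / 6
  out
}

#' Number of control points needed along an axis
#' @param n voxels along the axis.
#' @param spacing control-point spacing in voxels (>= 2).
#' @return integer count.
#' @export
bspline_n_ctrl <- function(n, spacing) {
  if (spacing < 2) stop("control spacing must be >= 2 voxels")
  as.integer(ceiling((n - 1) / spacing) + 3L)
}

# Dense basis matrix (n x n_ctrl) for one axis.
bspline_basis <- function(n, spacing) {
  nc <- bspline_n_ctrl(n, spacing)
  ctrl <- 1 + (seq_len(nc) - 2) * spacing
  B <- outer(seq_len(n), ctrl, function(x, c) bspline3((x - c) / spacing))
  B[abs(B) < 1e-14] <- 0
  B
}

#' Evaluate a B-spline field on a dense grid
#'
#' Tensor-product cubic B-spline interpolation of control values. If
#' `control_values` has one more dimension than `target_shape`, the last
#' dimension indexes vector components (e.g. an SVF); otherwise a scalar
#' field is produced.
#'
#' @param control_values array of control-point values; each spatial extent
#'   must equal [bspline_n_ctrl()] for the corresponding axis.
#' @param spacing control spacing in voxels (scalar or per axis, >= 2).
#' @param target_shape voxel counts of the dense grid.
#' @return dense array of shape `target_shape` (plus a component axis if
#'   present in the input).
#' @export
bspline_field <- function(control_values, spacing, target_shape) {
  d <- length(target_shape)
  spacing <- rep(spacing, length.out = d)
  dm <- dim(control_values)
  has_comp <- length(dm) == d + 1L
  if (!has_comp && length(dm) != d)
    stop("control_values rank does not match target_shape")
  for (a in seq_len(d)) {
    need <- bspline_n_ctrl(target_shape[a], spacing[a])
    if (dm[a] != need)
      stop(sprintf(
        "axis %d: %d control points supplied, %d required (cubic support)",
        a, dm[a], need))
  }
  X <- control_values
  for (a in seq_len(d)) {
    X <- mode_mult(X, bspline_basis(target_shape[a], spacing[a]), a)
  }
  X
}

# Adjoint of bspline_field: project a dense array (same layout) back onto the
# control grid, i.e. multiply by the transposed basis along each spatial mode.
bspline_project <- function(dense, spacing, target_shape) {
  d <- length(target_shape)
  spacing <- rep(spacing, length.out = d)
  X <- dense
  for (a in seq_len(d)) {
    X <- mode_mult(X, t(bspline_basis(target_shape[a], spacing[a])), a)
  }
  X
}

# Project with element-squared basis matrices: maps per-voxel curvature
# scalars to the diagonal of the Gauss-Newton Hessian in control space
# (separable approximation sum_i B_ij^2 c_i).
bspline_project_sq <- function(dense, spacing, target_shape) {
  d <- length(target_shape)
  spacing <- rep(spacing, length.out = d)
  X <- dense
  for (a in seq_len(d)) {
    X <- mode_mult(X, t(bspline_basis(target_shape[a], spacing[a])^2), a)
  }
  X
}

#' Random smooth SVF from B-spline control points
#'
#' Draws i.i.d. normal control values, evaluates the dense tensor-product
#' B-spline field and rescales it so the largest displacement-rate magnitude
#' equals `amplitude` (voxels). Amplitudes up to `0.4 * control_spacing` are
#' guaranteed safe: the exponential then has positive Jacobian determinant
#' everywhere (documented bound, checked in the test suite).
#'
#' @param grid_shape voxel counts (2D or 3D).
#' @param control_spacing control spacing in voxels (>= 2).
#' @param amplitude maximum velocity magnitude in voxels; 0 gives a zero field.
#' @param seed integer seed; identical arguments give identical fields.
#' @return a [velocity_field()].
#' @export
sample_svf <- function(grid_shape, control_spacing, amplitude, seed) {
  if (control_spacing < 2) stop("control_spacing must be >= 2 voxels")
  if (amplitude < 0) stop("amplitude must be >= 0")
  d <- length(grid_shape)
  nc <- vapply(seq_len(d), function(a)
    bspline_n_ctrl(grid_shape[a], control_spacing), integer(1))
  disp <- with_seed(seed, array(stats::rnorm(prod(nc) * d), c(nc, d)))
  dense <- bspline_field(disp, control_spacing, grid_shape)
  mag <- sqrt(rowSums(matrix(dense, ncol = d)^2))
  m <- max(mag)
  dense <- if (m > 0 && amplitude > 0) dense * (amplitude / m) else dense * 0
  velocity_field(array(dense, c(grid_shape, d)))
}
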