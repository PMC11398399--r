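# Bending energy: the sum of squared second spatial derivatives of a field,
# approximated by finite differences on the grid interior. Zero for any
# affine field; the standard smoothness regulariser for B-spline and SVF
# registration.

# Second difference along an axis, boundary slices zeroed ('valid' region).
d2_axis <- function(f, axis) {
  out <- shift_axis(f, axis, 1) + shift_axis(f, axis, -1) - 2 * f
  zero_boundary(out, axis)
}

# Central first difference along an axis, boundary slices zeroed.
d1_axis <- function(f, axis) {
  out <- (shift_axis(f, axis, -1) - shift_axis(f, axis, 1)) / 2
  zero_boundary(out, axis)
}

zero_boundary <- function(x, axis) {
  shape <- dim(x)
  n <- shape[axis]
  pre <- prod(shape[seq_len(axis - 1L)])
  post <- prod(shape) / (pre * n)
  dim(x) <- c(pre, n, post)
  x[, c(1L, n), ] <- 0
  dim(x) <- shape
  x
}

# Adjoints. For inputs supported away from the zeroed boundary these are the
# exact transposes of d2_axis / d1_axis (verified by a dot-product test).
d2t_axis <- function(r, axis) {
  r <- zero_boundary(r, axis)
  shift_axis(r, axis, 1) + shift_axis(r, axis, -1) - 2 * r
}

d1t_axis <- function(r, axis) {
  r <- zero_boundary(r, axis)
  (shift_axis(r, axis, 1) - shift_axis(r, axis, -1)) / 2
}

field_components <- function(field) {
  if (inherits(field, "velocity_field") || inherits(field, "deformation_field")) {
    lapply(seq_len(field_ndim(field)), function(a) field_comp(field, a))
  } else {
    list(field)
  }
}

#' Bending energy of a field
#'
#' Sum over voxels and components of the squared second spatial derivatives
#' (including mixed terms, counted twice), computed with finite differences on
#' the grid interior. Affine fields have zero energy; scaling a field by
#' `a` multiplies the energy by `a^2`.
#'
#' @param field a [velocity_field()], [deformation_field()] or plain array
#'   (scalar field).
#' @return non-negative scalar.
#' @export
bending_energy <- function(field) {
  comps <- field_components(field)
  d <- length(dim(comps[[1]]))
  e <- 0
  for (f in comps) {
    for (a in seq_len(d)) e <- e + sum(d2_axis(f, a)^2)
    for (a in seq_len(d - 1)) for (b in (a + 1):d) {
      e <- e + 2 * sum(d1_axis(d1_axis(f, a), b)^2)
    }
  }
  e
}

# Gradient of bending_energy with respect to the dense field values; returns
# an array shaped like the input component stack.
bending_energy_grad <- function(field) {
  comps <- field_components(field)
  d <- length(dim(comps[[1]]))
  gl <- lapply(comps, function(f) {
    g <- array(0, dim(f))
    for (a in seq_len(d)) g <- g + 2 * d2t_axis(d2_axis(f, a), a)
    for (a in seq_len(d - 1)) for (b in (a + 1):d) {
      g <- g + 4 * d1t_axis(d1t_axis(d1_axis(d1_axis(f, a), b), b), a)
    }
    g
  })
  if (length(gl) == 1L) gl[[1]] else {
    array(unlist(gl), c(dim(gl[[1]]), length(gl)))
  }
}
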