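# Joint blockface alignment: similarity poses (translation, rotation,
# isotropic log-scale) for each tissue block, optimised against normalised
# cross-correlation with the reference volume plus a differentiable
# overlap/gap regulariser, hierarchically from shared-group poses down to
# independent blocks.

# --- pose algebra -----------------------------------------------------------

rot_matrix <- function(rot) {
  if (length(rot) == 1L) {
    c1 <- cos(rot); s1 <- sin(rot)
    matrix(c(c1, s1, -s1, c1), 2, 2)
  } else {
    a <- rot[1]; b <- rot[2]; g <- rot[3]
    Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rx
  }
}

# Derivatives of the rotation matrix w.r.t. each angle.
rot_matrix_grad <- function(rot) {
  if (length(rot) == 1L) {
    c1 <- cos(rot); s1 <- sin(rot)
    list(matrix(c(-s1, c1, -c1, -s1), 2, 2))
  } else {
    a <- rot[1]; b <- rot[2]; g <- rot[3]
    Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
    dRx <- matrix(c(0, 0, 0, 0, -sin(a), cos(a), 0, -cos(a), -sin(a)), 3, 3)
    dRy <- matrix(c(-sin(b), 0, -cos(b), 0, 0, 0, cos(b), 0, -sin(b)), 3, 3)
    dRz <- matrix(c(-sin(g), cos(g), 0, -cos(g), -sin(g), 0, 0, 0, 0), 3, 3)
    list(Rz %*% Ry %*% dRx, Rz %*% dRy %*% Rx, dRz %*% Ry %*% Rx)
  }
}

pose_npar <- function(d) if (d == 3L) 7L else 4L

pose_to_vec <- function(pose) c(pose$trans, pose$rot, pose$logscale)

vec_to_pose <- function(p, d) {
  nr <- if (d == 3L) 3L else 1L
  list(trans = p[seq_len(d)], rot = p[d + seq_len(nr)],
       logscale = p[d + nr + 1L])
}

# Forward map: block-frame reference positions X (n x d) -> posed positions.
pose_forward <- function(pose, center, X) {
  R <- rot_matrix(pose$rot)
  s <- exp(pose$logscale)
  sweep(sweep(X, 2, center) %*% (s * t(R)), 2, center + pose$trans, `+`)
}

# Inverse map: reference positions Y -> block-frame positions.
pose_inverse <- function(pose, center, Y) {
  R <- rot_matrix(pose$rot)
  s <- exp(pose$logscale)
  sweep(sweep(Y, 2, center + pose$trans) %*% (R / s), 2, center, `+`)
}

# d(pose_inverse)/d(pose parameters): list of n x d matrices, one per
# parameter in pose_to_vec order.
pose_inverse_grad <- function(pose, center, Y) {
  d <- length(pose$trans)
  R <- rot_matrix(pose$rot)
  s <- exp(pose$logscale)
  Yc <- sweep(Y, 2, center + pose$trans)
  out <- vector("list", pose_npar(d))
  for (j in seq_len(d)) {            # translation: x = R^T (y - c - t)/s + c
    out[[j]] <- matrix(rep(-R[j, ] / s, each = nrow(Y)), nrow(Y), d)
  }
  dR <- rot_matrix_grad(pose$rot)
  for (k in seq_along(dR)) {
    out[[d + k]] <- Yc %*% (dR[[k]] / s)
  }
  out[[pose_npar(d)]] <- -(Yc %*% (R / s))   # d/d logscale
  out
}

# Zero-pad an array by one voxel on every side so its linear interpolant
# (and gradient) decays continuously to zero outside the support; keeps the
# overlap/gap penalty differentiable in the poses.
pad_zero <- function(x) {
  shape <- dim(x)
  out <- array(0, shape + 2)
  idx <- lapply(shape, function(n) 1 + seq_len(n))
  do.call(`[<-`, c(list(out), idx, list(x)))
}

# Soft-warp a block's mask (or image) onto the reference grid.
warp_block_to_ref <- function(block, pose, ref_shape, what = c("mask", "image")) {
  what <- match.arg(what)
  Y <- voxel_coords(ref_shape)
  X <- pose_inverse(pose, block$center, Y)
  Xl <- sweep(X, 2, block$origin - 2)   # block-local coords in padded array
  src <- pad_zero(if (what == "mask") block$mask else block$image)
  array(interp_linear(src, Xl, clamp = TRUE), ref_shape)
}

# --- overlap/gap regulariser -----------------------------------------------

#' Overlap/gap penalty for a set of posed blocks
#'
#' Soft-warps each block's mask onto the reference grid, forms the voxelwise
#' sum of mask values and penalises its squared deviation from 1 over the
#' reference foreground: both overlaps (sum > 1) and gaps (sum < 1) are
#' punished, and a perfect tiling scores exactly zero. Smooth in the pose
#' parameters; the analytic gradient is available via
#' `overlap_gap_penalty_grad`.
#'
#' @param blocks a [make_blocks()] block set.
#' @param poses optional list of poses (defaults to the stored ones).
#' @return non-negative scalar.
#' @export
overlap_gap_penalty <- function(blocks, poses = NULL) {
  if (length(blocks$blocks) == 0) return(0)
  if (is.null(poses)) poses <- lapply(blocks$blocks, `[[`, "pose")
  F <- blocks$foreground
  nf <- sum(F)
  if (nf == 0) return(0)
  S <- array(0, blocks$ref_shape)
  for (i in seq_along(blocks$blocks)) {
    S <- S + warp_block_to_ref(blocks$blocks[[i]], poses[[i]],
                               blocks$ref_shape)
  }
  sum((S - 1)^2 * F) / nf
}

# Analytic gradient of the penalty w.r.t. each block's pose vector.
overlap_gap_penalty_grad <- function(blocks, poses) {
  d <- length(blocks$ref_shape)
  F <- blocks$foreground
  nf <- sum(F)
  Y <- voxel_coords(blocks$ref_shape)
  S <- array(0, blocks$ref_shape)
  Xs <- vector("list", length(blocks$blocks))
  for (i in seq_along(blocks$blocks)) {
    b <- blocks$blocks[[i]]
    Xl <- sweep(pose_inverse(poses[[i]], b$center, Y), 2, b$origin - 2)
    Xs[[i]] <- Xl
    S <- S + array(interp_linear(pad_zero(b$mask), Xl, clamp = TRUE),
                   blocks$ref_shape)
  }
  resid <- 2 * (S - 1) * F / nf
  lapply(seq_along(blocks$blocks), function(i) {
    b <- blocks$blocks[[i]]
    gm <- interp_grad(pad_zero(b$mask), Xs[[i]])  # d mask / d local coords
    dX <- pose_inverse_grad(poses[[i]], b$center, Y)
    vapply(dX, function(D) sum(as.vector(resid) * rowSums(gm * D)),
           numeric(1))
  })
}

# --- joint hierarchical registration ---------------------------------------

# NCC similarity of all blocks against the reference at given poses; returns
# the (negated) mean of per-block NCC weighted by foreground voxel count.
blocks_ncc <- function(blocks, poses, reference) {
  tot <- 0; wsum <- 0
  for (i in seq_along(blocks$blocks)) {
    b <- blocks$blocks[[i]]
    sel <- b$mask > 0
    X <- voxel_coords(b$shape)[sel, , drop = FALSE]
    Y <- pose_forward(poses[[i]], b$center,
                      sweep(X, 2, b$origin - 1, `+`))
    ref_v <- interp_linear(reference, Y, fill = NA)
    ok <- !is.na(ref_v)
    if (sum(ok) < 8 || stats::sd(ref_v[ok]) == 0 ||
        stats::sd(b$image[sel][ok]) == 0) next
    tot <- tot + sum(ok) * stats::cor(b$image[sel][ok], ref_v[ok])
    wsum <- wsum + sum(ok)
  }
  if (wsum == 0) return(NA_real_)
  tot / wsum
}

#' Hierarchical joint similarity registration of blocks to a reference
#'
#' Optimises similarity poses (translation, rotation, isotropic log-scale)
#' for every block against the reference volume, maximising intensity NCC
#' while discouraging overlaps and gaps between blocks. The optimisation is
#' hierarchical: early levels force groups of blocks to share pose
#' parameters (reflecting how the tissue was cut), later levels free each
#' block; each level initialises the next and the objective never increases
#' across levels.
#'
#' @param blocks a [make_blocks()] block set (its stored poses are the
#'   initialisation).
#' @param reference 3D (or 2D) reference intensity array.
#' @param hierarchy_schedule list of character/factor vectors, one per level,
#'   assigning each block to a parameter-sharing group; defaults to the
#'   blocks' group tags followed by one group per block.
#' @param weights list with `overlap` (penalty weight, default 1).
#' @param maxit optimiser iteration cap per level.
#' @return list with `poses`, per-level `objective` values, and `trace`.
#' @export
register_blocks_joint <- function(blocks, reference,
                                  hierarchy_schedule = NULL,
                                  weights = list(overlap = 1),
                                  maxit = 50) {
  nb <- length(blocks$blocks)
  d <- length(blocks$ref_shape)
  npar <- pose_npar(d)
  if (is.null(hierarchy_schedule)) {
    hierarchy_schedule <- list(
      vapply(blocks$blocks, `[[`, character(1), "group"),
      as.character(seq_len(nb)))
  }
  poses <- lapply(blocks$blocks, `[[`, "pose")
  # zero-support guard
  ncc0 <- blocks_ncc(blocks, poses, reference)
  if (is.na(ncc0)) {
    warning("no intensity support between blocks and reference; ",
            "returning identity poses")
    ident <- lapply(blocks$blocks, function(b)
      list(trans = rep(0, d), rot = rep(0, if (d == 3) 3 else 1),
           logscale = 0))
    return(list(poses = ident, objective = NA_real_, trace = NULL))
  }
  objective <- function(poses) {
    v <- blocks_ncc(blocks, poses, reference)
    if (is.na(v)) return(1e6)
    -v + weights$overlap * overlap_gap_penalty(blocks, poses)
  }
  level_obj <- numeric(0)
  for (lev in seq_along(hierarchy_schedule)) {
    grp <- as.character(hierarchy_schedule[[lev]])
    ugrp <- unique(grp)
    # shared level: one pose per group, applied about the group centre;
    # initialise from the first member's current pose
    par0 <- unlist(lapply(ugrp, function(g)
      pose_to_vec(poses[[which(grp == g)[1]]])))
    centers <- lapply(ugrp, function(g) {
      members <- which(grp == g)
      colMeans(do.call(rbind,
        lapply(blocks$blocks[members], `[[`, "center")))
    })
    expand <- function(par) {
      out <- poses
      for (gi in seq_along(ugrp)) {
        gp <- vec_to_pose(par[(gi - 1) * npar + seq_len(npar)], d)
        members <- which(grp == ugrp[gi])
        for (m in members) {
          # shared pose acts about the group centre: re-express about the
          # block centre so downstream code sees a per-block pose
          b <- blocks$blocks[[m]]
          R <- rot_matrix(gp$rot); s <- exp(gp$logscale)
          dc <- b$center - centers[[gi]]
          tr <- as.vector(s * R %*% dc) - dc + gp$trans
          out[[m]] <- list(trans = tr, rot = gp$rot,
                           logscale = gp$logscale)
        }
      }
      out
    }
    f0 <- objective(expand(par0))
    opt <- stats::optim(par0, function(p) objective(expand(p)),
                        method = "L-BFGS-B",
                        control = list(maxit = maxit,
                                       parscale = rep(c(1, 0.05, 0.05)[
                                         c(rep(1, d),
                                           rep(2, if (d == 3) 3 else 1), 3)],
                                         length(ugrp))))
    if (is.finite(opt$value) && opt$value <= f0) {
      poses <- expand(opt$par)
      level_obj <- c(level_obj, opt$value)
    } else {
      level_obj <- c(level_obj, f0)
    }
  }
  list(poses = poses, objective = level_obj,
       trace = list(schedule = hierarchy_schedule))
}

# Pose error against ground truth: translation (voxels) and rotation (deg).
pose_error <- function(poses, poses_true) {
  terr <- vapply(seq_along(poses), function(i)
    sqrt(sum((poses[[i]]$trans - poses_true[[i]]$trans)^2)), numeric(1))
  rerr <- vapply(seq_along(poses), function(i)
    max(abs(poses[[i]]$rot - poses_true[[i]]$rot)) * 180 / pi, numeric(1))
  list(trans_voxels = terr, rot_deg = rerr)
}
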