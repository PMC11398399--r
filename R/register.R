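# Shared nonlinear registration engine: a B-spline-parameterised stationary
# velocity field optimised against a pluggable similarity term plus a bending
# energy penalty. Used by the histology reconstruction (local NCC), the atlas
# builder (label likelihood) and the Bayesian segmenter (GMM likelihood).
#
# The objective is evaluated with the full SVF exponential; gradients use the
# small-deformation approximation d(exp v)/dv = Id, which is standard for the
# modest per-step displacements involved. Steps that fail to improve the
# objective are rejected, so the reported objective never increases.

# A metric is a list: channels (list of moving arrays), fill (per channel)
# or clamp = TRUE (border replication; used for probability channels, whose
# objective must stay continuous at the field of view edge), and
# value_grad(warped_mat) -> list(value, gmat) with gmat the per-voxel loss
# derivative for each channel (matrix npts x nchan).

metric_ssd <- function(fixed, moving) {
  n <- length(fixed)
  fv <- as.vector(fixed)
  list(
    channels = list(moving), fill = 0,
    value_grad = function(wm) {
      r <- wm[, 1] - fv
      list(value = mean(r^2), gmat = matrix(2 * r / n, ncol = 1))
    })
}

metric_lncc <- function(fixed, moving, sigma = 2, eps = 1e-5) {
  if (stats::sd(as.vector(fixed)) == 0)
    stop("local NCC undefined: fixed image is constant")
  if (stats::sd(as.vector(moving)) == 0)
    stop("local NCC undefined: moving image is constant")
  shp <- dim(fixed)
  list(
    channels = list(moving), fill = 0,
    value_grad = function(wm) {
      w <- array(wm[, 1], shp)
      list(value = -lncc(fixed, w, sigma, eps),
           gmat = matrix(-as.vector(lncc_grad_moving(fixed, w, sigma, eps)),
                         ncol = 1))
    })
}

# Label likelihood against warped atlas probability channels, with a weak
# Dirichlet prior so logs stay finite: sum log((p_v(l_v)+alpha)/(1+alpha*L)).
# Each voxel reads a single channel (its observed label), so the engine uses
# the sparse per-label path: only |{v: l_v = l}| points are interpolated in
# channel l.
metric_labellik <- function(label_idx, atlas_channels, alpha = 1e-5) {
  L <- length(atlas_channels)
  n <- length(label_idx)
  norm <- log1p(alpha * L)
  list(
    channels = atlas_channels, clamp = TRUE, precond = TRUE,
    label_idx = label_idx,
    value_grad_sparse = function(p) {
      list(value = -(mean(log(p + alpha)) - norm),
           gvec = -1 / (n * (p + alpha)))
    })
}

# Mixture likelihood: lik is a npts x C matrix of per-voxel class likelihoods
# (fixed during the deformation update, rows scaled to sum 1); channels are
# class-aggregated atlas probability maps to be warped. A Dirichlet-style
# floor `alpha` is mixed into the priors so the log stays bounded where the
# atlas contradicts the intensities (the analogue of the atlas data term's
# pseudo-count).
metric_gmmlik <- function(lik, atlas_class_channels, alpha = 1e-5) {
  n <- nrow(lik)
  C <- ncol(lik)
  stopifnot(length(atlas_class_channels) == C)
  channels <- lapply(atlas_class_channels, function(ch)
    (1 - alpha) * ch + alpha / C)
  list(
    channels = channels, clamp = TRUE, precond = TRUE,
    value_grad = function(wm) {
      den <- rowSums(wm * lik)
      list(value = -mean(log(den)), gmat = -lik / (n * den))
    })
}

#' Optimise a B-spline SVF against a similarity metric
#'
#' Internal engine behind [register_section_nonlinear()],
#' [register_labels_to_atlas()] and the segmentation deformation update.
#'
#' @param metric metric object (see `metric_ssd`, `metric_lncc`, ...).
#' @param shape grid shape.
#' @param spacing control-point spacing in voxels.
#' @param reg_weight bending-energy weight (applied to the velocity field).
#' @param exp_steps squarings for the SVF exponential during optimisation.
#' @param maxit L-BFGS iteration cap.
#' @param init optional initial control-value array.
#' @return list with `v` ([velocity_field()]), control values, objective
#'   trace `objective` (initial and final; final <= initial by construction)
#'   and `convergence` from the optimiser.
#' @keywords internal
optimize_svf <- function(metric, shape, spacing, reg_weight = 0.01,
                         exp_steps = 5, maxit = 40, init = NULL) {
  d <- length(shape)
  nc <- vapply(seq_len(d), function(a)
    bspline_n_ctrl(shape[a], spacing), integer(1))
  cdim <- c(nc, d)
  if (is.null(init)) init <- array(0, cdim)
  stopifnot(identical(as.integer(dim(init)), as.integer(cdim)))
  base <- voxel_coords(shape)
  nch <- length(metric$channels)
  clamp <- isTRUE(metric$clamp)
  fill <- rep(metric$fill %||% 0, length.out = nch)
  sparse <- !is.null(metric$label_idx)
  label_groups <- if (sparse)
    split(seq_along(metric$label_idx), metric$label_idx)
  # precomputed central-difference gradient images per channel: smoother and
  # cheaper than differentiating the linear interpolant at each step
  chan_grad <- lapply(metric$channels, img_gradient)
  # bending penalty on the control lattice: second differences of the
  # control values approximate the field's derivatives up to the spacing
  # scaling, at a fraction of the dense cost
  # per-voxel normalisation keeps reg_weight comparable to the (mean)
  # similarity terms regardless of grid size
  bend_scale <- spacing^(d - 4) / prod(shape)

  evaluate <- function(par, want_grad) {
    C <- array(par, cdim)
    dense <- bspline_field(C, spacing, shape)
    vf <- velocity_field(dense)
    df <- exp_svf(vf, exp_steps)
    pts <- base + disp_matrix(df)
    prep <- interp_prep(shape, pts, clamp = clamp)
    Cc <- structure(list(disp = C), class = "velocity_field")
    pen <- reg_weight * bend_scale * bending_energy(Cc)
    if (sparse) {
      p <- numeric(nrow(pts))
      for (lname in names(label_groups)) {
        idx <- label_groups[[lname]]
        p[idx] <- interp_apply(prep_subset(prep, idx),
                               metric$channels[[as.integer(lname)]])
      }
      vg <- metric$value_grad_sparse(p)
    } else {
      wm <- matrix(0, nrow(pts), nch)
      for (ch in seq_len(nch)) {
        wm[, ch] <- interp_apply(prep, metric$channels[[ch]],
                                 fill = fill[ch])
      }
      vg <- metric$value_grad(wm)
    }
    value <- vg$value + pen
    if (!want_grad) return(list(value = value))
    gpts <- matrix(0, nrow(pts), d)
    if (sparse) {
      for (lname in names(label_groups)) {
        idx <- label_groups[[lname]]
        sub <- prep_subset(prep, idx)
        l <- as.integer(lname)
        for (a in seq_len(d)) {
          gpts[idx, a] <- vg$gvec[idx] *
            interp_apply(sub, chan_grad[[l]][[a]])
        }
      }
    } else {
      prep_cl <- if (clamp) prep else interp_prep(shape, pts, clamp = TRUE)
      for (ch in seq_len(nch)) {
        for (a in seq_len(d)) {
          gpts[, a] <- gpts[, a] + vg$gmat[, ch] *
            interp_apply(prep_cl, chan_grad[[ch]][[a]])
        }
      }
    }
    grad <- bspline_project(array(gpts, c(shape, d)), spacing, shape) +
      reg_weight * bend_scale * bending_energy_grad(Cc)
    out <- list(value = value, grad = as.vector(grad))
    if (isTRUE(metric$precond)) {
      # Fisher-style diagonal: n * sum_i B_ij^2 g_i^2 per control point,
      # plus a bound on the bending-operator curvature
      hd <- bspline_project_sq(array(gpts^2, c(shape, d)) * nrow(pts),
                               spacing, shape)
      out$hdiag <- as.vector(hd) + reg_weight * bend_scale * 64
    }
    out
  }

  cache <- new.env(parent = emptyenv())
  get_eval <- function(par) {
    key <- par
    if (!is.null(cache$par) && identical(cache$par, key)) return(cache$res)
    res <- evaluate(par, want_grad = TRUE)
    cache$par <- key
    cache$res <- res
    res
  }

  par <- as.vector(init)
  if (isTRUE(metric$precond)) {
    # Damped diagonally-preconditioned Gauss-Newton descent with
    # backtracking. Log-likelihood data terms have per-voxel curvature
    # ~ 1/(p+alpha)^2 that varies over orders of magnitude; raw gradient
    # steps stall, whereas Fisher scaling equalises them. Monotone by
    # construction.
    cur <- evaluate(par, want_grad = TRUE)
    f0 <- cur$value
    step <- NULL
    rel <- Inf
    for (it in seq_len(maxit)) {
      h <- cur$hdiag
      damp <- 0.05 * max(h) + 1e-12
      dir <- cur$grad / (h + damp)
      dmax <- max(abs(dir))
      if (!is.finite(dmax) || dmax < 1e-14) break
      # steps are sized in control-point displacement units (voxels)
      if (is.null(step)) step <- 0.5 / dmax
      step <- min(step, 2 / dmax)
      improved <- FALSE
      for (bt in seq_len(12)) {
        cand <- par - step * dir
        fc <- evaluate(cand, want_grad = FALSE)$value
        if (is.finite(fc) && fc < cur$value - 1e-12) {
          rel <- (cur$value - fc) / max(abs(cur$value), 1e-12)
          par <- cand
          cur <- evaluate(par, want_grad = TRUE)
          step <- step * 2
          improved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!improved) break
      if (rel < 1e-7) break
    }
    val <- cur$value
    conv <- 0L
  } else {
    f0 <- evaluate(par, want_grad = FALSE)$value
    opt <- stats::optim(par,
                        fn = function(p) get_eval(p)$value,
                        gr = function(p) get_eval(p)$grad,
                        method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 1e7))
    if (!is.finite(opt$value) || opt$value > f0) {
      # reject non-improving runs: the engine's contract is monotone
      par <- as.vector(init)
      val <- f0
    } else {
      par <- opt$par
      val <- opt$value
    }
    conv <- opt$convergence
  }
  C <- array(par, cdim)
  list(v = velocity_field(array(bspline_field(C, spacing, shape),
                                c(shape, d))),
       control = C, spacing = spacing,
       objective = c(initial = f0, final = val),
       convergence = conv)
}
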