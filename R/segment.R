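# Bayesian segmentation: joint estimation of an atlas deformation, one
# Gaussian mixture per tissue class, and a smooth bias field. The intensity
# model lives in the log domain, where the multiplicative bias becomes
# additive and its M-step is a responsibility-weighted least-squares solve.

variance_floor_frac <- 1e-6

#' Fit the GMM and bias field by Expectation Maximisation
#'
#' Alternates the E-step (class/component responsibilities given the priors,
#' the mixture and the current bias-corrected intensities) with closed-form
#' M-step updates for the weights, means and variances and a
#' responsibility-weighted least-squares update of the bias coefficients in
#' the log domain. The observed-data log-likelihood is non-decreasing (within
#' numerical tolerance) and iteration stops at relative change `tol`.
#'
#' @param log_intensities numeric vector of in-mask log intensities.
#' @param class_priors matrix (voxels x classes) of per-voxel class priors,
#'   rows summing to 1.
#' @param clustering a [tissue_clustering()] (class names/count).
#' @param bias_basis matrix (voxels x n_basis) of bias basis functions, or
#'   `NULL` to disable the bias model.
#' @param n_components_per_class integer (recycled per class).
#' @param tol relative log-likelihood change for convergence.
#' @param max_iters EM iteration cap.
#' @return list with `gmm` (class `gmm_params`), `bias` (class `bias_model`:
#'   coefficients and fitted log-bias), `responsibilities` (voxels x
#'   classes), the `loglik` trace and `collapsed` component flags.
#' @export
em_fit <- function(log_intensities, class_priors, clustering = NULL,
                   bias_basis = NULL, n_components_per_class = 1,
                   tol = 1e-6, max_iters = 100) {
  y <- as.numeric(log_intensities)
  V <- length(y)
  if (V == 0) stop("empty mask: no voxels to fit")
  C <- ncol(class_priors)
  stopifnot(nrow(class_priors) == V)
  ncomp <- rep(n_components_per_class, length.out = C)
  floor_var <- variance_floor_frac * stats::var(y)
  if (!is.finite(floor_var) || floor_var == 0) floor_var <- 1e-12
  nb <- if (is.null(bias_basis)) 0L else ncol(bias_basis)
  beta <- rep(0, nb)
  bias <- rep(0, V)

  # initialise means by prior-weighted moments, components spread +/- 1 sd
  means <- vars <- wts <- vector("list", C)
  m0 <- v0 <- numeric(C)
  for (c in seq_len(C)) {
    w <- class_priors[, c]
    sw <- sum(w)
    m0[c] <- if (sw > 0) sum(w * y) / sw else mean(y)
    v <- if (sw > 0) sum(w * (y - m0[c])^2) / sw else stats::var(y)
    v0[c] <- max(v, floor_var)
  }
  # uninformative priors give identical weighted means; spread such classes
  # over the intensity quantiles so EM can break the symmetry
  dup <- duplicated(round(m0 / max(stats::sd(y), 1e-12), 6))
  if (any(dup)) {
    m0 <- stats::quantile(y, (seq_len(C) - 0.5) / C, names = FALSE)
  }
  for (c in seq_len(C)) {
    k <- ncomp[c]
    off <- if (k > 1) seq(-1, 1, length.out = k) * sqrt(v0[c]) else 0
    means[[c]] <- m0[c] + off
    vars[[c]] <- rep(v0[c], k)
    wts[[c]] <- rep(1 / k, k)
  }

  comp_class <- rep(seq_len(C), ncomp)
  ll_trace <- numeric(0)
  collapsed <- FALSE
  R_class <- NULL
  for (it in seq_len(max_iters)) {
    yc <- y - bias
    # E-step: joint responsibilities over (class, component)
    logd <- matrix(-Inf, V, length(comp_class))
    j <- 0
    for (c in seq_len(C)) for (k in seq_along(means[[c]])) {
      j <- j + 1
      logd[, j] <- log(pmax(class_priors[, c], 1e-300)) +
        log(wts[[c]][k]) +
        stats::dnorm(yc, means[[c]][k], sqrt(vars[[c]][k]), log = TRUE)
    }
    mx <- apply(logd, 1, max)
    pr <- exp(logd - mx)
    den <- rowSums(pr)
    ll <- sum(mx + log(den))
    R <- pr / den
    ll_trace <- c(ll_trace, ll)
    if (it > 1) {
      rel <- abs(ll - ll_trace[it - 1]) /
        max(1, abs(ll_trace[it - 1]))
      if (rel < tol) break
    }
    # M-step: weights, means, variances
    j <- 0
    for (c in seq_len(C)) {
      nk <- numeric(length(means[[c]]))
      for (k in seq_along(means[[c]])) {
        j <- j + 1
        r <- R[, j]
        n <- sum(r)
        nk[k] <- n
        if (n < 1e-8) {
          collapsed <- TRUE
          next
        }
        means[[c]][k] <- sum(r * yc) / n
        v <- sum(r * (yc - means[[c]][k])^2) / n
        if (v < floor_var) {
          v <- floor_var
          collapsed <- TRUE
        }
        vars[[c]][k] <- v
      }
      tot <- sum(nk)
      if (tot > 0) wts[[c]] <- pmax(nk, 1e-12) / sum(pmax(nk, 1e-12))
    }
    # M-step: bias coefficients by weighted least squares in the log domain
    if (nb > 0) {
      prec <- rep(0, V)
      target <- rep(0, V)
      j <- 0
      for (c in seq_len(C)) for (k in seq_along(means[[c]])) {
        j <- j + 1
        prec_j <- R[, j] / vars[[c]][k]
        prec <- prec + prec_j
        target <- target + prec_j * (y - means[[c]][k])
      }
      A <- crossprod(bias_basis, bias_basis * prec)
      b <- crossprod(bias_basis, target)
      beta <- tryCatch(as.vector(solve(A, b)), error = function(e) beta)
      bias <- as.vector(bias_basis %*% beta)
    }
  }
  # class-level responsibilities
  R_class <- matrix(0, V, C)
  for (c in seq_len(C)) {
    R_class[, c] <- rowSums(R[, comp_class == c, drop = FALSE])
  }
  gmm <- structure(list(weights = wts, means = means, variances = vars,
                        class_names = if (!is.null(clustering))
                          clustering$class_names else paste0("class",
                                                             seq_len(C))),
                   class = "gmm_params")
  bias_model <- structure(list(coefficients = beta, log_bias = bias),
                          class = "bias_model")
  list(gmm = gmm, bias = bias_model, responsibilities = R_class,
       loglik = ll_trace, collapsed = collapsed)
}

# Per-voxel class likelihoods sum_k w_ck N(y - bias; m_ck, v_ck).
class_likelihood <- function(y, gmm, bias = 0) {
  yc <- y - bias
  C <- length(gmm$means)
  out <- matrix(0, length(y), C)
  for (c in seq_len(C)) for (k in seq_along(gmm$means[[c]])) {
    out[, c] <- out[, c] + gmm$weights[[c]][k] *
      stats::dnorm(yc, gmm$means[[c]][k], sqrt(gmm$variances[[c]][k]))
  }
  out
}

# Class-aggregated atlas channels under a clustering.
atlas_class_channels <- function(atlas, clustering) {
  shape <- atlas_shape(atlas)
  ci <- clustering$map[as.character(atlas$labels)]
  if (anyNA(ci)) stop("atlas labels not mapped to any tissue class: ",
                      paste(atlas$labels[is.na(ci)], collapse = ", "))
  C <- clustering$n_classes
  lapply(seq_len(C), function(c) {
    sel <- which(ci == c)
    ch <- array(0, shape)
    for (l in sel) ch <- ch + atlas_channel(atlas, l)
    ch
  })
}

#' Update the atlas deformation given the current GMM and bias
#'
#' Maximises the in-mask sum of `log sum_c Pi_c(x + d(x)) * N_c(y)` minus a
#' bending-energy penalty over the B-spline SVF control points, where `Pi_c`
#' are the class-aggregated atlas priors and `N_c` the per-voxel class
#' likelihoods (held fixed). The returned objective is never worse than at
#' entry.
#'
#' @param log_intensities full-grid array of log intensities.
#' @param atlas a [prob_atlas()].
#' @param gmm,bias current `gmm_params` / `bias_model`.
#' @param clustering a [tissue_clustering()].
#' @param mask logical array (in-mask voxels).
#' @param cp_spacing,reg_weight,maxit optimiser settings.
#' @param init optional initial control values (current SVF).
#' @return as [optimize_svf()], plus `min_jacobian`.
#' @export
optimize_deformation <- function(log_intensities, atlas, gmm, bias,
                                 clustering, mask, cp_spacing = 6,
                                 reg_weight = 0.01, maxit = 20,
                                 init = NULL) {
  shape <- atlas_shape(atlas)
  y <- as.vector(log_intensities)
  mv <- as.vector(mask)
  lik <- matrix(1, length(y), clustering$n_classes)
  bias_full <- rep(0, length(y))
  if (!is.null(bias) && length(bias$log_bias) == sum(mv)) {
    bias_full[mv] <- bias$log_bias
  }
  lik[mv, ] <- class_likelihood(y[mv], gmm, bias_full[mv])
  # scale likelihood rows for numerical range; a per-voxel constant factor
  # does not change the argmax of the objective
  rs <- pmax(rowSums(lik), 1e-300)
  lik <- lik / rs
  lik[!mv, ] <- 1 / clustering$n_classes   # constant rows: no gradient
  channels <- atlas_class_channels(atlas, clustering)
  res <- optimize_svf(metric_gmmlik(lik, channels), shape, cp_spacing,
                      reg_weight = reg_weight, maxit = maxit, init = init)
  if (!all(is.finite(res$objective)))
    stop("non-finite deformation objective")
  res$min_jacobian <- min(jacobian_det(exp_svf(res$v, 6)))
  res
}

#' Bayesian segmentation of an intensity volume with a probabilistic atlas
#'
#' Jointly estimates the tissue-class Gaussian mixtures, a multiplicative
#' bias field (additive in the log domain) and the atlas deformation that
#' best explain the image, by interleaving [em_fit()] with
#' [optimize_deformation()]. Voxels outside the mask (or with non-positive
#' intensity) are excluded.
#'
#' @param image intensity array.
#' @param atlas a [prob_atlas()].
#' @param clustering a [tissue_clustering()] covering all atlas labels.
#' @param mask logical array; required (no internal brain extraction).
#' @param options list: `n_components_per_class`, `bias_order` (polynomial
#'   degree; 0 disables), `cp_spacing`, `reg_weight`, `outer_iters`,
#'   `em_max_iters`, `em_tol`, `joint_tol`.
#' @return list with `posterior` (array `c(shape, L)`), `labels`
#'   ([label_volume()], argmax with ties to the lowest id), `volumes`
#'   (data.frame label/expected_volume_mm3), `gmm`, `bias`, `svf` and the
#'   joint objective trace.
#' @export
segment_bayes <- function(image, atlas, clustering, mask,
                          options = list()) {
  o <- utils::modifyList(list(n_components_per_class = 1, bias_order = 2,
                              cp_spacing = 6, reg_weight = 0.01,
                              outer_iters = 5, em_max_iters = 60,
                              em_tol = 1e-6, joint_tol = 1e-5,
                              def_maxit = 20), options)
  shape <- atlas_shape(atlas)
  stopifnot(identical(as.integer(dim(image)), as.integer(shape)))
  mask <- mask & (image > 0)
  mv <- as.vector(mask)
  if (!any(mv)) stop("empty mask")
  ylog <- array(0, shape)
  ylog[mask] <- log(image[mask])
  basis <- if (o$bias_order > 0)
    poly_basis(shape, o$bias_order)[mv, , drop = FALSE] else NULL
  control <- NULL
  fit <- NULL
  trace <- numeric(0)
  df <- zero_field(shape)
  for (outer in seq_len(o$outer_iters)) {
    channels <- atlas_class_channels(atlas, clustering)
    prep <- interp_prep(shape, voxel_coords(shape) + disp_matrix(df),
                        clamp = TRUE)
    priors_c <- vapply(channels, function(ch)
      interp_apply(prep, ch), numeric(prod(shape)))
    pri <- priors_c[mv, , drop = FALSE]
    rs <- rowSums(pri)
    bad <- rs <= 0
    pri[bad, ] <- 1 / ncol(pri)
    pri[!bad, ] <- pri[!bad, , drop = FALSE] / rs[!bad]
    fit <- em_fit(ylog[mask], pri, clustering, basis,
                  o$n_components_per_class, tol = o$em_tol,
                  max_iters = o$em_max_iters)
    reg <- optimize_deformation(ylog, atlas, fit$gmm, fit$bias, clustering,
                                mask, cp_spacing = o$cp_spacing,
                                reg_weight = o$reg_weight,
                                maxit = o$def_maxit, init = control)
    control <- reg$control
    df <- exp_svf(reg$v, 6)
    obj <- -reg$objective["final"]
    trace <- c(trace, obj)
    if (outer > 1 &&
        abs(trace[outer] - trace[outer - 1]) /
          max(1, abs(trace[outer - 1])) < o$joint_tol) break
  }
  # final label posteriors: warped label priors x class likelihood
  L <- length(atlas$labels)
  pts <- voxel_coords(shape) + disp_matrix(df)
  bias_full <- rep(0, prod(shape))
  if (!is.null(basis)) bias_full[mv] <- fit$bias$log_bias
  ci <- clustering$map[as.character(atlas$labels)]
  likc <- matrix(1, prod(shape), clustering$n_classes)
  likc[mv, ] <- class_likelihood(ylog[mask], fit$gmm, bias_full[mv])
  post <- matrix(0, prod(shape), L)
  for (l in seq_len(L)) {
    pl <- interp_linear(atlas_channel(atlas, l), pts, clamp = TRUE)
    post[, l] <- pl * likc[, ci[l]]
  }
  rs <- rowSums(post)
  bg <- which(atlas$labels == 0)[1]
  zero <- rs <= 0
  post[zero, ] <- 0
  if (!is.na(bg)) post[zero, bg] <- 1
  rs[zero] <- 1
  post <- post / rs
  # outside the mask everything is background
  if (!is.na(bg)) {
    post[!mv, ] <- 0
    post[!mv, bg] <- 1
  }
  arg <- atlas$labels[max.col(post, ties.method = "first")]
  vox_vol <- prod(atlas$voxel_size)
  volumes <- data.frame(label = atlas$labels,
                        expected_volume_mm3 = colSums(post) * vox_vol)
  list(posterior = array(post, c(shape, L)),
       labels = label_volume(array(as.integer(arg), shape),
                             atlas$voxel_size),
       volumes = volumes, gmm = fit$gmm, bias = fit$bias,
       svf = control, objective = trace)
}

#' Registration-based segmentation with a single labelled template
#'
#' Nonlinear B-spline/SVF registration of the template to the target with
#' local NCC similarity and bending-energy regularisation, followed by
#' nearest-neighbour label propagation. Defaults follow the conventional
#' registration-based-segmentation settings: control-point spacing 5 voxels
#' (2.5 mm at 0.5 mm voxels), local NCC standard deviation 2.5 mm, bending
#' weight 0.001.
#'
#' @param target_image,template_image intensity arrays on a common grid.
#' @param template_labels [label_volume()] for the template.
#' @param params list: `cp_spacing_vox` (5), `lncc_sd_mm` (2.5),
#'   `bend_weight` (0.001), `voxel_size_mm` (0.5), `maxit`.
#' @return a [label_volume()]; the parameter set used is attached as
#'   attribute `params`.
#' @export
segment_by_registration <- function(target_image, template_image,
                                    template_labels, params = list()) {
  p <- utils::modifyList(list(cp_spacing_vox = 5, lncc_sd_mm = 2.5,
                              bend_weight = 0.001, voxel_size_mm = 0.5,
                              maxit = 40), params)
  shape <- dim(target_image)
  res <- optimize_svf(metric_lncc(target_image, template_image,
                                  sigma = p$lncc_sd_mm / p$voxel_size_mm),
                      shape, p$cp_spacing_vox,
                      reg_weight = p$bend_weight, maxit = p$maxit)
  df <- exp_svf(res$v, 6)
  out <- label_volume(array(as.integer(warp(template_labels$data, df,
                                            mode = "nearest", fill = 0)),
                            shape),
                      template_labels$voxel_size)
  attr(out, "params") <- p[c("cp_spacing_vox", "lncc_sd_mm", "bend_weight")]
  out
}

#' Dice overlap per region
#'
#' `2|A∩B| / (|A|+|B|)` per evaluation label, after optionally merging fine
#' labels via `label_mapping` (named vector: fine id -> evaluation id).
#' Labels empty in both volumes are reported as `NA` (undefined), not 0.
#'
#' @param labels_a,labels_b [label_volume()]s or integer arrays on one grid.
#' @param label_mapping optional named vector merging labels.
#' @return data.frame with columns `label`, `dice`, `size_a`, `size_b`.
#' @export
dice <- function(labels_a, labels_b, label_mapping = NULL) {
  a <- if (inherits(labels_a, "label_volume")) labels_a$data else labels_a
  b <- if (inherits(labels_b, "label_volume")) labels_b$data else labels_b
  if (!identical(dim(a), dim(b))) stop("label volumes on different grids")
  a <- as.vector(a); b <- as.vector(b)
  if (!is.null(label_mapping)) {
    remap <- function(x) {
      hit <- as.character(x) %in% names(label_mapping)
      x[hit] <- label_mapping[as.character(x[hit])]
      x
    }
    a <- remap(a); b <- remap(b)
  }
  labs <- sort(setdiff(union(unique(a), unique(b)), 0))
  out <- data.frame(label = labs, dice = rep(NA_real_, length(labs)),
                    size_a = rep(0L, length(labs)),
                    size_b = rep(0L, length(labs)))
  for (i in seq_along(labs)) {
    ia <- a == labs[i]; ib <- b == labs[i]
    na <- sum(ia); nb <- sum(ib)
    out$size_a[i] <- na; out$size_b[i] <- nb
    if (na + nb > 0) out$dice[i] <- 2 * sum(ia & ib) / (na + nb)
  }
  out
}
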