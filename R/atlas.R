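# Probabilistic atlas construction: alternate diffeomorphic registration of
# each labelled subject to the current template (label log-likelihood with a
# weak Dirichlet prior, bending-energy regularisation, SVF model) with
# voxelwise averaging of the deformed one-hot segmentations, until the atlas
# stops changing.

#' Probabilistic label atlas
#'
#' Per-voxel categorical distribution over labels on a fixed grid.
#'
#' @param prob array `c(shape, L)` of probabilities; per-voxel sums must be 1
#'   within 1e-6.
#' @param labels integer vector of label ids (length L).
#' @param voxel_size mm per voxel.
#' @return object of class `prob_atlas`.
#' @export
prob_atlas <- function(prob, labels, voxel_size = 1) {
  dm <- dim(prob)
  L <- dm[length(dm)]
  if (L != length(labels)) stop("label list does not match probability axis")
  if (min(prob) < -1e-9 || max(prob) > 1 + 1e-9)
    stop("probabilities outside [0, 1]")
  sums <- rowSums(matrix(prob, ncol = L))
  if (max(abs(sums - 1)) > 1e-6)
    stop("per-voxel probabilities do not sum to 1")
  structure(list(prob = prob, labels = as.integer(labels),
                 voxel_size = rep(voxel_size,
                                  length.out = length(dm) - 1L)),
            class = "prob_atlas")
}

atlas_shape <- function(atlas) {
  dm <- dim(atlas$prob)
  dm[-length(dm)]
}

# Channel l of an atlas as a plain array.
atlas_channel <- function(atlas, l) {
  shape <- atlas_shape(atlas)
  idx <- slice.index(atlas$prob, length(shape) + 1L)
  array(atlas$prob[idx == l], shape)
}

#' One-hot encoding of a label volume
#' @param labels [label_volume()] or integer array.
#' @param label_list label ids defining the channel order.
#' @return array `c(shape, length(label_list))`.
#' @export
one_hot <- function(labels, label_list) {
  dat <- if (inherits(labels, "label_volume")) labels$data else labels
  shape <- dim(dat)
  out <- array(0, c(shape, length(label_list)))
  idx <- slice.index(out, length(shape) + 1L)
  for (li in seq_along(label_list)) {
    out[idx == li] <- (dat == label_list[li]) * 1
  }
  out
}

# Smooth each channel with a Gaussian and renormalise per voxel; gives the
# label data term usable gradients even for hard (one-hot) atlases.
smooth_channels <- function(prob, sigma = 1) {
  dm <- dim(prob)
  L <- dm[length(dm)]
  shape <- dm[-length(dm)]
  idx <- slice.index(prob, length(shape) + 1L)
  out <- prob
  for (l in seq_len(L)) {
    out[idx == l] <- smooth_gauss(array(prob[idx == l], shape), sigma)
  }
  s <- rowSums(matrix(out, ncol = L))
  s[s == 0] <- 1
  array(as.vector(out) / rep(s, L), dm)
}

#' Intensity-based initial template
#'
#' Registers each subject's intensity volume to a reference intensity volume
#' (local NCC similarity, SVF deformation, bending-energy penalty), applies
#' each deformation to the subject's one-hot labels and averages them into a
#' normalised probabilistic atlas.
#'
#' @param intensity_volumes list of intensity arrays.
#' @param label_volumes list of matching [label_volume()]s.
#' @param reference_intensity reference intensity array.
#' @param cp_spacing control spacing (voxels).
#' @param reg_weight bending weight.
#' @param lncc_sigma local NCC window sd (voxels).
#' @param maxit optimiser iterations per subject.
#' @return a [prob_atlas()].
#' @export
init_template <- function(intensity_volumes, label_volumes,
                          reference_intensity, cp_spacing = 4,
                          reg_weight = 0.01, lncc_sigma = 2, maxit = 30) {
  K <- length(intensity_volumes)
  stopifnot(K == length(label_volumes), K >= 1)
  labels_all <- sort(unique(unlist(lapply(label_volumes, function(l)
    unique(as.vector(l$data))))))
  shape <- dim(reference_intensity)
  deformed <- vector("list", K)
  for (k in seq_len(K)) {
    iv <- intensity_volumes[[k]]
    lv <- label_volumes[[k]]
    if (!identical(dim(iv), dim(lv$data)))
      stop(sprintf("subject %d: intensity and label grids differ", k))
    res <- optimize_svf(metric_lncc(reference_intensity, iv,
                                    sigma = lncc_sigma),
                        shape, cp_spacing, reg_weight = reg_weight,
                        maxit = maxit)
    df <- exp_svf(res$v, 6)
    deformed[[k]] <- warp_channels(one_hot(lv, labels_all), df,
                                   fills = as.numeric(labels_all == 0))
  }
  update_atlas(deformed, labels_all,
               voxel_size = label_volumes[[1]]$voxel_size)
}

#' Register a labelled volume to a probabilistic atlas
#'
#' Finds the SVF maximising the voxelwise log-probability of the observed
#' labels under the deformed atlas, `sum_v log[(p_v(l_v)+a)/(1+aL)]` with a
#' weak Dirichlet pseudo-count `a`, minus a bending-energy penalty; optimised
#' by damped preconditioned descent on the B-spline control points.
#' Gradients come from interpolated central-difference images of the atlas
#' channels, so they exist even for hard (one-hot) atlases; optional channel
#' smoothing (`smooth_sigma`) widens the capture range if needed.
#'
#' @param labels a [label_volume()].
#' @param atlas a [prob_atlas()].
#' @param cp_spacing control-point spacing (voxels).
#' @param reg_weight bending-energy weight.
#' @param dirichlet_alpha Dirichlet pseudo-count.
#' @param smooth_sigma optional channel-smoothing sd (voxels; 0 = off).
#' @param maxit optimiser iterations.
#' @param init optional initial control values.
#' @return list with `v` ([velocity_field()]), `control`, objective trace and
#'   `min_jacobian` of the accepted deformation.
#' @export
register_labels_to_atlas <- function(labels, atlas, cp_spacing = 4,
                                     reg_weight = 1,
                                     dirichlet_alpha = 1e-5,
                                     smooth_sigma = 0, maxit = 30,
                                     init = NULL) {
  shape <- atlas_shape(atlas)
  if (!identical(as.integer(dim(labels$data)), as.integer(shape)))
    stop("label volume and atlas grids differ")
  lv <- as.vector(labels$data)
  missing <- setdiff(unique(lv), atlas$labels)
  if (length(missing) > 0)
    stop("labels absent from atlas: ", paste(missing, collapse = ", "))
  sm <- smooth_channels(atlas$prob, smooth_sigma)
  channels <- lapply(seq_along(atlas$labels), function(l)
    array(sm[slice.index(sm, length(shape) + 1L) == l], shape))
  label_idx <- match(lv, atlas$labels)
  res <- optimize_svf(metric_labellik(label_idx, channels,
                                      alpha = dirichlet_alpha),
                      shape, cp_spacing, reg_weight = reg_weight,
                      maxit = maxit, init = init)
  res$min_jacobian <- min(jacobian_det(exp_svf(res$v, 6)))
  res
}

#' Average deformed one-hot segmentations into an atlas
#'
#' @param deformed_onehot_labels list of arrays `c(shape, L)` on the atlas
#'   grid.
#' @param labels label ids for the channel axis.
#' @param voxel_size mm per voxel.
#' @return a [prob_atlas()].
#' @export
update_atlas <- function(deformed_onehot_labels, labels, voxel_size = 1) {
  if (length(deformed_onehot_labels) == 0)
    stop("no segmentations supplied to average")
  m <- Reduce(`+`, deformed_onehot_labels) / length(deformed_onehot_labels)
  dm <- dim(m)
  L <- dm[length(dm)]
  s <- rowSums(matrix(m, ncol = L))
  s[s == 0] <- 1
  prob_atlas(array(as.vector(m) / rep(s, L), dm), labels, voxel_size)
}

# Mirror an array (or one-hot stack) along axis 1.
mirror_volume <- function(x) {
  idx <- lapply(dim(x), seq_len)
  idx[[1]] <- rev(idx[[1]])
  do.call(`[`, c(list(x), idx))
}

#' Iterative probabilistic atlas construction
#'
#' Alternates (i) registration of every subject's labels to the current atlas
#' and (ii) voxelwise averaging of the inverse-deformed one-hot
#' segmentations, until the maximum voxelwise probability change drops below
#' `tol` or `max_iters` is reached. Subjects flagged in `flip_spec` are
#' mirrored along the first axis before entering (hemisphere pooling).
#'
#' @param subjects list of [label_volume()]s on a common grid.
#' @param reference optional initial [prob_atlas()]; defaults to the plain
#'   average of the (unregistered) one-hot subjects.
#' @param max_iters maximum alternations.
#' @param tol convergence threshold on the max voxelwise probability change.
#' @param flip_spec logical vector (one per subject).
#' @param cp_spacing,reg_weight,dirichlet_alpha,smooth_sigma,maxit
#'   registration settings passed to [register_labels_to_atlas()].
#' @return list with `atlas`, per-iteration `change` log, `min_jacobian` per
#'   subject and iteration, and the per-subject registration objectives.
#' @export
build_atlas <- function(subjects, reference = NULL, max_iters = 5,
                        tol = 1e-3, flip_spec = NULL, cp_spacing = 4,
                        reg_weight = 1, dirichlet_alpha = 1e-5,
                        smooth_sigma = 0, maxit = 25) {
  K <- length(subjects)
  stopifnot(K >= 1)
  if (is.null(flip_spec)) flip_spec <- rep(FALSE, K)
  subjects <- lapply(seq_len(K), function(k) {
    s <- subjects[[k]]
    if (flip_spec[k]) s$data <- mirror_volume(s$data)
    s
  })
  labels_all <- sort(unique(unlist(lapply(subjects, function(l)
    unique(as.vector(l$data))))))
  shape <- dim(subjects[[1]]$data)
  onehots <- lapply(subjects, one_hot, label_list = labels_all)
  if (is.null(reference)) {
    atlas <- update_atlas(onehots, labels_all,
                          voxel_size = subjects[[1]]$voxel_size)
  } else atlas <- reference
  change_log <- numeric(0)
  minjac <- obj <- matrix(NA_real_, max_iters, K)
  controls <- vector("list", K)
  for (it in seq_len(max_iters)) {
    deformed <- vector("list", K)
    for (k in seq_len(K)) {
      reg <- tryCatch(
        register_labels_to_atlas(subjects[[k]], atlas,
                                 cp_spacing = cp_spacing,
                                 reg_weight = reg_weight,
                                 dirichlet_alpha = dirichlet_alpha,
                                 smooth_sigma = smooth_sigma,
                                 maxit = maxit, init = controls[[k]]),
        error = function(e) stop(sprintf("subject %d: %s", k,
                                         conditionMessage(e)),
                                 call. = FALSE))
      controls[[k]] <- reg$control
      minjac[it, k] <- reg$min_jacobian
      obj[it, k] <- reg$objective["final"]
      dinv <- invert(reg$v, 6)   # pull the subject into atlas space
      deformed[[k]] <- warp_channels(onehots[[k]], dinv,
                                     fills = as.numeric(labels_all == 0))
    }
    new_atlas <- update_atlas(deformed, labels_all,
                              voxel_size = subjects[[1]]$voxel_size)
    change <- max(abs(new_atlas$prob - atlas$prob))
    change_log <- c(change_log, change)
    atlas <- new_atlas
    if (change < tol) break
  }
  list(atlas = atlas, change = change_log,
       min_jacobian = minjac[seq_along(change_log), , drop = FALSE],
       objective = obj[seq_along(change_log), , drop = FALSE])
}
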