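# Phantom generators: every input class the pipeline consumes, produced with
# known ground truth (label geometry, mixture intensities, multiplicative
# bias, per-section distortions, block poses, cohort trajectories) so that
# recovery can be tested end to end. All generators are pure functions of
# their arguments including the seed.

#' Specification of a synthetic label phantom
#'
#' @param grid_shape voxel counts per axis (all >= 8).
#' @param voxel_size mm per voxel, recycled.
#' @param n_rois number of foreground labels (>= 1).
#' @param hierarchy optional named list grouping labels into parent
#'   structures: each element is an integer vector of child labels that will
#'   be placed inside a common parent blob.
#' @param seed integer seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_size = 1, n_rois = 3,
                         hierarchy = NULL, seed = 1) {
  if (any(grid_shape < 8)) stop("all grid_shape entries must be >= 8")
  if (n_rois < 1) stop("n_rois must be >= 1")
  if (!is.null(hierarchy)) {
    kids <- unlist(hierarchy)
    if (anyDuplicated(kids) || !all(kids %in% seq_len(n_rois)))
      stop("hierarchy children must be distinct labels in 1..n_rois")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = rep(voxel_size, length.out = length(grid_shape)),
                 n_rois = as.integer(n_rois), hierarchy = hierarchy,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Integer label volume
#' @param data integer array of label ids (0 = background).
#' @param voxel_size mm per voxel.
#' @param affine optional 4x4 (or 3x3 in 2D) voxel-to-world matrix; defaults
#'   to a diagonal scaling by `voxel_size`.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(data, voxel_size = 1, affine = NULL) {
  d <- length(dim(data))
  voxel_size <- rep(voxel_size, length.out = d)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  structure(list(data = data, voxel_size = voxel_size, affine = affine),
            class = "label_volume")
}

# Voxel mask of an axis-aligned ellipsoid.
ellipsoid_mask <- function(shape, center, semi) {
  pts <- voxel_coords(shape)
  r2 <- 0
  for (a in seq_along(shape)) r2 <- r2 + ((pts[, a] - center[a]) / semi[a])^2
  array(r2 <= 1, shape)
}

#' Generate a nested-ellipsoid label phantom
#'
#' Places `n_rois` non-overlapping ellipsoidal blobs (random centres and
#' semi-axes, rejection sampling) inside the grid; labels in the optional
#' hierarchy are placed inside a shared parent ellipsoid so that sub-labels
#' are spatially nested, mimicking anatomical containment.
#'
#' @param spec a [phantom_spec()].
#' @return a [label_volume()] with labels `0..n_rois` (0 = background) and an
#'   attribute `parents` naming the parent blob of each hierarchical label.
#' @export
make_label_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$grid_shape
  d <- length(shape)
  with_seed(spec$seed, {
    lab <- array(0L, shape)
    occupied <- array(FALSE, shape)
    place_blob <- function(frac_min, frac_max, within = NULL, label) {
      for (try in seq_len(400)) {
        semi <- stats::runif(d, frac_min, frac_max) * shape
        lo <- 1 + semi + 1
        hi <- shape - semi - 1
        if (any(hi <= lo)) next
        center <- stats::runif(d, lo, hi)
        m <- ellipsoid_mask(shape, center, semi)
        if (!is.null(within)) m <- m & within
        if (!any(m)) next
        if (!any(m & occupied)) {
          lab[m] <<- label
          occupied <<- occupied | m
          return(TRUE)
        }
      }
      FALSE
    }
    order_hier <- spec$hierarchy
    placed_in <- character(0)
    if (!is.null(order_hier)) {
      for (pname in names(order_hier)) {
        kids <- order_hier[[pname]]
        # parent blob reserved first, children nested inside it
        parent_mask <- NULL
        for (try in seq_len(400)) {
          semi <- stats::runif(d, 0.20, 0.30) * shape
          lo <- 1 + semi + 1; hi <- shape - semi - 1
          if (any(hi <= lo)) next
          center <- stats::runif(d, lo, hi)
          m <- ellipsoid_mask(shape, center, semi)
          if (any(m) && !any(m & occupied)) { parent_mask <- m; break }
        }
        if (is.null(parent_mask))
          stop(sprintf(
            "grid %s too small to place parent structure '%s'",
            paste(shape, collapse = "x"), pname))
        occupied <- occupied | parent_mask
        inner <- parent_mask
        occ_save <- occupied
        occupied <- array(FALSE, dim(occupied))  # children only avoid siblings
        for (k in kids) {
          if (!place_blob(0.04, 0.10, within = inner, label = k))
            stop(sprintf(
              "grid %s too small to place label %d inside '%s'",
              paste(shape, collapse = "x"), k, pname))
        }
        occupied <- occ_save | occupied
        placed_in <- c(placed_in, stats::setNames(rep(pname, length(kids)),
                                                  as.character(kids)))
      }
    }
    remaining <- setdiff(seq_len(spec$n_rois),
                         as.integer(names(placed_in)))
    for (k in remaining) {
      if (!place_blob(0.06, 0.16, label = k))
        stop(sprintf(
          "grid %s too small to place %d non-overlapping ROIs (failed at label %d)",
          paste(shape, collapse = "x"), spec$n_rois, k))
    }
    out <- label_volume(lab, spec$voxel_size)
    attr(out, "parents") <- placed_in
    out
  })
}

#' Per-tissue-class Gaussian mixture intensity model
#'
#' @param means list (one element per class) of component means.
#' @param variances list of component variances (> 0).
#' @param weights list of component weights (>= 0, summing to 1); defaults to
#'   uniform weights.
#' @param class_names optional class names.
#' @return object of class `class_intensity_model`.
#' @export
class_intensity_model <- function(means, variances, weights = NULL,
                                  class_names = NULL) {
  if (!is.list(means)) means <- as.list(means)
  if (!is.list(variances)) variances <- as.list(variances)
  C <- length(means)
  if (is.null(weights))
    weights <- lapply(means, function(m) rep(1 / length(m), length(m)))
  stopifnot(length(variances) == C, length(weights) == C)
  for (c in seq_len(C)) {
    if (length(means[[c]]) != length(variances[[c]]) ||
        length(means[[c]]) != length(weights[[c]]))
      stop("component counts disagree within class ", c)
    if (any(variances[[c]] <= 0)) stop("variances must be > 0 in class ", c)
    if (any(weights[[c]] < 0) || abs(sum(weights[[c]]) - 1) > 1e-8)
      stop("weights must be >= 0 and sum to 1 in class ", c)
  }
  if (is.null(class_names)) class_names <- paste0("class", seq_len(C))
  structure(list(means = means, variances = variances, weights = weights,
                 class_names = class_names),
            class = "class_intensity_model")
}

#' Label-to-tissue-class clustering
#'
#' Total map from anatomical label ids to tissue-class indices: many ROIs can
#' share one intensity class, which keeps the mixture model identifiable when
#' the label count is large.
#'
#' @param map named integer vector: names are label ids (as characters),
#'   values are class indices starting at 1.
#' @param class_names optional character vector of class names.
#' @return object of class `tissue_clustering`.
#' @export
tissue_clustering <- function(map, class_names = NULL) {
  if (is.null(names(map))) stop("map must be named by label id")
  map <- stats::setNames(as.integer(map), names(map))
  if (anyDuplicated(names(map))) stop("labels mapped more than once")
  C <- max(map)
  if (C < 1) stop("at least one tissue class required")
  if (is.null(class_names)) class_names <- paste0("class", seq_len(C))
  structure(list(map = map, class_names = class_names, n_classes = C),
            class = "tissue_clustering")
}

# Class index per voxel; errors on unmapped labels.
class_index <- function(labels, clustering) {
  lv <- as.vector(if (inherits(labels, "label_volume")) labels$data else labels)
  key <- as.character(lv)
  ci <- clustering$map[key]
  if (anyNA(ci)) {
    bad <- unique(lv[is.na(ci)])
    stop("labels not mapped to any tissue class: ",
         paste(bad, collapse = ", "))
  }
  unname(ci)
}

#' Sample an intensity volume from a label map and mixture model
#'
#' Each voxel's intensity is drawn from the Gaussian mixture of its tissue
#' class (labels mapped to classes by `clustering`). This is the generative
#' direction of the segmentation model.
#'
#' @param labels a [label_volume()] or integer array.
#' @param model a [class_intensity_model()].
#' @param clustering a [tissue_clustering()].
#' @param seed integer seed.
#' @return numeric array of intensities.
#' @export
sample_intensity <- function(labels, model, clustering, seed) {
  dat <- if (inherits(labels, "label_volume")) labels$data else labels
  ci <- class_index(dat, clustering)
  if (max(ci) > length(model$means))
    stop("clustering refers to classes missing from the intensity model")
  with_seed(seed, {
    out <- numeric(length(ci))
    for (c in unique(ci)) {
      idx <- which(ci == c)
      k <- sample.int(length(model$weights[[c]]), length(idx),
                      replace = TRUE, prob = model$weights[[c]])
      out[idx] <- stats::rnorm(length(idx), model$means[[c]][k],
                               sqrt(model$variances[[c]][k]))
    }
    array(out, dim(dat))
  })
}

# Polynomial basis in normalised coordinates [-1, 1]; all monomials of total
# degree 1..order (constant excluded: overall gain is not a bias shape).
poly_basis <- function(shape, order) {
  d <- length(shape)
  pts <- voxel_coords(shape)
  for (a in seq_len(d)) pts[, a] <- 2 * (pts[, a] - 1) / (shape[a] - 1) - 1
  expo <- as.matrix(expand.grid(rep(list(0:order), d)))
  expo <- expo[rowSums(expo) >= 1 & rowSums(expo) <= order, , drop = FALSE]
  B <- matrix(1, nrow(pts), nrow(expo))
  for (m in seq_len(nrow(expo))) {
    for (a in seq_len(d)) {
      if (expo[m, a] > 0) B[, m] <- B[, m] * pts[, a]^expo[m, a]
    }
  }
  B
}

#' Sample a smooth multiplicative bias field
#'
#' Exponential of a random low-order polynomial in normalised coordinates,
#' rescaled so the log-field has root-mean-square `amplitude`. Always
#' strictly positive; an amplitude of 0 gives the unit field.
#'
#' @param grid_shape voxel counts.
#' @param basis_order maximum total polynomial degree (default 2).
#' @param amplitude RMS of the log-field (>= 0).
#' @param seed integer seed.
#' @return object of class `bias_field`: list with `field` (multiplicative)
#'   and `log_field` arrays.
#' @export
sample_bias <- function(grid_shape, basis_order = 2, amplitude = 0.1, seed = 1) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  B <- poly_basis(grid_shape, basis_order)
  cf <- with_seed(seed, stats::rnorm(ncol(B)))
  lf <- as.vector(B %*% cf)
  rms <- sqrt(mean(lf^2))
  lf <- if (rms > 0 && amplitude > 0) lf * (amplitude / rms) else lf * 0
  lf <- array(lf, grid_shape)
  structure(list(field = exp(lf), log_field = lf,
                 basis_order = basis_order, amplitude = amplitude),
            class = "bias_field")
}

# Velocity field of a rigid motion: v(x) = W (x - c) + t, whose flow is an
# exact rotation (angle = |W|) plus translation. 2D only (sections).
rigid_velocity <- function(shape, theta, trans) {
  pts <- voxel_coords(shape)
  c0 <- (shape + 1) / 2
  vx <- -theta * (pts[, 2] - c0[2]) + trans[1]
  vy <-  theta * (pts[, 1] - c0[1]) + trans[2]
  velocity_field(array(c(vx, vy), c(shape, 2)))
}

#' Simulate a distorted multi-modal section stack
#'
#' Extracts `n_sections` contiguous slices from a volume as the undistorted
#' reference images, and simulates two stained modalities per slice as
#' monotone intensity remaps of the reference corrupted by a per-section SVF
#' (rigid motion plus a smooth B-spline distortion) and additive noise.
#' Ground-truth per-section velocity fields and planted landmark pairs are
#' retained for recovery tests.
#'
#' @param volume 3D intensity array (or `label_volume`-shaped list).
#' @param labels matching [label_volume()] (carried through for evaluation).
#' @param n_sections number of sections (<= slices available).
#' @param distortion list with `rigid` (sd of per-section translation in
#'   voxels and rotation in degrees) and `bspline` (max smooth displacement
#'   in voxels).
#' @param seed integer seed.
#' @param noise_sd additive Gaussian noise sd as a fraction of the intensity
#'   range.
#' @param n_landmarks landmark pairs planted per section and stain.
#' @return object of class `section_stack`.
#' @export
make_section_stack <- function(volume, labels = NULL, n_sections,
                               distortion = list(rigid = 1, bspline = 1),
                               seed = 1, noise_sd = 0.01, n_landmarks = 8) {
  vol <- if (is.list(volume) && !is.null(volume$data)) volume$data else volume
  shape <- dim(vol)
  if (n_sections > shape[3])
    stop(sprintf("n_sections (%d) exceeds available slices (%d)",
                 n_sections, shape[3]))
  z0 <- floor((shape[3] - n_sections) / 2)
  zs <- z0 + seq_len(n_sections)
  sh2 <- shape[1:2]
  rng <- diff(range(vol))
  if (rng == 0) rng <- 1
  remapA <- function(x) (pmax(x - min(vol), 0) / rng)^1.4
  remapB <- function(x) sqrt(pmax(x - min(vol), 0) / rng)
  sections <- with_seed(seed, lapply(seq_len(n_sections), function(s) {
    M <- vol[, , zs[s]]
    mk_stain <- function(remap, tag) {
      theta <- stats::rnorm(1, 0, distortion$rigid * pi / 180)
      trans <- stats::rnorm(2, 0, distortion$rigid)
      vb <- sample_svf(sh2, control_spacing = 8,
                       amplitude = distortion$bspline,
                       seed = stats::runif(1, 1, 2^30))
      v <- velocity_field(rigid_velocity(sh2, theta, trans)$disp + vb$disp)
      dfwd <- exp_svf(v, 6)
      img <- remap(M)
      if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
      stain <- warp(array(img, sh2), dfwd)
      # landmarks: points p in the stain map to q = p + d(p) in the reference
      p <- cbind(stats::runif(n_landmarks, sh2[1] * 0.3, sh2[1] * 0.7),
                 stats::runif(n_landmarks, sh2[2] * 0.3, sh2[2] * 0.7))
      q <- p + sample_disp(dfwd, p)
      list(image = stain, v_true = v, landmarks = list(p = p, q = q),
           modality = tag)
    }
    A <- mk_stain(remapA, "stainA")
    B <- mk_stain(remapB, "stainB")
    list(M = M, A = A$image, B = B$image,
         v_A = A$v_true, v_B = B$v_true,
         landmarks_A = A$landmarks, landmarks_B = B$landmarks)
  }))
  structure(list(sections = sections, S = n_sections, slice_indices = zs,
                 shape2d = sh2, labels = labels,
                 distortion = distortion, seed = seed),
            class = "section_stack")
}

#' Cut a volume into jittered blocks
#'
#' Splits a volume into an axis-aligned grid of blocks (the last block along
#' an axis absorbs the remainder). Each block keeps its image, its binary
#' foreground mask, a ground-truth identity pose, and a jittered similarity
#' pose (translation, rotation, log-scale) that serves as the perturbed
#' initialisation for joint alignment. Pre-jitter, the block masks partition
#' the volume foreground exactly.
#'
#' @param volume 3D numeric array; foreground is `volume != 0`.
#' @param block_grid integer vector of block counts per axis.
#' @param pose_jitter list with `trans` (sd, voxels), `rot_deg` (sd, degrees)
#'   and `logscale` (sd); a single number is shorthand for
#'   `list(trans = x, rot_deg = x, logscale = 0)`.
#' @param seed integer seed.
#' @return object of class `block_set`.
#' @export
make_blocks <- function(volume, block_grid, pose_jitter = 0, seed = 1) {
  if (all(volume == 0)) stop("volume is empty: no foreground to cut")
  if (is.numeric(pose_jitter) && length(pose_jitter) == 1)
    pose_jitter <- list(trans = pose_jitter, rot_deg = pose_jitter,
                        logscale = 0)
  shape <- dim(volume)
  d <- length(shape)
  cuts <- lapply(seq_len(d), function(a) {
    size <- floor(shape[a] / block_grid[a])
    starts <- 1 + size * (seq_len(block_grid[a]) - 1)
    ends <- c(starts[-1] - 1, shape[a])
    cbind(starts, ends)
  })
  idx <- as.matrix(expand.grid(lapply(block_grid, seq_len)))
  blocks <- with_seed(seed, lapply(seq_len(nrow(idx)), function(b) {
    rng <- lapply(seq_len(d), function(a) {
      cuts[[a]][idx[b, a], 1]:cuts[[a]][idx[b, a], 2]
    })
    img <- do.call(`[`, c(list(volume), rng))
    origin <- vapply(rng, min, numeric(1))
    bshape <- vapply(rng, length, numeric(1))
    pose_true <- list(trans = rep(0, d), rot = rep(0, if (d == 3) 3 else 1),
                      logscale = 0)
    pose <- pose_true
    pose$trans <- stats::rnorm(d, 0, pose_jitter$trans)
    pose$rot <- stats::rnorm(length(pose$rot), 0,
                             pose_jitter$rot_deg * pi / 180)
    pose$logscale <- stats::rnorm(1, 0, pose_jitter$logscale)
    list(image = img, mask = (img != 0) * 1, origin = origin,
         shape = bshape, center = origin - 1 + (bshape + 1) / 2,
         pose = pose, pose_true = pose_true,
         group = as.character(idx[b, 1]))
  }))
  structure(list(blocks = blocks, ref_shape = shape,
                 foreground = (volume != 0) * 1, volume = volume),
            class = "block_set")
}

#' Ageing-trajectory specification
#'
#' Location and scale curves for each ROI as B-splines over age: control
#' values `theta_mu` (volume units) and `theta_b` (> 0) at the given knot
#' ages.
#'
#' @param knot_ages ordered knot ages in years.
#' @param theta_mu matrix (ROIs x knots) of location control values.
#' @param theta_b matrix (ROIs x knots) of scale control values (> 0).
#' @param roi_names optional ROI names.
#' @return object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(knot_ages, theta_mu, theta_b, roi_names = NULL) {
  theta_mu <- rbind(theta_mu)
  theta_b <- rbind(theta_b)
  K <- length(knot_ages)
  if (is.unsorted(knot_ages)) stop("knot_ages must be ordered")
  if (ncol(theta_mu) != K || ncol(theta_b) != K)
    stop("control value count must equal the number of knots")
  if (any(theta_b <= 0)) stop("scale control values must be > 0")
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(nrow(theta_mu)))
  structure(list(knot_ages = knot_ages, theta_mu = theta_mu,
                 theta_b = theta_b, roi_names = roi_names),
            class = "trajectory_spec")
}

#' Normalised cubic B-spline basis over age knots
#'
#' Uniform cubic B-spline bumps centred at the knot ages, renormalised to sum
#' to one at every age so that constant control values reproduce a constant
#' curve.
#'
#' @param ages numeric vector of ages (years).
#' @param knot_ages ordered knot ages.
#' @return matrix `length(ages) x length(knot_ages)`.
#' @export
trajectory_basis <- function(ages, knot_ages) {
  h <- mean(diff(knot_ages))
  B <- outer(ages, knot_ages, function(a, k) bspline3((a - k) / h))
  s <- rowSums(B)
  s[s == 0] <- 1
  B / s
}

# Evaluate a trajectory curve at given ages.
trajectory_eval <- function(theta, ages, knot_ages) {
  as.vector(trajectory_basis(ages, knot_ages) %*% theta)
}

# Laplace(0, b) sampler via inverse CDF.
rlaplace <- function(n, b) {
  u <- stats::runif(n) - 0.5
  -b * sign(u) * log1p(-2 * abs(u))
}

#' Simulate a volumetric cohort
#'
#' Ages uniform over `age_range`; sex exactly balanced; intracranial volume
#' (ICV) lognormal. Each ROI volume is the ICV-scaled location curve
#' `mu(a)` plus a symmetric additive sex offset (+/- half the effect) and
#' Laplace noise with age-dependent scale `b(a)` — exactly the noise model
#' the trajectory-fitting routine assumes. Ground-truth curves are retained
#' in the `truth` attribute.
#'
#' @param n_subjects number of subjects (>= 0).
#' @param age_range length-2 numeric range in years.
#' @param trajectories a [trajectory_spec()].
#' @param seed integer seed.
#' @param icv_meanlog,icv_sdlog lognormal ICV parameters (mm^3).
#' @param sex_effect additive offset between sexes after ICV division, per
#'   ROI (recycled); default 2% of the mean location curve.
#' @return data.frame with columns `subject_id, age_years, sex, icv_mm3` and
#'   one `<roi>_mm3` column per ROI.
#' @export
make_cohort <- function(n_subjects, age_range, trajectories, seed = 1,
                        icv_meanlog = log(1.45e6), icv_sdlog = 0.08,
                        sex_effect = NULL) {
  stopifnot(inherits(trajectories, "trajectory_spec"), n_subjects >= 0)
  R <- nrow(trajectories$theta_mu)
  roi_cols <- paste0(trajectories$roi_names, "_mm3")
  if (n_subjects == 0) {
    out <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 4 + R)),
      c("subject_id", "age_years", "sex", "icv_mm3", roi_cols))
    attr(out, "truth") <- list(trajectories = trajectories)
    return(out)
  }
  if (is.null(sex_effect))
    sex_effect <- 0.02 * abs(rowMeans(trajectories$theta_mu))
  sex_effect <- rep(sex_effect, length.out = R)
  icv_ref <- exp(icv_meanlog)
  with_seed(seed, {
    age <- stats::runif(n_subjects, age_range[1], age_range[2])
    sex <- sample(rep(c("F", "M"), length.out = n_subjects))
    icv <- stats::rlnorm(n_subjects, icv_meanlog, icv_sdlog)
    out <- data.frame(subject_id = sprintf("sub%04d", seq_len(n_subjects)),
                      age_years = age, sex = sex, icv_mm3 = icv,
                      stringsAsFactors = FALSE)
    ssign <- ifelse(sex == "M", 0.5, -0.5)
    for (r in seq_len(R)) {
      mu <- trajectory_eval(trajectories$theta_mu[r, ], age,
                            trajectories$knot_ages)
      b <- trajectory_eval(trajectories$theta_b[r, ], age,
                           trajectories$knot_ages)
      v <- (icv / icv_ref) *
        (mu + ssign * sex_effect[r] + rlaplace(n_subjects, b))
      out[[roi_cols[r]]] <- v
    }
    attr(out, "truth") <- list(trajectories = trajectories,
                               sex_effect = sex_effect, icv_ref = icv_ref)
    out
  })
}
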