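# Heavier end-to-end pipelines shared by the acceptance checks (built once
# per session through fixture()).

# Curved-structure stack: anatomy drifts across sections, per-section
# distortions are planted, and one stain-to-reference measurement is
# corrupted to emulate a catastrophically failed registration (fold/tear).
build_curved_recon <- function() {
  shape <- c(24, 24, 12)
  set.seed(31)
  vol <- histatlas:::smooth_gauss(
    array(stats::rnorm(prod(shape)), shape), c(2, 2, 1))
  pts <- histatlas:::voxel_coords(shape[1:2])
  for (z in seq_len(shape[3])) {
    cx <- 12 + 5 * sin(pi * (z - 1) / (shape[3] - 1))
    blob <- exp(-((pts[, 1] - cx)^2 + (pts[, 2] - 12)^2) / 18)
    vol[, , z] <- vol[, , z] + 6 * array(blob, shape[1:2]) + 4
  }
  st <- make_section_stack(vol, NULL, n_sections = 6,
                           distortion = list(rigid = 1, bspline = 1),
                           seed = 32)
  g <- build_registration_graph(st)
  g <- run_pairwise_registrations(st, g, cp_spacing = 8, maxit = 15)
  # plant a gross outlier on one stain-to-reference measurement
  k_out <- which(g$measured$type == "AM")[3]
  sig <- max(abs(unlist(g$svfs)))
  g$svfs[[k_out]] <- g$svfs[[k_out]] + 10 * sig
  fit <- refine_bayesian(g)
  list(
    bayes = evaluate_reconstruction(st, stack_transforms(g, fit$latents)),
    independent = evaluate_reconstruction(
      st, histatlas:::independent_transforms(g)),
    chain = evaluate_reconstruction(st, histatlas:::chain_transforms(g)))
}

# Five subjects deformed from a 64-cube template -> atlas build -> intensity
# phantom sampled from the built atlas -> Bayesian segmentation.
build_end_to_end_64 <- function() {
  shape <- c(64, 64, 64)
  tmpl <- make_label_phantom(phantom_spec(shape, n_rois = 5, seed = 7))
  subs <- lapply(1:5, function(k) {
    v <- sample_svf(shape, 12, 2, seed = 300 + k)
    label_volume(array(as.integer(warp(tmpl$data, exp_svf(v, 6),
                                       mode = "nearest")), shape))
  })
  build <- build_atlas(subs, max_iters = 2, cp_spacing = 8, maxit = 8)
  L <- length(build$atlas$labels)
  arg <- array(as.integer(build$atlas$labels[
    max.col(matrix(build$atlas$prob, ncol = L), ties.method = "first")]),
    shape)
  atlas_dice <- dice(arg, tmpl$data)
  cl <- identity_clustering(0:5)
  gm <- class_intensity_model(
    means = list(15, 60, 100, 140, 180, 220),
    variances = list(9, 16, 16, 16, 16, 16))
  seglab <- label_volume(arg)
  img <- sample_intensity(seglab, gm, cl, seed = 41)
  img[img <= 0] <- 0.01
  seg <- segment_bayes(img, build$atlas, cl, array(TRUE, shape),
                       options = list(outer_iters = 2, cp_spacing = 8,
                                      def_maxit = 6))
  list(build = build, atlas_dice = atlas_dice,
       seg_dice = dice(seg$labels, seglab), template = tmpl)
}
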