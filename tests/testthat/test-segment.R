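# Bayesian segmentation: EM with bias correction, deformation updates,
# end-to-end posteriors, the registration baseline and Dice evaluation.

test_that("EM recovers well-separated mixture means with monotone
           likelihood", {
  set.seed(1)
  V <- 50000
  z <- sample(1:2, V, TRUE)
  y <- stats::rnorm(V, c(2, 4)[z], 0.1)
  cl <- identity_clustering(0:1)
  fit <- em_fit(y, matrix(0.5, V, 2), cl, NULL, 1)
  means <- sort(unlist(fit$gmm$means))
  expect_lt(abs(means[1] - 2) / 2, 0.02)
  expect_lt(abs(means[2] - 4) / 4, 0.02)
  ll <- fit$loglik
  expect_true(all(diff(ll) > -1e-8 * pmax(1, abs(ll[-length(ll)]))))
  expect_error(em_fit(numeric(0), matrix(0, 0, 2), cl), "empty mask")
})

test_that("EM estimates a planted log-bias field", {
  shape <- c(36, 36, 24)
  bf <- sample_bias(shape, 2, 0.15, seed = 9)
  set.seed(2)
  z <- sample(1:2, prod(shape), TRUE)
  y <- stats::rnorm(prod(shape), c(2, 4)[z], 0.1) + as.vector(bf$log_field)
  B <- histatlas:::poly_basis(shape, 2)
  fit <- em_fit(y, matrix(0.5, length(y), 2), identity_clustering(0:1), B, 1)
  expect_gte(stats::cor(fit$bias$log_bias, as.vector(bf$log_field)), 0.95)
})

segmentation_fixture <- function() {
  fixture("seg_fixture", function() {
    shape <- c(28, 28, 28)
    tmpl <- make_label_phantom(phantom_spec(shape, n_rois = 3, seed = 21))
    atlas <- prob_atlas(one_hot(tmpl, 0:3), 0:3)
    cl <- identity_clustering(0:3)
    gm <- class_intensity_model(means = list(10, 60, 110, 160),
                                variances = list(4, 16, 16, 16))
    img <- sample_intensity(tmpl, gm, cl, seed = 31)
    img[img <= 0] <- 0.01
    list(shape = shape, tmpl = tmpl, atlas = atlas, cl = cl, img = img)
  })
}

test_that("deformation update is stationary on aligned data and recovers a
           planted shift", {
  fx <- segmentation_fixture()
  y <- array(0, fx$shape)
  mask <- fx$img > 0
  y[mask] <- log(fx$img[mask])
  fit <- em_fit(y[mask],
                matrix(histatlas:::one_hot(fx$tmpl, 0:3),
                       ncol = 4)[as.vector(mask), ],
                fx$cl, NULL, 1, max_iters = 30)
  r0 <- optimize_deformation(y, fx$atlas, fit$gmm, fit$bias, fx$cl, mask,
                             cp_spacing = 6, maxit = 8)
  expect_lt(max(abs(r0$v$disp)), 0.2)
  expect_lte(r0$objective["final"], r0$objective["initial"] + 1e-12)
  # atlas shifted 3 voxels relative to the image
  sh <- array(0L, fx$shape)
  sh[1:25, , ] <- fx$tmpl$data[4:28, , ]
  gm <- class_intensity_model(means = list(10, 60, 110, 160),
                              variances = list(4, 16, 16, 16))
  img2 <- sample_intensity(label_volume(sh), gm, fx$cl, seed = 32)
  img2[img2 <= 0] <- 0.01
  y2 <- log(img2)
  fit2 <- em_fit(as.vector(y2),
                 matrix(histatlas:::one_hot(label_volume(sh), 0:3),
                        ncol = 4),
                 fx$cl, NULL, 1, max_iters = 30)
  r3 <- optimize_deformation(y2, fx$atlas, fit2$gmm, fit2$bias, fx$cl,
                             array(TRUE, fx$shape), cp_spacing = 6,
                             maxit = 25)
  fg <- as.vector(sh) > 0
  md <- colMeans(histatlas:::disp_matrix(r3$v)[fg, ])
  expect_lt(abs(md[1] - 3), 0.5)
})

test_that("end-to-end segmentation recovers the phantom", {
  fx <- segmentation_fixture()
  res <- segment_bayes(fx$img, fx$atlas, fx$cl, array(TRUE, fx$shape),
                       options = list(outer_iters = 2, cp_spacing = 6,
                                      def_maxit = 8))
  sums <- rowSums(matrix(res$posterior, ncol = 4))
  expect_lt(max(abs(sums - 1)), 1e-6)
  dd <- dice(res$labels, fx$tmpl$data)
  expect_gt(min(dd$dice), 0.95)
  # expected volumes of a one-hot posterior are exact voxel counts
  post <- res$posterior
  hard <- one_hot(res$labels, 0:3)
  vols <- colSums(matrix(hard, ncol = 4)) * prod(res$labels$voxel_size)
  manual <- vapply(0:3, function(l)
    sum(res$labels$data == l) * prod(res$labels$voxel_size), numeric(1))
  expect_equal(vols, manual)
  expect_error(segment_bayes(fx$img, fx$atlas,
                             tissue_clustering(stats::setNames(1, "0")),
                             array(TRUE, fx$shape)),
               "not mapped")
})

test_that("an informative atlas beats a uniform one", {
  fx <- segmentation_fixture()
  res_true <- segment_bayes(fx$img, fx$atlas, fx$cl, array(TRUE, fx$shape),
                            options = list(outer_iters = 1, def_maxit = 4))
  uni <- prob_atlas(array(0.25, c(fx$shape, 4)), 0:3)
  res_uni <- segment_bayes(fx$img, uni, fx$cl, array(TRUE, fx$shape),
                           options = list(outer_iters = 1, def_maxit = 4))
  d_true <- mean(dice(res_true$labels, fx$tmpl$data)$dice, na.rm = TRUE)
  d_uni <- mean(dice(res_uni$labels, fx$tmpl$data)$dice, na.rm = TRUE)
  expect_gt(d_true, d_uni)
})

test_that("segmentation is robust to multiplicative bias", {
  fx <- segmentation_fixture()
  opts <- list(outer_iters = 1, def_maxit = 4, bias_order = 2)
  res0 <- segment_bayes(fx$img, fx$atlas, fx$cl, array(TRUE, fx$shape),
                        options = opts)
  bf <- sample_bias(fx$shape, 2, 0.1, seed = 12)
  res1 <- segment_bayes(fx$img * bf$field, fx$atlas, fx$cl,
                        array(TRUE, fx$shape), options = opts)
  v0 <- res0$volumes$expected_volume_mm3
  v1 <- res1$volumes$expected_volume_mm3
  keep <- v0 > 100
  expect_lt(max(abs(v1[keep] - v0[keep]) / v0[keep]), 0.05)
})

test_that("registration-based segmentation propagates labels with the
           conventional defaults", {
  fx <- segmentation_fixture()
  out0 <- segment_by_registration(fx$img, fx$img, fx$tmpl,
                                  params = list(maxit = 5))
  expect_identical(out0$data, fx$tmpl$data)
  p <- attr(out0, "params")
  expect_equal(p$cp_spacing_vox, 5)
  expect_equal(p$lncc_sd_mm, 2.5)
  expect_equal(p$bend_weight, 0.001)
  # two-voxel translated target
  sh <- array(0L, fx$shape)
  sh[1:26, , ] <- fx$tmpl$data[3:28, , ]
  img_t <- array(0, fx$shape)
  img_t[1:26, , ] <- fx$img[3:28, , ]
  img_t[img_t <= 0] <- 0.01
  out2 <- segment_by_registration(img_t, fx$img, fx$tmpl,
                                  params = list(maxit = 30))
  dd <- dice(out2, sh)
  big <- dd$size_a > 100
  expect_gt(min(dd$dice[big]), 0.85)
})

test_that("dice matches hand counts and flags undefined labels", {
  a <- array(0L, c(6, 6, 6))
  expect_equal(dice(a, a)$dice, numeric(0))   # nothing but background
  a[2:3, 2:3, 2:3] <- 1L                      # 8-voxel cube
  b <- array(0L, c(6, 6, 6))
  b[2:3, 2:3, 3:4] <- 1L                      # shifted: 4 voxels overlap
  expect_equal(dice(a, b)$dice, 0.5)
  expect_equal(dice(a, a)$dice, 1)
  disj <- array(0L, c(6, 6, 6))
  disj[5, 5, 5] <- 1L
  expect_equal(dice(a, disj)$dice, 0)
  # label present in the mapping but empty in both volumes: NA, not 0
  mp <- c("1" = 1, "7" = 7)
  d <- dice(a, b, mp)
  expect_false(any(d$label == 7))
  a2 <- a; a2[1, 1, 1] <- 7L
  b2 <- b
  d2 <- dice(a2, b2)
  expect_equal(d2$dice[d2$label == 7], 0)     # present in a only
  expect_error(dice(a, array(0L, c(4, 4, 4))), "grids")
})
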