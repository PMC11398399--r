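# Synthetic-data generators: geometry, intensities, bias, stacks, blocks,
# cohorts — all seeded and returning ground truth.

test_that("label phantom places the requested ROIs deterministically", {
  spec <- phantom_spec(c(32, 32, 32), n_rois = 5, seed = 1)
  lv <- make_label_phantom(spec)
  # brute-force histogram oracle
  counts <- tabulate(as.vector(lv$data) + 1L, nbins = 6)
  expect_equal(sum(counts > 0), 6)
  expect_true(all(counts[2:6] >= 1))
  lv2 <- make_label_phantom(spec)
  expect_identical(lv$data, lv2$data)
  one <- make_label_phantom(phantom_spec(c(16, 16, 16), n_rois = 1,
                                         seed = 2))
  expect_setequal(unique(as.vector(one$data)), c(0L, 1L))
  expect_gt(mean(one$data == 0), 0)
  expect_error(phantom_spec(c(4, 32, 32), n_rois = 1), ">= 8")
  expect_error(make_label_phantom(phantom_spec(c(8, 8, 8), n_rois = 60,
                                               seed = 1)),
               "too small")
})

test_that("hierarchical labels nest inside their parent blob", {
  spec <- phantom_spec(c(32, 32, 32), n_rois = 4,
                       hierarchy = list(P = c(1, 2)), seed = 2)
  lv <- make_label_phantom(spec)
  expect_setequal(unique(as.vector(lv$data)), 0:4)
  parents <- attr(lv, "parents")
  expect_equal(unname(parents[c("1", "2")]), c("P", "P"))
  # children of one parent are closer to each other than the grid diagonal
  vc <- histatlas:::voxel_coords(dim(lv$data))
  c1 <- colMeans(vc[as.vector(lv$data) == 1, , drop = FALSE])
  c2 <- colMeans(vc[as.vector(lv$data) == 2, , drop = FALSE])
  expect_lt(sqrt(sum((c1 - c2)^2)), sqrt(sum(c(32, 32, 32)^2)) / 2)
})

test_that("intensity sampling follows the class mixture model", {
  spec <- phantom_spec(c(20, 20, 20), n_rois = 2, seed = 3)
  lv <- make_label_phantom(spec)
  cl <- identity_clustering(0:2)
  # near-degenerate variances give (almost) deterministic intensities
  m <- class_intensity_model(means = list(0, 10, 100),
                             variances = list(1e-12, 1e-12, 1e-12))
  img <- sample_intensity(lv, m, cl, seed = 4)
  expect_lt(max(abs(img[lv$data == 0])), 1e-4)
  expect_lt(max(abs(img[lv$data == 1] - 10)), 1e-4)
  expect_lt(max(abs(img[lv$data == 2] - 100)), 1e-4)
  # CLT bound: ROI sample mean within 3 standard errors
  m2 <- class_intensity_model(means = list(0, 50, 80),
                              variances = list(1, 25, 25))
  img2 <- sample_intensity(lv, m2, cl, seed = 5)
  for (lab in 1:2) {
    n <- sum(lv$data == lab)
    se <- 5 / sqrt(n)
    expect_lt(abs(mean(img2[lv$data == lab]) - c(50, 80)[lab]), 3 * se)
  }
  bad_cl <- tissue_clustering(stats::setNames(1:2, c("0", "1")))
  expect_error(sample_intensity(lv, m, bad_cl, seed = 1), "2")
})

test_that("bias fields are positive, smooth and seeded", {
  bf <- sample_bias(c(16, 16, 16), basis_order = 2, amplitude = 0.15,
                    seed = 6)
  expect_gt(min(bf$field), 0)
  expect_equal(sqrt(mean(bf$log_field^2)), 0.15, tolerance = 1e-10)
  expect_true(all(sample_bias(c(8, 8), 2, 0, 1)$field == 1))
  expect_error(sample_bias(c(8, 8), 2, -1, 1), "amplitude")
  # smoother than white noise of the same variance
  set.seed(7)
  wn <- array(stats::rnorm(prod(c(16, 16, 16))), c(16, 16, 16))
  wn <- wn * stats::sd(bf$log_field) / stats::sd(wn)
  expect_lt(bending_energy(bf$log_field), bending_energy(wn))
})

test_that("sample_svf respects amplitude, determinism and safety", {
  expect_true(all(sample_svf(c(16, 16), 4, 0, seed = 1)$disp == 0))
  v1 <- sample_svf(c(16, 16), 4, 1, seed = 2)
  v2 <- sample_svf(c(16, 16), 4, 1, seed = 2)
  expect_identical(v1$disp, v2$disp)
  mag <- sqrt(rowSums(histatlas:::disp_matrix(v1)^2))
  expect_equal(max(mag), 1, tolerance = 1e-10)
  expect_error(sample_svf(c(16, 16), 1, 1, seed = 1), "spacing")
})

test_that("section stacks carry consistent ground truth", {
  vol <- array(0, c(24, 24, 10))
  for (z in 1:10) {
    set.seed(100 + z)
    vol[, , z] <- histatlas:::smooth_gauss(
      array(stats::rnorm(24 * 24), c(24, 24)), 2) + 3
  }
  st <- make_section_stack(vol, NULL, n_sections = 5,
                           distortion = list(rigid = 1, bspline = 1),
                           seed = 5)
  expect_equal(st$S, 5)
  for (s in seq_len(st$S)) {
    sec <- st$sections[[s]]
    expect_equal(length(sec[c("M", "A", "B")]), 3)
    # landmarks are exact by construction: p + d_true(p) = q
    d <- exp_svf(sec$v_A, 6)
    q <- sec$landmarks_A$p +
      histatlas:::sample_disp(d, sec$landmarks_A$p)
    expect_lt(max(abs(q - sec$landmarks_A$q)), 1e-6)
  }
  # zero distortion: stains are deterministic remaps of the reference
  st0 <- make_section_stack(vol, NULL, 4,
                            distortion = list(rigid = 0, bspline = 0),
                            seed = 6, noise_sd = 0)
  sec <- st0$sections[[2]]
  rng <- diff(range(vol))
  expect_equal(sec$A, (pmax(sec$M - min(vol), 0) / rng)^1.4,
               tolerance = 1e-12)
  expect_error(make_section_stack(vol, NULL, 99), "exceeds")
})

test_that("blocks partition the foreground and reassemble exactly", {
  vol <- textured_body(c(24, 24, 24))
  bs <- make_blocks(vol, c(2, 2, 1), pose_jitter = 0, seed = 7)
  expect_equal(length(bs$blocks), 4)
  # pre-jitter masks are pairwise disjoint and tile the foreground
  acc <- array(0, dim(vol))
  for (b in bs$blocks) {
    sub <- array(0, dim(vol))
    rng <- lapply(1:3, function(a) b$origin[a]:(b$origin[a] + b$shape[a] - 1))
    sub <- do.call(`[<-`, c(list(sub), rng, list(b$mask)))
    acc <- acc + sub
  }
  expect_true(all(acc <= 1))
  expect_identical(acc == 1, vol != 0)
  # zero jitter: reassembly at stored poses is bit-exact (nearest neighbour)
  rec <- array(0, dim(vol))
  for (b in bs$blocks) {
    rng <- lapply(1:3, function(a) b$origin[a]:(b$origin[a] + b$shape[a] - 1))
    rec <- do.call(`[<-`, c(list(rec), rng, list(b$image)))
  }
  expect_identical(rec, vol)
  bs2 <- make_blocks(vol, c(2, 2, 1), pose_jitter = 1, seed = 8)
  bs3 <- make_blocks(vol, c(2, 2, 1), pose_jitter = 1, seed = 8)
  expect_identical(lapply(bs2$blocks, `[[`, "pose"),
                   lapply(bs3$blocks, `[[`, "pose"))
  expect_error(make_blocks(array(0, c(8, 8, 8)), c(2, 1, 1)), "empty")
})

test_that("cohorts realise the Laplace trajectory model", {
  tr <- trajectory_spec(c(30, 51.6, 73.3, 95),
                        theta_mu = matrix(c(5000, 4800, 4400, 4000), 1),
                        theta_b = matrix(rep(120, 4), 1),
                        roi_names = "hippocampus")
  empty <- make_cohort(0, c(30, 95), tr)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("subject_id", "age_years", "sex", "icv_mm3",
                        "hippocampus_mm3"))
  coh <- make_cohort(2000, c(30, 95), tr, seed = 8)
  expect_equal(sum(coh$sex == "M"), 1000)
  icv_ref <- attr(coh, "truth")$icv_ref
  vols <- coh$hippocampus_mm3 / coh$icv_mm3 * icv_ref
  # per-decade sample median tracks mu(a) within 3%
  for (lo in seq(30, 80, 10)) {
    sel <- coh$age_years >= lo & coh$age_years < lo + 10
    mu <- histatlas:::trajectory_eval(tr$theta_mu[1, ], lo + 5,
                                      tr$knot_ages)
    expect_lt(abs(stats::median(vols[sel]) - mu) / mu, 0.03)
  }
  # monotone-decreasing location with small scale: negative rank correlation
  expect_lt(stats::cor(vols, coh$age_years, method = "spearman"), 0)
  expect_error(trajectory_spec(c(30, 60), matrix(1:2, 1),
                               matrix(c(1, -1), 1)), "> 0")
})
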