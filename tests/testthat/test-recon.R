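# Reconstruction: registration graph arithmetic, robust L1 tree inference,
# overlap/gap regulariser, joint block alignment and section registration.

test_that("graph enumeration matches the count formulas for all S", {
  for (S in 3:50) {
    g <- build_registration_graph(S)
    expect_equal(nrow(g$measured), 15 * S - 18)
    expect_equal(nrow(g$latent), 3 * S - 1)
  }
  expect_error(build_registration_graph(2), "S >= 3")
})

test_that("the path matrix has full column rank and consistent signs", {
  g <- build_registration_graph(6)
  expect_equal(qr(g$P)$rank, 3 * 6 - 1)
  expect_true(all(g$P %in% c(-1, 0, 1)))
  # within-section inter-modality rows touch no reference-chain edge
  am <- which(g$measured$type == "AM")[2]
  expect_equal(sum(g$P[am, ] != 0), 1)
  ba <- which(g$measured$type == "BA")[2]
  expect_equal(sum(g$P[ba, ] != 0), 2)
})

test_that("L1 tree inference recovers exactly and resists outliers", {
  g <- build_registration_graph(10)
  set.seed(1)
  X <- matrix(stats::rnorm(29 * 3), 29, 3)
  Y <- g$P %*% X
  fit <- refine_bayesian(list(P = g$P, Y = Y))
  expect_lt(max(abs(fit$latents - X)), 1e-6)
  # all-zero measurements give all-zero latents
  z <- refine_bayesian(list(P = g$P, Y = Y * 0))
  expect_true(all(z$latents == 0))
  # one gross outlier: L1 stays accurate, least squares does not
  Y2 <- Y + matrix(stats::rnorm(length(Y)) * 0.01, nrow(Y))
  Y2[5, ] <- Y2[5, ] + 10 * max(abs(Y))
  l1 <- refine_bayesian(list(P = g$P, Y = Y2))
  l2 <- histatlas:::solve_tree_l2(g$P, Y2)
  expect_lt(max(abs(l1$latents - X)), 0.2)
  expect_gt(max(abs(l2 - X)), max(abs(l1$latents - X)))
  # the L1 objective at the LP solution is no worse than at the LS solution
  obj <- function(Z) sum(abs(Y2 - g$P %*% Z))
  expect_lte(obj(matrix(l1$latents, 29, 3)), obj(l2) + 1e-9)
  # rank-deficient path matrix is refused
  Pbad <- g$P
  Pbad[, 2] <- Pbad[, 1]
  expect_error(refine_bayesian(list(P = Pbad, Y = Y)), "rank")
})

test_that("overlap/gap penalty is zero at tiling, positive elsewhere,
           and differentiable", {
  vol <- textured_body(c(20, 20, 20))
  bs <- make_blocks(vol, c(2, 1, 1), pose_jitter = 0, seed = 4)
  expect_lt(overlap_gap_penalty(bs), 1e-6)
  poses <- lapply(bs$blocks, `[[`, "pose")
  poses[[2]]$trans <- c(-8, 0, 0)   # slide one block onto the other
  expect_gt(overlap_gap_penalty(bs, poses), overlap_gap_penalty(bs))
  empty <- bs
  empty$blocks <- list()
  expect_equal(overlap_gap_penalty(empty), 0)
  # analytic pose gradient matches central finite differences
  poses[[2]]$trans <- c(0.31, -0.22, 0.17)
  poses[[2]]$rot <- c(0.02, -0.015, 0.025)
  poses[[2]]$logscale <- 0.013
  g_an <- histatlas:::overlap_gap_penalty_grad(bs, poses)[[2]]
  fd <- vapply(1:7, function(j) {
    e <- 1e-5
    pv <- histatlas:::pose_to_vec(poses[[2]])
    up <- pv; up[j] <- up[j] + e
    dn <- pv; dn[j] <- dn[j] - e
    p1 <- poses; p1[[2]] <- histatlas:::vec_to_pose(up, 3)
    p2 <- poses; p2[[2]] <- histatlas:::vec_to_pose(dn, 3)
    (overlap_gap_penalty(bs, p1) - overlap_gap_penalty(bs, p2)) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(g_an - fd) / pmax(abs(fd), 1e-6)), 1e-4)
})

test_that("joint block alignment recovers jittered poses hierarchically", {
  vol <- textured_body(c(20, 20, 20))
  bs <- make_blocks(vol, c(2, 1, 1),
                    pose_jitter = list(trans = 1.2, rot_deg = 2,
                                       logscale = 0), seed = 5)
  res <- register_blocks_joint(bs, vol, maxit = 40)
  pe <- histatlas:::pose_error(res$poses,
                               lapply(bs$blocks, `[[`, "pose_true"))
  expect_lt(max(pe$trans_voxels), 0.5)
  expect_lt(max(pe$rot_deg), 0.5)
  # objective is non-increasing across hierarchy levels
  expect_true(all(diff(res$objective) <= 1e-9))
  # started at truth, the optimiser stays there
  bs0 <- make_blocks(vol, c(2, 1, 1), pose_jitter = 0, seed = 6)
  res0 <- register_blocks_joint(bs0, vol, maxit = 15)
  pe0 <- histatlas:::pose_error(res0$poses,
                                lapply(bs0$blocks, `[[`, "pose_true"))
  expect_lt(max(pe0$trans_voxels), 0.05)
  # zero intensity support: warning + identity poses
  far <- make_blocks(vol, c(2, 1, 1), pose_jitter = 0, seed = 7)
  for (i in seq_along(far$blocks)) far$blocks[[i]]$pose$trans <- c(500, 0, 0)
  expect_warning(rf <- register_blocks_joint(far, vol), "support")
  expect_true(all(vapply(rf$poses, function(p) all(p$trans == 0),
                         logical(1))))
})

test_that("shared-parameter levels tie the group pose parameters", {
  vol <- textured_body(c(20, 20, 20))
  bs <- make_blocks(vol, c(2, 1, 1),
                    pose_jitter = list(trans = 0.8, rot_deg = 1,
                                       logscale = 0), seed = 8)
  res <- register_blocks_joint(bs, vol,
                               hierarchy_schedule = list(c("g", "g")),
                               maxit = 25)
  # one shared similarity: identical rotation and scale for all members
  expect_equal(res$poses[[1]]$rot, res$poses[[2]]$rot)
  expect_equal(res$poses[[1]]$logscale, res$poses[[2]]$logscale)
})

test_that("section registration is exact at identity and recovers warps", {
  img <- smooth_image_2d(48)
  res <- register_section_nonlinear(img, img, cp_spacing = 8, maxit = 20)
  expect_lt(max(abs(res$v$disp)), 0.1)
  expect_equal(lncc(img, img, sigma = 3), 1, tolerance = 1e-2)
  tr <- sample_svf(c(48, 48), 8, 2, seed = 7)
  fix <- warp(img, exp_svf(tr, 6))
  res2 <- register_section_nonlinear(img, fix, cp_spacing = 8,
                                     lncc_radius = 3, reg_weight = 0.01,
                                     maxit = 40)
  derr <- histatlas:::disp_matrix(exp_svf(res2$v, 6)) -
    histatlas:::disp_matrix(exp_svf(tr, 6))
  expect_lt(sqrt(mean(rowSums(derr^2))), 0.5)
  expect_error(register_section_nonlinear(array(1, c(8, 8)), img),
               "constant")
})

test_that("pairwise measurements on an undistorted stack are near zero
           and antisymmetric", {
  vol <- array(0, c(24, 24, 8))
  for (z in 1:8) {
    set.seed(500 + z)
    vol[, , z] <- histatlas:::smooth_gauss(
      array(stats::rnorm(24 * 24), c(24, 24)), 2.5) + 4
  }
  st <- make_section_stack(vol, NULL, 4,
                           distortion = list(rigid = 0, bspline = 0),
                           seed = 9, noise_sd = 0)
  g <- build_registration_graph(st)
  g <- run_pairwise_registrations(st, g, cp_spacing = 8, maxit = 15)
  sh <- st$shape2d
  amax <- vapply(which(g$measured$type %in% c("AM", "BM", "BA")),
                 function(k) {
    max(abs(bspline_field(g$svfs[[k]], g$spacing, sh)))
  }, numeric(1))
  expect_lt(max(amax), 0.2)
  # forward and reverse neighbour measurements approximately negate
  fwd <- which(g$measured$type == "Mnbr" & g$measured$offset == 1)
  rev <- which(g$measured$type == "Mnbr" & g$measured$offset == -1)
  resid <- vapply(seq_along(fwd), function(i) {
    mean(abs(g$svfs[[fwd[i]]] + g$svfs[[rev[i]]]))
  }, numeric(1))
  expect_lt(mean(resid), 0.3)
  # deterministic given stack and settings
  g2 <- run_pairwise_registrations(st, build_registration_graph(st),
                                   cp_spacing = 8, maxit = 15)
  expect_identical(g$svfs, g2$svfs)
})

test_that("evaluation reports zero error for ground-truth transforms", {
  vol <- array(0, c(24, 24, 8))
  for (z in 1:8) {
    set.seed(700 + z)
    vol[, , z] <- histatlas:::smooth_gauss(
      array(stats::rnorm(24 * 24), c(24, 24)), 2.5) + 4
  }
  st <- make_section_stack(vol, NULL, 4,
                           distortion = list(rigid = 1, bspline = 1),
                           seed = 10)
  truth <- lapply(seq_len(st$S), function(s)
    list(A = velocity_field(-st$sections[[s]]$v_A$disp),
         B = velocity_field(-st$sections[[s]]$v_B$disp)))
  ev <- evaluate_reconstruction(st, truth)
  expect_lt(ev$mean, 1e-6)
  nolm <- st
  for (s in seq_len(nolm$S)) {
    nolm$sections[[s]]$landmarks_A <- list(p = matrix(0, 0, 2),
                                           q = matrix(0, 0, 2))
    nolm$sections[[s]]$landmarks_B <- list(p = matrix(0, 0, 2),
                                           q = matrix(0, 0, 2))
  }
  expect_error(evaluate_reconstruction(nolm, truth), "landmark")
})

test_that("the decoupled LAD linear program matches an independent
           quantile-regression solver", {
  set.seed(41)
  K <- 40; E <- 6
  repeat {
    P <- matrix(sample(c(-1, 0, 1), K * E, TRUE), K, E)
    if (qr(P)$rank == E) break
  }
  x0 <- stats::rnorm(E)
  y <- as.vector(P %*% x0 + stats::rnorm(K) * 0.1)
  y[3] <- y[3] + 5
  ours <- histatlas:::lad_lp(P, y, rep(1, K))$x
  ref <- quantreg::rq.fit.br(P, y, tau = 0.5)$coefficients
  obj <- function(b) sum(abs(y - P %*% b))
  # LAD solutions can be non-unique; the attained objectives must agree
  expect_lt(abs(obj(ours) - obj(ref)), 1e-8)
})
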