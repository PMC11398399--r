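# Volumetric statistics: covariate correction, LOO-LDA, ROC/DeLong,
# Spearman maps, Laplace trajectory fits.

cohort_fixture <- function(n = 400, seed = 5) {
  tr <- trajectory_spec(c(30, 51.6, 73.3, 95),
                        theta_mu = matrix(c(5000, 4800, 4400, 4000), 1),
                        theta_b = matrix(rep(120, 4), 1),
                        roi_names = "hippocampus")
  make_cohort(n, c(30, 95), tr, seed = seed)
}

test_that("volume correction divides by ICV and removes covariates", {
  coh <- cohort_fixture(100)
  X <- correct_volumes(coh, character(0))
  expect_equal(unname(X[, 1]), coh$hippocampus_mm3 / coh$icv_mm3)
  coh2 <- coh
  coh2$icv_mm3[1] <- 2 * coh$icv_mm3[1]
  X2 <- correct_volumes(coh2, character(0))
  expect_equal(X2[1, 1], X[1, 1] / 2)
  # after sex regression the per-sex means agree
  Xs <- correct_volumes(coh, "sex")
  expect_lt(abs(mean(Xs[coh$sex == "M", 1]) -
                mean(Xs[coh$sex == "F", 1])), 1e-10)
  expect_error(correct_volumes(coh[, setdiff(names(coh), "icv_mm3")]),
               "icv_mm3")
})

test_that("the LDA criterion follows the printed formula", {
  # Sigma = I, mu0 = (0,0), mu1 = (2,0), x = (2,0): L = 2
  expect_equal(lda_criterion(c(2, 0), c(0, 0), c(2, 0), diag(2)), 2)
  # midpoint of the class means scores exactly zero
  expect_equal(lda_criterion(c(1, 0), c(0, 0), c(2, 0), diag(2)), 0)
  expect_error(lda_criterion(c(1, 0), c(0, 0), c(2, 0),
                             matrix(0, 2, 2)), "singular")
})

test_that("LOO-LDA is sign-antisymmetric and scale-invariant", {
  set.seed(1)
  n <- 60
  g <- rep(0:1, each = n / 2)
  X <- matrix(stats::rnorm(n * 3), n, 3)
  X[g == 1, 1] <- X[g == 1, 1] + 2.5
  cr <- loo_lda(X, g, lambda = 1)
  expect_equal(loo_lda(X, 1 - g, lambda = 1), -cr)
  # common affine rescaling of one feature is absorbed by unit-variance
  # normalisation (up to the shift entering the mean structure equally)
  X2 <- X
  X2[, 2] <- X[, 2] * 37
  expect_equal(loo_lda(X2, g, lambda = 1), cr, tolerance = 1e-10)
  expect_error(loo_lda(X[1:5, ], c(0, 0, 0, 1, 1)), ">= 2")
})

test_that("ROC: separation, chance level, oracle and invariance", {
  sep <- c(rep(0, 10), rep(1, 10))
  r <- roc(c(stats::rnorm(10, -5), stats::rnorm(10, 5)), sep)
  expect_equal(r$auroc, 1)
  expect_equal(r$accuracy, 100)
  set.seed(2)
  g <- rep(0:1, 5000)
  cr <- stats::rnorm(10000)
  expect_lt(abs(roc(cr, g)$auroc - 0.5), 0.02)
  # exhaustive pairwise oracle on a tied sample
  set.seed(3)
  crt <- sample(1:5, 20, TRUE)
  gt <- rep(0:1, 10)
  oracle <- mean(outer(crt[gt == 1], crt[gt == 0],
                       function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(roc(crt, gt)$auroc, oracle)
  # monotone transform invariance
  set.seed(4)
  cr2 <- stats::rnorm(50)
  g2 <- rep(0:1, 25)
  expect_equal(roc(exp(cr2), g2)$auroc, roc(cr2, g2)$auroc)
  expect_error(roc(cr2, rep(1, 50)), "non-empty")
})

test_that("DeLong test: degenerate and bootstrap-checked cases", {
  set.seed(5)
  n <- 120
  g <- rep(0:1, each = n / 2)
  x <- stats::rnorm(n) + 1.2 * g
  same <- delong_test(x, x, g)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  y <- 0.5 * x + stats::rnorm(n) * 1.2
  dl <- delong_test(x, y, g)
  expect_gte(dl$var_diff, 0)
  # paired bootstrap oracle for the AUC difference
  auc <- function(cr, gg) {
    r <- rank(cr)
    n1 <- sum(gg == 1)
    (sum(r[gg == 1]) - n1 * (n1 + 1) / 2) / (n1 * sum(gg == 0))
  }
  set.seed(6)
  B <- 10000
  diffs <- replicate(B, {
    i <- sample(n, replace = TRUE)
    if (length(unique(g[i])) < 2) return(NA_real_)
    auc(x[i], g[i]) - auc(y[i], g[i])
  })
  diffs <- diffs[!is.na(diffs)]
  d0 <- auc(x, g) - auc(y, g)
  p_boot <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  expect_lt(abs(dl$p - p_boot), 0.02)
  expect_error(delong_test(x[1:10], y, g), "paired")
})

test_that("Spearman maps match a rank oracle and detect ageing", {
  coh <- cohort_fixture(120, seed = 9)
  res <- spearman_age_map(coh)
  X <- correct_volumes(coh, "sex")
  # brute-force average-rank Pearson-on-ranks oracle
  rx <- rank(X[, 1]); ry <- rank(coh$age_years)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res$rho[1], oracle, tolerance = 1e-12)
  # strictly monotone volumes give rho = +/-1
  mono <- coh[1:20, ]
  mono$icv_mm3 <- 1
  mono$hippocampus_mm3 <- mono$age_years^2
  expect_equal(spearman_age_map(mono, character(0))$rho, 1)
  mono$hippocampus_mm3 <- -mono$age_years
  expect_equal(spearman_age_map(mono, character(0))$rho, -1)
  # power at n = 500 on a declining trajectory
  big <- cohort_fixture(500, seed = 10)
  rs <- spearman_age_map(big)
  expect_lt(rs$rho[1], 0)
  expect_lt(rs$p[1], 0.01)
  # constant volumes: undefined, not zero
  const <- coh[1:20, ]
  const$hippocampus_mm3 <- const$icv_mm3 * 3
  expect_true(is.na(spearman_age_map(const, character(0))$rho))
})

test_that("Laplace trajectory fit recovers curves and calibrated bands", {
  # constant data with tiny noise
  set.seed(11)
  ages <- stats::runif(200, 30, 95)
  v <- 100 + stats::rnorm(200) * 0.1
  fc <- fit_laplace_bspline(ages, v)
  bc <- fc$band(seq(30, 95, 5))
  expect_lt(max(abs(bc$mu - 100)) / 100, 0.01)
  # parameter recovery at n = 1000 from the generator truth
  tr <- trajectory_spec(c(30, 51.6, 73.3, 95),
                        theta_mu = matrix(c(5000, 4800, 4400, 4000), 1),
                        theta_b = matrix(rep(120, 4), 1),
                        roi_names = "hippocampus")
  coh <- make_cohort(1000, c(30, 95), tr, seed = 6)
  icv_ref <- attr(coh, "truth")$icv_ref
  X <- correct_volumes(coh, "sex")
  fit <- fit_laplace_bspline(coh$age_years, X[, 1] * icv_ref)
  ag <- seq(30, 95, 1)
  mu_true <- histatlas:::trajectory_eval(tr$theta_mu[1, ], ag, tr$knot_ages)
  rmse <- sqrt(mean((fit$band(ag)$mu - mu_true)^2))
  expect_lt(rmse / diff(range(mu_true)), 0.05)
  # log-likelihood is non-decreasing across accepted steps
  expect_true(all(diff(fit$trace) > 0))
  # empirical coverage of mu +/- 3b on fresh draws
  set.seed(7)
  aa <- stats::runif(10000, 30, 95)
  btrue <- histatlas:::trajectory_eval(tr$theta_b[1, ], aa, tr$knot_ages)
  vv <- histatlas:::trajectory_eval(tr$theta_mu[1, ], aa, tr$knot_ages) +
    histatlas:::rlaplace(10000, btrue)
  bd <- fit$band(aa)
  cov <- mean(vv >= bd$lo & vv <= bd$hi)
  expect_lt(abs(cov - 0.95), 0.01)
  expect_error(fit_laplace_bspline(c(1, 2, 3), c(1, 2, 3)), ">= 10")
})

test_that("AUROC and DeLong agree with an independent reference
           implementation", {
  set.seed(31)
  n <- 80
  g <- rep(0:1, each = 40)
  x <- stats::rnorm(n) + g
  y <- 0.6 * x + stats::rnorm(n)
  ra <- pROC::roc(g, x, quiet = TRUE, direction = "<")
  expect_equal(roc(x, g)$auroc, as.numeric(pROC::auc(ra)),
               tolerance = 1e-12)
  rb <- pROC::roc(g, y, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  mine <- delong_test(x, y, g)
  expect_equal(mine$p, as.numeric(ref$p.value), tolerance = 1e-8)
})
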