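# Downstream volumetric statistics: covariate correction, regularised
# leave-one-out LDA with ROC and DeLong comparison, Spearman age-volume
# maps, and Laplace-noise B-spline ageing trajectories.

roi_columns <- function(cohort) {
  grep("_mm3$", names(cohort), value = TRUE)
}

#' Correct ROI volumes for head size and covariates
#'
#' Volumes are divided by intracranial volume (ICV), then the requested
#' covariates (`"sex"`, `"age"`) are regressed out by ordinary least squares;
#' the corrected feature is the residual plus the grand mean. When a `fit`
#' from a training fold is supplied, its coefficients are applied instead of
#' re-estimating (as required inside leave-one-out loops).
#'
#' @param cohort cohort data.frame (`subject_id, age_years, sex, icv_mm3`,
#'   ROI columns ending `_mm3`).
#' @param covariates character subset of `c("sex", "age")`.
#' @param fit optional correction fit from a previous call.
#' @return matrix of corrected features (subjects x ROIs) with the fitted
#'   correction attached as attribute `fit`.
#' @export
correct_volumes <- function(cohort, covariates = c("sex"), fit = NULL) {
  need <- c("icv_mm3",
            if ("sex" %in% covariates) "sex",
            if ("age" %in% covariates) "age_years")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0)
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  rois <- roi_columns(cohort)
  rois <- setdiff(rois, "icv_mm3")
  X <- as.matrix(cohort[rois]) / cohort$icv_mm3
  if (length(covariates) == 0 || nrow(cohort) == 0) {
    attr(X, "fit") <- list(covariates = character(0))
    return(X)
  }
  D <- cbind(intercept = rep(1, nrow(cohort)))
  if ("sex" %in% covariates)
    D <- cbind(D, sexM = as.numeric(cohort$sex == "M"))
  if ("age" %in% covariates) D <- cbind(D, age = cohort$age_years)
  if (is.null(fit)) {
    B <- qr.coef(qr(D), X)          # per-ROI regression coefficients
    B[is.na(B)] <- 0
    gm <- colMeans(X)
    fit <- list(covariates = covariates, coef = B, grand_mean = gm)
  }
  Xc <- X - D %*% fit$coef
  Xc <- sweep(Xc, 2, fit$grand_mean, `+`)
  attr(Xc, "fit") <- fit
  Xc
}

#' Linear discriminant criterion
#'
#' `L(x) = (mu1 - mu0)' Sigma^-1 (x - 0.5 (mu1 + mu0))`: zero at the class
#' midpoint, positive on the group-1 side.
#'
#' @param x feature vector.
#' @param m0,m1 class mean vectors.
#' @param Sigma (regularised) covariance matrix.
#' @return scalar criterion value.
#' @export
lda_criterion <- function(x, m0, m1, Sigma) {
  sol <- tryCatch(solve(Sigma, m1 - m0), error = function(e)
    stop("covariance is singular; regularise with lambda > 0",
         call. = FALSE))
  sum(sol * (x - 0.5 * (m1 + m0)))
}

#' Leave-one-out regularised linear discriminant criterion
#'
#' For each subject, the model is fitted on all the others: features are
#' scaled to unit variance, class means and the pooled covariance `S` are
#' estimated, the covariance is regularised as `Sigma = S + lambda I`, and
#' the criterion
#' `L(x) = (mu1 - mu0)' Sigma^-1 (x - 0.5 (mu1 + mu0))`
#' is evaluated at the left-out feature vector. Positive values vote for
#' group 1.
#'
#' @param features numeric matrix (subjects x features), already corrected.
#' @param group_labels vector coercible to 0/1 (two groups).
#' @param lambda ridge regulariser (> 0 recommended; unit-variance scaling
#'   makes `lambda = 1` a sensible fixed choice).
#' @param covariate_data optional data.frame with `sex`/`age_years`/`icv_mm3`
#'   plus raw ROI columns; when supplied together with `covariates`, the
#'   correction is re-fit on each training fold and applied to the held-out
#'   subject.
#' @param covariates covariates for fold-wise correction.
#' @return numeric vector of per-subject criterion values.
#' @export
loo_lda <- function(features, group_labels, lambda = 1,
                    covariate_data = NULL, covariates = NULL) {
  g <- as.integer(factor(group_labels)) - 1L
  if (length(unique(g)) != 2) stop("exactly two groups required")
  n <- length(g)
  foldwise <- !is.null(covariate_data) && !is.null(covariates)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (foldwise) {
      tr <- correct_volumes(covariate_data[-i, , drop = FALSE], covariates)
      te <- correct_volumes(covariate_data[i, , drop = FALSE], covariates,
                            fit = attr(tr, "fit"))
      Xtr <- tr; xte <- te[1, ]
    } else {
      Xtr <- features[-i, , drop = FALSE]
      xte <- features[i, ]
    }
    gtr <- g[-i]
    if (min(table(gtr)) < 2)
      stop("each group needs >= 2 training members after leave-one-out")
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xs <- sweep(Xtr, 2, sdv, `/`)
    xs <- xte / sdv
    m0 <- colMeans(Xs[gtr == 0, , drop = FALSE])
    m1 <- colMeans(Xs[gtr == 1, , drop = FALSE])
    S0 <- stats::cov(Xs[gtr == 0, , drop = FALSE])
    S1 <- stats::cov(Xs[gtr == 1, , drop = FALSE])
    n0 <- sum(gtr == 0); n1 <- sum(gtr == 1)
    S <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
    Sig <- S + lambda * diag(ncol(S))
    out[i] <- lda_criterion(xs, m0, m1, Sig)
  }
  out
}

#' ROC analysis of a criterion
#'
#' AUROC by the rank formulation (ties count one half); the operating point
#' is the ROC elbow, taken as the threshold maximising sensitivity +
#' specificity (Youden's J; ties broken towards higher sensitivity), where
#' the accuracy is reported.
#'
#' @param criteria numeric criterion values (higher favours group 1).
#' @param group_labels two-group labels.
#' @return list with `auroc`, `accuracy` (percent), `threshold`, and the
#'   ROC `curve` data.frame (threshold, sensitivity, specificity).
#' @export
roc <- function(criteria, group_labels) {
  g <- as.integer(factor(group_labels)) - 1L
  n1 <- sum(g == 1); n0 <- sum(g == 0)
  if (n0 == 0 || n1 == 0) stop("both groups must be non-empty")
  r <- rank(criteria, ties.method = "average")
  auc <- (sum(r[g == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  th <- c(-Inf, sort(unique(criteria)))
  curve <- data.frame(threshold = th,
                      sensitivity = vapply(th, function(t)
                        mean(criteria[g == 1] > t), numeric(1)),
                      specificity = vapply(th, function(t)
                        mean(criteria[g == 0] <= t), numeric(1)))
  J <- curve$sensitivity + curve$specificity
  best <- which(J == max(J))
  best <- best[which.max(curve$sensitivity[best])]
  thr <- curve$threshold[best]
  acc <- 100 * mean((criteria > thr) == (g == 1))
  list(auroc = auc, accuracy = acc, threshold = thr, curve = curve)
}

#' Paired DeLong test for two correlated AUROCs
#'
#' Compares the AUROCs of two criteria evaluated on the same subjects using
#' the DeLong structural-component variance estimate; returns the z statistic
#' and the two-sided p value.
#'
#' @param criteria_a,criteria_b paired criterion vectors.
#' @param group_labels two-group labels (same subjects for both criteria).
#' @return list with `z`, `p`, `auc_a`, `auc_b`, `var_diff`.
#' @export
delong_test <- function(criteria_a, criteria_b, group_labels) {
  if (length(criteria_a) != length(criteria_b) ||
      length(criteria_a) != length(group_labels))
    stop("criteria must be paired on identical subjects")
  g <- as.integer(factor(group_labels)) - 1L
  pos <- which(g == 1); neg <- which(g == 0)
  if (length(pos) == 0 || length(neg) == 0)
    stop("both groups must be non-empty")
  comp <- function(x) {
    psi <- outer(x[pos], x[neg], function(a, b)
      (a > b) + 0.5 * (a == b))
    list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
  }
  ca <- comp(criteria_a); cb <- comp(criteria_b)
  m <- length(pos); n <- length(neg)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  Svar <- s10 / m + s01 / n
  var_diff <- Svar[1, 1] + Svar[2, 2] - 2 * Svar[1, 2]
  d <- ca$auc - cb$auc
  if (var_diff <= 0) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(z = z, p = p, auc_a = ca$auc, auc_b = cb$auc, var_diff = var_diff)
}

#' Spearman age-volume correlation map
#'
#' Rank-based correlation of each corrected ROI volume with age, with
#' average-rank tie handling; rank statistics suit the monotone but
#' non-linear shape of ageing trajectories. Volumes are ICV-divided and
#' sex-corrected before correlation.
#'
#' @param cohort cohort data.frame.
#' @param covariates covariates regressed out before correlation.
#' @return data.frame with `roi`, `rho`, `p`, `p_bh` (Benjamini-Hochberg).
#' @export
spearman_age_map <- function(cohort, covariates = c("sex")) {
  if (nrow(cohort) < 3) stop("need >= 3 subjects")
  X <- correct_volumes(cohort, covariates)
  rois <- colnames(X)
  res <- data.frame(roi = sub("_mm3$", "", rois), rho = NA_real_,
                    p = NA_real_)
  for (j in seq_along(rois)) {
    x <- X[, j]
    if (stats::sd(x) < 1e-12 * (abs(mean(x)) + 1)) next  # constant: undefined
    ct <- suppressWarnings(
      stats::cor.test(x, cohort$age_years, method = "spearman",
                      exact = FALSE))
    res$rho[j] <- unname(ct$estimate)
    res$p[j] <- ct$p.value
  }
  res$p_bh <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Half-width of the central Laplace interval in units of the scale
#'
#' For Laplace noise, `P(|X| <= t b) = 1 - exp(-t)`; the central interval at
#' confidence `conf` therefore extends `-log(1 - conf)` scale units either
#' side of the location (about 3 for 95%).
#'
#' @param conf central coverage (default 0.95).
#' @return half-width in units of `b`.
#' @export
laplace_interval_halfwidth <- function(conf = 0.95) {
  -log(1 - conf)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))

# Least-absolute-deviation spline fit by iteratively reweighted least
# squares (initialisation for the Laplace trajectory fit).
lad_spline <- function(B, v, iters = 30) {
  th <- qr.coef(qr(B), v)
  for (i in seq_len(iters)) {
    r <- as.vector(v - B %*% th)
    w <- 1 / pmax(abs(r), 1e-6)
    th_new <- qr.coef(qr(B * sqrt(w)), v * sqrt(w))
    if (max(abs(th_new - th)) < 1e-10) { th <- th_new; break }
    th <- th_new
  }
  as.vector(th)
}

#' Fit an age-dependent Laplace model with B-spline location and scale
#'
#' Maximises the Laplace log-likelihood
#' `sum_n log p(v_n; mu(a_n), b(a_n))` where both the location `mu` and the
#' scale `b` are B-splines over age (scale through a softplus positivity
#' transform), by gradient ascent with backtracking step halving. The 95%
#' band is `mu(a) +/- 3 b(a)`.
#'
#' @param ages subject ages (years).
#' @param volumes corrected ROI volumes (same length).
#' @param knot_ages ordered control-point ages (default the four points
#'   30, 51.6, 73.3, 95 used for adult lifespan fits).
#' @param max_iters gradient-ascent cap.
#' @param tol relative log-likelihood convergence tolerance.
#' @return object of class `trajectory_fit`: `theta_mu`, `theta_b_raw`,
#'   `knot_ages`, `converged`, `loglik`, `trace`, and a `band(ages)`
#'   evaluator returning `mu`, `b`, `lo`, `hi`.
#' @export
fit_laplace_bspline <- function(ages, volumes,
                                knot_ages = c(30, 51.6, 73.3, 95),
                                max_iters = 5000, tol = 1e-10) {
  stopifnot(length(ages) == length(volumes))
  if (sum(ages >= min(knot_ages) & ages <= max(knot_ages)) < 10)
    stop("need >= 10 subjects within the knot age range")
  B <- trajectory_basis(ages, knot_ages)
  K <- ncol(B)
  b_floor <- 1e-6
  th_mu <- lad_spline(B, volumes)
  r0 <- volumes - B %*% th_mu
  scale0 <- max(stats::mad(as.vector(r0)), 10 * b_floor)
  th_braw <- rep(softplus_inv(scale0), K)
  ll_fun <- function(tm, tb) {
    mu <- B %*% tm
    b <- softplus(B %*% tb) + b_floor
    r <- volumes - mu
    sum(-log(2 * b) - abs(r) / b)
  }
  grad_fun <- function(tm, tb) {
    mu <- as.vector(B %*% tm)
    eta <- as.vector(B %*% tb)
    b <- softplus(eta) + b_floor
    r <- volumes - mu
    gmu <- crossprod(B, sign(r) / b)
    sig <- 1 / (1 + exp(-eta))
    gb <- crossprod(B, (abs(r) / b^2 - 1 / b) * sig)
    c(as.vector(gmu), as.vector(gb))
  }
  ll <- ll_fun(th_mu, th_braw)
  trace <- ll
  step <- 1 / max(1, length(ages))
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    gr <- grad_fun(th_mu, th_braw)
    moved <- FALSE
    for (h in seq_len(30)) {
      tm <- th_mu + step * gr[seq_len(K)]
      tb <- th_braw + step * gr[K + seq_len(K)]
      ll_new <- ll_fun(tm, tb)
      if (is.finite(ll_new) && ll_new > ll) {
        rel <- (ll_new - ll) / max(1, abs(ll))
        th_mu <- tm; th_braw <- tb; ll <- ll_new
        trace <- c(trace, ll)
        step <- step * 2
        moved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!moved) { converged <- TRUE; break }
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("Laplace B-spline fit did not converge after ", max_iters,
         " iterations; log-likelihood trace: ",
         paste(utils::tail(round(trace, 4), 5), collapse = ", "))
  band <- function(a) {
    Ba <- trajectory_basis(a, knot_ages)
    mu <- as.vector(Ba %*% th_mu)
    b <- as.vector(softplus(Ba %*% th_braw)) + b_floor
    # the 95% interval of a Laplace is mu +/- 3b (rounded convention;
    # the exact half-width is -log(0.05) = 2.996 scale units)
    data.frame(age = a, mu = mu, b = b, lo = mu - 3 * b, hi = mu + 3 * b)
  }
  structure(list(theta_mu = th_mu, theta_b_raw = th_braw,
                 theta_b = softplus(th_braw) + b_floor,
                 knot_ages = knot_ages, converged = converged,
                 loglik = ll, trace = trace, band = band),
            class = "trajectory_fit")
}
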