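# Outlier-removal MR estimators: L1-penalised per-SNP intercepts
# (MR-Lasso) and simulation-based residual testing (MR-PRESSO).

outlier_report <- function(method, removed, retained, estimate,
                           heterogeneity, extra = list()) {
  structure(c(list(method = method, removed = removed,
                   retained = retained, estimate = estimate,
                   heterogeneity = heterogeneity), extra),
            class = "mr_outlier_report")
}

#' @export
print.mr_outlier_report <- function(x, ...) {
  cat("<mr_outlier_report:", x$method, ">\n")
  cat("  removed:", if (length(x$removed)) paste(x$removed, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("  corrected estimate: theta = %.4f (se %.4f, p = %.3g)\n",
              x$estimate$theta, x$estimate$se, x$estimate$p))
  cat(sprintf("  retained-set heterogeneity: Q = %.2f on %d df, I2 = %.3f\n",
              x$heterogeneity$Q, x$heterogeneity$df, x$heterogeneity$i2))
  invisible(x)
}

# coordinate descent for the penalised objective
#   sum_j w_j (by_j - a_j - theta bx_j)^2 + lambda sum_j |a_j|
# with w_j = se_outcome^-2; exact soft-threshold update in a_j and
# weighted LS update in theta.
lasso_fit_lambda <- function(bx, by, w, lambda, theta0 = NULL,
                             tol = 1e-12, max_iter = 10000) {
  theta <- theta0 %||% (sum(w * bx * by) / sum(w * bx^2))
  alpha <- rep(0, length(bx))
  for (iter in seq_len(max_iter)) {
    r <- by - theta * bx
    alpha_new <- sign(r) * pmax(abs(r) - lambda / (2 * w), 0)
    theta_new <- sum(w * bx * (by - alpha_new)) / sum(w * bx^2)
    delta <- max(abs(theta_new - theta), max(abs(alpha_new - alpha)))
    theta <- theta_new
    alpha <- alpha_new
    if (delta < tol) break
  }
  obj <- sum(w * (by - alpha - theta * bx)^2) + lambda * sum(abs(alpha))
  list(theta = theta, alpha = alpha, objective = obj)
}

#' MR-Lasso outlier-removal estimate
#'
#' Augments the IVW regression with one L1-penalised intercept per
#' instrument: variants whose intercept is shrunk away from zero are
#' treated as pleiotropic and removed. The penalty is tuned by the
#' heterogeneity stopping rule: scanning the penalty path from large to
#' small, the first (largest) penalty whose zero-intercept set has
#' Cochran's Q at or below its 95% chi-square quantile is selected. The
#' post-selection causal estimate is IVW on the retained set.
#'
#' @param instruments instrument tibble (J >= 3).
#' @param lambda optional fixed penalty, bypassing the stopping rule
#'   (used mainly for validation against brute-force solutions).
#' @param n_lambda,lambda_min_ratio penalty-path resolution.
#' @param ivw_mode IVW mode for the post-selection estimate.
#' @return an `mr_outlier_report`: `removed`, `retained` instrument
#'   tibble, post-selection `estimate` and `heterogeneity`, plus the
#'   fitted `lambda`, `theta_lasso` and per-SNP `alpha`.
#' @export
mr_lasso <- function(instruments, lambda = NULL, n_lambda = 60,
                     lambda_min_ratio = 1e-4, ivw_mode = "re") {
  validate_instruments(instruments, 3, "mr_lasso")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  w <- instruments$se_outcome^-2
  theta_ivw <- sum(w * bx * by) / sum(w * bx^2)
  # smallest lambda at which every alpha is exactly zero
  lambda_max <- 2 * max(w * abs(by - theta_ivw * bx)) * 1.0001

  fit_and_report <- function(lam) lasso_fit_lambda(bx, by, w, lam)
  if (!is.null(lambda)) {
    fit <- fit_and_report(lambda)
    lam_sel <- lambda
  } else {
    path <- lambda_max * exp(seq(0, log(lambda_min_ratio),
                                 length.out = n_lambda))
    fit <- NULL
    lam_sel <- path[length(path)]
    theta_warm <- theta_ivw
    for (lam in path) {
      cand <- lasso_fit_lambda(bx, by, w, lam, theta0 = theta_warm)
      theta_warm <- cand$theta
      valid <- abs(cand$alpha) < 1e-9
      if (sum(valid) >= 2) {
        het <- mr_heterogeneity(instruments[valid, , drop = FALSE])
        if (het$Q <= qchisq(0.95, het$df)) {
          fit <- cand
          lam_sel <- lam
          break
        }
      }
    }
    if (is.null(fit)) fit <- cand   # fall through: most-relaxed fit
  }
  valid <- abs(fit$alpha) < 1e-9
  assert_that(sum(valid) >= 2,
              "no valid instruments remain after MR-Lasso selection")
  retained <- instruments[valid, , drop = FALSE]
  est <- mr_ivw(retained, mode = ivw_mode)
  est$method <- "mr-lasso"
  het <- mr_heterogeneity(retained)
  outlier_report(
    "mr-lasso",
    removed = instruments$snp[!valid],
    retained = retained,
    estimate = est[, c("method", "theta", "se", "ci_lo", "ci_hi", "p",
                       "or", "or_lo", "or_hi")],
    heterogeneity = het,
    extra = list(lambda = lam_sel, theta_lasso = fit$theta,
                 alpha = setNames(fit$alpha, instruments$snp))
  )
}

# leave-one-out fixed-effect IVW slopes in O(J) via running sums;
# columns of `by_mat` are datasets (observed or simulated)
loo_slopes <- function(bx, by_mat, w) {
  sxx <- sum(w * bx^2)
  sxy <- colSums(w * bx * by_mat)                  # one per dataset
  num <- sweep(-(w * bx) * by_mat, 2, sxy, "+")    # sxy - w_j bx_j by_j
  num / (sxx - w * bx^2)
}

#' MR-PRESSO global test and outlier correction
#'
#' Residual-sum-of-squares outlier detection: each instrument's
#' residual is measured against the leave-one-out IVW fit, and the
#' observed global RSS is compared with a parametric null in which
#' outcome betas are redrawn around their leave-one-out predictions.
#' Instruments whose per-SNP residual is extreme under the null
#' (Bonferroni-adjusted p < `outlier_alpha`) are removed, and the
#' corrected estimate is IVW on the remainder.
#'
#' @param instruments instrument tibble (J >= 4).
#' @param reps simulated null datasets (default 1000; below 100 a
#'   warning is issued).
#' @param seed simulation seed (default 1).
#' @param outlier_alpha per-family outlier significance (default 0.05).
#' @param ivw_mode IVW mode for the corrected estimate.
#' @return an `mr_outlier_report` with `global_rss`, `global_p` and the
#'   per-SNP outlier table `outlier_tests` in addition to the standard
#'   fields.
#' @export
mr_presso <- function(instruments, reps = 1000, seed = 1,
                      outlier_alpha = 0.05, ivw_mode = "re") {
  validate_instruments(instruments, 4, "mr_presso")
  if (reps < 100) warn("mr_presso with fewer than 100 replicates is unstable")
  j <- nrow(instruments)
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sey <- instruments$se_outcome
  w <- sey^-2

  theta_loo <- loo_slopes(bx, cbind(by), w)[, 1]
  obs_resid <- w * (by - theta_loo * bx)^2
  obs_rss <- sum(obs_resid)

  sims <- withr::with_seed(seed, {
    matrix(rnorm(j * reps, mean = theta_loo * bx, sd = sey),
           nrow = j, ncol = reps)
  })
  theta_loo_sim <- loo_slopes(bx, sims, w)
  sim_resid <- w * (sims - theta_loo_sim * bx)^2
  sim_rss <- colSums(sim_resid)

  global_p <- (1 + sum(sim_rss >= obs_rss)) / (reps + 1)
  p_raw <- (1 + rowSums(sim_resid >= obs_resid)) / (reps + 1)
  p_bonf <- pmin(1, p_raw * j)
  outliers <- p_bonf < outlier_alpha

  outlier_tests <- tibble(snp = instruments$snp,
                          rss = obs_resid, p = p_raw, p_bonf = p_bonf,
                          outlier = outliers)
  retained <- instruments[!outliers, , drop = FALSE]
  assert_that(nrow(retained) >= 2,
              "no valid instruments remain after MR-PRESSO correction")
  est <- mr_ivw(retained, mode = ivw_mode)
  est$method <- "mr-presso"
  outlier_report(
    "mr-presso",
    removed = instruments$snp[outliers],
    retained = retained,
    estimate = est[, c("method", "theta", "se", "ci_lo", "ci_hi", "p",
                       "or", "or_lo", "or_hi")],
    heterogeneity = mr_heterogeneity(retained),
    extra = list(global_rss = obs_rss, global_p = global_p,
                 outlier_tests = outlier_tests, reps = reps, seed = seed)
  )
}
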