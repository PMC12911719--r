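#' Run the full two-sample MR analysis
#'
#' The complete pipeline for one exposure-outcome pair: instrument
#' selection (genome-wide significance, instrument strength), LD
#' clumping, harmonisation, then the five causal estimators — IVW with
#' multiplicative random effects (the main estimate), MR-Egger,
#' weighted median, MR-Lasso and MR-PRESSO — plus heterogeneity
#' statistics and a leave-one-out analysis. The outcome is labelled
#' robust only when all five point estimates agree in sign and the
#' IVW-RE interval excludes the null, or when all five are individually
#' null.
#'
#' @param exposure,outcome GWAS summary tibbles (`snp`, `chr`, `pos`,
#'   `ea`, `nea`, `eaf`, `beta`, `se`, `p`, `n`).
#' @param ld optional r-squared matrix for clumping.
#' @param p_threshold,f_threshold instrument-selection thresholds.
#' @param r2_threshold,window_kb clumping parameters.
#' @param presso_reps,wm_boot_reps replicate counts for the seeded
#'   resampling estimators.
#' @param seed seed for all stochastic components.
#' @param clump set `FALSE` to skip clumping (instruments already
#'   independent).
#' @return an `mr_suite` object; see [tidy.mr_suite()],
#'   [glance.mr_suite()] and [autoplot.mr_suite()].
#' @export
run_mr_suite <- function(exposure, outcome, ld = NULL,
                         p_threshold = 5e-8, f_threshold = 10,
                         r2_threshold = 0.001, window_kb = 10000,
                         presso_reps = 1000, wm_boot_reps = 1000,
                         seed = 1, clump = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("MR stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  sel <- stage("select_instruments",
               mr_select_instruments(exposure, p_threshold, f_threshold))
  if (clump) {
    sel <- stage("clump",
                 suppressWarnings(
                   mr_clump(sel, ld, r2_threshold, window_kb)))
  }
  instruments <- stage("harmonize", mr_harmonize(sel, outcome))
  assert_that(nrow(instruments) >= 4,
              "fewer than 4 instruments survive selection/harmonisation")

  ivw <- stage("ivw", mr_ivw(instruments, "re"))
  egger <- stage("egger", mr_egger(instruments))
  wm <- stage("weighted_median",
              mr_weighted_median(instruments, wm_boot_reps,
                                 seed = derive_seed(seed, 1)))
  lasso <- stage("mr_lasso", mr_lasso(instruments))
  presso <- stage("mr_presso",
                  mr_presso(instruments, reps = presso_reps,
                            seed = derive_seed(seed, 2)))
  loo <- stage("leave_one_out", mr_leave_one_out(instruments))

  core <- c("method", "theta", "se", "ci_lo", "ci_hi", "p",
            "or", "or_lo", "or_hi")
  methods_tbl <- dplyr::bind_rows(
    ivw[, core], egger[, core], wm[, core],
    lasso$estimate[, core], presso$estimate[, core]
  )
  het_tbl <- dplyr::bind_rows(
    dplyr::mutate(ivw[, c("Q", "df", "p_het", "i2")], method = "ivw-re"),
    dplyr::mutate(lasso$heterogeneity, method = "mr-lasso"),
    dplyr::mutate(presso$heterogeneity, method = "mr-presso")
  )[, c("method", "Q", "df", "p_het", "i2")]

  same_sign <- length(unique(sign(methods_tbl$theta))) == 1
  ivw_sig <- ivw$p < 0.05
  all_null <- all(methods_tbl$p >= 0.05, na.rm = TRUE)
  verdict <- if (same_sign && ivw_sig) "robust effect"
  else if (all_null) "robust null"
  else "not robust"

  structure(list(
    instruments = instruments,
    methods = methods_tbl,
    heterogeneity = het_tbl,
    egger_intercept = egger[, c("intercept", "intercept_se", "intercept_p")],
    lasso = lasso,
    presso = presso,
    leave_one_out = loo,
    verdict = verdict,
    seed = seed
  ), class = "mr_suite")
}

#' @export
print.mr_suite <- function(x, ...) {
  cat("<mr_suite>", nrow(x$instruments), "instruments; verdict:",
      x$verdict, "\n")
  print(as.data.frame(x$methods), digits = 3)
  invisible(x)
}

#' Tidy the per-method causal estimates of an MR suite
#'
#' @param x an `mr_suite`.
#' @param ... unused.
#' @return tibble with one row per method: estimate on the log and OR
#'   scales with 95% CIs and p-values, joined with heterogeneity
#'   statistics where available.
#' @method tidy mr_suite
#' @export
tidy.mr_suite <- function(x, ...) {
  dplyr::left_join(x$methods, x$heterogeneity, by = "method")
}

#' One-row summary of an MR suite
#'
#' @param x an `mr_suite`.
#' @param ... unused.
#' @return tibble with instrument count, the main (IVW-RE) estimate,
#'   Egger intercept p, MR-PRESSO global p, outlier counts and the
#'   robustness verdict.
#' @method glance mr_suite
#' @export
glance.mr_suite <- function(x, ...) {
  ivw <- x$methods[x$methods$method == "ivw-re", ]
  tibble(
    n_instruments = nrow(x$instruments),
    theta_ivw = ivw$theta, se_ivw = ivw$se, p_ivw = ivw$p,
    or_ivw = ivw$or,
    q = x$heterogeneity$Q[x$heterogeneity$method == "ivw-re"],
    i2 = x$heterogeneity$i2[x$heterogeneity$method == "ivw-re"],
    egger_intercept_p = x$egger_intercept$intercept_p,
    presso_global_p = x$presso$global_p,
    n_lasso_removed = length(x$lasso$removed),
    n_presso_removed = length(x$presso$removed),
    verdict = x$verdict
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Render the MR results as a forest-plot table
#'
#' One row per method with the odds ratio and 95% CI formatted to three
#' significant figures, the p-value, and heterogeneity statistics where
#' defined (dashes otherwise).
#'
#' @param results an `mr_suite` or a tidy per-method tibble with
#'   columns `method`, `or`, `or_lo`, `or_hi`, `p` (optionally `Q`,
#'   `i2`).
#' @return tibble with formatted character columns `or_ci`, `p`, `Q`,
#'   `i2`.
#' @export
render_forest_table <- function(results) {
  tbl <- if (inherits(results, "mr_suite")) tidy(results) else
    as_tibble(results)
  assert_cols(tbl, c("method", "or", "or_lo", "or_hi", "p"),
              "MR results")
  assert_that(nrow(tbl) >= 1, "no MR results to render")
  sig3 <- function(v) formatC(signif(v, 3), format = "fg", flag = "#",
                              digits = 3)
  dash_or <- function(v, fmt) ifelse(is.na(v), "-", sprintf(fmt, v))
  tibble(
    method = tbl$method,
    or_ci = sprintf("%s (%s–%s)", sig3(tbl$or), sig3(tbl$or_lo),
                    sig3(tbl$or_hi)),
    p = dash_or(tbl$p, "%.3g"),
    Q = if ("Q" %in% names(tbl)) dash_or(tbl$Q, "%.2f") else
      rep("-", nrow(tbl)),
    i2 = if ("i2" %in% names(tbl)) dash_or(tbl$i2, "%.3f") else
      rep("-", nrow(tbl))
  )
}

#' Forest plot of MR causal estimates
#'
#' @param object an `mr_suite`.
#' @param ... unused.
#' @return a ggplot: odds ratio with 95% CI per method, log-scaled
#'   x-axis, null line at OR = 1.
#' @method autoplot mr_suite
#' @export
autoplot.mr_suite <- function(object, ...) {
  tbl <- object$methods
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$or, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$or_lo, xmax = .data$or_hi), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
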