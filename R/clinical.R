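#' Classify 12-month disease progression
#'
#' A subject progresses when their relative FVC decline over 12 months,
#' `(baseline - follow-up)/baseline`, is at least 10%, or when they die
#' within 12 months of baseline. Where follow-up lung function is
#' missing and the subject is alive, an adjudicated call is used if
#' supplied, otherwise the row is flagged missing. The rule is
#' scale-invariant: FVC in litres or millilitres gives identical calls.
#'
#' @param clinical tibble with `subject_id`, `fvc_baseline`,
#'   `fvc_12m` (may be NA), `death_12m` (logical), and optionally
#'   `adjudicated_progression` (logical, NA where not adjudicated).
#' @param decline_threshold relative-decline boundary, inclusive
#'   (default 0.10).
#' @return tibble `subject_id`, `rel_decline`, `progressed`, `basis`
#'   (`fvc-decline`, `death`, `adjudicated`, `not-progressed`,
#'   `missing`).
#' @export
classify_progression <- function(clinical, decline_threshold = 0.10) {
  assert_cols(clinical, c("subject_id", "fvc_baseline", "fvc_12m",
                          "death_12m"), "clinical table")
  assert_that(all(clinical$fvc_baseline > 0, na.rm = FALSE),
              "baseline FVC must be positive")
  adj <- if ("adjudicated_progression" %in% names(clinical))
    clinical$adjudicated_progression else rep(NA, nrow(clinical))
  decline <- (clinical$fvc_baseline - clinical$fvc_12m) /
    clinical$fvc_baseline
  # inclusive boundary, robust to floating-point representation of the
  # ratio (3.0 -> 2.7 is exactly a 10% decline and must progress)
  at_or_over <- decline >= decline_threshold - 1e-9
  basis <- dplyr::case_when(
    clinical$death_12m ~ "death",
    !is.na(decline) & at_or_over ~ "fvc-decline",
    !is.na(decline) ~ "not-progressed",
    !is.na(adj) ~ "adjudicated",
    TRUE ~ "missing"
  )
  progressed <- dplyr::case_when(
    basis %in% c("death", "fvc-decline") ~ TRUE,
    basis == "not-progressed" ~ FALSE,
    basis == "adjudicated" ~ as.logical(adj),
    TRUE ~ NA
  )
  tibble(subject_id = clinical$subject_id,
         rel_decline = decline,
         progressed = progressed,
         basis = basis)
}

#' Age propensity matching of cases to controls
#'
#' Fits a logistic propensity model of case status on age, then matches
#' greedily without replacement on the linear predictor, processing
#' cases in descending propensity order. With age as the single
#' covariate this reduces to nearest-age matching.
#'
#' @param cases tibble with `subject_id` and `age` for cases.
#' @param controls tibble with `subject_id` and `age` for the control
#'   pool.
#' @param ratio controls matched per case (default 1).
#' @return an object of class `match_result`: `pairs` tibble
#'   (`case_id`, `control_id`, `case_age`, `control_age`, `distance`),
#'   the propensity `model` summary, and pre/post standardised mean age
#'   differences.
#' @export
propensity_match <- function(cases, controls, ratio = 1) {
  assert_cols(cases, c("subject_id", "age"), "cases")
  assert_cols(controls, c("subject_id", "age"), "controls")
  assert_that(nrow(controls) >= nrow(cases) * ratio,
              "control pool smaller than cases * ratio")
  df <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(cases), case = 1L),
    dplyr::mutate(as_tibble(controls), case = 0L)
  )
  fit <- glm(case ~ age, family = binomial(), data = df)
  lp <- stats::predict(fit, type = "link")
  case_lp <- lp[df$case == 1]
  ctrl_lp <- lp[df$case == 0]
  ctrl_ids <- controls$subject_id
  ctrl_age <- controls$age
  available <- rep(TRUE, length(ctrl_lp))

  case_order <- order(case_lp, decreasing = TRUE)
  pairs <- vector("list", length(case_order) * ratio)
  k <- 0
  for (i in case_order) {
    for (r in seq_len(ratio)) {
      assert_that(any(available), "control pool exhausted")
      d <- abs(ctrl_lp - case_lp[i])
      d[!available] <- Inf
      jmin <- which.min(d)
      available[jmin] <- FALSE
      k <- k + 1
      pairs[[k]] <- tibble(case_id = cases$subject_id[i],
                           control_id = ctrl_ids[jmin],
                           case_age = cases$age[i],
                           control_age = ctrl_age[jmin],
                           distance = d[jmin])
    }
  }
  pairs <- dplyr::bind_rows(pairs)
  smd <- function(a, b) {
    (mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
  }
  pre <- smd(cases$age, controls$age)
  post <- smd(pairs$case_age, pairs$control_age)
  structure(list(pairs = pairs,
                 model = summary(fit)$coefficients,
                 smd_age_pre = pre, smd_age_post = post),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result>", nrow(x$pairs), "pairs; standardised mean age",
      sprintf("difference %.3f -> %.3f\n", x$smd_age_pre, x$smd_age_post))
  invisible(x)
}

#' Nonparametric group comparisons
#'
#' Thin, auditable wrappers around the standard tests used for the
#' cohort tables: Wilcoxon rank-sum for two groups, Kruskal-Wallis for
#' three or more, and Fisher's exact test for a 2x2 count table. All
#' p-values are two-sided, and group sizes are carried in the output so
#' every reported comparison is auditable.
#'
#' @param values numeric vector of the variable compared (rank-sum /
#'   Kruskal-Wallis), or a 2x2 count matrix (Fisher).
#' @param groups grouping factor aligned with `values` (ignored for
#'   Fisher).
#' @param test `"rank-sum"`, `"kruskal-wallis"` or `"fisher-exact"`.
#' @return one-row tibble `test`, `statistic`, `p`, `group_sizes`
#'   (list-column).
#' @export
compare_groups <- function(values, groups = NULL,
                           test = c("rank-sum", "kruskal-wallis",
                                    "fisher-exact")) {
  test <- match.arg(test)
  if (test == "fisher-exact") {
    assert_that(is.matrix(values) && all(dim(values) == c(2, 2)),
                "fisher-exact expects a 2x2 count matrix")
    ft <- fisher.test(values)
    return(tibble(test = test, statistic = unname(ft$estimate),
                  p = ft$p.value,
                  group_sizes = list(rowSums(values))))
  }
  groups <- factor(groups)
  sizes <- table(groups)
  assert_that(all(sizes > 0) && nlevels(groups) >= 2,
              "need at least 2 non-empty groups")
  if (test == "rank-sum") {
    assert_that(nlevels(groups) == 2,
                "rank-sum compares exactly 2 groups")
    ht <- wilcox.test(values ~ groups, exact = FALSE)
  } else {
    ht <- kruskal.test(values ~ groups)
  }
  tibble(test = test, statistic = unname(ht$statistic), p = ht$p.value,
         group_sizes = list(as.integer(sizes)))
}

#' Spearman rank correlation between two variables
#'
#' Tie-corrected rank correlation with a two-sided p-value. Constant
#' input makes the coefficient undefined; such calls are flagged rather
#' than erroring so that batch correlation tables stay rectangular.
#'
#' @param x,y paired numeric vectors (n >= 3 after removing incomplete
#'   pairs).
#' @param method correlation method (default `"spearman"`).
#' @return one-row tibble `rho`, `p`, `n`, `defined`.
#' @export
correlate_variables <- function(x, y, method = "spearman") {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  assert_that(length(x) >= 3, "need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = NA_real_, p = NA_real_, n = length(x),
                  defined = FALSE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method))
  tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
         defined = TRUE)
}
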