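# Two-sample Mendelian randomisation engine.
#
# Instruments are carried as a tibble with columns
#   snp, beta_exposure, se_exposure, beta_outcome, se_outcome, f_stat
# produced by mr_harmonize(); every estimator consumes that shape.

validate_instruments <- function(instruments, min_n = 1,
                                 caller = "this estimator") {
  assert_cols(instruments,
              c("snp", "beta_exposure", "se_exposure",
                "beta_outcome", "se_outcome"), "instrument set")
  assert_that(nrow(instruments) >= min_n,
              paste0(caller, " needs at least ", min_n, " instruments",
                     if (min_n == 2) "; use mr_wald_ratio() for one" else ""))
  assert_that(all(instruments$se_exposure > 0) &&
                all(instruments$se_outcome > 0),
              "standard errors must be positive")
  invisible(instruments)
}

mr_result_row <- function(method, theta, se, p = NULL, df = NULL) {
  p <- p %||% (if (is.null(df)) two_sided_p(theta / se) else
    2 * pt(-abs(theta / se), df = df))
  tibble(method = method, theta = theta, se = se,
         ci_lo = theta - Z95 * se, ci_hi = theta + Z95 * se, p = p,
         or = exp(theta), or_lo = exp(theta - Z95 * se),
         or_hi = exp(theta + Z95 * se))
}

#' Select genetic instruments from GWAS summary statistics
#'
#' Keeps variants at genome-wide significance (p strictly below the
#' threshold) whose instrument-strength F statistic, (beta/se)^2,
#' strictly exceeds the F threshold (guarding against weak-instrument
#' bias).
#'
#' @param rows GWAS summary tibble with at least `beta`, `se`, `p`.
#' @param p_threshold significance threshold (default 5e-8).
#' @param f_threshold instrument-strength threshold (default 10).
#' @return the retained rows with an `f_stat` column.
#' @export
mr_select_instruments <- function(rows, p_threshold = 5e-8,
                                  f_threshold = 10) {
  assert_cols(rows, c("beta", "se", "p"), "summary statistics")
  out <- as_tibble(rows)
  out$f_stat <- (out$beta / out$se)^2
  out <- out[out$p < p_threshold & out$f_stat > f_threshold, , drop = FALSE]
  assert_that(nrow(out) > 0, "no instruments pass the selection thresholds")
  out
}

#' Greedy LD clumping of summary statistics
#'
#' Sorts variants by ascending p, accepts each in turn, and discards
#' not-yet-accepted variants on the same chromosome within the window
#' whose r-squared with an accepted variant meets the threshold. Without
#' an LD matrix, falls back to distance-only pruning (any variant within
#' the window of an accepted one is discarded) with a warning.
#'
#' @param rows summary tibble with `snp`, `chr`, `pos`, `p`.
#' @param ld optional symmetric r-squared matrix with snp ids as
#'   dimnames; variants absent from it are treated as unlinked.
#' @param r2_threshold r-squared threshold (default 0.001).
#' @param window_kb window in kilobases (default 10000).
#' @return retained rows, sorted by chromosome and position.
#' @export
mr_clump <- function(rows, ld = NULL, r2_threshold = 0.001,
                     window_kb = 10000) {
  assert_cols(rows, c("snp", "chr", "pos", "p"), "summary statistics")
  rows <- as_tibble(rows)
  if (is.null(ld)) {
    warn("no LD matrix supplied; clumping by distance only")
  }
  window <- window_kb * 1000
  ord <- order(rows$p, rows$snp)   # snp id as deterministic tiebreak
  alive <- rep(TRUE, nrow(rows))
  accepted <- logical(nrow(rows))
  r2_of <- function(a, b) {
    if (is.null(ld)) return(1)     # distance-only: treat as linked
    if (!(a %in% rownames(ld)) || !(b %in% colnames(ld))) return(0)
    ld[a, b]
  }
  for (i in ord) {
    if (!alive[i]) next
    accepted[i] <- TRUE
    near <- which(alive & !accepted &
                    rows$chr == rows$chr[i] &
                    abs(rows$pos - rows$pos[i]) <= window)
    for (j in near) {
      if (r2_of(rows$snp[i], rows$snp[j]) >= r2_threshold) alive[j] <- FALSE
    }
  }
  out <- rows[accepted, , drop = FALSE]
  out[order(out$chr, out$pos), , drop = FALSE]
}

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonise exposure and outcome summary statistics
#'
#' Joins the two tables on variant id and aligns outcome effects to the
#' exposure's effect allele: swapped alleles flip the outcome beta and
#' complement its frequency; strand-flipped alleles are complemented
#' first. Palindromic variants (A/T, C/G) are dropped when the effect-
#' allele frequency is in the ambiguity band \[0.42, 0.58\] on either
#' side, otherwise aligned by frequency. Irreconcilable allele pairs are
#' dropped. The dropped variants and reasons are attached as attribute
#' `drops`.
#'
#' @param exposure,outcome summary tibbles with `snp`, `ea`, `nea`,
#'   `eaf`, `beta`, `se` (exposure rows typically from
#'   [mr_select_instruments()], so `f_stat` is carried through when
#'   present).
#' @param eaf_band palindromic ambiguity band (default `c(0.42, 0.58)`).
#' @return instrument tibble: `snp`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`, `f_stat`.
#' @export
mr_harmonize <- function(exposure, outcome, eaf_band = c(0.42, 0.58)) {
  assert_cols(exposure, c("snp", "ea", "nea", "eaf", "beta", "se"),
              "exposure")
  assert_cols(outcome, c("snp", "ea", "nea", "eaf", "beta", "se"),
              "outcome")
  ex <- as_tibble(exposure)
  if (!"f_stat" %in% names(ex)) ex$f_stat <- (ex$beta / ex$se)^2
  out <- as_tibble(outcome)
  j <- dplyr::inner_join(
    ex, out, by = "snp", suffix = c("_x", "_y")
  )
  comp <- function(a) unname(ALLELE_COMPLEMENT[a])
  keep <- logical(nrow(j))
  flip <- logical(nrow(j))
  reason <- character(nrow(j))
  for (i in seq_len(nrow(j))) {
    eax <- j$ea_x[i]; nex <- j$nea_x[i]
    eay <- j$ea_y[i]; ney <- j$nea_y[i]
    palindromic <- identical(comp(eax), nex)
    if (palindromic) {
      if ((j$eaf_x[i] >= eaf_band[1] && j$eaf_x[i] <= eaf_band[2]) ||
          (j$eaf_y[i] >= eaf_band[1] && j$eaf_y[i] <= eaf_band[2])) {
        reason[i] <- "palindromic_ambiguous_eaf"
        next
      }
      if (!identical(sort(c(eay, ney)), sort(c(eax, nex)))) {
        reason[i] <- "allele_mismatch"
        next
      }
      # align by frequency: same minor/major orientation means the
      # reported effect alleles refer to the same haplotype
      same_side <- (j$eaf_x[i] < 0.5) == (j$eaf_y[i] < 0.5)
      aligned_letters <- identical(eay, eax)
      keep[i] <- TRUE
      flip[i] <- aligned_letters != same_side
      if (!aligned_letters && same_side) flip[i] <- TRUE # swapped labels
      if (aligned_letters) flip[i] <- !same_side
    } else {
      if (identical(eay, eax) && identical(ney, nex)) {
        keep[i] <- TRUE
      } else if (identical(eay, nex) && identical(ney, eax)) {
        keep[i] <- TRUE; flip[i] <- TRUE
      } else if (identical(comp(eay), eax) && identical(comp(ney), nex)) {
        keep[i] <- TRUE
      } else if (identical(comp(eay), nex) && identical(comp(ney), eax)) {
        keep[i] <- TRUE; flip[i] <- TRUE
      } else {
        reason[i] <- "allele_mismatch"
      }
    }
  }
  beta_y <- ifelse(flip, -j$beta_y, j$beta_y)
  res <- tibble(snp = j$snp[keep],
                beta_exposure = j$beta_x[keep],
                se_exposure = j$se_x[keep],
                beta_outcome = beta_y[keep],
                se_outcome = j$se_y[keep],
                f_stat = j$f_stat[keep])
  drops <- tibble(snp = j$snp[!keep], reason = reason[!keep])
  if (nrow(drops) > 0) {
    inform(paste0("harmonisation dropped ", nrow(drops), " variant(s): ",
                  paste(unique(drops$reason), collapse = ", ")))
  }
  attr(res, "drops") <- drops
  res
}

wald_ratios <- function(instruments) {
  theta <- instruments$beta_outcome / instruments$beta_exposure
  se <- instruments$se_outcome / abs(instruments$beta_exposure)
  list(theta = theta, se = se, w = se^-2)
}

#' Wald ratio for a single instrument
#'
#' The per-SNP causal estimate: outcome effect divided by exposure
#' effect, with the first-order standard error
#' `se_outcome / |beta_exposure|`.
#'
#' @param instrument one-row instrument tibble.
#' @return one-row MR result tibble.
#' @export
mr_wald_ratio <- function(instrument) {
  validate_instruments(instrument, 1, "mr_wald_ratio")
  assert_that(nrow(instrument) == 1, "mr_wald_ratio takes one instrument")
  assert_that(instrument$beta_exposure != 0,
              "exposure effect is zero; Wald ratio undefined")
  wr <- wald_ratios(instrument)
  mr_result_row("wald", wr$theta, wr$se)
}

#' Cochran's Q and I-squared over Wald ratios
#'
#' @param instruments instrument tibble (J >= 2).
#' @return one-row tibble `Q`, `df`, `p_het`, `i2` where
#'   `i2 = max(0, (Q - df)/Q)`.
#' @export
mr_heterogeneity <- function(instruments) {
  validate_instruments(instruments, 2, "mr_heterogeneity")
  wr <- wald_ratios(instruments)
  theta <- sum(wr$w * wr$theta) / sum(wr$w)
  q <- sum(wr$w * (wr$theta - theta)^2)
  df <- length(wr$theta) - 1
  tibble(Q = q, df = df,
         p_het = stats::pchisq(q, df, lower.tail = FALSE),
         i2 = max(0, (q - df) / q))
}

#' Inverse-variance-weighted causal estimate
#'
#' Meta-analysis of per-SNP Wald ratios with weights `se^-2`. The
#' fixed-effect standard error is `(sum w)^-1/2`; the multiplicative
#' random-effects flavour (`"re"`, the default, used for main causal
#' estimates) inflates it by `max(1, sqrt(Q/df))` so that between-
#' instrument heterogeneity beyond chance widens the interval but can
#' never shrink it.
#'
#' @param instruments instrument tibble (J >= 2).
#' @param mode `"re"` (multiplicative random effects) or `"fixed"`.
#' @return one-row tibble combining the MR result and the heterogeneity
#'   statistics (`Q`, `df`, `p_het`, `i2`).
#' @export
mr_ivw <- function(instruments, mode = c("re", "fixed")) {
  mode <- match.arg(mode)
  validate_instruments(instruments, 2, "mr_ivw")
  wr <- wald_ratios(instruments)
  sw <- sum(wr$w)
  theta <- sum(wr$w * wr$theta) / sw
  se_fixed <- sw^-0.5
  het <- mr_heterogeneity(instruments)
  se <- if (mode == "re") {
    se_fixed * max(1, sqrt(het$Q / het$df))
  } else {
    se_fixed
  }
  dplyr::bind_cols(
    mr_result_row(paste0("ivw-", mode), theta, se),
    het
  )
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept, weights `se_outcome^-2`, after orienting all instruments
#' to non-negative exposure effects. The slope is the pleiotropy-robust
#' causal estimate under the InSIDE assumption; the intercept estimates
#' the average directional pleiotropic effect, and its two-sided test is
#' the directional-pleiotropy test. Standard errors are inflated by
#' `max(1, sqrt(RSS/(J-2)))` and p-values use a t distribution on J-2
#' degrees of freedom.
#'
#' @param instruments instrument tibble (J >= 3).
#' @return one-row tibble: slope MR result plus `intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(instruments) {
  validate_instruments(instruments, 3, "mr_egger")
  j <- nrow(instruments)
  sgn <- sign(instruments$beta_exposure)
  sgn[sgn == 0] <- 1
  bx <- instruments$beta_exposure * sgn
  by <- instruments$beta_outcome * sgn
  w <- instruments$se_outcome^-2
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X, X * w)
  xtwy <- crossprod(X, by * w)
  beta <- solve(xtwx, xtwy)[, 1]
  resid <- by - X %*% beta
  rss <- sum(w * resid^2)
  scale <- max(1, sqrt(rss / (j - 2)))
  se <- sqrt(diag(solve(xtwx))) * scale
  slope <- mr_result_row("egger", beta[["slope"]], se[["slope"]],
                         df = j - 2)
  slope$intercept <- beta[["intercept"]]
  slope$intercept_se <- se[["intercept"]]
  slope$intercept_p <- 2 * pt(-abs(beta[["intercept"]] / se[["intercept"]]),
                              df = j - 2)
  slope$residual_scale <- scale
  slope
}

weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(theta[1])
  if (s[length(s)] <= 0.5) return(theta[length(theta)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios (consistent when at
#' least half the instrument weight comes from valid instruments), with
#' the standardised cumulative-weight interpolation estimator. The
#' standard error comes from a seeded parametric bootstrap that redraws
#' each Wald ratio from `Normal(theta_j, se_j^2)`.
#'
#' @param instruments instrument tibble (J >= 3).
#' @param boot_reps bootstrap replicates for the SE (default 1000); 0
#'   returns the point estimate with `se = NA`.
#' @param seed bootstrap seed (default 1).
#' @return one-row MR result tibble.
#' @export
mr_weighted_median <- function(instruments, boot_reps = 1000, seed = 1) {
  validate_instruments(instruments, 3, "mr_weighted_median")
  wr <- wald_ratios(instruments)
  est <- weighted_median_point(wr$theta, wr$w)
  if (boot_reps > 0) {
    boots <- withr::with_seed(seed, {
      vapply(seq_len(boot_reps), function(i) {
        th <- rnorm(length(wr$theta), wr$theta, wr$se)
        weighted_median_point(th, wr$w)
      }, numeric(1))
    })
    se <- sd(boots)
    mr_result_row("weighted-median", est, se)
  } else {
    out <- mr_result_row("weighted-median", est, 1)
    out$se <- NA_real_; out$ci_lo <- NA_real_; out$ci_hi <- NA_real_
    out$p <- NA_real_; out$or_lo <- NA_real_; out$or_hi <- NA_real_
    out
  }
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect with each instrument omitted in turn,
#' flagging omissions that change the significance conclusion relative
#' to the full-set estimate (an instrument single-handedly driving or
#' suppressing the effect).
#'
#' @param instruments instrument tibble (J >= 3).
#' @param mode IVW mode passed to [mr_ivw()].
#' @return tibble with one row per omitted variant plus the full-set
#'   row (`omitted = "(none)"`); `flagged` marks conclusion changes.
#' @export
mr_leave_one_out <- function(instruments, mode = "re") {
  validate_instruments(instruments, 3, "mr_leave_one_out")
  full <- mr_ivw(instruments, mode)
  full_sig <- full$p < 0.05
  rows <- purrr::map_dfr(seq_len(nrow(instruments)), function(i) {
    r <- mr_ivw(instruments[-i, , drop = FALSE], mode)
    r$omitted <- instruments$snp[i]
    r
  })
  rows$flagged <- (rows$p < 0.05) != full_sig |
    (full_sig & sign(rows$theta) != sign(full$theta))
  full$omitted <- "(none)"
  full$flagged <- FALSE
  dplyr::bind_rows(full, rows)
}
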