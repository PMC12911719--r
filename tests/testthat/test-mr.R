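# Core MR machinery: selection, clumping, harmonisation, and the
# closed-form estimators.

test_that("instrument selection applies strict p and F thresholds", {
  rows <- tibble::tibble(
    snp = c("a", "b", "c", "d"),
    beta = c(0.1, 0.1, 0.01, 0.2),
    se = c(0.03, 0.01, 0.01, 0.01),
    p = c(1e-9, 5e-8, 1e-9, 1e-20)
  )
  kept <- mr_select_instruments(rows)
  # b excluded (p not < 5e-8), c excluded (F = 1 <= 10)
  expect_equal(kept$snp, c("a", "d"))
  expect_equal(kept$f_stat[1], (0.1 / 0.03)^2)
  expect_gt(kept$f_stat[1], 10)
  expect_error(mr_select_instruments(dplyr::mutate(rows, p = 0.5)),
               "no instruments")
})

test_that("selection keeps exactly the constructed true associations", {
  set.seed(2)
  n <- 100
  true <- seq_len(n) <= 20
  beta <- ifelse(true, 0.2, 0.002)
  se <- rep(0.01, n)
  rows <- tibble::tibble(snp = sprintf("s%03d", 1:n), beta = beta,
                         se = se, p = 2 * pnorm(-abs(beta / se)))
  kept <- mr_select_instruments(rows)
  expect_setequal(kept$snp, rows$snp[true])
})

test_that("clumping keeps the best of a linked pair and respects the window", {
  rows <- tibble::tibble(snp = c("a", "b"), chr = 1L,
                         pos = c(1e6, 2e6), p = c(1e-20, 1e-9))
  ld <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(mr_clump(rows, ld)$snp, "a")
  far <- dplyr::mutate(rows, pos = c(1e6, 2.1e7))   # 20 Mb apart
  expect_equal(sort(mr_clump(far, ld)$snp), c("a", "b"))
  expect_warning(mr_clump(rows), "distance only")
})

test_that("greedy clumping matches a brute-force oracle on LD blocks", {
  set.seed(33)
  n <- 20
  block <- rep(1:5, each = 4)
  rows <- tibble::tibble(
    snp = sprintf("v%02d", 1:n), chr = 1L,
    pos = block * 3e6 + rep(1:4, 5) * 1000,
    p = 10^-runif(n, 4, 30)
  )
  ld <- outer(block, block, function(a, b) ifelse(a == b, 0.8, 0))
  diag(ld) <- 1
  dimnames(ld) <- list(rows$snp, rows$snp)

  # oracle: plain loop version of greedy selection by ascending p
  remaining <- rows[order(rows$p), ]
  picked <- character()
  while (nrow(remaining) > 0) {
    top <- remaining[1, ]
    picked <- c(picked, top$snp)
    keep <- rep(TRUE, nrow(remaining))
    for (k in seq_len(nrow(remaining))) {
      same_chr <- remaining$chr[k] == top$chr
      close <- abs(remaining$pos[k] - top$pos) <= 1e7
      linked <- ld[top$snp, remaining$snp[k]] >= 0.001
      if (same_chr && close && linked) keep[k] <- FALSE
    }
    remaining <- remaining[keep, ]
  }
  expect_setequal(mr_clump(rows, ld)$snp, picked)
  # exactly one index variant per block survives
  expect_equal(length(picked), 5)
})

test_that("harmonisation aligns, flips, and drops by the allele rules", {
  exposure <- tibble::tibble(
    snp = c("same", "swap", "strand", "pal_ok", "pal_amb", "bad"),
    ea = c("A", "A", "A", "A", "A", "A"),
    nea = c("G", "G", "G", "T", "T", "C"),
    eaf = c(0.3, 0.3, 0.3, 0.2, 0.50, 0.3),
    beta = 0.1, se = 0.01, p = 1e-10
  )
  outcome <- tibble::tibble(
    snp = exposure$snp,
    ea = c("A", "G", "T", "A", "A", "A"),
    nea = c("G", "A", "C", "T", "T", "G"),
    eaf = c(0.3, 0.7, 0.3, 0.22, 0.50, 0.3),
    beta = 0.05, se = 0.01, p = 0.01
  )
  h <- suppressMessages(mr_harmonize(exposure, outcome))
  expect_setequal(h$snp, c("same", "swap", "strand", "pal_ok"))
  expect_equal(h$beta_outcome[h$snp == "same"], 0.05)
  expect_equal(h$beta_outcome[h$snp == "swap"], -0.05)
  expect_equal(h$beta_outcome[h$snp == "strand"], 0.05)
  expect_equal(h$beta_outcome[h$snp == "pal_ok"], 0.05)
  drops <- attr(h, "drops")
  expect_equal(drops$reason[drops$snp == "pal_amb"],
               "palindromic_ambiguous_eaf")
  expect_equal(drops$reason[drops$snp == "bad"], "allele_mismatch")
})

test_that("frequency-discordant palindromic variants are flipped", {
  exposure <- tibble::tibble(snp = "p", ea = "A", nea = "T", eaf = 0.2,
                             beta = 0.1, se = 0.01, p = 1e-10)
  outcome <- tibble::tibble(snp = "p", ea = "A", nea = "T", eaf = 0.8,
                            beta = 0.05, se = 0.01, p = 0.01)
  h <- mr_harmonize(exposure, outcome)
  expect_equal(h$beta_outcome, -0.05)
})

test_that("Wald ratio and its first-order SE are exact", {
  i <- make_instruments(by = 0.05, sey = 0.01, bx = 0.1)
  r <- mr_wald_ratio(i)
  expect_equal(r$theta, 0.5)
  expect_equal(r$se, 0.1)
  expect_equal(mr_wald_ratio(make_instruments(by = 0, bx = 0.1))$theta, 0)
  flip <- mr_wald_ratio(make_instruments(by = 0.05, sey = 0.01, bx = -0.1))
  expect_equal(flip$theta, -0.5)
  expect_equal(flip$se, 0.1)
  expect_error(mr_wald_ratio(make_instruments(by = 0.05, bx = 0)),
               "zero")
})

test_that("IVW matches the hand-computed meta-analysis", {
  ins <- make_instruments(by = c(0.2, 0.4, 0.6))
  fixed <- mr_ivw(ins, "fixed")
  expect_equal(fixed$theta, 0.4)
  expect_equal(fixed$se, sqrt(1 / 300))
  expect_equal(fixed$Q, 8, tolerance = 1e-12)
  expect_equal(fixed$df, 2)
  expect_equal(fixed$i2, 0.75)
  re <- mr_ivw(ins, "re")
  expect_equal(re$se, 2 * fixed$se)   # sqrt(Q/df) = 2

  const <- mr_ivw(make_instruments(by = rep(0.3, 4)))
  expect_equal(const$theta, 0.3)
  expect_equal(const$Q, 0)
  expect_equal(const$i2, 0)
  expect_equal(const$se, sqrt(1 / (4 / 0.01)))  # floor at 1
  expect_error(mr_ivw(make_instruments(by = 0.2)), "wald_ratio")
})

test_that("fixed-effect IVW equals weighted regression through the origin", {
  set.seed(4)
  for (i in 1:5) {
    ins <- make_instruments(by = rnorm(30, 0.1, 0.05),
                            sey = runif(30, 0.05, 0.2),
                            bx = rnorm(30, 0.2, 0.05))
    wls <- lm(beta_outcome ~ 0 + beta_exposure, data = ins,
              weights = ins$se_outcome^-2)
    expect_equal(mr_ivw(ins, "fixed")$theta, unname(coef(wls)),
                 tolerance = 1e-10)
  }
})

test_that("heterogeneity identities hold exactly", {
  # Q = df: three ratios spaced exactly one SE apart
  base <- make_instruments(by = c(0.3, 0.4, 0.5), sey = rep(0.1, 3))
  het <- mr_heterogeneity(base)
  expect_equal(het$Q, het$df, tolerance = 1e-12)
  expect_equal(het$i2, 0)
  re <- mr_ivw(base, "re")
  fx <- mr_ivw(base, "fixed")
  expect_equal(re$se, fx$se, tolerance = 1e-12)  # scale floor at 1

  doubled <- make_instruments(by = c(0.3, 0.4, 0.5),
                              sey = rep(0.1 / sqrt(2), 3))
  het2 <- mr_heterogeneity(doubled)
  expect_equal(het2$Q, 2 * het2$df, tolerance = 1e-12)
  expect_equal(het2$i2, 0.5)
  expect_true(mr_heterogeneity(make_instruments(by = rep(1, 5)))$i2 >= 0)
})

test_that("Egger recovers an exact affine relationship", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  ins <- make_instruments(by = 0.1 + 0.5 * bx, bx = bx)
  e <- mr_egger(ins)
  expect_equal(e$theta, 0.5, tolerance = 1e-10)
  expect_equal(e$intercept, 0.1, tolerance = 1e-10)
  expect_equal(e$residual_scale, 1)    # floor: RSS is zero
  expect_error(mr_egger(make_instruments(by = c(1, 2))), "3")
})

test_that("Egger is invariant to pre-orientation sign flips", {
  set.seed(6)
  ins <- make_instruments(by = rnorm(10, 0.05, 0.02),
                          bx = rnorm(10, 0.2, 0.05),
                          sey = runif(10, 0.05, 0.1))
  flipped <- ins
  flipped$beta_exposure[3] <- -flipped$beta_exposure[3]
  flipped$beta_outcome[3] <- -flipped$beta_outcome[3]
  expect_equal(mr_egger(ins)$theta, mr_egger(flipped)$theta)
  expect_equal(mr_egger(ins)$intercept, mr_egger(flipped)$intercept)
})

test_that("weighted median interpolates and resists a minority outlier", {
  expect_equal(mr_weighted_median(make_instruments(by = c(1, 2, 9)),
                                  boot_reps = 0)$theta, 2)
  expect_equal(mr_weighted_median(make_instruments(by = c(1, 2, 3, 4)),
                                  boot_reps = 0)$theta, 2.5)
  wm <- mr_weighted_median(make_instruments(by = c(1, 2, 9)),
                           boot_reps = 200, seed = 7)
  wm2 <- mr_weighted_median(make_instruments(by = c(1, 2, 9)),
                            boot_reps = 200, seed = 7)
  expect_equal(wm$se, wm2$se)  # seeded bootstrap is reproducible
})

test_that("estimators are invariant to ordering and joint sign flips", {
  set.seed(10)
  ins <- make_instruments(by = rnorm(20, 0.06, 0.03),
                          bx = rnorm(20, 0.2, 0.04),
                          sey = runif(20, 0.05, 0.15))
  perm <- ins[sample(nrow(ins)), ]
  signs <- sample(c(-1, 1), nrow(ins), replace = TRUE)
  flipped <- dplyr::mutate(ins,
                           beta_exposure = beta_exposure * signs,
                           beta_outcome = beta_outcome * signs)
  for (variant in list(perm, flipped)) {
    expect_equal(mr_ivw(variant)$theta, mr_ivw(ins)$theta,
                 tolerance = 1e-12)
    expect_equal(mr_egger(variant)$theta, mr_egger(ins)$theta,
                 tolerance = 1e-10)
    expect_equal(mr_weighted_median(variant, boot_reps = 0)$theta,
                 mr_weighted_median(ins, boot_reps = 0)$theta,
                 tolerance = 1e-12)
  }
})

test_that("leave-one-out reproduces weight algebra and flags drivers", {
  ins <- make_instruments(by = rep(0.3, 5))
  loo <- mr_leave_one_out(ins)
  expect_equal(nrow(loo), 6)
  expect_true(all(abs(loo$theta - 0.3) < 1e-12))
  expect_false(any(loo$flagged))

  # a zero-weight (huge-SE) instrument cannot move the estimate
  with_null <- dplyr::bind_rows(
    make_instruments(by = rnorm(10, 0.2, 0.05)),
    make_instruments(by = 5)[, ] |> dplyr::mutate(se_outcome = 1e6))
  full <- mr_ivw(with_null)$theta
  wo <- mr_ivw(with_null[1:10, ])$theta
  expect_lt(abs(full - wo), 1e-10)

  # one dominant instrument constructed to carry the significance
  dom <- dplyr::bind_rows(
    make_instruments(by = rnorm(6, 0, 1), sey = rep(2, 6)),
    dplyr::mutate(make_instruments(by = 0.5), se_outcome = 0.01))
  dom$snp <- sprintf("u%02d", seq_len(nrow(dom)))
  loo2 <- mr_leave_one_out(dom)
  dom_row <- loo2[loo2$omitted == dom$snp[7], ]
  if (mr_ivw(dom)$p < 0.05) expect_true(dom_row$flagged)
})

test_that("self-regression of an exposure on itself gives theta of 1", {
  sim <- simulate_gwas_pair(n_snps = 40, theta = 0.2, seed = 19)
  ins <- suppressMessages(
    mr_harmonize(mr_select_instruments(sim$exposure), sim$exposure))
  expect_equal(mr_ivw(ins)$theta, 1, tolerance = 1e-12)
  expect_equal(mr_ivw(ins)$Q, 0, tolerance = 1e-9)
})
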