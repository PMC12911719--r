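# Seeded generators for every input the pipeline consumes. Each is a
# pure function of its arguments and seed, and returns the generated
# tables together with the ground truth used to generate them.

#' Simulate a bulk WGS depth cohort with known mosaic fractions
#'
#' Depth model: each sample has an autosomal mean depth D (lognormal
#' jitter around `mean_depth`); total aligned bases over a region set of
#' length L are Poisson with mean depth*L, so region mean depths carry
#' realistic counting noise. The MSY mean depth has expectation
#' `0.5 * mappability * (1 - f) * D` for a sample with mosaic loss in a
#' fraction f of cells, so the expected copy number is
#' `0.5 * mappability * (1 - f)`.
#'
#' @param n_samples samples to generate (recycled over
#'   `mosaic_fractions`).
#' @param mosaic_fractions true per-sample mosaic fractions in \[0,1\].
#' @param mean_depth autosomal sequencing depth (default 20).
#' @param mappability effective MSY mappability factor in (0,1\]
#'   (default 0.75, putting the no-loss copy number at 0.375).
#' @param depth_cv lognormal coefficient of variation of per-sample
#'   depth (default 0.1).
#' @param msy_length,autosome_length,chr20_length simulated region-set
#'   lengths in bp (reduced from genome scale; counting noise at these
#'   lengths is already far below biological variation).
#' @param seed mandatory integer seed.
#' @return list with `depths` (long depth tibble), `truth` (per-sample
#'   tibble incl. expected copy number) and `config`.
#' @export
simulate_depth_cohort <- function(n_samples = 200,
                                  mosaic_fractions = c(0, 0.2, 0.5, 0.8),
                                  mean_depth = 20,
                                  mappability = 0.75,
                                  depth_cv = 0.1,
                                  msy_length = 1e6,
                                  autosome_length = 2e7,
                                  chr20_length = 1e6,
                                  seed) {
  assert_that(!missing(seed), "seed is mandatory")
  assert_that(all(mosaic_fractions >= 0 & mosaic_fractions <= 1),
              "mosaic fractions must be in [0, 1]")
  assert_that(mappability > 0 && mappability <= 1,
              "mappability must be in (0, 1]")
  f <- rep_len(mosaic_fractions, n_samples)
  withr::with_seed(seed, {
    sdlog <- sqrt(log(1 + depth_cv^2))
    d <- stats::rlnorm(n_samples, log(mean_depth) - sdlog^2 / 2, sdlog)
    mean_pois <- function(lambda_per_base, len) {
      rpois(n_samples, lambda_per_base * len) / len
    }
    depth_auto <- mean_pois(d, autosome_length)
    depth_chr20 <- mean_pois(d, chr20_length)
    depth_msy <- mean_pois(0.5 * mappability * (1 - f) * d, msy_length)
  })
  ids <- sprintf("S%04d", seq_len(n_samples))
  depths <- tibble(
    sample_id = rep(ids, times = 3),
    region_set = rep(c("MSY", "AUTOSOMES", "CHR20"), each = n_samples),
    mean_depth = c(depth_msy, depth_auto, depth_chr20)
  )
  truth <- tibble(sample_id = ids, mosaic_fraction = f,
                  depth = d,
                  expected_cn = 0.5 * mappability * (1 - f))
  list(depths = depths, truth = truth,
       config = list(n_samples = n_samples, mean_depth = mean_depth,
                     mappability = mappability, depth_cv = depth_cv,
                     seed = seed))
}

#' Simulate a single-cell cohort with known per-cell mLOY status
#'
#' Per cell: true chromosome-Y loss is Bernoulli with probability given
#' by a logistic model (baseline rate for controls, plus configurable
#' log-odds shifts for disease and, within a target cell type, for
#' more-fibrotic regions). Autosomal reads are Poisson(`autosome_mean`);
#' chrY reads are 0 for cells that truly lost Y and
#' Poisson(`lambda_y`) otherwise, so a fraction `exp(-lambda_y)` of
#' retained cells are technical zeros and the observed zero-ratio
#' proportion converges to `f + (1 - f) * exp(-lambda_y)`.
#'
#' @param n_subjects subjects (split between control and disease).
#' @param cells_per_sample cells per sample.
#' @param disease_prop proportion of subjects with disease.
#' @param base_rate control mLOY probability (default 0.2).
#' @param disease_shift disease log-odds shift (default 0.7).
#' @param region_shift extra log-odds in "more" fibrotic samples for
#'   `region_cell_type` cells (default 0; the paired design is only
#'   generated when `paired = TRUE`).
#' @param region_cell_type cell type receiving the region shift.
#' @param paired if TRUE every disease subject contributes a "less" and
#'   a "more" fibrotic sample; controls contribute one sample.
#' @param lambda_y mean chrY reads in cells that retain Y (default 3).
#' @param autosome_mean mean autosomal reads per cell (default 2000).
#' @param cell_types,cell_type_props cell-identity labels and their
#'   sampling proportions; lineages are derived from
#'   `lineage_of` (a named map cell type -> lineage).
#' @param lineage_of named character map from cell type to lineage.
#' @param diseases disease labels sampled (uniformly) for disease
#'   subjects.
#' @param seed mandatory integer seed.
#' @return list with `cells` (cell records + annotations), `samples`
#'   (sample metadata), `truth` (per-cell true loss + config-level
#'   expectations) and `config`.
#' @export
simulate_sc_cohort <- function(n_subjects = 24, cells_per_sample = 400,
                               disease_prop = 0.5,
                               base_rate = 0.2, disease_shift = 0.7,
                               region_shift = 0,
                               region_cell_type = "Alveolar macrophage",
                               paired = FALSE,
                               lambda_y = 3, autosome_mean = 2000,
                               cell_types = c("Alveolar macrophage",
                                              "Monocyte-derived macrophage",
                                              "CD4+ T cell", "AT2",
                                              "Fibroblast", "Endothelial"),
                               cell_type_props = c(0.3, 0.15, 0.15, 0.15,
                                                   0.15, 0.1),
                               lineage_of = c(
                                 "Alveolar macrophage" = "immune",
                                 "Monocyte-derived macrophage" = "immune",
                                 "CD4+ T cell" = "immune",
                                 "AT2" = "epithelial",
                                 "Fibroblast" = "mesenchymal",
                                 "Endothelial" = "endothelial"),
                               diseases = c("IPF", "sarcoidosis", "cHP"),
                               seed) {
  assert_that(!missing(seed), "seed is mandatory")
  assert_that(base_rate > 0 && base_rate < 1,
              "base_rate must be in (0, 1)")
  n_disease <- round(n_subjects * disease_prop)
  subj <- tibble(
    subject_id = sprintf("P%03d", seq_len(n_subjects)),
    disease = c(rep("control", n_subjects - n_disease),
                rep(diseases, length.out = n_disease))
  )
  samples <- subj |>
    dplyr::mutate(n_samp = ifelse(paired & .data$disease != "control",
                                  2L, 1L)) |>
    tidyr::uncount(.data$n_samp, .id = "rep") |>
    dplyr::mutate(
      region = dplyr::case_when(
        .data$disease == "control" ~ "none",
        paired & .data$rep == 1L ~ "less",
        paired & .data$rep == 2L ~ "more",
        TRUE ~ "none"
      ),
      sample_id = paste0(.data$subject_id, "_", .data$rep)
    ) |>
    dplyr::select(dplyr::all_of(c("sample_id", "subject_id", "disease",
                                  "region")))

  n_cells <- nrow(samples) * cells_per_sample
  cells <- samples[rep(seq_len(nrow(samples)), each = cells_per_sample), ]
  withr::with_seed(seed, {
    ct <- sample(cell_types, n_cells, replace = TRUE,
                 prob = cell_type_props)
    eta <- stats::qlogis(base_rate) +
      disease_shift * (cells$disease != "control") +
      region_shift * (cells$region == "more" & ct == region_cell_type)
    lost <- rbinom(n_cells, 1, plogis(eta)) == 1
    a_reads <- rpois(n_cells, autosome_mean)
    y_reads <- ifelse(lost, 0L, rpois(n_cells, lambda_y))
  })
  cells <- dplyr::mutate(
    cells,
    barcode = sprintf("%s-%06d", .data$sample_id,
                      seq_len(n_cells)),
    cell_type = ct,
    lineage = unname(lineage_of[ct]),
    y_reads = as.integer(y_reads),
    autosome_reads = as.integer(a_reads)
  )
  truth <- tibble(barcode = cells$barcode, true_loss = lost,
                  eta = eta)
  list(cells = as_tibble(cells), samples = samples, truth = truth,
       config = list(base_rate = base_rate, disease_shift = disease_shift,
                     region_shift = region_shift, lambda_y = lambda_y,
                     autosome_mean = autosome_mean, paired = paired,
                     expected_zero_proportion_control =
                       base_rate + (1 - base_rate) * exp(-lambda_y),
                     seed = seed))
}

#' Simulate a two-sample GWAS summary-statistics pair
#'
#' Generates exposure and outcome summary statistics for J independent
#' SNPs with a known causal effect theta. True exposure effects are
#' positive (effect alleles coded exposure-increasing); observed betas
#' carry sampling noise with standard errors derived from the allele
#' frequency and GWAS sample size, `se = 1/sqrt(2 p (1-p) N)`. An
#' `invalid_fraction` of SNPs receive a horizontal-pleiotropy intercept
#' alpha, drawn mean-zero (`"balanced"`) or with positive mean
#' (`"directional"`), specified in multiples of the per-SNP outcome SE.
#'
#' @param n_snps number of instruments.
#' @param theta true causal effect (log-OR of outcome per unit
#'   exposure; default 0).
#' @param n_exposure,n_outcome GWAS sample sizes (defaults 200000 and
#'   25000, the scale of the source GWAS pair).
#' @param beta_min,beta_mean true exposure effects are drawn from a
#'   shifted exponential, `beta_min + Exp(mean = beta_mean - beta_min)`:
#'   many instruments near the significance floor and a heavy tail of
#'   strong ones, the canonical GWAS effect-size shape. The spread of
#'   instrument strengths is what gives MR-Egger its power to separate
#'   an intercept from the slope.
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param invalid_fraction fraction of SNPs with pleiotropic effects
#'   (default 0.3; a warning is issued at or above 0.5, the weighted-
#'   median breakdown point).
#' @param alpha_mean,alpha_sd pleiotropy distribution in units of the
#'   outcome SE (directional default mean 10, sd 1 — pleiotropic
#'   effects around ten outcome SEs, clearly outside sampling noise:
#'   the outlier regime the removal estimators are designed for;
#'   balanced uses mean 0 with sd `alpha_sd`).
#' @param ld_blocks optional number of LD blocks; when given, SNPs are
#'   grouped into blocks with within-block r-squared `block_r2`,
#'   otherwise the LD matrix is the identity.
#' @param block_r2 within-block r-squared (default 0.8).
#' @param seed mandatory integer seed.
#' @return list with `exposure`, `outcome` (summary tibbles `snp, chr,
#'   pos, ea, nea, eaf, beta, se, p, n`), `ld` (r-squared matrix),
#'   `truth` (per-SNP validity and alpha; true theta) and `config`.
#' @export
simulate_gwas_pair <- function(n_snps = 100, theta = 0,
                               n_exposure = 200000, n_outcome = 25000,
                               beta_min = 0.02, beta_mean = 0.08,
                               pleiotropy = c("none", "balanced",
                                              "directional"),
                               invalid_fraction = 0.3,
                               alpha_mean = 10, alpha_sd = 1,
                               ld_blocks = NULL, block_r2 = 0.8,
                               seed) {
  assert_that(!missing(seed), "seed is mandatory")
  pleiotropy <- match.arg(pleiotropy)
  assert_that(invalid_fraction >= 0 && invalid_fraction <= 1,
              "invalid_fraction must be in [0, 1]")
  if (pleiotropy != "none" && invalid_fraction >= 0.5) {
    warn(paste("invalid fraction at or above 0.5 exceeds the",
               "weighted-median breakdown point"))
  }
  withr::with_seed(seed, {
    eaf <- runif(n_snps, 0.1, 0.9)
    se_x <- 1 / sqrt(2 * eaf * (1 - eaf) * n_exposure)
    se_y <- 1 / sqrt(2 * eaf * (1 - eaf) * n_outcome)
    true_bx <- beta_min + rexp(n_snps, rate = 1 / (beta_mean - beta_min))
    n_invalid <- if (pleiotropy == "none") 0L else
      round(n_snps * invalid_fraction)
    invalid <- seq_len(n_snps) %in%
      sample(seq_len(n_snps), n_invalid)
    alpha <- rep(0, n_snps)
    if (n_invalid > 0) {
      mu <- if (pleiotropy == "directional") alpha_mean else 0
      alpha[invalid] <- rnorm(n_invalid, mu, alpha_sd) * se_y[invalid]
    }
    obs_bx <- rnorm(n_snps, true_bx, se_x)
    obs_by <- rnorm(n_snps, theta * true_bx + alpha, se_y)
    alleles <- t(vapply(seq_len(n_snps), function(i) {
      sample(c("A", "C", "G", "T"), 2)
    }, character(2)))
  })
  # place SNPs far apart (one per 20 Mb) so default clumping keeps
  # independent instruments; LD blocks share a locus
  block <- if (is.null(ld_blocks)) seq_len(n_snps) else
    rep(seq_len(ld_blocks), length.out = n_snps)
  pos <- block * 2e7 + ave(seq_len(n_snps), block, FUN = seq_along) * 1000
  chrom <- rep(1L, n_snps)
  snp <- sprintf("rs%06d", seq_len(n_snps))
  ld <- diag(1, n_snps)
  dimnames(ld) <- list(snp, snp)
  if (!is.null(ld_blocks)) {
    same_block <- outer(block, block, "==")
    ld[same_block & ld < 1] <- block_r2
  }
  mk <- function(beta, se, n) {
    tibble(snp = snp, chr = chrom, pos = as.integer(pos),
           ea = alleles[, 1], nea = alleles[, 2], eaf = eaf,
           beta = beta, se = se, p = two_sided_p(beta / se), n = n)
  }
  list(exposure = mk(obs_bx, se_x, n_exposure),
       outcome = mk(obs_by, se_y, n_outcome),
       ld = ld,
       truth = tibble(snp = snp, true_beta_exposure = true_bx,
                      alpha = alpha, valid = !invalid),
       config = list(theta = theta, pleiotropy = pleiotropy,
                     invalid_fraction = invalid_fraction,
                     alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                     seed = seed))
}

#' Simulate a clinical cohort with configurable rank correlations
#'
#' Draws copy number, age, telomere length and lung-function variables
#' from a Gaussian copula whose correlation targets are specified on
#' the Spearman scale (converted to the latent Pearson scale via
#' `2*sin(pi*rho/6)`). The defaults mirror the observed cohort pattern:
#' copy number falls with age, rises with telomere length, and is
#' unrelated to lung function; survival is independent of mLOY.
#'
#' @param n subjects (default 387, the bulk case-cohort size).
#' @param rho_age,rho_telomere,rho_ppfvc,rho_pptlco target Spearman
#'   correlations of each variable with copy number (defaults -0.24,
#'   0.2, 0, 0).
#' @param cn_mean,cn_sd copy-number margin (defaults 0.312 / 0.0555, so
#'   the mean-minus-SD threshold sits near 0.2565).
#' @param seed mandatory integer seed.
#' @return list with `clinical` tibble (`subject_id`, `cn`, `age`,
#'   `telomere`, `ppfvc`, `pptlco`, `cpi`, `gap_stage`,
#'   `fvc_baseline`, `fvc_12m`, `death_12m`, `survival_days`,
#'   `event`), `truth` (the correlation targets) and `config`.
#' @export
simulate_clinical <- function(n = 387, rho_age = -0.24,
                              rho_telomere = 0.2, rho_ppfvc = 0,
                              rho_pptlco = 0,
                              cn_mean = 0.312, cn_sd = 0.0555, seed) {
  assert_that(!missing(seed), "seed is mandatory")
  rho_s <- c(age = rho_age, telomere = rho_telomere,
             ppfvc = rho_ppfvc, pptlco = rho_pptlco)
  rho_p <- 2 * sin(pi * rho_s / 6)
  k <- length(rho_p) + 1
  sigma <- diag(1, k)
  sigma[1, 2:k] <- rho_p
  sigma[2:k, 1] <- rho_p
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  assert_that(all(ev > 1e-10), "infeasible correlation targets")
  cholS <- chol(sigma)
  withr::with_seed(seed, {
    z <- matrix(rnorm(n * k), n, k) %*% cholS
    u <- pnorm(z)
    cn <- stats::qnorm(u[, 1], cn_mean, cn_sd)
    age <- stats::qnorm(u[, 2], 70.6, 8.3)
    telomere <- stats::qnorm(u[, 3], 0.77, 0.09)
    ppfvc <- stats::qnorm(u[, 4], 80, 18)
    pptlco <- stats::qnorm(u[, 5], 45, 15)
    decline <- rnorm(n, 0.08, 0.10)
    death_12m <- runif(n) < 0.05
    survival_days <- round(rexp(n, rate = 1 / 900))
    event <- runif(n) < 0.45
  })
  clinical <- tibble(
    subject_id = sprintf("P%04d", seq_len(n)),
    cn = pmax(cn, 0),
    age = pmax(age, 30),
    telomere = pmax(telomere, 0.2),
    ppfvc = pmax(ppfvc, 15),
    pptlco = pmax(pptlco, 10),
    cpi = pmax(pmin(100 - 0.6 * pmax(ppfvc, 15), 95), 5),
    gap_stage = as.integer(cut(age + (100 - pmax(ppfvc, 15)) / 2,
                               breaks = quantile(
                                 age + (100 - pmax(ppfvc, 15)) / 2,
                                 c(0, 0.45, 0.8, 1)),
                               include.lowest = TRUE, labels = FALSE)),
    fvc_baseline = pmax(2.9 + 0.015 * (ppfvc - 80), 1),
    fvc_12m = ifelse(death_12m, NA_real_,
                     pmax(fvc_baseline * (1 - decline), 0.5)),
    death_12m = death_12m,
    survival_days = survival_days,
    event = event
  )
  list(clinical = clinical,
       truth = tibble(variable = names(rho_s), rho_spearman = rho_s),
       config = list(n = n, cn_mean = cn_mean, cn_sd = cn_sd,
                     seed = seed))
}
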