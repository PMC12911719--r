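test_that("per-cell records compute the ratio and zero-ratio call", {
  counts <- tibble::tibble(
    barcode = c("b1", "b2", "b3"),
    sample_id = "s1",
    y_reads = c(3L, 0L, 0L),
    autosome_reads = c(97L, 100L, 0L)
  )
  expect_message(rec <- cell_read_counts(counts), "zero autosomal")
  expect_equal(nrow(rec), 2)            # zero-autosome cell dropped
  expect_equal(rec$ratio, c(3 / 97, 0))
  expect_equal(rec$mloy, c(FALSE, TRUE))
  expect_equal(nrow(attr(rec, "dropped")), 1)
})

test_that("matrix dialect sums chrY and autosomal features per barcode", {
  m <- Matrix::Matrix(
    matrix(c(3, 10, 87, 0, 5, 95), nrow = 3,
           dimnames = list(c("gY", "g1", "g2"), c("b1", "b2"))),
    sparse = TRUE)
  ann <- tibble::tibble(feature_id = c("gY", "g1", "g2"),
                        chromosome = c("chrY", "chr1", "chr22"))
  rec <- cell_read_counts(m, annotation = ann, sample_id = "s1")
  expect_equal(rec$y_reads, c(3, 0))
  expect_equal(rec$autosome_reads, c(97, 100))
  expect_equal(rec$mloy, c(FALSE, TRUE))
  bad_ann <- ann[1:2, ]
  expect_error(cell_read_counts(m, annotation = bad_ann), "g2")
  expect_error(cell_read_counts(m, annotation = ann, whitelist = character()),
               "empty")
})

test_that("per-cell calls match generator ground truth when lambda_y is high", {
  sim <- simulate_sc_cohort(n_subjects = 6, cells_per_sample = 200,
                            lambda_y = 30, seed = 12)
  rec <- cell_read_counts(sim$cells)
  joined <- dplyr::inner_join(rec, sim$truth, by = "barcode")
  # at lambda_y = 30 technical zeros have probability exp(-30)
  expect_equal(joined$mloy, joined$true_loss)
})

test_that("subject collapsing pools cells and preserves totals", {
  cells <- dplyr::bind_rows(
    make_cells(10, 100, "IPF", sample_id = "S1", subject_id = "P1"),
    make_cells(20, 50, "IPF", sample_id = "S2", subject_id = "P1"),
    make_cells(5, 80, "control", sample_id = "S3", subject_id = "P2")
  )
  samples <- tibble::tibble(sample_id = c("S1", "S2", "S3"),
                            subject_id = c("P1", "P1", "P2"),
                            disease = c("IPF", "IPF", "control"))
  rec <- cell_read_counts(cells)
  col <- collapse_subject(rec, samples)
  expect_equal(nrow(col), 230)
  expect_equal(sum(col$y_reads), sum(rec$y_reads))
  expect_equal(sum(col$autosome_reads), sum(rec$autosome_reads))
  smry <- sc_mloy_summary(col, by = "subject_id")
  p1 <- smry[smry$subject_id == "P1", ]
  expect_equal(p1$n_cells, 150)
  # pooled proportion = cell-count-weighted mean of sample proportions
  expect_equal(p1$mloy_proportion, (10 + 20) / 150)
  # single-sample subject is unchanged
  expect_equal(smry$mloy_proportion[smry$subject_id == "P2"], 5 / 80)

  bad <- samples
  bad$disease[2] <- "control"
  expect_error(collapse_subject(rec, bad), "conflicting disease")
})

test_that("two-level logistic association equals the closed-form odds ratio", {
  cells <- dplyr::bind_rows(make_cells(30, 100, "IPF"),
                            make_cells(10, 100, "control"))
  rec <- cell_read_counts(cells)
  res <- mloy_association(rec, "disease")
  or_oracle <- (30 / 70) / (10 / 90)
  expect_equal(signif(res$or, 4), signif(or_oracle, 4))
  expect_equal(res$log_odds, log(or_oracle), tolerance = 1e-6)
  expect_equal(res$or, exp(res$log_odds))
  expect_equal(res$ci_lo, exp(res$log_odds - qnorm(0.975) * res$se))

  same <- dplyr::bind_rows(make_cells(20, 100, "IPF"),
                           make_cells(20, 100, "control"))
  res0 <- mloy_association(cell_read_counts(same), "disease")
  expect_equal(res0$log_odds, 0, tolerance = 1e-8)
  expect_equal(res0$or, 1, tolerance = 1e-8)
})

test_that("completely separated levels are flagged unestimable, not dropped", {
  cells <- dplyr::bind_rows(make_cells(30, 100, "IPF"),
                            make_cells(0, 100, "sarcoidosis"),
                            make_cells(10, 100, "control"))
  res <- mloy_association(cell_read_counts(cells), "disease")
  expect_equal(nrow(res), 2)
  sarc <- res[res$level == "sarcoidosis", ]
  expect_false(sarc$estimable)
  expect_true(is.na(sarc$log_odds))
  expect_true(res$estimable[res$level == "IPF"])
})

test_that("FDR adjustment never falls below raw p and preserves order", {
  cells <- dplyr::bind_rows(make_cells(35, 100, "IPF"),
                            make_cells(18, 100, "cHP"),
                            make_cells(12, 100, "NSIP"),
                            make_cells(10, 100, "control"))
  res <- mloy_association(cell_read_counts(cells), "disease")
  expect_true(all(res$p_fdr >= res$p))
  ord <- order(res$p)
  expect_true(all(diff(res$p_fdr[ord]) >= -1e-12))
  expect_equal(res$p_fdr, p.adjust(res$p, "BH"))
})

test_that("disease log-odds shift is recovered by the association model", {
  sim <- simulate_sc_cohort(n_subjects = 10, cells_per_sample = 400,
                            disease_shift = 0.7, lambda_y = 9,
                            diseases = "IPF", seed = 8)
  rec <- collapse_subject(cell_read_counts(sim$cells), sim$samples)
  res <- mloy_association(rec, "disease")
  expect_lt(res$ci_lo, exp(0.7))
  expect_gt(res$ci_hi, exp(0.7))
})

test_that("paired-region model matches the 2x2 oracle for one subject", {
  cells <- dplyr::bind_rows(
    make_cells(20, 100, "IPF", sample_id = "S1", subject_id = "P1"),
    make_cells(10, 100, "IPF", sample_id = "S2", subject_id = "P1")
  )
  samples <- tibble::tibble(sample_id = c("S1", "S2"),
                            subject_id = "P1", disease = "IPF",
                            region = c("more", "less"))
  rec <- collapse_subject(cell_read_counts(cells), samples)
  res <- paired_region_association(rec)
  expect_equal(res$or, (20 / 80) / (10 / 90), tolerance = 1e-6)

  flat <- dplyr::bind_rows(
    make_cells(10, 100, "IPF", sample_id = "S1", subject_id = "P1"),
    make_cells(10, 100, "IPF", sample_id = "S2", subject_id = "P1")
  )
  rec2 <- collapse_subject(cell_read_counts(flat), samples)
  expect_equal(paired_region_association(rec2)$or, 1, tolerance = 1e-6)

  unpaired <- paired_region_association(
    dplyr::mutate(rec, region = "less"))
  expect_equal(nrow(unpaired), 0)
  expect_match(attr(unpaired, "reason"), "no subjects")
})

test_that("region effect concentrates in the shifted cell type", {
  sim <- simulate_sc_cohort(n_subjects = 16, cells_per_sample = 700,
                            disease_prop = 1, paired = TRUE,
                            region_shift = 0.5,
                            region_cell_type = "Alveolar macrophage",
                            lambda_y = 9, seed = 14)
  rec <- collapse_subject(cell_read_counts(sim$cells), sim$samples)
  mac <- paired_region_association(rec, "Alveolar macrophage")
  expect_gt(mac$or, 1)
  expect_lt(mac$p, 0.05)
  fib <- paired_region_association(rec, "Fibroblast")
  # no shift was injected here: estimate well inside +/-0.25 log-odds
  expect_lt(abs(fib$log_odds), 0.25)
})

test_that("DE comparator is the top quartile of non-mLOY ratios, tie-inclusive", {
  rec <- tibble::tibble(
    barcode = as.character(1:6), sample_id = "s",
    y_reads = c(0L, 0L, 1L, 2L, 3L, 4L),
    autosome_reads = 100L,
    ratio = c(0, 0, 0.01, 0.02, 0.03, 0.04),
    mloy = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  grp <- select_de_groups(rec)
  expect_equal(attr(grp, "cutoff"), 0.0375)
  expect_equal(as.character(grp$de_group),
               c("mloy", "mloy", "excluded", "excluded", "excluded",
                 "comparator"))

  equal_rec <- dplyr::mutate(rec, ratio = c(0, 0, rep(0.02, 4)))
  grp2 <- select_de_groups(equal_rec)
  expect_equal(sum(grp2$de_group == "comparator"), 4)

  no_mloy <- dplyr::mutate(rec, mloy = FALSE,
                           ratio = c(0.01, 0.015, 0.01, 0.02, 0.03, 0.04))
  grp3 <- select_de_groups(no_mloy)
  expect_equal(sum(grp3$de_group == "mloy"), 0)
  expect_true(all(grp3$de_group %in% c("comparator", "excluded")))
})
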