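#' Per-cell chrY and autosomal read counts
#'
#' Builds the per-cell record the single-cell mLOY analysis works from:
#' reads (or UMIs) on chromosome-Y features, reads on autosomal
#' features, their ratio, and the binary mLOY call. A cell is called
#' mLOY exactly when its chrY/autosome ratio is zero, i.e. no reads map
#' to chromosome Y at all. Cells with zero autosomal reads carry no
#' information about the ratio and are dropped (recorded in the
#' `dropped` attribute).
#'
#' @param counts either a per-cell count table (columns `barcode`,
#'   `sample_id`, `y_reads`, `autosome_reads`) or a feature-by-cell
#'   sparse/dense count matrix with feature ids as row names and
#'   barcodes as column names.
#' @param annotation required when `counts` is a matrix: data frame
#'   mapping `feature_id` to `chromosome` (`chrY`, `chr1`..`chr22`;
#'   other chromosomes are ignored).
#' @param whitelist optional barcode whitelist; when `counts` is a
#'   matrix it must be non-empty and all whitelisted barcodes present.
#' @param sample_id sample id to attach when the matrix dialect is used.
#' @return tibble of cell records: `barcode`, `sample_id`, `y_reads`,
#'   `autosome_reads`, `ratio`, `mloy` (logical).
#' @export
cell_read_counts <- function(counts, annotation = NULL, whitelist = NULL,
                             sample_id = NULL) {
  if (is.data.frame(counts)) {
    assert_cols(counts, c("barcode", "sample_id", "y_reads",
                          "autosome_reads"), "cell count table")
    rec <- as_tibble(counts)
    if (!is.null(whitelist)) {
      assert_that(length(whitelist) > 0, "empty barcode whitelist")
      rec <- rec[rec$barcode %in% whitelist, , drop = FALSE]
    }
  } else {
    assert_that(!is.null(annotation),
                "a feature annotation is required for matrix input")
    assert_cols(annotation, c("feature_id", "chromosome"), "annotation")
    feats <- rownames(counts)
    assert_that(!is.null(feats), "count matrix must have feature rownames")
    ann <- setNames(as.character(annotation$chromosome),
                    as.character(annotation$feature_id))
    unknown <- feats[!feats %in% names(ann)]
    assert_that(length(unknown) == 0,
                paste0("annotation missing chromosome for feature(s): ",
                       paste(head(unknown, 10), collapse = ", ")))
    chrom <- ann[feats]
    if (!is.null(whitelist)) {
      assert_that(length(whitelist) > 0, "empty barcode whitelist")
      missing <- setdiff(whitelist, colnames(counts))
      assert_that(length(missing) == 0,
                  paste0("whitelisted barcode(s) absent from matrix: ",
                         paste(head(missing, 5), collapse = ", ")))
      counts <- counts[, colnames(counts) %in% whitelist, drop = FALSE]
    }
    autosomes <- paste0("chr", 1:22)
    y_counts <- Matrix::colSums(counts[chrom == "chrY", , drop = FALSE])
    a_counts <- Matrix::colSums(counts[chrom %in% autosomes, , drop = FALSE])
    rec <- tibble(barcode = colnames(counts),
                  sample_id = sample_id %||% "sample",
                  y_reads = as.double(y_counts),
                  autosome_reads = as.double(a_counts))
  }
  dropped <- rec[rec$autosome_reads <= 0, , drop = FALSE]
  if (nrow(dropped) > 0) {
    inform(paste0("dropping ", nrow(dropped),
                  " cell(s) with zero autosomal reads"))
  }
  rec <- rec[rec$autosome_reads > 0, , drop = FALSE]
  rec$ratio <- rec$y_reads / rec$autosome_reads
  rec$mloy <- rec$y_reads == 0
  attr(rec, "dropped") <- dropped
  rec
}

#' Pool cells from multiple samples of the same subject
#'
#' Re-keys cell records to subject level, joining on a sample metadata
#' table. Per-sample identity (and fibrotic-region label) is retained so
#' that paired within-subject analyses remain possible after collapsing.
#'
#' @param records cell records from [cell_read_counts()].
#' @param samples metadata tibble: `sample_id`, `subject_id`, `disease`,
#'   and optionally `region` (`"less"`, `"more"`, `"none"`).
#' @return records joined with subject-level metadata.
#' @export
collapse_subject <- function(records, samples) {
  assert_cols(records, c("barcode", "sample_id"), "cell records")
  assert_cols(samples, c("sample_id", "subject_id", "disease"),
              "sample metadata")
  unmapped <- setdiff(unique(records$sample_id), samples$sample_id)
  assert_that(length(unmapped) == 0,
              paste0("sample(s) without subject mapping: ",
                     paste(head(unmapped, 5), collapse = ", ")))
  conflict <- samples |>
    dplyr::distinct(.data$subject_id, .data$disease) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n > 1)
  assert_that(nrow(conflict) == 0,
              paste0("conflicting disease labels for subject(s): ",
                     paste(head(conflict$subject_id, 5), collapse = ", ")))
  # sample metadata is authoritative for subject/disease/region keys
  rec <- as_tibble(records)
  rec <- rec[, setdiff(names(rec),
                       setdiff(names(samples), "sample_id")),
             drop = FALSE]
  dplyr::left_join(rec, as_tibble(samples), by = "sample_id")
}

#' Per-sample (or per-subject) mLOY proportion summary
#'
#' @param records cell records, optionally already subject-collapsed.
#' @param by grouping column, `"sample_id"` or `"subject_id"`.
#' @return tibble with `n_cells`, `n_mloy`, `mloy_proportion` per group
#'   (plus disease/region labels when present).
#' @export
sc_mloy_summary <- function(records, by = "sample_id") {
  assert_cols(records, c(by, "mloy"), "cell records")
  keep <- intersect(c(by, "disease", "region"), names(records))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keep))) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_mloy = sum(.data$mloy),
                     mloy_proportion = mean(.data$mloy),
                     .groups = "drop")
}

#' Logistic association of per-cell mLOY with a covariate
#'
#' Fits one logistic regression of the binary per-cell mLOY call on a
#' single categorical covariate (disease type, lineage, or cell
#' identity), reporting per-level odds ratios against the reference
#' level with Wald 95% CIs and Benjamini-Hochberg FDR across the levels
#' of that covariate. Levels with no mLOY-positive or no mLOY-negative
#' cells are completely separated and are reported as unestimable rather
#' than dropped.
#'
#' @param records cell records carrying the covariate column.
#' @param covariate name of the covariate column (string).
#' @param reference reference level (default `"control"` when present,
#'   else the first level).
#' @return tibble: `covariate`, `level`, `n_cells`, `n_mloy`,
#'   `log_odds`, `se`, `or`, `ci_lo`, `ci_hi`, `p`, `p_fdr`,
#'   `direction`, `estimable`.
#' @export
mloy_association <- function(records, covariate, reference = NULL) {
  assert_cols(records, c("mloy", covariate), "cell records")
  x <- factor(records[[covariate]])
  assert_that(nlevels(x) >= 2,
              "covariate must have at least 2 observed levels")
  reference <- reference %||%
    (if ("control" %in% levels(x)) "control" else levels(x)[1])
  assert_that(reference %in% levels(x),
              paste0("reference level not present: ", reference))
  x <- relevel(x, ref = reference)

  counts <- tibble(level = x, mloy = records$mloy) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(n_cells = dplyr::n(), n_mloy = sum(.data$mloy),
                     .groups = "drop")
  counts$estimable <- counts$n_mloy > 0 & counts$n_mloy < counts$n_cells

  ref_ok <- counts$estimable[counts$level == reference]
  fit_levels <- counts$level[counts$estimable]
  res <- counts |>
    dplyr::filter(.data$level != reference) |>
    dplyr::mutate(log_odds = NA_real_, se = NA_real_, p = NA_real_)

  if (isTRUE(ref_ok) && length(fit_levels) >= 2) {
    keep <- x %in% fit_levels
    xf <- droplevels(x[keep])
    fit <- glm(records$mloy[keep] ~ xf, family = binomial())
    cf <- summary(fit)$coefficients
    term <- paste0("xf", res$level)
    hit <- match(term, rownames(cf))
    res$log_odds <- cf[hit, 1]
    res$se <- cf[hit, 2]
    res$p <- two_sided_p(cf[hit, 1] / cf[hit, 2])
  }
  res$estimable <- res$estimable & isTRUE(ref_ok)
  res$log_odds[!res$estimable] <- NA_real_
  res$se[!res$estimable] <- NA_real_
  res$p[!res$estimable] <- NA_real_

  res |>
    dplyr::mutate(
      covariate = covariate,
      level = as.character(.data$level),
      or = exp(.data$log_odds),
      ci_lo = exp(.data$log_odds - Z95 * .data$se),
      ci_hi = exp(.data$log_odds + Z95 * .data$se),
      p_fdr = p.adjust(.data$p, method = "BH"),
      direction = ifelse(.data$log_odds > 0, "increased", "decreased")
    ) |>
    dplyr::select(dplyr::all_of(c(
      "covariate", "level", "n_cells", "n_mloy", "log_odds", "se", "or",
      "ci_lo", "ci_hi", "p", "p_fdr", "direction", "estimable"
    )))
}

#' Paired fibrotic-region mLOY association within subjects
#'
#' Among subjects contributing a given cell type from both a
#' less-fibrotic and a more-fibrotic sample, fits a logistic model of
#' the per-cell mLOY call on the region indicator with subject
#' indicators as covariates. An odds ratio above 1 means a higher mLOY
#' probability in more-fibrotic regions.
#'
#' @param records subject-collapsed cell records with `region` and
#'   `cell_type` columns.
#' @param cell_type cell type to restrict to (NULL = all cells).
#' @return one-row association tibble, or a zero-row tibble with a
#'   `reason` attribute when no paired subjects exist.
#' @export
paired_region_association <- function(records, cell_type = NULL) {
  assert_cols(records, c("mloy", "region", "subject_id"), "cell records")
  rec <- as_tibble(records)
  if (!is.null(cell_type)) {
    assert_cols(rec, "cell_type", "cell records")
    rec <- rec[rec$cell_type == cell_type, , drop = FALSE]
  }
  rec <- rec[rec$region %in% c("less", "more"), , drop = FALSE]
  paired <- rec |>
    dplyr::distinct(.data$subject_id, .data$region) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n == 2)
  empty <- tibble(covariate = character(), level = character(),
                  log_odds = double(), se = double(), or = double(),
                  ci_lo = double(), ci_hi = double(), p = double())
  if (nrow(paired) == 0) {
    attr(empty, "reason") <- "no subjects with cells from both regions"
    return(empty)
  }
  rec <- rec[rec$subject_id %in% paired$subject_id, , drop = FALSE]
  region <- factor(rec$region, levels = c("less", "more"))
  subject <- factor(rec$subject_id)
  fit <- if (nlevels(subject) > 1) {
    glm(rec$mloy ~ region + subject, family = binomial())
  } else {
    glm(rec$mloy ~ region, family = binomial())
  }
  cf <- summary(fit)$coefficients
  b <- cf["regionmore", 1]; s <- cf["regionmore", 2]
  tibble(covariate = "region",
         level = "more",
         n_subjects = nrow(paired),
         n_cells = nrow(rec),
         log_odds = b, se = s, or = exp(b),
         ci_lo = exp(b - Z95 * s), ci_hi = exp(b + Z95 * s),
         p = two_sided_p(b / s))
}

#' Assign cells to differential-expression comparison groups
#'
#' Comparison groups for downstream per-gene models: all mLOY disease
#' cells versus the non-mLOY disease cells whose chrY/autosome ratio
#' lies at or above the 75th percentile of non-mLOY ratios (the "high-Y"
#' comparator). The percentile uses an interpolated sample quantile and
#' the cutoff is tie-inclusive.
#'
#' @param records disease-sample cell records.
#' @return `records` with a `de_group` factor column (`"mloy"`,
#'   `"comparator"`, `"excluded"`); the ratio cutoff is attached as
#'   attribute `cutoff`.
#' @export
select_de_groups <- function(records) {
  assert_cols(records, c("ratio", "mloy"), "cell records")
  nonmloy <- records$ratio[!records$mloy]
  assert_that(length(nonmloy) >= 4,
              "need at least 4 non-mLOY cells to define the comparator")
  cutoff <- unname(quantile(nonmloy, 0.75, type = 6))
  out <- dplyr::mutate(
    as_tibble(records),
    de_group = factor(
      dplyr::case_when(
        .data$mloy ~ "mloy",
        .data$ratio >= cutoff ~ "comparator",
        TRUE ~ "excluded"
      ),
      levels = c("mloy", "comparator", "excluded")
    )
  )
  attr(out, "cutoff") <- cutoff
  out
}
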