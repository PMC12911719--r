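#' Chromosome-Y copy number from region depths
#'
#' The mLOY proxy statistic: mean read depth over the male-specific
#' region of chromosome Y divided by mean depth over a diploid
#' denominator. Two dialects are supported: `"autosomes22"` (all 22
#' autosomes, the primary definition) and `"chr20"` (chromosome 20 only,
#' used where only per-chromosome summary depths are available). In a
#' male without loss the ratio is about 0.5 times the effective MSY
#' mappability; mosaic loss in a fraction f of cells scales it by (1-f).
#'
#' @param depths a depth tibble from [compute_region_depth()] or
#'   [read_depth_table()]; may contain many samples.
#' @param dialect `"autosomes22"` or `"chr20"`.
#' @return tibble with one row per sample: `sample_id`, `value`,
#'   `dialect`.
#' @export
#' @examples
#' d <- tibble::tibble(sample_id = "s1",
#'                     region_set = c("MSY", "AUTOSOMES"),
#'                     mean_depth = c(15, 30))
#' copy_number_y(d)
copy_number_y <- function(depths, dialect = c("autosomes22", "chr20")) {
  dialect <- match.arg(dialect)
  assert_cols(depths, c("sample_id", "region_set", "mean_depth"),
              "depth table")
  denom_set <- if (dialect == "autosomes22") "AUTOSOMES" else "CHR20"
  wide <- tidyr::pivot_wider(as_tibble(depths), id_cols = "sample_id",
                             names_from = "region_set",
                             values_from = "mean_depth")
  for (nm in c("MSY", denom_set)) {
    assert_that(nm %in% names(wide) && !anyNA(wide[[nm]]),
                paste0("depth for region set ", nm,
                       " missing for some samples"))
  }
  bad <- wide$sample_id[wide[[denom_set]] <= 0]
  assert_that(length(bad) == 0,
              paste0("zero denominator depth (failed or female sample?): ",
                     paste(head(bad, 5), collapse = ", ")))
  tibble(sample_id = wide$sample_id,
         value = wide$MSY / wide[[denom_set]],
         dialect = dialect)
}

#' Cohort mean-minus-SD mLOY threshold
#'
#' The cohort grouping rule: samples whose copy number falls strictly
#' below the cohort mean minus one sample standard deviation are called
#' mLOY. Returns the threshold with its components.
#'
#' @param values tibble from [copy_number_y()] (columns `value`,
#'   `dialect`).
#' @return one-row tibble `mean`, `sd`, `threshold`, `dialect`, `n`.
#' @export
cohort_threshold <- function(values) {
  assert_cols(values, c("value", "dialect"), "copy-number table")
  assert_that(nrow(values) >= 2, "need at least 2 samples for a threshold")
  assert_that(length(unique(values$dialect)) == 1,
              "mixed copy-number dialects in one cohort")
  m <- mean(values$value)
  s <- sd(values$value)   # n - 1 denominator
  tibble(mean = m, sd = s, threshold = m - s,
         dialect = values$dialect[1], n = nrow(values))
}

#' Call mLOY / non-mLOY groups against a threshold
#'
#' Strict inequality: `value < threshold` is mLOY; a value exactly equal
#' to the threshold is non-mLOY (the boundary is inclusive on the
#' non-mLOY side).
#'
#' @param values tibble from [copy_number_y()].
#' @param threshold one-row tibble from [cohort_threshold()], or a bare
#'   number (dialect then unchecked).
#' @return `values` with a `group` factor column (`"mLOY"`,
#'   `"non-mLOY"`) and the threshold echoed.
#' @export
call_mloy <- function(values, threshold) {
  assert_cols(values, c("sample_id", "value", "dialect"),
              "copy-number table")
  if (is.data.frame(threshold)) {
    assert_that(identical(unique(values$dialect), threshold$dialect[1]),
                "threshold dialect does not match values")
    thr <- threshold$threshold[1]
  } else {
    thr <- as.double(threshold)
  }
  dplyr::mutate(
    as_tibble(values),
    threshold = thr,
    group = factor(ifelse(.data$value < thr, "mLOY", "non-mLOY"),
                   levels = c("non-mLOY", "mLOY"))
  )
}

#' Invert the depth model to a mosaic fraction estimate
#'
#' Under the depth model the copy number of a sample with mosaic loss in
#' a fraction f of cells is `reference * (1 - f)`, where `reference` is
#' the expected copy number of a no-loss male under the same dialect and
#' filters. The inverse is clamped to \[0, 1\].
#'
#' @param values tibble from [copy_number_y()], or a numeric vector.
#' @param reference expected no-loss copy number (> 0).
#' @return input with an `f_hat` column (or a numeric vector).
#' @export
estimate_mosaic_fraction <- function(values, reference) {
  assert_that(is.numeric(reference) && length(reference) == 1 &&
                reference > 0, "reference must be a single positive number")
  f_of <- function(v) pmin(pmax(1 - v / reference, 0), 1)
  if (is.data.frame(values)) {
    assert_cols(values, "value", "copy-number table")
    dplyr::mutate(as_tibble(values), f_hat = f_of(.data$value))
  } else {
    f_of(values)
  }
}

#' Full bulk mLOY calling for one cohort
#'
#' Convenience wrapper: depth table in, per-sample calls out, with the
#' cohort threshold attached as an attribute.
#'
#' @inheritParams copy_number_y
#' @return call tibble as from [call_mloy()]; `attr(, "threshold")`
#'   holds the [cohort_threshold()] row.
#' @export
call_mloy_cohort <- function(depths, dialect = c("autosomes22", "chr20")) {
  values <- copy_number_y(depths, dialect)
  thr <- cohort_threshold(values)
  out <- call_mloy(values, thr)
  attr(out, "threshold") <- thr
  out
}
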