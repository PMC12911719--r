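#' Run the full synthetic end-to-end mLOY pipeline
#'
#' Orchestrates every stage on generated data with known ground truth:
#' bulk depth simulation and cohort mLOY calling, clinical correlation
#' tables, single-cell simulation with covariate association, and the
#' bidirectional MR suite. Stages run in dependency order; a failure in
#' one stage still leaves completed stage outputs in the returned
#' manifest, with the failed stage named.
#'
#' @param seed master seed; each stage derives its own stream from it.
#' @param out_dir optional directory; when given, every stage output is
#'   written as TSV/JSON alongside a `manifest.json`.
#' @param bulk,sc,clinical,mr named lists of overrides passed to the
#'   corresponding simulators / analysis calls.
#' @return a list of stage results plus a `manifest` (tool version,
#'   seed, stage status and warnings).
#' @export
run_mloy_pipeline <- function(seed, out_dir = NULL,
                              bulk = list(), sc = list(),
                              clinical = list(), mr = list()) {
  assert_that(!missing(seed), "seed is mandatory")
  results <- list()
  manifest <- list(tool = "mloyr",
                   version = as.character(packageVersion("mloyr")),
                   seed = seed, stages = list(), warnings = character())
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      NULL
    } else {
      manifest$stages[[name]] <<- list(status = "ok")
      res
    }
  }

  results$bulk <- run_stage("bulk", function() {
    sim <- do.call(simulate_depth_cohort,
                   c(list(seed = derive_seed(seed, 1)), bulk))
    calls <- call_mloy_cohort(sim$depths)
    list(sim = sim, calls = calls,
         threshold = attr(calls, "threshold"),
         recovery = dplyr::left_join(
           estimate_mosaic_fraction(calls,
                                    reference = 0.5 *
                                      (sim$config$mappability %||% 0.75)),
           sim$truth, by = "sample_id"))
  })

  results$clinical <- run_stage("clinical", function() {
    sim <- do.call(simulate_clinical,
                   c(list(seed = derive_seed(seed, 2)), clinical))
    cl <- sim$clinical
    correlations <- purrr::map_dfr(
      c("age", "telomere", "ppfvc", "pptlco"),
      function(v) dplyr::mutate(correlate_variables(cl$cn, cl[[v]]),
                                variable = v, .before = 1))
    progression <- classify_progression(cl)
    list(sim = sim, correlations = correlations,
         progression = progression)
  })

  results$sc <- run_stage("sc", function() {
    sim <- do.call(simulate_sc_cohort,
                   c(list(seed = derive_seed(seed, 3)), sc))
    records <- cell_read_counts(sim$cells)
    records <- collapse_subject(records, sim$samples)
    list(sim = sim,
         summary = sc_mloy_summary(records, by = "subject_id"),
         association = mloy_association(records, "disease"))
  })

  results$mr <- run_stage("mr", function() {
    sim <- do.call(simulate_gwas_pair,
                   c(list(seed = derive_seed(seed, 4)), mr))
    suite <- run_mr_suite(sim$exposure, sim$outcome, ld = sim$ld,
                          seed = derive_seed(seed, 5))
    list(sim = sim, suite = suite,
         forest = render_forest_table(suite))
  })

  results$manifest <- manifest
  if (!is.null(out_dir)) write_pipeline_outputs(results, out_dir)
  results
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(results$bulk)) {
    write_tsv_file(results$bulk$calls,
                   file.path(out_dir, "bulk_mloy_calls.tsv"))
    jsonlite::write_json(
      as.list(results$bulk$threshold),
      file.path(out_dir, "bulk_threshold.json"), auto_unbox = TRUE)
  }
  if (!is.null(results$clinical)) {
    write_tsv_file(results$clinical$correlations,
                   file.path(out_dir, "clinical_correlations.tsv"))
    write_tsv_file(results$clinical$progression,
                   file.path(out_dir, "clinical_progression.tsv"))
  }
  if (!is.null(results$sc)) {
    write_tsv_file(results$sc$summary,
                   file.path(out_dir, "sc_mloy_summary.tsv"))
    write_tsv_file(results$sc$association,
                   file.path(out_dir, "sc_association.tsv"))
  }
  if (!is.null(results$mr)) {
    write_tsv_file(tidy(results$mr$suite),
                   file.path(out_dir, "mr_methods.tsv"))
    write_tsv_file(results$mr$forest,
                   file.path(out_dir, "mr_forest_table.tsv"))
  }
  jsonlite::write_json(results$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Copy-number distribution plot with the cohort threshold
#'
#' @param calls output of [call_mloy_cohort()] / [call_mloy()].
#' @return a ggplot histogram of copy numbers coloured by group, with
#'   the mean-minus-SD threshold marked.
#' @export
plot_copy_number <- function(calls) {
  assert_cols(calls, c("value", "group", "threshold"), "mLOY calls")
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$value,
                                      fill = .data$group)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.8,
                            position = "identity") +
    ggplot2::geom_vline(xintercept = calls$threshold[1],
                        linetype = "dashed") +
    ggplot2::labs(x = "chrY copy number", y = "samples",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Odds-ratio plot for single-cell mLOY associations
#'
#' @param association output of [mloy_association()].
#' @return a ggplot of per-level ORs with 95% CIs against the
#'   reference, significant levels (FDR < 0.05) emphasised.
#' @export
plot_mloy_association <- function(association) {
  assert_cols(association, c("level", "or", "ci_lo", "ci_hi", "p_fdr"),
              "association table")
  df <- dplyr::mutate(association,
                      significant = !is.na(.data$p_fdr) &
                        .data$p_fdr < 0.05)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$level,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
      height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mLOY odds ratio (95% CI)", y = NULL,
                  colour = "FDR < 0.05") +
    ggplot2::theme_minimal()
}
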