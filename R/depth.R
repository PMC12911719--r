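#' Read-filtering settings for depth computation
#'
#' The MSY copy-number statistic relies on reads mapping uniquely to the
#' male-specific region, so low-mapping-quality reads, duplicates and
#' secondary/supplementary alignments are excluded by default.
#'
#' @param min_mapq minimum mapping quality (default 10).
#' @param exclude_duplicates drop reads flagged as PCR/optical duplicates.
#' @param exclude_secondary drop secondary and supplementary alignments.
#' @return a `read_filter` list.
#' @export
read_filter <- function(min_mapq = 10L, exclude_duplicates = TRUE,
                        exclude_secondary = TRUE) {
  assert_that(min_mapq >= 0, "min_mapq must be >= 0")
  structure(list(min_mapq = as.integer(min_mapq),
                 exclude_duplicates = isTRUE(exclude_duplicates),
                 exclude_secondary = isTRUE(exclude_secondary)),
            class = "read_filter")
}

#' Mean per-base read depth over each region set
#'
#' Computes, for one sample, the mean per-base depth over every region
#' set: total aligned bases falling in the set divided by the total set
#' length, so bases with zero coverage count in the denominator. This is
#' the raw material of the chromosome-Y copy-number ratio.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param regions a [genome_regions()] object.
#' @param filter a [read_filter()].
#' @param sample_id sample identifier; defaults to the BAM basename.
#' @return a one-row-per-region-set tibble (`sample_id`, `region_set`,
#'   `mean_depth`) with the filter recorded as an attribute.
#' @export
compute_region_depth <- function(bam, regions = genome_regions(),
                                 filter = read_filter(),
                                 sample_id = NULL) {
  for (pkg in c("Rsamtools", "GenomicRanges", "IRanges")) {
    if (!requireNamespace(pkg, quietly = TRUE))
      abort(paste0("package ", pkg, " is required to read BAM files"))
  }
  validate_genome_regions(regions)
  sample_id <- sample_id %||% sub("\\.bam$", "", basename(bam))

  bf <- Rsamtools::BamFile(bam)
  header_chroms <- names(Rsamtools::scanBamHeader(bf)$targets)
  needed <- unique(unlist(lapply(regions, function(r) unique(r$chrom))))
  missing <- setdiff(needed, header_chroms)
  assert_that(length(missing) == 0,
              paste0("chromosome(s) absent from BAM header: ",
                     paste(missing, collapse = ", ")))

  flag <- Rsamtools::scanBamFlag(
    isDuplicate = if (filter$exclude_duplicates) FALSE else NA,
    isSecondaryAlignment = if (filter$exclude_secondary) FALSE else NA,
    isSupplementaryAlignment = if (filter$exclude_secondary) FALSE else NA,
    isUnmappedQuery = FALSE
  )
  pparam <- Rsamtools::PileupParam(
    max_depth = 100000L, min_base_quality = 0L,
    min_mapq = filter$min_mapq, min_nucleotide_depth = 1L,
    distinguish_strands = FALSE, distinguish_nucleotides = FALSE
  )

  depths <- vapply(names(regions), function(nm) {
    r <- regions[[nm]]
    gr <- GenomicRanges::GRanges(
      seqnames = r$chrom,
      ranges = IRanges::IRanges(start = r$start + 1L, end = r$end)
    )
    sparam <- Rsamtools::ScanBamParam(which = gr, flag = flag,
                                      mapqFilter = filter$min_mapq)
    pu <- Rsamtools::pileup(bf, scanBamParam = sparam,
                            pileupParam = pparam)
    sum(as.double(pu$count)) / region_set_length(regions, nm)
  }, numeric(1))

  out <- tibble(sample_id = sample_id,
                region_set = names(depths),
                mean_depth = unname(depths))
  attr(out, "read_filter") <- filter
  out
}

#' Read a precomputed per-region-set depth table
#'
#' Accepts the long TSV format `sample_id, region_set, mean_depth`,
#' decoupling cohort-level analysis from alignment files.
#'
#' @param path TSV path, or a data frame already in that shape.
#' @return tibble with columns `sample_id`, `region_set`, `mean_depth`.
#' @export
read_depth_table <- function(path) {
  df <- if (is.data.frame(path)) path else
    read.delim(path, stringsAsFactors = FALSE)
  assert_cols(df, c("sample_id", "region_set", "mean_depth"), "depth table")
  assert_that(all(df$mean_depth >= 0), "mean_depth must be non-negative")
  as_tibble(df[, c("sample_id", "region_set", "mean_depth")])
}
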