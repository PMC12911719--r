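# GRCh38 assembly constants used by the default region sets.
# PAR coordinates are 0-based half-open on chrY.
GRCH38_CHRY_LENGTH <- 57227415
GRCH38_PAR1_Y <- c(10000L, 2781479L)
GRCH38_PAR2_Y <- c(56887902L, 57217415L)

GRCH38_AUTOSOME_LENGTHS <- c(
  chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
  chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
  chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
  chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
  chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
  chr21 = 46709983, chr22 = 50818468
)

#' Genome region sets for the chromosome-Y copy-number statistic
#'
#' Builds the named region sets the copy-number ratio is computed over.
#' Intervals are 0-based half-open. The defaults are GRCh38: `MSY` is
#' chromosome Y with both pseudoautosomal regions removed (the
#' male-specific region, whose sequence is not shared with chromosome X),
#' `AUTOSOMES` is the 22 full autosomes, and `CHR20` is chromosome 20
#' alone (the alternative denominator used for cohorts where only per-
#' chromosome summary depths are available).
#'
#' @param msy optional data frame (`chrom`, `start`, `end`) overriding the
#'   default MSY intervals, e.g. read from a BED file with
#'   [read_regions_bed()].
#' @param autosomes,chr20 optional overrides with the same shape.
#' @return a named list of tibbles with columns `chrom`, `start`, `end`,
#'   of class `genome_regions`.
#' @export
#' @examples
#' regs <- genome_regions()
#' names(regs)
genome_regions <- function(msy = NULL, autosomes = NULL, chr20 = NULL) {
  default_msy <- tibble(
    chrom = "chrY",
    start = c(0L, GRCH38_PAR1_Y[2], GRCH38_PAR2_Y[2]),
    end   = c(GRCH38_PAR1_Y[1], GRCH38_PAR2_Y[1], GRCH38_CHRY_LENGTH)
  )
  default_autosomes <- tibble(
    chrom = names(GRCH38_AUTOSOME_LENGTHS),
    start = 0L,
    end   = unname(GRCH38_AUTOSOME_LENGTHS)
  )
  default_chr20 <- tibble(chrom = "chr20", start = 0L,
                          end = unname(GRCH38_AUTOSOME_LENGTHS["chr20"]))
  regions <- list(
    MSY = as_region_tbl(msy %||% default_msy, "MSY"),
    AUTOSOMES = as_region_tbl(autosomes %||% default_autosomes, "AUTOSOMES"),
    CHR20 = as_region_tbl(chr20 %||% default_chr20, "CHR20")
  )
  assert_that(length(unique(regions$AUTOSOMES$chrom)) == 22 ||
                !is.null(autosomes),
              "default AUTOSOMES must span exactly 22 chromosomes")
  validate_genome_regions(regions)
  structure(regions, class = c("genome_regions", "list"))
}

as_region_tbl <- function(df, set) {
  assert_cols(df, c("chrom", "start", "end"), paste0("region set ", set))
  out <- as_tibble(df[, c("chrom", "start", "end")])
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out
}

validate_genome_regions <- function(regions) {
  for (nm in c("MSY", "AUTOSOMES", "CHR20")) {
    assert_that(nm %in% names(regions),
                paste0("required region set missing: ", nm))
    r <- regions[[nm]]
    assert_that(nrow(r) > 0, paste0("region set ", nm, " is empty"))
    assert_that(all(r$start < r$end),
                paste0("region set ", nm, " has intervals with start >= end"))
    assert_that(all(r$start >= 0),
                paste0("region set ", nm, " has negative coordinates"))
  }
  # the MSY definition excludes pseudoautosomal sequence by construction;
  # guard user overrides against re-introducing it on the default assembly
  msy_y <- regions$MSY[regions$MSY$chrom == "chrY", , drop = FALSE]
  if (nrow(msy_y) > 0 && max(msy_y$end) <= GRCH38_CHRY_LENGTH) {
    overlaps_par <- function(s, e, par) s < par[2] && e > par[1]
    bad <- mapply(function(s, e) {
      overlaps_par(s, e, GRCH38_PAR1_Y) || overlaps_par(s, e, GRCH38_PAR2_Y)
    }, msy_y$start, msy_y$end)
    assert_that(!any(bad),
                "MSY intervals overlap a GRCh38 pseudoautosomal region")
  }
  invisible(regions)
}

#' Read region intervals from a BED file
#'
#' BED is 0-based half-open, matching the internal representation, so
#' coordinates pass through unchanged.
#'
#' @param path path to a BED file (first three columns used).
#' @return tibble with columns `chrom`, `start`, `end`.
#' @export
read_regions_bed <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 3, "BED file must have at least 3 columns")
  tibble(chrom = as.character(df[[1]]),
         start = as.integer(df[[2]]),
         end = as.integer(df[[3]]))
}

region_set_length <- function(regions, set) {
  r <- regions[[set]]
  sum(as.double(r$end) - as.double(r$start))
}
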