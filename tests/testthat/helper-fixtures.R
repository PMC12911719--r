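# Shared fixture builders. Everything is generated in code; BAM
# fixtures are written to tempdir() from SAM text at test time.

# instrument tibble with explicit per-SNP values; equal exposure
# effects of 1 make the Wald ratios equal the outcome betas
make_instruments <- function(by, sey = rep(0.1, length(by)),
                             bx = rep(1, length(by)),
                             sex = rep(0.01, length(by))) {
  tibble::tibble(
    snp = sprintf("rs%03d", seq_along(by)),
    beta_exposure = bx, se_exposure = sex,
    beta_outcome = by, se_outcome = sey,
    f_stat = (bx / sex)^2
  )
}

# instruments straight from a simulate_gwas_pair() result, bypassing
# allele harmonisation (the generator emits aligned effect alleles)
instruments_from_sim <- function(sim) {
  tibble::tibble(
    snp = sim$exposure$snp,
    beta_exposure = sim$exposure$beta,
    se_exposure = sim$exposure$se,
    beta_outcome = sim$outcome$beta,
    se_outcome = sim$outcome$se,
    f_stat = (sim$exposure$beta / sim$exposure$se)^2
  )
}

# write an aligned, sorted, indexed BAM from read coordinates
write_test_bam <- function(pos, rname = "chrY",
                           seqlens = c(chrY = 10000),
                           read_len = 100, mapq = 60,
                           flag = rep(0L, length(pos)),
                           dir = tempfile("bam")) {
  dir.create(dir, showWarnings = FALSE)
  sam <- file.path(dir, "reads.sam")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens),
                      as.integer(seqlens)))
  rname <- rep_len(rname, length(pos))
  mapq <- rep_len(mapq, length(pos))
  ord <- order(rname, pos)
  body <- sprintf(
    "r%06d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
    seq_along(pos), flag[ord], rname[ord], pos[ord], mapq[ord],
    read_len, strrep("A", read_len), strrep("I", read_len)
  )
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"),
                          overwrite = TRUE, indexDestination = TRUE)
  bam
}

# toy region sets on a short synthetic chrY/chr1 pair
toy_regions <- function(msy_end = 1000, auto_chrom = "chr1",
                        auto_end = 1000) {
  genome_regions(
    msy = tibble::tibble(chrom = "chrY", start = 0L,
                         end = as.integer(msy_end)),
    autosomes = tibble::tibble(chrom = auto_chrom, start = 0L,
                               end = as.integer(auto_end)),
    chr20 = tibble::tibble(chrom = auto_chrom, start = 0L,
                           end = as.integer(auto_end))
  )
}

# depth tibble for one or more samples from named per-set depths
make_depths <- function(msy, autosomes, chr20 = autosomes,
                        ids = sprintf("s%d", seq_along(msy))) {
  tibble::tibble(
    sample_id = rep(ids, times = 3),
    region_set = rep(c("MSY", "AUTOSOMES", "CHR20"), each = length(msy)),
    mean_depth = c(msy, autosomes, chr20)
  )
}

# minimal cell-record table with explicit mLOY structure
make_cells <- function(n_mloy, n_total, label, sample_id = label,
                       subject_id = sample_id, y_pos = 3L) {
  tibble::tibble(
    barcode = sprintf("%s-%04d", sample_id, seq_len(n_total)),
    sample_id = sample_id,
    y_reads = c(rep(0L, n_mloy), rep(y_pos, n_total - n_mloy)),
    autosome_reads = 100L,
    disease = label,
    subject_id = subject_id
  )
}
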