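# Independent brute-force oracles (plain R, no interval machinery) and
# shared fixtures. BED-style 0-based half-open coordinates throughout.

# Boolean coverage mask of a BED-style interval table on one chromosome.
mask_of <- function(df, len) {
  m <- logical(len)
  for (i in seq_len(nrow(df))) m[(df$start[i] + 1):df$end[i]] <- TRUE
  m
}

# BED-style data.frame view of a GRanges.
bed_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# Random BED-style interval table on one chromosome.
random_bed <- function(n, len, max_w = 500) {
  w <- sample.int(max_w, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(len - wi, 1), integer(1)) - 1L
  df <- data.frame(chrom = "chrT", start = s, end = s + w)
  df[order(df$start, df$end), ]
}

as_ps <- function(df, genome = NULL) {
  peak_set(df$chrom, df$start, df$end, genome = genome)
}

# All-pairs base overlap of one query interval with every subject interval.
pair_overlap_bp <- function(qs, qe, ss, se) {
  pmax(0, pmin(qe, se) - pmax(qs, ss))
}

# Memoized small synthetic cohort shared by simulator/pipeline tests.
.cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (!is.null(.cohort_cache$coh)) return(.cohort_cache$coh)
  cfg <- simulation_config(
    seed = 42, n_chromosomes = 4, chromosome_length = 3e6,
    n_genes = 800, n_ares = c(ERY = 120, iMK = 200, shared = 160),
    n_background_atac = 120, n_background_marks = 60,
    n_background_methylation = 60, n_replicate_private_peaks = 20)
  dir <- file.path(tempdir(), "commitpoint-small-cohort")
  .cohort_cache$coh <- list(cfg = cfg, cohort = generate_cohort(cfg, dir))
  .cohort_cache$coh
}

# Truth consensus peak sets written by the generator (bypassing replicate
# jitter), read back per stage.
cohort_truth_atac <- function(coh) {
  stages <- unique(unlist(coh$cfg$lineages))
  out <- lapply(stages, function(sg)
    read_bed(file.path(coh$cohort$dir, sprintf("atac_%s_consensus.bed", sg))))
  names(out) <- stages
  out
}
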