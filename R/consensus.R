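#' Consensus peaks across biological replicates
#'
#' Pools all replicate peaks, merges them, and keeps each merged region iff
#' the required number of distinct replicates each contribute at least one
#' peak overlapping it. This is the replicate-consensus rule used for ATAC
#' (`require = "all"` over two replicates, i.e. "both") and for ChIP
#' (`require = "all"` over all replicates). Output coordinates are the
#' merged-region footprint.
#'
#' @param replicates list of `GRanges`, one per replicate (length >= 2).
#' @param require `"all"` or `"at_least_two"`.
#' @return A `GRanges` of consensus regions.
#' @export
consensus_in_merged_regions <- function(replicates,
                                        require = c("all", "at_least_two")) {
  require <- match.arg(require)
  if (!is.list(replicates) || length(replicates) < 2)
    stop("need at least 2 replicates")
  pool <- merge_peaks(do.call(c, unname(lapply(replicates, GenomicRanges::granges))))
  if (length(pool) == 0L) return(pool)
  support <- vapply(replicates,
                    function(r) GenomicRanges::countOverlaps(pool, r) > 0,
                    logical(length(pool)))
  if (length(pool) == 1L) support <- matrix(support, nrow = 1)
  need <- if (require == "all") length(replicates) else 2L
  pool[rowSums(support) >= need]
}

#' Consensus peaks across a peak-caller ensemble
#'
#' Pools calls from several peak-calling tools, merges them, and keeps a
#' merged region iff (i) at least `min_tools` distinct tools contribute a
#' peak overlapping it and (ii) some pair of peaks from distinct tools within
#' the region overlap each other by at least `min_overlap_bp` bases (the
#' best supporting pair). This is the MBD-seq rule: called by two or more
#' tools and overlapped by at least 100 bp.
#'
#' @param tool_calls list of `GRanges`, one per tool.
#' @param min_tools minimum number of distinct supporting tools (default 2).
#' @param min_overlap_bp minimum pairwise overlap in bp (default 100).
#' @return A `GRanges` of consensus regions.
#' @export
ensemble_consensus <- function(tool_calls, min_tools = 2, min_overlap_bp = 100) {
  if (!is.numeric(min_overlap_bp) || min_overlap_bp < 1)
    stop("min_overlap_bp must be a positive integer")
  if (!is.list(tool_calls) || length(tool_calls) < min_tools)
    stop("need at least min_tools = ", min_tools, " tool call sets")
  pool <- merge_peaks(do.call(c, unname(lapply(tool_calls, GenomicRanges::granges))))
  if (length(pool) == 0L) return(pool)
  support <- vapply(tool_calls,
                    function(tc) GenomicRanges::countOverlaps(pool, tc) > 0,
                    logical(length(pool)))
  if (length(pool) == 1L) support <- matrix(support, nrow = 1)
  qualified <- rep(FALSE, length(pool))
  nt <- length(tool_calls)
  for (i in seq_len(nt - 1)) {
    for (j in seq(i + 1, nt)) {
      hits <- GenomicRanges::findOverlaps(tool_calls[[i]], tool_calls[[j]],
                                          minoverlap = min_overlap_bp)
      if (length(hits) == 0L) next
      # two mutually overlapping peaks fall in one merged region
      reg <- GenomicRanges::findOverlaps(
        tool_calls[[i]][unique(S4Vectors::queryHits(hits))], pool)
      qualified[unique(S4Vectors::subjectHits(reg))] <- TRUE
    }
  }
  pool[qualified & rowSums(support) >= min_tools]
}
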