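#' Merge a peak set
#'
#' Coalesces overlapping or abutting intervals into their union footprint.
#' Total covered bases are conserved; the result has no two intervals on the
#' same chromosome that overlap or abut, and `merge_peaks()` is idempotent.
#'
#' @param x a `GRanges`.
#' @return A merged, sorted `GRanges`.
#' @export
merge_peaks <- function(x) {
  GenomicRanges::reduce(GenomicRanges::sort(x))
}

#' Select query peaks overlapping another set
#'
#' Returns the subset of `a`'s intervals having at least `min_bp` bases of
#' overlap with the merged coverage of `b`. `a`'s own coordinates are kept
#' unchanged (peak-level filtering, not geometric intersection).
#'
#' @param a query `GRanges`.
#' @param b subject `GRanges`.
#' @param min_bp minimum overlapping bases (default 1).
#' @return The qualifying subset of `a`.
#' @export
intersect_any <- function(a, b, min_bp = 1) {
  if (!is.numeric(min_bp) || length(min_bp) != 1 || min_bp < 1)
    stop("min_bp must be a positive integer")
  if (length(a) == 0L || length(b) == 0L) return(a[integer(0)])
  bm <- merge_peaks(b)
  hits <- GenomicRanges::findOverlaps(a, bm)
  if (length(hits) == 0L) return(a[integer(0)])
  ow <- GenomicRanges::width(GenomicRanges::pintersect(
    a[S4Vectors::queryHits(hits)], bm[S4Vectors::subjectHits(hits)]))
  tot <- tapply(ow, S4Vectors::queryHits(hits), sum)
  keep <- as.integer(names(tot))[tot >= min_bp]
  a[sort(keep)]
}

#' Select query peaks with no overlap in another set
#'
#' Returns the subset of `a`'s intervals sharing zero bases with `b`.
#' Together with [intersect_any()] (at `min_bp = 1`) this partitions `a`.
#'
#' @param a query `GRanges`.
#' @param b subject `GRanges`.
#' @return The non-overlapping subset of `a`.
#' @export
subtract_any <- function(a, b) {
  if (length(a) == 0L) return(a)
  if (length(b) == 0L) return(a)
  a[GenomicRanges::countOverlaps(a, b) == 0]
}

#' Distance from intervals to a genomic point
#'
#' BED-style semantics: for an interval `[start, end)` and a 0-based point
#' `p`, the distance is 0 when `start <= p < end`, otherwise
#' `min(|p - start|, |p - (end - 1)|)` — the distance to the nearest
#' contained base. Chromosome identity is not checked here; callers
#' compare positions on one chromosome at a time.
#'
#' @param x a `GRanges`.
#' @param p 0-based point position(s); scalar or one per interval.
#' @return Non-negative integer distances, one per interval.
#' @export
nearest_point_distance <- function(x, p) {
  if (length(x) == 0L) return(integer(0))
  p1 <- as.numeric(p) + 1  # to 1-based
  s <- GenomicRanges::start(x)
  e <- GenomicRanges::end(x)
  inside <- p1 >= s & p1 <= e
  d <- pmin(abs(p1 - s), abs(p1 - e))
  d[inside] <- 0
  as.integer(d)
}

# Total covered bases of a peak set; internal.
covered_bases <- function(x) sum(GenomicRanges::width(merge_peaks(x)))
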