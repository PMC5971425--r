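#' Build a peak set from BED-style coordinates
#'
#' Constructs a sorted `GRanges` from BED-style (0-based, half-open)
#' coordinates. This is the in-memory form of every peak set in the package.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive starts.
#' @param end integer vector, exclusive ends (`start < end`).
#' @param genome optional `Seqinfo`; when given, chromosomes are validated
#'   against it and interval ends against chromosome lengths.
#' @param label optional label (assay/cell/replicate) stored as metadata.
#' @return A sorted `GRanges`.
#' @examples
#' peak_set("chr1", 100, 200)
#' @export
peak_set <- function(chrom, start, end, genome = NULL, label = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) == 0L) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(genome)) GenomeInfoDb::seqinfo(gr) <- genome
    if (!is.null(label)) S4Vectors::metadata(gr)$label <- label
    return(gr)
  }
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | start >= end)
  if (length(bad))
    stop("invalid interval at position ", bad[1], ": start=", start[bad[1]],
         " end=", end[bad[1]], " (need 0 <= start < end)")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(chrom), GenomeInfoDb::seqnames(genome))
    if (length(unknown))
      stop("chromosome(s) absent from genome: ", paste(unknown, collapse = ", "))
    lens <- GenomeInfoDb::seqlengths(genome)[chrom]
    over <- which(end > lens)
    if (length(over))
      stop("interval end ", end[over[1]], " exceeds length of ", chrom[over[1]])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end)
  )
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  gr <- GenomicRanges::sort(gr)
  if (!is.null(label)) S4Vectors::metadata(gr)$label <- label
  gr
}

#' Read a BED3+ file into a peak set
#'
#' Parses the first three columns (chrom, start, end; 0-based half-open),
#' ignoring any extra columns. Unsorted input is sorted with a warning.
#' Malformed coordinates raise an error naming the offending line.
#'
#' @param path path to a BED file.
#' @param genome optional `Seqinfo` used to validate chromosome names and
#'   interval bounds.
#' @param label optional label stored as metadata.
#' @return A sorted `GRanges`.
#' @export
read_bed <- function(path, genome = NULL, label = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L)
    return(peak_set(character(), numeric(), numeric(), genome, label))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED parse error at line ", which(nf < 3)[1], " of ", path,
         ": fewer than 3 fields")
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop("BED parse error at line ", bad[1], " of ", path, ": '",
         lines[bad[1]], "' (need integer 0 <= start < end)")
  extra <- max(nf) - 3L
  if (extra > 0)
    message("read_bed: ", extra, " extra BED column(s) ignored in ", path)
  # sorted = chromosomes in contiguous blocks, coordinates sorted within each;
  # the block order itself is a convention we don't police
  interleaved <- anyDuplicated(rle(chrom)$values) > 0
  within_unsorted <- any(unlist(tapply(seq_along(chrom), chrom, function(i)
    diff(start[i]) < 0 | (diff(start[i]) == 0 & diff(end[i]) < 0))))
  if (isTRUE(interleaved) || isTRUE(within_unsorted))
    warning("read_bed: input not sorted; sorting (", path, ")")
  peak_set(chrom, start, end, genome = genome,
           label = if (is.null(label)) basename(path) else label)
}

#' Write a peak set as BED3
#'
#' Emits 0-based half-open coordinates.
#'
#' @param x a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                   start = GenomicRanges::start(x) - 1,
                   end = GenomicRanges::end(x))
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# BED-style data.frame view of a GRanges (0-based half-open); internal.
as_bed_df <- function(x) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
             start = GenomicRanges::start(x) - 1,
             end = GenomicRanges::end(x),
             stringsAsFactors = FALSE)
}
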