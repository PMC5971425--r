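#' Construct a genome assembly
#'
#' A genome assembly is the universe for coordinate validation and for region
#' randomization: an ordered set of chromosome names with their lengths.
#' Represented as a [GenomeInfoDb::Seqinfo] object.
#'
#' @param chromosomes character vector of unique chromosome names.
#' @param lengths integer vector of chromosome lengths in bp (all >= 1).
#' @return A `Seqinfo` object.
#' @examples
#' genome_assembly(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_assembly <- function(chromosomes, lengths) {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (length(chromosomes) != length(lengths))
    stop("chromosomes and lengths must have equal length")
  if (anyDuplicated(chromosomes))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths < 1))
    stop("chromosome lengths must be >= 1")
  GenomeInfoDb::Seqinfo(seqnames = chromosomes, seqlengths = as.integer(lengths))
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two whitespace-separated columns: chromosome name, length in bp.
#'
#' @param path path to a chrom.sizes file.
#' @return A `Seqinfo` object.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_assembly(df$chrom, df$length)
}

#' Write a chrom.sizes file
#'
#' @param genome a `Seqinfo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  df <- data.frame(chrom = GenomeInfoDb::seqnames(genome),
                   length = GenomeInfoDb::seqlengths(genome))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
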