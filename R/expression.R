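#' Read a gene-by-cell-type TPM table
#'
#' Tab-separated, header line, first column gene ids, remaining columns one
#' TPM column per cell type.
#'
#' @param path path to the TSV.
#' @return A numeric matrix (genes x cell types) with gene-id rownames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs a gene column plus >= 1 TPM column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (anyNA(m)) stop("expression table contains missing values")
  if (any(m < 0)) stop("TPM values must be non-negative")
  m
}

#' Expressed gene set of one cell type
#'
#' Genes with TPM at or above the threshold (boundary inclusive; the
#' conventional cutoff is TPM >= 1).
#'
#' @param expr TPM matrix from [read_expression()].
#' @param cell cell-type column name.
#' @param threshold TPM threshold (default 1).
#' @return Character vector of gene ids.
#' @export
expressed_set <- function(expr, cell, threshold = 1.0) {
  if (!cell %in% colnames(expr)) stop("unknown cell type: ", cell)
  rownames(expr)[expr[, cell] >= threshold]
}

#' Transcript maintenance along a lineage
#'
#' Counts, at each stage of an ordered lineage (most primitive first), the
#' genes expressed at every stage up to and including it (cumulative
#' intersection). The sequence is non-increasing by construction.
#'
#' @param expr TPM matrix.
#' @param stages ordered character vector of cell-type names.
#' @param threshold TPM threshold (default 1).
#' @return Named integer vector of maintained-transcript counts per stage.
#' @export
maintenance_chain <- function(expr, stages, threshold = 1.0) {
  if (length(stages) < 2) stop("a lineage needs >= 2 stages")
  missing <- setdiff(stages, colnames(expr))
  if (length(missing)) stop("stage(s) missing from expression table: ",
                            paste(missing, collapse = ", "))
  kept <- expressed_set(expr, stages[1], threshold)
  counts <- integer(length(stages))
  counts[1] <- length(kept)
  for (k in seq_along(stages)[-1]) {
    kept <- intersect(kept, expressed_set(expr, stages[k], threshold))
    counts[k] <- length(kept)
  }
  names(counts) <- stages
  counts
}

#' Half-up rounded percentage
#'
#' `100 * numerator / denominator`, rounded half-up (0.5 always rounds away
#' from zero, unlike [round()]'s banker's rounding) to `digits` decimals.
#'
#' @param numerator,denominator counts; `denominator > 0`.
#' @param digits decimal places (0 for integer percent, 1 for one decimal).
#' @return The rounded percentage.
#' @export
rounded_percent <- function(numerator, denominator, digits = 0) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  x <- 100 * numerator / denominator
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Seven-region exclusive overlap of three sets
#'
#' Counts the 7 exclusive regions of a three-set Venn diagram. Region names
#' are built from the names of `sets`; counts sum to the union size.
#'
#' @param sets named list of three character vectors.
#' @return Named integer vector of length 7.
#' @export
exclusive_overlap <- function(sets) {
  if (!is.list(sets) || length(sets) != 3 || is.null(names(sets)))
    stop("sets must be a named list of three gene sets")
  sets <- lapply(sets, unique)
  nm <- names(sets)
  universe <- unique(unlist(sets))
  inA <- universe %in% sets[[1]]
  inB <- universe %in% sets[[2]]
  inC <- universe %in% sets[[3]]
  key <- paste0(as.integer(inA), as.integer(inB), as.integer(inC))
  out <- c(sum(key == "100"), sum(key == "010"), sum(key == "001"),
           sum(key == "110"), sum(key == "101"), sum(key == "011"),
           sum(key == "111"))
  names(out) <- c(paste0(nm[1], "_only"), paste0(nm[2], "_only"),
                  paste0(nm[3], "_only"),
                  paste(nm[1], nm[2], sep = "&"),
                  paste(nm[1], nm[3], sep = "&"),
                  paste(nm[2], nm[3], sep = "&"),
                  paste(nm, collapse = "&"))
  out
}

#' Pooled two-proportion z-test
#'
#' Compares `k1/n1` against `k2/n2` with the pooled-variance two-proportion
#' z statistic (no continuity correction); the two-sided p-value comes from
#' the standard normal and is clipped to `[0, 1]`.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return List with elements `z` and `p`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("n1 and n2 must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stop("need 0 <= k <= n in both groups")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  p <- min(1, max(0, 2 * stats::pnorm(-abs(z))))
  list(z = z, p = p)
}
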