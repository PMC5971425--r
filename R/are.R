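#' Derive active regulatory elements (AREs)
#'
#' An ARE is an H3K27ac peak that also lies in accessible chromatin: the
#' H3K27ac peaks (their own coordinates) are retained iff they overlap an
#' ATAC peak by at least 1 bp. The retained fraction is reported alongside
#' (in well-behaved data well over 90% of acetylation peaks are accessible).
#'
#' @param h3k27ac consensus H3K27ac `GRanges` for one cell type.
#' @param atac consensus ATAC `GRanges` for the same cell type.
#' @return List with `ares` (a `GRanges`) and `frac_k27ac_in_atac`.
#' @export
derive_ares <- function(h3k27ac, atac) {
  if (length(h3k27ac) == 0L) {
    warning("empty H3K27ac set: retained fraction undefined")
    return(list(ares = h3k27ac, frac_k27ac_in_atac = NA_real_))
  }
  ares <- intersect_any(h3k27ac, atac, min_bp = 1)
  list(ares = ares, frac_k27ac_in_atac = length(ares) / length(h3k27ac))
}

#' Partition two ARE sets by cell specificity
#'
#' `a_specific` are `a`'s AREs with no overlap in `b`; `b_specific`
#' symmetrically; `shared` is the merged union of reciprocally overlapping
#' AREs, so each overlap cluster is counted once.
#'
#' @param ares_a,ares_b ARE `GRanges` from two cell types.
#' @return List with `a_specific`, `b_specific`, `shared` (`GRanges`).
#' @export
partition_specificity <- function(ares_a, ares_b) {
  a_specific <- subtract_any(ares_a, ares_b)
  b_specific <- subtract_any(ares_b, ares_a)
  shared <- merge_peaks(c(GenomicRanges::granges(intersect_any(ares_a, ares_b)),
                          GenomicRanges::granges(intersect_any(ares_b, ares_a))))
  list(a_specific = a_specific, b_specific = b_specific, shared = shared)
}

#' Establishment stage of each ARE along a lineage
#'
#' For each ARE, records presence (>= 1 bp ATAC overlap) at every stage of
#' an ordered lineage (most primitive first), and calls the earliest stage
#' with presence its establishment stage. AREs absent from all earlier
#' stages but present at stage s are "established de novo" at s. Per-stage
#' presence fractions are the cumulative quantity usually reported (e.g.
#' "89% present in the stem/progenitor population").
#'
#' @param ares ARE `GRanges`.
#' @param stage_atac named, ordered list of per-stage ATAC `GRanges`; the
#'   final stage should be the ARE's own cell type.
#' @return List with `establishment` (factor of stage names, `NA` if absent
#'   everywhere), `de_novo` (logical: established after the first stage),
#'   `presence` (logical ARE x stage matrix) and `presence_fractions`.
#' @export
establishment_profile <- function(ares, stage_atac) {
  if (!is.list(stage_atac) || length(stage_atac) == 0L)
    stop("stage_atac must be a non-empty ordered list of (stage, PeakSet)")
  if (is.null(names(stage_atac)) || any(!nzchar(names(stage_atac))))
    stop("stage_atac must be named by stage")
  stages <- names(stage_atac)
  presence <- vapply(stage_atac,
                     function(s) GenomicRanges::countOverlaps(ares, s) > 0,
                     logical(length(ares)))
  if (length(ares) == 1L) presence <- matrix(presence, nrow = 1)
  if (length(ares) == 0L) presence <- matrix(logical(0), 0, length(stages))
  colnames(presence) <- stages
  first <- apply(presence, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  first <- as.integer(first)
  if (anyNA(first))
    warning(sum(is.na(first)), " ARE(s) absent from every stage")
  establishment <- factor(stages[first], levels = stages)
  list(establishment = establishment,
       de_novo = !is.na(first) & first > 1L,
       presence = presence,
       presence_fractions = colMeans(presence))
}

#' Classify ARE chromatin state against progenitor reference marks
#'
#' Overlap flags against progenitor H3K4me1 and H3K27ac reference peak sets
#' give four states: `active` (both marks), `poised` (H3K4me1 only),
#' `open` (neither), `acetylated_only` (H3K27ac only). The fourth state is
#' reported explicitly so the fractions always sum to 1.
#'
#' @param ares ARE `GRanges`.
#' @param ref_h3k4me1,ref_h3k27ac reference mark `GRanges` (progenitor).
#' @return List with `state` (factor per ARE) and `fractions` (length 4,
#'   summing to 1 when `ares` is non-empty).
#' @export
classify_chromatin_state <- function(ares, ref_h3k4me1, ref_h3k27ac) {
  levels <- c("active", "poised", "open", "acetylated_only")
  me1 <- GenomicRanges::countOverlaps(ares, ref_h3k4me1) > 0
  ac <- GenomicRanges::countOverlaps(ares, ref_h3k27ac) > 0
  state <- ifelse(me1 & ac, "active",
           ifelse(me1, "poised",
           ifelse(ac, "acetylated_only", "open")))
  state <- factor(state, levels = levels)
  fr <- if (length(ares)) as.numeric(table(state)) / length(ares) else rep(NA_real_, 4)
  names(fr) <- levels
  list(state = state, fractions = fr)
}

#' Read a TSS annotation table
#'
#' Four tab-separated columns with header: gene id, chromosome, position
#' (0-based bp), strand (+/-).
#'
#' @param path path to the TSV.
#' @param genome optional `Seqinfo` for bounds validation.
#' @return A data.frame with columns `gene`, `chrom`, `pos`, `strand`.
#' @export
read_tss <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("TSS table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:4] <- c("gene", "chrom", "pos", "strand")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(df$chrom), GenomeInfoDb::seqnames(genome))
    if (length(unknown))
      stop("TSS chromosome(s) absent from genome: ",
           paste(unknown, collapse = ", "))
    if (any(df$pos < 0 | df$pos >= GenomeInfoDb::seqlengths(genome)[df$chrom]))
      stop("TSS position outside chromosome bounds")
  }
  df
}

#' Assign each ARE to its nearest TSS
#'
#' Distance is [nearest_point_distance()] (0 if the TSS falls inside the
#' ARE, else distance from the nearest ARE edge), minimized over all TSS on
#' the ARE's chromosome. Ties are broken by the lexicographically smallest
#' gene id. AREs on chromosomes without any TSS are left unassigned
#' (`NA` gene and distance).
#'
#' @param ares ARE `GRanges`.
#' @param tss TSS annotation data.frame from [read_tss()].
#' @return Data.frame with one row per ARE: `gene`, `distance`.
#' @export
assign_nearest_tss <- function(ares, tss) {
  if (nrow(tss) == 0L) stop("TSS annotation is empty")
  n <- length(ares)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  if (n == 0L) return(data.frame(gene = gene, distance = dist))
  achr <- as.character(GenomicRanges::seqnames(ares))
  s0 <- GenomicRanges::start(ares) - 1  # BED-style
  e0 <- GenomicRanges::end(ares)
  for (ch in unique(achr)) {
    t <- tss[tss$chrom == ch, , drop = FALSE]
    if (nrow(t) == 0L) next
    o <- order(t$pos, t$gene)
    P <- t$pos[o]
    G <- t$gene[o]
    idx <- which(achr == ch)
    iL <- findInterval(s0[idx] - 1, P)   # count of P <= s0 - 1
    iR <- findInterval(e0[idx] - 1, P)   # count of P <= e0 - 1
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (iR[k] > iL[k]) {               # some TSS inside [s0, e0)
        dist[i] <- 0L
        gene[i] <- min(G[(iL[k] + 1):iR[k]])
        next
      }
      cand_d <- c(if (iL[k] >= 1) s0[i] - P[iL[k]] else NA,
                  if (iL[k] < length(P)) P[iL[k] + 1] - (e0[i] - 1) else NA)
      dmin <- min(cand_d, na.rm = TRUE)
      genes <- character(0)
      if (!is.na(cand_d[1]) && cand_d[1] == dmin)
        genes <- c(genes, G[P == P[iL[k]]])
      if (!is.na(cand_d[2]) && cand_d[2] == dmin)
        genes <- c(genes, G[P == P[iL[k] + 1]])
      dist[i] <- as.integer(dmin)
      gene[i] <- min(genes)
    }
  }
  data.frame(gene = gene, distance = dist, stringsAsFactors = FALSE)
}

#' Promoter/enhancer proximity class
#'
#' AREs within `threshold` bp of the nearest TSS (boundary inclusive) are
#' candidate promoter elements (cPE); farther AREs are candidate enhancer
#' elements (cEE).
#'
#' @param distance non-negative distances in bp (`NA` allowed: unassigned).
#' @param threshold proximity cutoff in bp (default 1000).
#' @return Factor with levels `cPE`, `cEE` (`NA` for unassigned input).
#' @export
classify_proximity <- function(distance, threshold = 1000) {
  if (any(distance < 0, na.rm = TRUE)) stop("distances must be non-negative")
  factor(ifelse(distance <= threshold, "cPE", "cEE"), levels = c("cPE", "cEE"))
}

#' Expressed fraction of ARE target genes
#'
#' Given per-ARE nearest-gene assignments and an expressed gene set, counts
#' assigned AREs, unique target genes, the expressed subset, and the
#' integer-rounded percentage. Unassigned AREs are excluded and counted
#' separately.
#'
#' @param nearest data.frame from [assign_nearest_tss()].
#' @param expressed character vector of expressed gene ids.
#' @return List: `n_ares`, `n_unassigned`, `n_target_genes`, `n_expressed`,
#'   `percent_expressed`.
#' @export
target_expressed_fraction <- function(nearest, expressed) {
  assigned <- nearest[!is.na(nearest$gene), , drop = FALSE]
  genes <- unique(assigned$gene)
  n_exp <- sum(genes %in% expressed)
  pct <- if (length(genes)) rounded_percent(n_exp, length(genes), 0) else NA_real_
  list(n_ares = nrow(assigned),
       n_unassigned = sum(is.na(nearest$gene)),
       n_target_genes = length(genes),
       n_expressed = n_exp,
       percent_expressed = pct)
}

#' Fraction of AREs overlapping methylation peaks
#'
#' @param ares ARE `GRanges`.
#' @param methylation methylation peak `GRanges` (same assembly).
#' @return List: `k` (AREs overlapping >= 1 methylation peak), `n`,
#'   `percent` (half-up, one decimal; `NA` with a warning when `n = 0`).
#' @export
methylation_overlap_fraction <- function(ares, methylation) {
  n <- length(ares)
  if (n == 0L) {
    warning("empty ARE set: methylation overlap percent undefined")
    return(list(k = 0L, n = 0L, percent = NA_real_))
  }
  k <- sum(GenomicRanges::countOverlaps(ares, methylation) > 0)
  list(k = k, n = n, percent = rounded_percent(k, n, 1))
}

#' Build an annotated ARE catalog
#'
#' Combines the per-ARE annotations produced by the individual steps into
#' one table with BED-style coordinates, ready to write as TSV.
#'
#' @param ares ARE `GRanges`.
#' @param specificity per-ARE specificity labels (recycled if scalar).
#' @param establishment factor from [establishment_profile()].
#' @param de_novo logical from [establishment_profile()].
#' @param state factor from [classify_chromatin_state()].
#' @param nearest data.frame from [assign_nearest_tss()].
#' @param expressed character vector of expressed genes (for the
#'   `target_expressed` flag).
#' @param methylation methylation `GRanges` (for the `methylated` flag), or
#'   `NULL`.
#' @param tss_threshold proximity cutoff in bp (default 1000).
#' @return Data.frame with one row per ARE.
#' @export
build_are_catalog <- function(ares, specificity, establishment, de_novo,
                              state, nearest, expressed,
                              methylation = NULL, tss_threshold = 1000) {
  df <- as_bed_df(ares)
  df$specificity <- rep_len(as.character(specificity), length(ares))
  df$establishment_stage <- as.character(establishment)
  df$de_novo <- de_novo
  df$chromatin_state <- as.character(state)
  df$nearest_gene <- nearest$gene
  df$tss_distance <- nearest$distance
  df$proximity_class <- as.character(classify_proximity(nearest$distance,
                                                        tss_threshold))
  df$target_expressed <- !is.na(nearest$gene) & nearest$gene %in% expressed
  df$methylated <- if (is.null(methylation)) NA else
    GenomicRanges::countOverlaps(ares, methylation) > 0
  df
}
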