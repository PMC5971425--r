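# Synthetic cohort generator: genome, TSS, hierarchically nested ATAC peak
# sets, H3K27ac marks, progenitor reference marks, methylation peaks and a
# TPM table, all with planted per-ARE ground truth. Collision-free placement
# (rejection sampling with a padding margin wider than the replicate jitter)
# keeps every planted label exactly recoverable by the pipeline.

# Largest-remainder apportionment: integer counts summing to n, proportional
# to fractions; exact planted aggregate fractions up to +-1 per category.
.apportion <- function(n, fractions) {
  raw <- n * fractions / sum(fractions)
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    o <- order(raw - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

# Occupied-space ledger: per-chromosome sorted disjoint 1-based intervals.
.occ_new <- function(genome) {
  e <- new.env(parent = emptyenv())
  for (ch in GenomeInfoDb::seqnames(genome))
    assign(ch, list(start = numeric(0), end = numeric(0)), envir = e)
  e
}

.occ_hits <- function(occ, ch, s, e) {
  o <- get(ch, envir = occ)
  if (length(o$start) == 0L) return(rep(FALSE, length(s)))
  pos <- findInterval(e, o$start)
  pos > 0 & o$end[pmax(pos, 1L)] >= s
}

.occ_add <- function(occ, ch, s, e) {
  o <- get(ch, envir = occ)
  ord <- order(c(o$start, s))
  assign(ch, list(start = c(o$start, s)[ord], end = c(o$end, e)[ord]),
         envir = occ)
}

# Place n intervals of the given widths collision-free (with `pad` margin on
# both sides) on the genome, rejection-sampling in batches; errors out when
# any interval needs more than max_rounds proposal rounds.
.place_intervals <- function(widths, genome, occ, pad, max_rounds = 1000) {
  n <- length(widths)
  if (n == 0L)
    return(GenomicRanges::GRanges(seqinfo = genome))
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
  out_chr <- character(n); out_s <- numeric(n)
  todo <- seq_len(n)
  rounds <- 0
  while (length(todo)) {
    rounds <- rounds + 1
    if (rounds > max_rounds)
      stop("placement failed after ", max_rounds,
           " rounds: requested peak density is infeasible")
    ci <- sample.int(length(chroms), length(todo), replace = TRUE,
                     prob = lens / sum(lens))
    L <- lens[ci]
    w <- widths[todo]
    ok_fit <- w + 2 * pad <= L
    span <- pmax(L - w - 2 * pad + 1, 1)
    s <- pad + 1 + floor(stats::runif(length(todo)) * span)
    keep <- ok_fit
    # reject against occupied space (padded footprint)
    for (ch in unique(chroms[ci])) {
      sel <- which(chroms[ci] == ch & keep)
      if (!length(sel)) next
      hit <- .occ_hits(occ, ch, s[sel] - pad, s[sel] + w[sel] - 1 + pad)
      keep[sel[hit]] <- FALSE
    }
    # reject self-collisions within the batch: greedy sweep over sorted
    # candidates, accepting only those clear of every accepted predecessor
    if (any(keep)) {
      ki <- which(keep)
      o <- ki[order(chroms[ci[ki]], s[ki])]
      last_chr <- ""
      last_end <- -Inf
      for (ii in o) {
        ch <- chroms[ci[ii]]
        ps <- s[ii] - pad
        pe <- s[ii] + w[ii] - 1 + pad
        if (ch == last_chr && ps <= last_end) {
          keep[ii] <- FALSE
        } else {
          last_chr <- ch
          last_end <- pe
        }
      }
    }
    acc <- which(keep)
    if (length(acc)) {
      out_chr[todo[acc]] <- chroms[ci[acc]]
      out_s[todo[acc]] <- s[acc]
      for (ch in unique(chroms[ci[acc]])) {
        sel <- acc[chroms[ci[acc]] == ch]
        .occ_add(occ, ch, s[sel] - pad, s[sel] + w[sel] - 1 + pad)
      }
    }
    todo <- todo[!keep]
  }
  gr <- GenomicRanges::GRanges(out_chr,
                               IRanges::IRanges(start = out_s, width = widths))
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
  GenomeInfoDb::seqinfo(gr) <- genome
  gr
}

# Jitter intervals by a uniform integer shift in [-j, j], clamped to the
# chromosome; width preserved.
.jitter <- function(gr, j, genome) {
  if (j == 0 || length(gr) == 0L) return(gr)
  sh <- floor(stats::runif(length(gr), -j, j + 1))
  L <- as.numeric(GenomeInfoDb::seqlengths(genome)[
    as.character(GenomicRanges::seqnames(gr))])
  w <- GenomicRanges::width(gr)
  s <- pmin(pmax(GenomicRanges::start(gr) + sh, 1), L - w + 1)
  GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                         IRanges::IRanges(start = s, width = w),
                         seqinfo = GenomeInfoDb::seqinfo(gr))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of a two-branch
#' erythro-megakaryopoietic study: ARE counts per specificity class,
#' per-stage establishment fractions, poised/active/open/acetylated-only
#' state proportions, per-stage methylation overlap rates, and per-stage
#' expression retention with a TPM >= 1 on/off structure. See the methods
#' vignette for the provenance of each default.
#'
#' @param seed RNG seed; the whole bundle is a deterministic function of it.
#' @param n_chromosomes,chromosome_length genome shape (default 10 x 20 Mb).
#' @param n_genes number of genes / TSS.
#' @param lineages named list of ordered stage vectors sharing a common
#'   prefix (the trunk); names are the class labels of the branch-specific
#'   ARE classes.
#' @param n_ares named counts per specificity class; names must be the
#'   lineage names plus `"shared"`.
#' @param establishment_fractions named list (per class) of per-stage
#'   fractions summing to 1; the shared class uses trunk stages only.
#' @param state_proportions named list (per class) of fractions for
#'   active/poised/open/acetylated_only, each summing to 1.
#' @param methylation_overlap_rate named list (per class) of per-stage rates
#'   in `[0, 1]`: the fraction of AREs established at or before that stage
#'   that overlap a methylation peak of that stage.
#' @param peak_width mean and sd of peak widths in bp (truncated at 150 bp).
#' @param tpm_lognormal meanlog and sdlog of expressed-gene TPM above 1.
#' @param base_expressed_fraction fraction of genes expressed at the root.
#' @param expression_retention named list (per lineage) of per-stage
#'   probabilities that an expressed gene stays expressed.
#' @param expression_gain probability that a silent gene turns on at a stage.
#' @param n_background_atac ATAC peaks outside AREs (present at all stages).
#' @param n_background_marks background peaks per reference mark set.
#' @param n_background_methylation background methylation peaks per stage.
#' @param n_replicates replicates per assay (`atac`, `chip`).
#' @param n_methylation_tools peak-caller ensemble size for methylation.
#' @param replicate_jitter max per-replicate coordinate shift in bp.
#' @param n_replicate_private_peaks noise peaks private to one replicate/tool.
#' @param k27ac_without_atac_fraction fraction of H3K27ac peaks placed
#'   outside accessible chromatin (so ARE retention is below 1).
#' @param nested if `TRUE` (default) a peak established at stage s is present
#'   at all later stages of its lineage; `FALSE` plants presence only at the
#'   establishment stage (stress mode for the earliest-stage rule).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_chromosomes = 10,
    chromosome_length = 2e7,
    n_genes = 20000,
    lineages = list(
      ERY = c("LSK", "CMP", "CFU-E", "ERY"),
      iMK = c("LSK", "CMP", "CFU-MK", "iMK")),
    n_ares = c(ERY = 2098, iMK = 6386, shared = 5989),
    establishment_fractions = list(
      ERY = c("LSK" = 0.64, "CMP" = 0.20, "CFU-E" = 0.14, "ERY" = 0.02),
      iMK = c("LSK" = 0.89, "CMP" = 0.08, "CFU-MK" = 0.01, "iMK" = 0.02),
      shared = c("LSK" = 0.98, "CMP" = 0.02)),
    state_proportions = list(
      ERY = c(active = 0.20, poised = 0.57, open = 0.21, acetylated_only = 0.02),
      iMK = c(active = 0.46, poised = 0.41, open = 0.09, acetylated_only = 0.04),
      shared = c(active = 0.79, poised = 0.15, open = 0.04, acetylated_only = 0.02)),
    methylation_overlap_rate = list(
      ERY = c("LSK" = 0.186, "CMP" = 0.037, "CFU-E" = 0.115, "ERY" = 0.021),
      iMK = c("LSK" = 0.078, "CMP" = 0.023, "CFU-MK" = 0.178, "iMK" = 0.124),
      shared = c("LSK" = 0.05, "CMP" = 0.05)),
    peak_width = c(mean = 500, sd = 100),
    tpm_lognormal = c(mu = 1.5, sigma = 1.2),
    base_expressed_fraction = 0.65,
    expression_retention = list(
      ERY = c("CMP" = 0.90, "CFU-E" = 0.74, "ERY" = 0.94),
      iMK = c("CMP" = 0.90, "CFU-MK" = 0.95, "iMK" = 0.94)),
    expression_gain = 0.10,
    n_background_atac = 2000,
    n_background_marks = 1000,
    n_background_methylation = 1000,
    n_replicates = c(atac = 2, chip = 4),
    n_methylation_tools = 2,
    replicate_jitter = 20,
    n_replicate_private_peaks = 100,
    k27ac_without_atac_fraction = 0.03,
    nested = TRUE) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              chromosome_length = chromosome_length, n_genes = n_genes,
              lineages = lineages, n_ares = n_ares,
              establishment_fractions = establishment_fractions,
              state_proportions = state_proportions,
              methylation_overlap_rate = methylation_overlap_rate,
              peak_width = peak_width, tpm_lognormal = tpm_lognormal,
              base_expressed_fraction = base_expressed_fraction,
              expression_retention = expression_retention,
              expression_gain = expression_gain,
              n_background_atac = n_background_atac,
              n_background_marks = n_background_marks,
              n_background_methylation = n_background_methylation,
              n_replicates = n_replicates,
              n_methylation_tools = n_methylation_tools,
              replicate_jitter = replicate_jitter,
              n_replicate_private_peaks = n_replicate_private_peaks,
              k27ac_without_atac_fraction = k27ac_without_atac_fraction,
              nested = isTRUE(nested))
  # --- validation ---
  if (length(lineages) < 1 || is.null(names(lineages)))
    stop("lineages must be a named list of stage vectors")
  trunk <- lineages[[1]]
  for (l in lineages) {
    k <- 0
    while (k < min(length(trunk), length(l)) && trunk[k + 1] == l[k + 1]) k <- k + 1
    trunk <- trunk[seq_len(k)]
  }
  if (length(trunk) < 1) stop("lineages must share a common root stage")
  cfg$trunk <- trunk
  classes <- names(n_ares)
  if (!all(classes %in% c(names(lineages), "shared")))
    stop("n_ares names must be lineage names plus 'shared'")
  for (cl in classes) {
    st <- if (cl == "shared") trunk else lineages[[cl]]
    ef <- establishment_fractions[[cl]]
    if (is.null(ef) || !setequal(names(ef), st))
      stop("establishment_fractions for class '", cl,
           "' must cover exactly its stages")
    if (abs(sum(ef) - 1) > 1e-8)
      stop("establishment_fractions for class '", cl, "' must sum to 1")
    sp <- state_proportions[[cl]]
    if (is.null(sp) || abs(sum(sp) - 1) > 1e-8)
      stop("state_proportions for class '", cl, "' must sum to 1")
    mr <- methylation_overlap_rate[[cl]]
    if (is.null(mr) || any(mr < 0 | mr > 1))
      stop("methylation_overlap_rate for class '", cl, "' must lie in [0,1]")
  }
  if (peak_width["mean"] <= 0) stop("peak widths must be positive")
  class(cfg) <- "simulation_config"
  cfg
}

.truncated_widths <- function(n, mean, sd, min_width = 150) {
  pmax(round(stats::rnorm(n, mean, sd)), min_width)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Writes a complete file bundle under `dir`: `chrom.sizes`, a TSS table, a
#' TPM table, per-stage replicate ATAC BEDs (hierarchically nested),
#' per-final-cell replicate H3K27ac BEDs, progenitor reference H3K4me1 and
#' H3K27ac BEDs, per-stage methylation tool-call BEDs, a per-ARE
#' ground-truth TSV, and a ready-to-run pipeline config YAML. All
#' randomness is driven by `cfg$seed`; the bundle is byte-identical across
#' reruns with the same config.
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory (created if missing).
#' @return List with `dir`, `files` (named paths), `config_path` (pipeline
#'   YAML), `genome` (`Seqinfo`) and `ground_truth` (list: `ares`
#'   data.frame, `expressed` logical gene x stage matrix, `meth` logical
#'   ARE x stage matrix).
#' @export
generate_cohort <- function(cfg, dir) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  jit <- cfg$replicate_jitter
  pad <- 2 * jit + 10
  lineage_names <- names(cfg$lineages)
  stages_all <- unique(unlist(cfg$lineages))
  final_cells <- vapply(cfg$lineages, function(s) s[length(s)], character(1))
  classes <- names(cfg$n_ares)
  class_stages <- lapply(classes, function(cl)
    if (cl == "shared") cfg$trunk else cfg$lineages[[cl]])
  names(class_stages) <- classes

  genome <- genome_assembly(paste0("chr", seq_len(cfg$n_chromosomes)),
                            rep(cfg$chromosome_length, cfg$n_chromosomes))

  # feasibility: anchors to place (AREs, backgrounds, extras, noise)
  n_extra_k27 <- vapply(lineage_names, function(l) {
    nk <- cfg$n_ares[[l]] + if ("shared" %in% classes) cfg$n_ares[["shared"]] else 0
    f <- cfg$k27ac_without_atac_fraction
    as.integer(round(nk * f / (1 - f)))
  }, integer(1))
  n_noise <- cfg$n_replicate_private_peaks *
    (length(stages_all) * cfg$n_replicates[["atac"]] +
       length(final_cells) * cfg$n_replicates[["chip"]] +
       length(stages_all) * cfg$n_methylation_tools)
  n_anchor <- sum(cfg$n_ares) + cfg$n_background_atac + sum(n_extra_k27) +
    2 * cfg$n_background_marks +
    cfg$n_background_methylation * length(stages_all) + n_noise
  need <- n_anchor * (cfg$peak_width[["mean"]] + 2 * pad)
  if (need > 0.5 * cfg$n_chromosomes * cfg$chromosome_length)
    stop("config error: requested peak bases (", format(need, big.mark = ","),
         ") exceed ~50% of the genome")

  occ <- .occ_new(genome)

  # --- TSS / genes ---
  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
  tchr_i <- sample.int(cfg$n_chromosomes, cfg$n_genes, replace = TRUE)
  tss <- data.frame(
    gene = gene_ids,
    chrom = paste0("chr", tchr_i),
    pos = floor(stats::runif(cfg$n_genes) * cfg$chromosome_length),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)

  # --- ARE anchors, planted labels ---
  n_total <- sum(cfg$n_ares)
  are_class <- rep(classes, times = cfg$n_ares[classes])
  widths <- .truncated_widths(n_total, cfg$peak_width[["mean"]],
                              cfg$peak_width[["sd"]])
  ares <- .place_intervals(widths, genome, occ, pad)
  estab <- character(n_total)
  state <- character(n_total)
  for (cl in classes) {
    sel <- which(are_class == cl)
    st <- class_stages[[cl]]
    counts <- .apportion(length(sel), cfg$establishment_fractions[[cl]][st])
    estab[sel] <- sample(rep(st, counts))   # shuffle within class
    for (sg in st) {                         # states stratified by stage
      ssel <- sel[estab[sel] == sg]
      sp <- cfg$state_proportions[[cl]]
      scounts <- .apportion(length(ssel), sp)
      state[ssel] <- sample(rep(names(sp), scounts))
    }
  }
  estab_idx <- integer(n_total)
  for (cl in classes) {
    sel <- are_class == cl
    estab_idx[sel] <- match(estab[sel], class_stages[[cl]])
  }

  # --- methylation flags: ARE x stage ---
  meth <- matrix(FALSE, n_total, length(stages_all),
                 dimnames = list(NULL, stages_all))
  for (cl in classes) {
    st <- class_stages[[cl]]
    rates <- cfg$methylation_overlap_rate[[cl]]
    for (k in seq_along(st)) {
      cum <- which(are_class == cl & estab_idx <= k)
      km <- as.integer(round(rates[[st[k]]] * length(cum)))
      if (km > 0) meth[sample(cum, km), st[k]] <- TRUE
    }
  }

  # --- background features ---
  bg_atac <- .place_intervals(
    .truncated_widths(cfg$n_background_atac, cfg$peak_width[["mean"]],
                      cfg$peak_width[["sd"]]), genome, occ, pad)
  extra_k27 <- lapply(lineage_names, function(l)
    .place_intervals(.truncated_widths(n_extra_k27[[l]],
                                       cfg$peak_width[["mean"]],
                                       cfg$peak_width[["sd"]]),
                     genome, occ, pad))
  names(extra_k27) <- lineage_names
  bg_me1 <- .place_intervals(
    .truncated_widths(cfg$n_background_marks, cfg$peak_width[["mean"]],
                      cfg$peak_width[["sd"]]), genome, occ, pad)
  bg_ac <- .place_intervals(
    .truncated_widths(cfg$n_background_marks, cfg$peak_width[["mean"]],
                      cfg$peak_width[["sd"]]), genome, occ, pad)
  bg_meth <- lapply(stages_all, function(sg) .place_intervals(
    .truncated_widths(cfg$n_background_methylation, cfg$peak_width[["mean"]],
                      cfg$peak_width[["sd"]]), genome, occ, pad))
  names(bg_meth) <- stages_all

  # --- expression flags and TPM ---
  expressed <- matrix(FALSE, cfg$n_genes, length(stages_all),
                      dimnames = list(gene_ids, stages_all))
  root <- cfg$trunk[1]
  expressed[, root] <- stats::runif(cfg$n_genes) < cfg$base_expressed_fraction
  done <- root
  for (l in lineage_names) {
    st <- cfg$lineages[[l]]
    ret <- cfg$expression_retention[[l]]
    for (k in seq_along(st)[-1]) {
      sg <- st[k]
      if (sg %in% done) next
      parent <- expressed[, st[k - 1]]
      keep <- parent & stats::runif(cfg$n_genes) < ret[[sg]]
      gain <- !parent & stats::runif(cfg$n_genes) < cfg$expression_gain
      expressed[, sg] <- keep | gain
      done <- c(done, sg)
    }
  }
  tpm <- matrix(0, cfg$n_genes, length(stages_all),
                dimnames = list(gene_ids, stages_all))
  for (sg in stages_all) {
    on <- expressed[, sg]
    tpm[on, sg] <- 1 + stats::rlnorm(sum(on), cfg$tpm_lognormal[["mu"]],
                                     cfg$tpm_lognormal[["sigma"]])
    tpm[!on, sg] <- stats::runif(sum(!on), 0, 0.99)
  }
  tpm <- round(tpm, 3)
  # rounding must not cross the TPM=1 boundary
  stopifnot(identical(unname(tpm >= 1), unname(expressed)))

  # --- ground-truth nearest TSS (independent brute force, per chromosome) ---
  gt_gene <- rep(NA_character_, n_total)
  gt_dist <- rep(NA_integer_, n_total)
  achr <- as.character(GenomicRanges::seqnames(ares))
  as0 <- GenomicRanges::start(ares) - 1
  ae0 <- GenomicRanges::end(ares)
  for (ch in unique(achr)) {
    ts <- tss[tss$chrom == ch, , drop = FALSE]
    if (nrow(ts) == 0L) next
    ai <- which(achr == ch)
    D <- pmax(outer(as0[ai], ts$pos, "-"),
              outer(-(ae0[ai] - 1), ts$pos, "+"), 0)
    for (r in seq_along(ai)) {
      dmin <- min(D[r, ])
      gt_dist[ai[r]] <- as.integer(dmin)
      gt_gene[ai[r]] <- min(ts$gene[D[r, ] == dmin])
    }
  }
  gt_prox <- ifelse(gt_dist <= 1000, "cPE", "cEE")
  gt_expr <- vapply(seq_len(n_total), function(i) {
    if (is.na(gt_gene[i])) return(FALSE)
    cl <- are_class[i]
    cells <- if (cl == "shared") final_cells else final_cells[[cl]]
    any(expressed[gt_gene[i], cells])
  }, logical(1))

  # --- stage membership of ATAC truth sets ---
  stage_members <- lapply(stages_all, function(sg) {
    idx <- integer(0)
    for (cl in classes) {
      st <- class_stages[[cl]]
      # shared AREs live in the trunk and both branches; branch classes only
      # in trunk + their own branch
      if (cl != "shared" && !(sg %in% st)) next
      k <- if (cl == "shared") {
        # stage index: trunk index, or branch index for later stages
        li <- vapply(cfg$lineages, function(x) match(sg, x), integer(1))
        suppressWarnings(min(li, na.rm = TRUE))
      } else match(sg, st)
      if (!is.finite(k)) next
      sel <- which(are_class == cl &
                     (if (cfg$nested) estab_idx <= k else estab_idx == k))
      idx <- c(idx, sel)
    }
    sort(idx)
  })
  names(stage_members) <- stages_all

  files <- character(0)
  path <- function(f) file.path(dir, f)
  reg <- function(name, p) { files[[name]] <<- basename(p); p }

  write_chrom_sizes(genome, reg("genome", path("chrom.sizes")))
  utils::write.table(tss, reg("tss", path("tss.tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tpm_df <- data.frame(gene = gene_ids, tpm, check.names = FALSE)
  utils::write.table(tpm_df, reg("expression", path("tpm.tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- ATAC replicates per stage ---
  atac_files <- list()
  for (sg in stages_all) {
    truth <- sort(c(ares[stage_members[[sg]]], bg_atac))
    write_bed(truth, path(sprintf("atac_%s_consensus.bed", sg)))
    reps <- character(cfg$n_replicates[["atac"]])
    for (r in seq_len(cfg$n_replicates[["atac"]])) {
      noise <- .place_intervals(
        .truncated_widths(cfg$n_replicate_private_peaks,
                          cfg$peak_width[["mean"]], cfg$peak_width[["sd"]]),
        genome, occ, pad)
      rep_gr <- sort(c(.jitter(truth, jit, genome), noise))
      f <- sprintf("atac_%s_rep%d.bed", sg, r)
      write_bed(rep_gr, path(f))
      reps[r] <- f
    }
    atac_files[[sg]] <- reps
  }

  # --- H3K27ac replicates per final cell ---
  k27_files <- list()
  for (l in lineage_names) {
    cell <- final_cells[[l]]
    members <- which(are_class %in% c(l, if ("shared" %in% classes) "shared"))
    truth <- sort(c(ares[members], extra_k27[[l]]))
    write_bed(truth, path(sprintf("h3k27ac_%s_consensus.bed", cell)))
    reps <- character(cfg$n_replicates[["chip"]])
    for (r in seq_len(cfg$n_replicates[["chip"]])) {
      noise <- .place_intervals(
        .truncated_widths(cfg$n_replicate_private_peaks,
                          cfg$peak_width[["mean"]], cfg$peak_width[["sd"]]),
        genome, occ, pad)
      rep_gr <- sort(c(.jitter(truth, jit, genome), noise))
      f <- sprintf("h3k27ac_%s_rep%d.bed", cell, r)
      write_bed(rep_gr, path(f))
      reps[r] <- f
    }
    k27_files[[cell]] <- reps
  }

  # --- progenitor reference marks ---
  ref_me1 <- sort(c(ares[state %in% c("active", "poised")], bg_me1))
  ref_ac <- sort(c(ares[state %in% c("active", "acetylated_only")], bg_ac))
  write_bed(ref_me1, reg("ref_h3k4me1", path("ref_LSK_h3k4me1.bed")))
  write_bed(ref_ac, reg("ref_h3k27ac", path("ref_LSK_h3k27ac.bed")))

  # --- methylation tool calls per stage ---
  meth_files <- list()
  for (sg in stages_all) {
    truth <- sort(c(ares[meth[, sg]], bg_meth[[sg]]))
    write_bed(truth, path(sprintf("meth_%s_consensus.bed", sg)))
    tools <- character(cfg$n_methylation_tools)
    for (r in seq_len(cfg$n_methylation_tools)) {
      noise <- .place_intervals(
        .truncated_widths(cfg$n_replicate_private_peaks,
                          cfg$peak_width[["mean"]], cfg$peak_width[["sd"]]),
        genome, occ, pad)
      tool_gr <- sort(c(.jitter(truth, jit, genome), noise))
      f <- sprintf("meth_%s_tool%d.bed", sg, r)
      write_bed(tool_gr, path(f))
      tools[r] <- f
    }
    meth_files[[sg]] <- tools
  }

  # --- ground truth table ---
  gt <- data.frame(are_id = sprintf("are%06d", seq_len(n_total)),
                   as_bed_df(ares),
                   class = are_class,
                   establishment_stage = estab,
                   chromatin_state = state,
                   nearest_gene = gt_gene,
                   tss_distance = gt_dist,
                   proximity_class = gt_prox,
                   target_expressed = gt_expr,
                   stringsAsFactors = FALSE)
  for (sg in stages_all) gt[[paste0("meth_", sg)]] <- meth[, sg]
  utils::write.table(gt, reg("ground_truth", path("ground_truth_ares.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- pipeline config ---
  pcfg <- list(
    genome = "chrom.sizes",
    tss = "tss.tsv",
    expression = "tpm.tsv",
    lineages = cfg$lineages,
    atac = atac_files,
    h3k27ac = k27_files,
    reference_marks = list(h3k4me1 = "ref_LSK_h3k4me1.bed",
                           h3k27ac = "ref_LSK_h3k27ac.bed"),
    methylation = meth_files,
    thresholds = list(tpm = 1.0, tss_proximity = 1000, min_overlap = 1,
                      mbd_min_tools = cfg$n_methylation_tools,
                      mbd_min_overlap = 100),
    permutation = list(n = 500, seed = cfg$seed))
  config_path <- path("cohort_config.yaml")
  yaml::write_yaml(pcfg, config_path)

  list(dir = dir, files = files, config_path = config_path, genome = genome,
       ground_truth = list(ares = gt, expressed = expressed, meth = meth))
}
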