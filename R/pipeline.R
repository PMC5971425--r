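# Pipeline orchestration: consensus -> ARE derivation -> specificity ->
# establishment -> chromatin state -> TSS/proximity -> expression and
# methylation fractions -> permutation tests, with summary tables as TSV.

#' Read a pipeline configuration
#'
#' YAML with keys: `genome` (chrom.sizes path), `tss`, `expression`,
#' `lineages` (named ordered stage lists), `atac` (per-stage replicate BED
#' lists), `h3k27ac` (per-final-cell replicate BED lists),
#' `reference_marks` (`h3k4me1`, `h3k27ac`), `methylation` (per-stage
#' tool-call BED lists), `thresholds` (`tpm`, `tss_proximity`,
#' `min_overlap`, `mbd_min_tools`, `mbd_min_overlap`) and `permutation`
#' (`n`, `seed`). Relative paths are resolved against the config file's
#' directory.
#'
#' @param path path to the YAML file.
#' @return A list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("pipeline config not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  cfg$genome <- resolve(cfg$genome)
  cfg$tss <- resolve(cfg$tss)
  cfg$expression <- resolve(cfg$expression)
  cfg$atac <- lapply(cfg$atac, resolve)
  cfg$h3k27ac <- lapply(cfg$h3k27ac, resolve)
  cfg$reference_marks <- lapply(cfg$reference_marks, resolve)
  cfg$methylation <- lapply(cfg$methylation, resolve)
  defaults <- list(tpm = 1.0, tss_proximity = 1000, min_overlap = 1,
                   mbd_min_tools = 2, mbd_min_overlap = 100)
  cfg$thresholds <- utils::modifyList(defaults, as.list(cfg$thresholds))
  if (is.null(cfg$permutation)) cfg$permutation <- list(n = 500, seed = 1)
  class(cfg) <- "pipeline_config"
  cfg
}

# Fail fast, naming every missing input file, before any computation.
.validate_pipeline_files <- function(cfg) {
  paths <- c(cfg$genome, cfg$tss, cfg$expression,
             unlist(cfg$atac), unlist(cfg$h3k27ac),
             unlist(cfg$reference_marks), unlist(cfg$methylation))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  th <- cfg$thresholds
  if (any(unlist(th) <= 0)) stop("all thresholds must be positive")
  invisible(TRUE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full establishment-timing pipeline
#'
#' Executes every stage on the configured inputs and writes paper-style
#' summary tables under `out_dir`: per-cell feature counts, transcript
#' maintenance chains with proportion tests, per-class target-gene
#' expression by establishment stage, chromatin-state fractions,
#' methylation-overlap tables, permutation-test results, and one annotated
#' ARE catalog per terminal cell type. A fixed permutation seed makes the
#' whole report reproducible.
#'
#' @param cfg a `pipeline_config` from [read_pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (`consensus`,
#'   `ares`, `partition`, `profiles`, `states`, `catalogs`, `tables`,
#'   `permutation`), plus `files` naming every TSV written.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  .validate_pipeline_files(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds
  log_lines <- c("commitpoint pipeline run",
                 sprintf("thresholds: tpm=%g tss_proximity=%g min_overlap=%g mbd_min_tools=%g mbd_min_overlap=%g",
                         th$tpm, th$tss_proximity, th$min_overlap,
                         th$mbd_min_tools, th$mbd_min_overlap),
                 sprintf("permutation: n=%d seed=%d",
                         cfg$permutation$n, cfg$permutation$seed))
  genome <- read_chrom_sizes(cfg$genome)
  tss <- read_tss(cfg$tss, genome)
  expr <- read_expression(cfg$expression)
  lineages <- lapply(cfg$lineages, unlist)
  stages_all <- unique(unlist(lineages))
  final_cells <- vapply(lineages, function(s) s[length(s)], character(1))

  # stage 1: consensus peak sets
  atac <- lapply(names(cfg$atac), function(sg) {
    reps <- lapply(cfg$atac[[sg]], read_bed, genome = genome)
    consensus_in_merged_regions(reps, require = "all")
  })
  names(atac) <- names(cfg$atac)
  k27 <- lapply(names(cfg$h3k27ac), function(cell) {
    reps <- lapply(cfg$h3k27ac[[cell]], read_bed, genome = genome)
    consensus_in_merged_regions(reps, require = "all")
  })
  names(k27) <- names(cfg$h3k27ac)
  meth <- lapply(names(cfg$methylation), function(sg) {
    calls <- lapply(cfg$methylation[[sg]], read_bed, genome = genome)
    ensemble_consensus(calls, min_tools = th$mbd_min_tools,
                       min_overlap_bp = th$mbd_min_overlap)
  })
  names(meth) <- names(cfg$methylation)
  ref_me1 <- read_bed(cfg$reference_marks$h3k4me1, genome)
  ref_ac <- read_bed(cfg$reference_marks$h3k27ac, genome)

  # table 1 style: feature counts per cell type
  tab1 <- data.frame(
    cell = stages_all,
    n_expressed_tpm1 = vapply(stages_all, function(sg)
      length(expressed_set(expr, sg, th$tpm)), integer(1)),
    n_expressed_tpm10 = vapply(stages_all, function(sg)
      length(expressed_set(expr, sg, 10)), integer(1)),
    n_atac_peaks = vapply(stages_all, function(sg)
      if (sg %in% names(atac)) length(atac[[sg]]) else NA_integer_, integer(1)),
    n_methylation_peaks = vapply(stages_all, function(sg)
      if (sg %in% names(meth)) length(meth[[sg]]) else NA_integer_, integer(1)))

  # table 2 style: maintenance chains + proportion test between lineages
  tab2 <- do.call(rbind, lapply(names(lineages), function(l) {
    st <- lineages[[l]]
    counts <- maintenance_chain(expr, st, th$tpm)
    data.frame(lineage = l, stage = st, stage_index = seq_along(st),
               n_maintained = as.integer(counts),
               pct_since_root = rounded_percent(counts, counts[1], 0),
               pct_from_parent = c(100, rounded_percent(
                 counts[-1], counts[-length(counts)], 0)))
  }))
  chains <- lapply(lineages, function(st) maintenance_chain(expr, st, th$tpm))
  prop_tests <- NULL
  if (length(lineages) == 2) {
    c1 <- chains[[1]]; c2 <- chains[[2]]
    kmax <- min(length(c1), length(c2))
    pt <- two_proportion_test(c1[kmax], c1[1], c2[kmax], c2[1])
    prop_tests <- data.frame(
      comparison = sprintf("maintained_to_final_%s_vs_%s",
                           names(lineages)[1], names(lineages)[2]),
      k1 = c1[kmax], n1 = c1[1], k2 = c2[kmax], n2 = c2[1],
      z = pt$z, p = pt$p)
  }

  # stage 2: ARE derivation per terminal cell
  ares <- list(); frac <- numeric(0)
  for (cell in names(k27)) {
    d <- derive_ares(k27[[cell]], atac[[cell]])
    ares[[cell]] <- d$ares
    frac[[cell]] <- d$frac_k27ac_in_atac
    log_lines <- c(log_lines, sprintf(
      "derive_ares[%s]: %d/%d H3K27ac peaks in accessible chromatin (%.1f%%)",
      cell, length(d$ares), length(k27[[cell]]),
      100 * d$frac_k27ac_in_atac))
  }

  # stage 3: specificity partition (two terminal cells)
  if (length(ares) != 2)
    stop("specificity partition expects exactly 2 terminal cell types, got ",
         length(ares))
  cells <- names(ares)
  part <- partition_specificity(ares[[1]], ares[[2]])
  class_sets <- list(part$a_specific, part$b_specific, part$shared)
  names(class_sets) <- c(cells[1], cells[2], "shared")
  log_lines <- c(log_lines, sprintf(
    "specificity: %d %s-specific, %d %s-specific, %d shared",
    length(part$a_specific), cells[1], length(part$b_specific), cells[2],
    length(part$shared)))

  # map terminal cell -> lineage name
  cell_lineage <- names(final_cells)[match(cells, final_cells)]
  class_stage_sets <- list()
  for (i in 1:2) {
    st <- lineages[[cell_lineage[i]]]
    class_stage_sets[[cells[i]]] <- atac[st]
  }
  # shared AREs: presence at stage index k = overlap with either lineage's
  # stage-k ATAC set
  kmax <- min(lengths(lineages))
  shared_stages <- lapply(seq_len(kmax), function(k) {
    sets <- lapply(lineages, function(st) atac[[st[k]]])
    merge_peaks(do.call(c, unname(lapply(sets, GenomicRanges::granges))))
  })
  names(shared_stages) <- vapply(seq_len(kmax), function(k) {
    nm <- unique(vapply(lineages, `[`, character(1), k))
    paste(nm, collapse = "|")
  }, character(1))
  class_stage_sets[["shared"]] <- shared_stages

  # stage 4: establishment profiles per class
  profiles <- lapply(names(class_sets), function(cl)
    establishment_profile(class_sets[[cl]], class_stage_sets[[cl]]))
  names(profiles) <- names(class_sets)
  estab_tab <- do.call(rbind, lapply(names(profiles), function(cl) {
    pr <- profiles[[cl]]
    data.frame(class = cl, stage = names(pr$presence_fractions),
               stage_index = seq_along(pr$presence_fractions),
               presence_fraction = as.numeric(pr$presence_fractions),
               n_established = as.integer(table(pr$establishment)))
  }))

  # stage 5: chromatin state of progenitor-established AREs, per class
  states <- lapply(names(class_sets), function(cl) {
    pr <- profiles[[cl]]
    root_established <- class_sets[[cl]][
      !is.na(pr$establishment) &
        as.integer(pr$establishment) == 1L]
    classify_chromatin_state(root_established, ref_me1, ref_ac)
  })
  names(states) <- names(class_sets)
  state_tab <- do.call(rbind, lapply(names(states), function(cl)
    data.frame(class = cl, state = names(states[[cl]]$fractions),
               fraction = as.numeric(states[[cl]]$fractions))))

  # stage 6: catalogs with TSS assignment, proximity, expression, methylation
  catalogs <- list()
  tab3 <- NULL
  for (i in 1:2) {
    cell <- cells[i]
    lin <- cell_lineage[i]
    expressed <- expressed_set(expr, cell, th$tpm)
    meth_final <- meth[[cell]]
    for (cl in c(cell, "shared")) {
      set <- class_sets[[cl]]
      if (cl == "shared" && i == 2) next  # shared catalogued once (with cell 1)
      pr <- profiles[[cl]]
      st <- classify_chromatin_state(set, ref_me1, ref_ac)
      nearest <- assign_nearest_tss(set, tss)
      cat_df <- build_are_catalog(set, cl, pr$establishment, pr$de_novo,
                                  st$state, nearest, expressed,
                                  methylation = meth_final,
                                  tss_threshold = th$tss_proximity)
      catalogs[[cl]] <- cat_df
      # table 3 style: cumulative establishment x target expression
      stages_cl <- names(pr$presence_fractions)
      rows <- lapply(seq_along(stages_cl), function(k) {
        sel <- !is.na(pr$establishment) & as.integer(pr$establishment) <= k
        tf <- target_expressed_fraction(nearest[sel, , drop = FALSE], expressed)
        data.frame(class = cl, established_by = stages_cl[k],
                   stage_index = k, n_ares = tf$n_ares,
                   n_target_genes = tf$n_target_genes,
                   n_expressed = tf$n_expressed,
                   percent_expressed = tf$percent_expressed)
      })
      tab3 <- rbind(tab3, do.call(rbind, rows))
    }
  }

  # table 5 style: methylation overlap of AREs established by stage s,
  # against stage-s methylation peaks
  tab5 <- NULL
  for (i in 1:2) {
    cell <- cells[i]
    lin <- cell_lineage[i]
    st <- lineages[[lin]]
    pr <- profiles[[cell]]
    set <- class_sets[[cell]]
    for (k in seq_along(st)) {
      if (!st[k] %in% names(meth)) next
      sel <- !is.na(pr$establishment) & as.integer(pr$establishment) <= k
      mo <- methylation_overlap_fraction(set[sel], meth[[st[k]]])
      tab5 <- rbind(tab5, data.frame(
        class = cell, stage = st[k], stage_index = k,
        k_methylated = mo$k, n_ares = mo$n, percent = mo$percent))
    }
  }
  # table 6 style: root-established AREs by chromatin state vs root methylation
  root_stage <- lineages[[1]][1]
  tab6 <- NULL
  if (root_stage %in% names(meth)) {
    for (cl in cells) {
      pr <- profiles[[cl]]
      root_sel <- !is.na(pr$establishment) & as.integer(pr$establishment) == 1L
      set <- class_sets[[cl]][root_sel]
      stt <- states[[cl]]$state
      for (s in levels(stt)) {
        sub <- set[stt == s]
        if (length(sub) == 0L) next
        mo <- methylation_overlap_fraction(sub, meth[[root_stage]])
        tab6 <- rbind(tab6, data.frame(class = cl, state = s,
                                       k_methylated = mo$k, n_ares = mo$n,
                                       percent = mo$percent))
      }
    }
  }

  # stage 7: permutation tests (class AREs vs each stage's ATAC peaks)
  perm_tab <- NULL
  perm_results <- list()
  pi <- 0
  for (cl in cells) {
    lin <- cell_lineage[match(cl, cells)]
    for (sg in lineages[[lin]]) {
      pi <- pi + 1
      set.seed(cfg$permutation$seed + pi)
      pres <- permutation_overlap_test(class_sets[[cl]], atac[[sg]], genome,
                                       n_permutations = cfg$permutation$n,
                                       alternative = "greater")
      perm_results[[paste(cl, sg, sep = "_vs_")]] <- pres
      perm_tab <- rbind(perm_tab, data.frame(
        class = cl, stage = sg, observed = pres$observed,
        null_mean = pres$null_mean, null_sd = pres$null_sd,
        z = pres$z, p_empirical = pres$p_empirical,
        n_permutations = pres$n_permutations))
    }
  }

  files <- c(
    table1_counts = .write_tsv(tab1, file.path(out_dir, "table1_counts.tsv")),
    table2_maintenance = .write_tsv(tab2, file.path(out_dir, "table2_maintenance.tsv")),
    establishment = .write_tsv(estab_tab, file.path(out_dir, "establishment_profile.tsv")),
    states = .write_tsv(state_tab, file.path(out_dir, "state_classification.tsv")),
    table3_targets = .write_tsv(tab3, file.path(out_dir, "table3_target_expression.tsv")),
    table5_methylation = if (!is.null(tab5))
      .write_tsv(tab5, file.path(out_dir, "table5_methylation.tsv")) else NULL,
    table6_state_methylation = if (!is.null(tab6))
      .write_tsv(tab6, file.path(out_dir, "table6_state_methylation.tsv")) else NULL,
    permutation = .write_tsv(perm_tab, file.path(out_dir, "permutation_tests.tsv")))
  if (!is.null(prop_tests))
    files["proportion_tests"] <- .write_tsv(
      prop_tests, file.path(out_dir, "proportion_tests.tsv"))
  for (cl in names(catalogs))
    files[paste0("catalog_", cl)] <- .write_tsv(
      catalogs[[cl]], file.path(out_dir, sprintf("are_catalog_%s.tsv", cl)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(consensus = list(atac = atac, h3k27ac = k27, methylation = meth),
                 ares = ares, frac_k27ac_in_atac = frac, partition = part,
                 class_sets = class_sets, profiles = profiles, states = states,
                 catalogs = catalogs,
                 tables = list(counts = tab1, maintenance = tab2,
                               establishment = estab_tab, states = state_tab,
                               targets = tab3, methylation = tab5,
                               state_methylation = tab6,
                               proportion_tests = prop_tests,
                               permutation = perm_tab),
                 permutation = perm_results,
                 files = files))
}
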