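# Synthetic cohort generator: determinism, exact planted aggregate labels,
# end-to-end recoverability from the emitted files, and config validation.

test_that("the generated bundle is byte-identical across reruns with one seed", {
  cfg <- simulation_config(
    seed = 5, n_chromosomes = 2, chromosome_length = 2e6,
    n_genes = 200, n_ares = c(ERY = 40, iMK = 60, shared = 50),
    n_background_atac = 40, n_background_marks = 20,
    n_background_methylation = 20, n_replicate_private_peaks = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
})

test_that("planted aggregate fractions match the configuration exactly", {
  coh <- small_cohort()
  gt <- coh$cohort$ground_truth$ares
  cfg <- coh$cfg
  for (cl in names(cfg$n_ares)) {
    sub <- gt[gt$class == cl, ]
    expect_equal(nrow(sub), unname(cfg$n_ares[[cl]]))
    # establishment counts are the largest-remainder apportionment
    ef <- cfg$establishment_fractions[[cl]]
    counts <- table(factor(sub$establishment_stage, levels = names(ef)))
    expect_true(all(abs(counts - nrow(sub) * ef) <= 1))
    # state proportions stratified within establishment stage
    sp <- cfg$state_proportions[[cl]]
    st_counts <- table(factor(sub$chromatin_state, levels = names(sp)))
    expect_true(all(abs(st_counts - nrow(sub) * sp) <= length(ef)))
  }
})

test_that("the pipeline operations recover every planted per-ARE label from the files", {
  coh <- small_cohort()
  gt <- coh$cohort$ground_truth$ares
  cfg <- coh$cfg
  dir <- coh$cohort$dir
  genome <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  atac <- cohort_truth_atac(coh)

  for (cl in c("ERY", "iMK")) {
    sub <- gt[gt$class == cl, ]
    ares <- peak_set(sub$chrom, sub$start, sub$end, genome = genome)
    ord <- order(sub$chrom, sub$start)   # peak_set sorts; align truth rows
    sub <- sub[ord, ]
    stages <- cfg$lineages[[cl]]
    pr <- establishment_profile(ares, atac[stages])
    expect_identical(as.character(pr$establishment), sub$establishment_stage)
    # cumulative presence fractions equal planted cumulative establishment
    ef <- cfg$establishment_fractions[[cl]][stages]
    planted_cum <- cumsum(table(factor(sub$establishment_stage,
                                       levels = stages))) / nrow(sub)
    expect_equal(unname(pr$presence_fractions), unname(as.numeric(planted_cum)))

    st <- classify_chromatin_state(
      ares,
      read_bed(file.path(dir, "ref_LSK_h3k4me1.bed"), genome),
      read_bed(file.path(dir, "ref_LSK_h3k27ac.bed"), genome))
    expect_identical(as.character(st$state), sub$chromatin_state)

    # per-stage methylation flags recovered from the stage methylation peaks
    final <- stages[length(stages)]
    meth <- read_bed(file.path(dir, sprintf("meth_%s_consensus.bed", final)),
                     genome)
    hit <- GenomicRanges::countOverlaps(ares, meth) > 0
    expect_identical(hit, sub[[paste0("meth_", final)]])

    # nearest TSS assignment agrees with the generator's brute-force truth
    tss <- read_tss(file.path(dir, "tss.tsv"), genome)
    nt <- assign_nearest_tss(ares, tss)
    expect_identical(nt$gene, sub$nearest_gene)
    expect_identical(nt$distance, sub$tss_distance)
  }
})

test_that("maintenance chains on the synthetic TPM table match the analytic expectation", {
  coh <- small_cohort()
  cfg <- coh$cfg
  expr <- read_expression(file.path(coh$cohort$dir, "tpm.tsv"))
  for (l in names(cfg$lineages)) {
    st <- cfg$lineages[[l]]
    chain <- maintenance_chain(expr, st, 1.0)
    expected <- cfg$n_genes * cfg$base_expressed_fraction *
      cumprod(c(1, cfg$expression_retention[[l]][st[-1]]))
    # binomial 99% envelope around each expected count
    sds <- sqrt(pmax(expected, 1))
    expect_true(all(abs(chain - expected) < 2.58 * 3 * sds))
  }
})

test_that("infeasible peak density and inconsistent configs are rejected", {
  expect_error(
    simulation_config(establishment_fractions = list(
      ERY = c("LSK" = 0.5, "CMP" = 0.2, "CFU-E" = 0.1, "ERY" = 0.1),
      iMK = c("LSK" = 0.89, "CMP" = 0.08, "CFU-MK" = 0.01, "iMK" = 0.02),
      shared = c("LSK" = 0.98, "CMP" = 0.02))),
    "sum to 1")
  cfg <- simulation_config(
    seed = 3, n_chromosomes = 1, chromosome_length = 5e4,
    n_genes = 50, n_ares = c(ERY = 500, iMK = 500, shared = 500))
  expect_error(generate_cohort(cfg, withr::local_tempdir()), "50%")
})
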