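# ARE derivation, specificity partition, establishment inference, chromatin
# state, nearest-TSS assignment and methylation overlap.

test_that("derive_ares keeps acetylation peaks in accessible chromatin and reports the fraction", {
  k27 <- peak_set("chr1", 0, 500)
  atac <- peak_set("chr1", 400, 900)
  d <- derive_ares(k27, atac)
  expect_equal(bed_df(d$ares), data.frame(chrom = "chr1", start = 0, end = 500))
  expect_equal(d$frac_k27ac_in_atac, 1.0)

  d2 <- derive_ares(peak_set("chr1", 0, 100), peak_set("chr1", 500, 600))
  expect_equal(length(d2$ares), 0L)
  expect_equal(d2$frac_k27ac_in_atac, 0)

  expect_warning(d3 <- derive_ares(GenomicRanges::GRanges(), atac), "undefined")
  expect_true(is.na(d3$frac_k27ac_in_atac))

  set.seed(91)
  len <- 40000
  dk <- random_bed(50, len)
  da <- random_bed(50, len)
  d4 <- derive_ares(as_ps(dk), as_ps(da))
  hit <- vapply(seq_len(nrow(dk)), function(i)
    any(pair_overlap_bp(dk$start[i], dk$end[i], da$start, da$end) > 0),
    logical(1))
  expect_equal(bed_df(d4$ares), bed_df(as_ps(dk[hit, ])), ignore_attr = TRUE)
  expect_equal(d4$frac_k27ac_in_atac, mean(hit))
})

test_that("partition_specificity splits AREs into specific and shared clusters symmetrically", {
  a <- peak_set(c("chr1", "chr1"), c(0, 1000), c(200, 1200))
  p_id <- partition_specificity(a, a)
  expect_equal(length(p_id$a_specific), 0L)
  expect_equal(length(p_id$b_specific), 0L)
  expect_equal(bed_df(p_id$shared), bed_df(a))

  b <- peak_set("chr1", 5000, 5200)
  p_dis <- partition_specificity(a, b)
  expect_equal(bed_df(p_dis$a_specific), bed_df(a))
  expect_equal(bed_df(p_dis$b_specific), bed_df(b))
  expect_equal(length(p_dis$shared), 0L)

  set.seed(93)
  len <- 30000
  da <- random_bed(40, len)
  db <- random_bed(40, len)
  pa <- partition_specificity(as_ps(da), as_ps(db))
  # partition identity under the all-pairs oracle
  a_hits <- vapply(seq_len(nrow(da)), function(i)
    any(pair_overlap_bp(da$start[i], da$end[i], db$start, db$end) > 0),
    logical(1))
  expect_equal(length(pa$a_specific), sum(!a_hits))
  # symmetry: swapping inputs swaps the specific sets, preserves shared
  pb <- partition_specificity(as_ps(db), as_ps(da))
  expect_identical(bed_df(pa$a_specific), bed_df(pb$b_specific))
  expect_identical(bed_df(pa$shared), bed_df(pb$shared))
})

test_that("establishment_profile finds the earliest accessible stage and flags de novo", {
  ares <- peak_set(c("chr1", "chr1", "chr1"), c(0, 1000, 2000),
                   c(200, 1200, 2200))
  st1 <- peak_set("chr1", 0, 200)                          # only ARE 1
  st2 <- peak_set(c("chr1", "chr1"), c(0, 1000), c(200, 1200))
  st3 <- ares                                              # all three
  pr <- establishment_profile(ares, list(root = st1, mid = st2, final = st3))
  expect_equal(as.character(pr$establishment), c("root", "mid", "final"))
  expect_equal(pr$de_novo, c(FALSE, TRUE, TRUE))
  expect_equal(unname(pr$presence_fractions), c(1 / 3, 2 / 3, 1))
  expect_true(all(diff(pr$presence_fractions) >= 0))  # nested => non-decreasing
  expect_error(establishment_profile(ares, list()), "non-empty")
})

test_that("classify_chromatin_state equals the 2x2 overlap-flag tally", {
  set.seed(97)
  len <- 30000
  da <- random_bed(60, len)
  dm <- random_bed(30, len)
  dc <- random_bed(30, len)
  cs <- classify_chromatin_state(as_ps(da), as_ps(dm), as_ps(dc))
  me1 <- vapply(seq_len(nrow(da)), function(i)
    any(pair_overlap_bp(da$start[i], da$end[i], dm$start, dm$end) > 0),
    logical(1))
  ac <- vapply(seq_len(nrow(da)), function(i)
    any(pair_overlap_bp(da$start[i], da$end[i], dc$start, dc$end) > 0),
    logical(1))
  oracle <- ifelse(me1 & ac, "active",
            ifelse(me1, "poised", ifelse(ac, "acetylated_only", "open")))
  expect_equal(as.character(cs$state), oracle)
  expect_equal(sum(cs$fractions), 1)
})

test_that("assign_nearest_tss minimizes edge distance with lexicographic tie-break", {
  tss <- data.frame(gene = c("geneB", "geneA"), chrom = "chr1",
                    pos = c(350, 50), strand = "+")
  ares <- peak_set(c("chr1", "chr1"), c(100, 300), c(200, 400))
  nt <- assign_nearest_tss(ares, tss)
  # TSS inside second ARE
  expect_equal(nt$gene[2], "geneB")
  expect_equal(nt$distance[2], 0L)
  # first ARE: geneA at 100-50=50, geneB at 350-199=151
  expect_equal(nt$gene[1], "geneA")
  expect_equal(nt$distance[1], 50L)

  # equidistant TSS -> lexicographically smallest gene id
  tss2 <- data.frame(gene = c("geneB", "geneA"), chrom = "chr1",
                     pos = c(260, 40), strand = "+")
  nt2 <- assign_nearest_tss(peak_set("chr1", 100, 201), tss2)
  expect_equal(nt2$gene, "geneA")  # both at distance 60

  # chromosome without TSS stays unassigned
  nt3 <- assign_nearest_tss(peak_set("chr9", 0, 100), tss)
  expect_true(is.na(nt3$gene) && is.na(nt3$distance))

  # random layout vs exhaustive scan
  set.seed(101)
  for (rep in 1:5) {
    nt_tss <- data.frame(gene = sprintf("g%03d", sample(999, 30)),
                         chrom = "chrT",
                         pos = sample(20000, 30), strand = "+")
    da <- random_bed(40, 20000)
    nt4 <- assign_nearest_tss(as_ps(da), nt_tss)
    for (i in seq_len(nrow(da))) {
      d <- pmax(da$start[i] - nt_tss$pos,
                nt_tss$pos - (da$end[i] - 1), 0)
      expect_equal(nt4$distance[i], as.integer(min(d)))
      expect_equal(nt4$gene[i], min(nt_tss$gene[d == min(d)]))
    }
  }
})

test_that("classify_proximity is inclusive at the promoter boundary", {
  expect_equal(as.character(classify_proximity(c(0, 1000, 1001))),
               c("cPE", "cPE", "cEE"))
  expect_true(is.na(classify_proximity(NA_integer_)))
  expect_error(classify_proximity(-1), "non-negative")
})

test_that("target_expressed_fraction tallies unique targets and their expressed subset", {
  nearest <- data.frame(gene = c("g1", "g1", "g2", "g3", NA),
                        distance = c(0L, 10L, 5L, 2000L, NA))
  out <- target_expressed_fraction(nearest, expressed = c("g1", "g3"))
  expect_equal(out$n_ares, 4)
  expect_equal(out$n_unassigned, 1)
  expect_equal(out$n_target_genes, 3)
  expect_equal(out$n_expressed, 2)
  expect_equal(out$percent_expressed, 67)

  all_on <- target_expressed_fraction(nearest[1:3, ], expressed = c("g1", "g2"))
  expect_equal(all_on$percent_expressed, 100)
})

test_that("methylation_overlap_fraction counts AREs touching methylation peaks", {
  a <- peak_set(c("chr1", "chr1"), c(0, 1000), c(200, 1200))
  m_dis <- peak_set("chr1", 5000, 5100)
  out <- methylation_overlap_fraction(a, m_dis)
  expect_equal(out$k, 0L)
  expect_equal(out$percent, 0)

  set.seed(103)
  len <- 30000
  da <- random_bed(50, len)
  dm <- random_bed(20, len)
  out2 <- methylation_overlap_fraction(as_ps(da), as_ps(dm))
  k_oracle <- sum(vapply(seq_len(nrow(da)), function(i)
    any(pair_overlap_bp(da$start[i], da$end[i], dm$start, dm$end) > 0),
    logical(1)))
  expect_equal(out2$k, k_oracle)
  expect_equal(out2$percent, rounded_percent(k_oracle, 50, 1))

  expect_warning(out3 <- methylation_overlap_fraction(GenomicRanges::GRanges(), m_dis),
                 "undefined")
  expect_true(is.na(out3$percent))
})
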