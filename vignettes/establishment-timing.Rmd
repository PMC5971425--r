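---
title: "Timing regulatory-element establishment: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing regulatory-element establishment: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commitpoint)
```

# The inference

`commitpoint` works on one object: a set of genomic intervals ("peaks") per
assay, cell type and replicate. Coordinates are BED-style 0-based half-open at
every interface (files, constructors, reported tables); internally intervals
live in `GRanges` and conversion happens only at the boundary. "Overlap"
between two peaks means ≥ 1 shared base unless a rule says otherwise — the
one exception is the methylation ensemble rule, which demands a 100 bp
pairwise overlap.

The pipeline runs in seven steps.

1. **Consensus.** Replicates of one assay/cell are pooled and merged
   (union of covered bases; abutting intervals coalesce). A merged region is
   kept iff the required number of distinct replicates each contribute at
   least one overlapping peak — all replicates for ATAC ("both") and ChIP,
   and for the methylation ensemble at least `mbd_min_tools = 2` peak-calling
   tools whose best supporting pair of peaks overlaps by
   `mbd_min_overlap = 100` bp. Consensus coordinates are the merged-region
   footprint, not a per-replicate intersection: retaining the region keeps
   the downstream overlap logic monotone in replicate noise, at the cost of
   slightly widened peaks.
2. **ARE derivation.** H3K27ac consensus peaks are retained (own
   coordinates) iff they overlap the same cell's ATAC consensus. Peak-level
   filtering rather than geometric intersection keeps ARE counts
   interpretable as acetylation-peak counts and keeps TSS distances stable.
3. **Specificity.** Between the two terminal cells, an ARE with no overlap
   in the other cell's ARE set is cell-specific; reciprocally overlapping
   AREs are merged into shared clusters, each cluster counted once. The
   operation is symmetric in its inputs.
4. **Establishment.** Each ARE is intersected with the ATAC consensus of
   every stage of its lineage, ordered most primitive first. The earliest
   overlapping stage is its establishment stage; an ARE first seen after the
   root is "established de novo" at that stage. The per-stage presence
   fractions are cumulative and, on nested data, non-decreasing. Shared AREs
   have no unique lineage, so stage *k* presence is scored against the union
   of both lineages' stage-*k* ATAC sets (stages aligned by index); this is
   a package choice where the underlying question is ambiguous.
5. **Chromatin state.** Root-established AREs are flagged against
   progenitor reference H3K4me1/H3K27ac peak sets: both marks → `active`,
   H3K4me1 only → `poised`, neither → `open`. The 2×2 table has a fourth
   cell, H3K27ac-only; three-state schemes leave it undefined, so it is
   reported explicitly as `acetylated_only` and the four fractions always
   sum to 1.
6. **Annotation.** Nearest TSS by edge distance (0 if the TSS falls inside
   the ARE), minimized genome-wide on the ARE's chromosome, ties broken by
   the lexicographically smallest gene id; AREs on chromosomes without a TSS
   stay unassigned rather than silently dropped. Distance ≤ 1000 bp
   (inclusive) classifies a candidate promoter element, else candidate
   enhancer element. Target expression uses TPM ≥ `tpm = 1` (boundary
   inclusive); methylation flags use ≥ 1 bp overlap with the methylation
   consensus.
7. **Enrichment.** The permutation test re-places each query interval
   uniformly on its own chromosome (width preserved, self-overlap allowed,
   no masking model — matching the default behavior of uniform/circular
   randomization frameworks), recomputes the overlap count
   `n_permutations = 500` times, and reports
   `z = (obs − mean)/sd` and the add-one empirical p,
   `(#{null ≥ obs} + 1)/(n + 1)`, floor `1/501`. The alternative defaults to
   "greater" (enrichment); "less" exists for completeness. The query set is
   the one randomized. When the null is degenerate (sd = 0, e.g. saturated
   tilings) the z-score is flagged undefined while the empirical p is still
   valid.

# Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `tpm` | 1 | TPM | conventional expressed/not-expressed cutoff; boundary inclusive |
| `tss_proximity` | 1000 | bp | promoter vs enhancer band, inclusive at 1000 |
| `min_overlap` | 1 | bp | peak "presence"; any shared base counts |
| `mbd_min_tools` | 2 | tools | ensemble support for methylation peaks |
| `mbd_min_overlap` | 100 | bp | pairwise tool agreement for methylation |
| `permutation$n` | 500 | iterations | resolution 1/501 ≈ 0.002 on empirical p |

Statistical choices: the transcript-maintenance comparison uses the pooled
two-proportion z-test without continuity correction; at the 10^4-scale counts
it is applied to, the normal approximation error is negligible (the test
suite bounds it against a Monte-Carlo binomial null, which also documents
that at n ≈ 10 the approximation is off by up to ~0.04 — do not use this test
on tiny counts). Percentages are rounded half-up (never banker's), to the
integer for maintenance/target tables and to one decimal for methylation
tables.

# What the synthetic cohort emulates

`simulation_config()` defaults encode the study conditions the pipeline is
meant to resolve: two lineages LSK → CMP → CFU-E → ERY and
LSK → CMP → CFU-MK → iMK; 2098 ERY-specific, 6386 iMK-specific and 5989
shared AREs; establishment fractions (ERY 0.64/0.20/0.14/0.02,
iMK 0.89/0.08/0.01/0.02, shared 0.98/0.02 across its trunk); progenitor
state proportions (ERY 0.20 active/0.57 poised/0.21 open/0.02 acetylated-only,
iMK 0.46/0.41/0.09/0.04, shared 0.79/0.15/0.04/0.02); per-stage methylation
overlap rates (ERY 0.186/0.037/0.115/0.021, iMK 0.078/0.023/0.178/0.124);
and expression with 65% of 20,000 genes on at the root, per-stage retention
0.90/0.74/0.94 (erythroid) and 0.90/0.95/0.94 (megakaryocytic), a 0.10
per-stage gain rate, and lognormal TPM above the threshold.

Where no study value exists, a single realistic choice was made and kept: a
10 × 20 Mb genome (large enough for ~30,000 features at < 10% occupancy),
peak widths N(500, 100²) bp truncated at 150 bp (so jittered replicate pairs
always clear the 100 bp ensemble rule), replicate jitter ±20 bp, 2 ATAC / 4
ChIP replicates and 2 methylation tools, ~3% of H3K27ac peaks placed outside
accessible chromatin (so derived ARE retention sits near 0.97, in the
"well over 90%" regime), and background peak sets for every assay so
consensus and randomization run against non-ARE structure.

Generation details that make ground truth exact:

- **Collision-free placement.** Every anchor feature is placed by batched
  rejection sampling with a padding margin wider than twice the replicate
  jitter, so no two features ever overlap or merge across replicates; a
  request whose padded footprint exceeds ~50% of the genome, or any peak
  that cannot be placed within 1000 proposal rounds, raises a config error
  rather than silently degrading.
- **Exact apportionment.** Establishment stages, chromatin states (stratified
  within establishment stage) and per-stage methylation flags are assigned by
  largest-remainder apportionment, so planted aggregate fractions are exact
  to ±1 count, and the only error the recovery tests can see is placement
  failure — which the generator excludes by construction.
- **Nesting.** A peak established at stage *s* is present at all later
  stages of its lineage (`nested = TRUE`); shared AREs are present in both
  branches. A non-nested switch plants presence only at the establishment
  stage, to stress the earliest-stage rule under loss of accessibility.
- **Determinism.** The whole bundle is a function of `seed`; reruns are
  byte-identical.

What the generator does **not** emulate — and what passing tests therefore do
not show about real data: peaks in real data overlap, split and drift between
replicates far more than a ±20 bp jitter; establishment is confounded by
peak-calling sensitivity differences between stages; genome sequence,
mappability and masked regions are absent, so the randomization null is
cleaner than a real genome's; expression is independent across genes; and
TSS density is uniform rather than clustered into gene-rich regions.
Recovery tests validate the interval logic and bookkeeping, not the
biological robustness of the thresholds.

# Numerical and degenerate-input choices

- Merging treats abutting intervals ([0,10) + [10,20)) as one region.
- Unsorted BED input is sorted with a warning, not rejected; per-line parse
  errors name the offending line; chromosome-block order in files is not
  policed (only interleaving or within-chromosome disorder warns).
- `derive_ares` on an empty H3K27ac set returns an empty set and a flagged
  `NA` fraction; `methylation_overlap_fraction` on an empty ARE set likewise.
- Empirical p-values never reach 0 (add-one correction); under the null they
  are approximately uniform, which the acceptance suite checks over 200
  simulated tests.
- Permutation reproducibility is bit-exact under `set.seed()`; the pipeline
  derives one sub-seed per test from `permutation$seed` so report files are
  byte-identical across reruns.

# Problem sizes used by the test suite

The shipped tests run a 4 × 3 Mb cohort with 480 AREs for end-to-end
pipeline checks, a 10 × 20 Mb cohort with 7000 AREs (5000 in the
megakaryocyte-like class) for parameter recovery, 200 × 500-iteration
permutation tests for null calibration, and ≤ 100 kb toy chromosomes for the
brute-force oracle comparisons — sizes chosen so the whole suite exercises
every code path at full fidelity while staying comfortably interactive.

# Known limitations

- Exactly two terminal cell types are supported by the specificity partition
  and the pipeline driver; the per-module functions are n-ary where
  meaningful.
- Strand is carried but ignored: peaks are unstranded, and TSS distance is
  measured to the annotated position regardless of gene orientation.
- The establishment rule is presence/absence at ≥ 1 bp; it does not model
  quantitative accessibility, so a weak but called peak counts as present.
- The permutation null preserves chromosome and width only; it does not
  condition on GC, mappability or distance-to-TSS structure.
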