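# Expressed-set thresholding, maintenance chains, Venn accounting,
# half-up percentages and the pooled two-proportion z-test.

make_expr <- function(tpm_by_cell) {
  m <- do.call(cbind, tpm_by_cell)
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  m
}

test_that("expressed_set includes the TPM threshold boundary", {
  m <- make_expr(list(A = c(1.0, 0.99, 0, 5), B = c(0, 0, 0, 0)))
  expect_setequal(expressed_set(m, "A"), c("g01", "g04"))
  expect_length(expressed_set(m, "B"), 0)
  expect_error(expressed_set(m, "Z"), "unknown cell")
  # threshold monotonicity: higher threshold => subset
  expect_true(all(expressed_set(m, "A", 2) %in% expressed_set(m, "A", 1)))
  expect_length(expressed_set(m, "B", 0), 4)  # threshold 0 returns all genes
})

test_that("maintenance_chain is the cumulative intersection and is non-increasing", {
  m <- make_expr(list(S1 = c(2, 2, 2, 0), S2 = c(0, 2, 2, 2)))
  expect_equal(unname(maintenance_chain(m, c("S1", "S2"))), c(3L, 2L))
  expect_equal(unname(maintenance_chain(m, c("S1", "S1"))), c(3L, 3L))
  expect_error(maintenance_chain(m, c("S1", "SX")), "missing")

  # synthetic matrix with known per-stage retention vs direct enumeration
  set.seed(61)
  n <- 2000
  stages <- c("P0", "P1", "P2", "P3")
  on <- matrix(FALSE, n, 4, dimnames = list(sprintf("g%04d", 1:n), stages))
  on[, 1] <- runif(n) < 0.7
  for (k in 2:4) on[, k] <- on[, k - 1] & runif(n) < 0.85
  tpm <- ifelse(on, 2, 0.5)
  chain <- maintenance_chain(tpm, stages)
  oracle <- vapply(1:4, function(k) {
    sets <- lapply(1:k, function(j) rownames(tpm)[tpm[, j] >= 1])
    length(Reduce(intersect, sets))
  }, integer(1))
  expect_equal(unname(chain), oracle)
  expect_true(all(diff(chain) <= 0))
})

test_that("rounded_percent rounds half-up at both precisions", {
  expect_equal(rounded_percent(8239, 13066), 63)
  expect_equal(rounded_percent(789, 6386, 1), 12.4)
  expect_equal(rounded_percent(1527, 1853), 82)
  expect_equal(rounded_percent(0, 10), 0)
  expect_equal(rounded_percent(25, 200), 13)      # 12.5 -> 13, not banker's 12
  expect_equal(rounded_percent(1, 800, 1), 0.1)   # 0.125 -> 0.1
  expect_error(rounded_percent(1, 0), "positive")
})

test_that("exclusive_overlap tallies the seven Venn regions", {
  s <- list(A = letters[1:5], B = letters[1:5], C = letters[1:5])
  v <- exclusive_overlap(s)
  expect_equal(unname(v["A&B&C"]), 5)
  expect_equal(sum(v), 5)

  s2 <- list(A = letters[1:3], B = letters[4:6], C = letters[7:9])
  v2 <- exclusive_overlap(s2)
  expect_equal(unname(v2[c("A_only", "B_only", "C_only")]), c(3, 3, 3))
  expect_equal(sum(v2), 9)

  set.seed(71)
  for (rep in 1:10) {
    s3 <- list(A = sample(letters, sample(5:20, 1)),
               B = sample(letters, sample(5:20, 1)),
               C = sample(letters, sample(5:20, 1)))
    v3 <- exclusive_overlap(s3)
    u <- unique(unlist(s3))
    # membership oracle: classify every element of the union
    key <- table(factor(paste0(
      as.integer(u %in% s3$A), as.integer(u %in% s3$B), as.integer(u %in% s3$C)),
      levels = c("100", "010", "001", "110", "101", "011", "111")))
    expect_equal(unname(v3), as.vector(key))
    expect_equal(sum(v3), length(u))
  }
})

test_that("two_proportion_test matches symmetry, the large-count significance call, and a Monte-Carlo null", {
  eq <- two_proportion_test(30, 100, 60, 200)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  big <- two_proportion_test(8239, 13066, 10522, 13066)
  expect_lt(big$p, 0.001)

  expect_error(two_proportion_test(5, 0, 1, 10), "positive")
  expect_error(two_proportion_test(11, 10, 1, 10), "0 <= k <= n")

  # Monte-Carlo oracle under the pooled null for small counts; at n = 10 the
  # discrete null (exact tail 0.1153) sits ~0.04 above the normal
  # approximation (0.0736), so the agreement bound is 0.05 here
  res <- two_proportion_test(3, 10, 7, 10)
  set.seed(81)
  B <- 200000
  k1 <- rbinom(B, 10, 0.5)
  k2 <- rbinom(B, 10, 0.5)
  mc_p <- mean(abs(k1 / 10 - k2 / 10) >= abs(3 / 10 - 7 / 10))
  expect_lt(abs(res$p - mc_p), 0.05)

  # at moderate counts the z-test matches the Monte-Carlo null tightly
  res2 <- two_proportion_test(30, 100, 45, 100)
  p_pool <- 75 / 200
  k1 <- rbinom(B, 100, p_pool)
  k2 <- rbinom(B, 100, p_pool)
  mc_p2 <- mean(abs(k1 / 100 - k2 / 100) >= abs(30 / 100 - 45 / 100))
  expect_lt(abs(res2$p - mc_p2), 0.02)
})
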