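test_that("Pearson chi-squared reproduces the published table statistics", {
  expect_equal(unname(pearson_chi2(rbind(c(1237, 375),
                                         c(528, 106)))$statistic),
               11.578, tolerance = 0.0005)
  expect_equal(unname(pearson_chi2(rbind(c(623, 11),
                                         c(1237, 375)))$statistic),
               148.174, tolerance = 0.0005)
  expect_equal(unname(pearson_chi2(cow_printed_table("T6"))$statistic),
               51.117, tolerance = 0.0005)
  expect_equal(unname(pearson_chi2(cow_printed_table("S34"))$statistic),
               14.165, tolerance = 0.0005)
  r <- pearson_chi2(matrix(10, 2, 2))
  expect_equal(unname(r$statistic), 0.0)
  expect_equal(r$p.value, 1.0)
})

test_that("chi-squared expected counts carry the observed margins", {
  m <- random_table(3, 4)
  r <- pearson_chi2(m)
  expect_equal(rowSums(r$expected), rowSums(m))
  expect_equal(colSums(r$expected), colSums(m))
  expect_equal(unname(r$parameter), 6)
  expect_error(pearson_chi2(rbind(c(0, 0), c(3, 4))), "empty margin")
})

test_that("chi-squared agrees with the reference implementation on random tables", {
  set.seed(42)
  for (i in 1:25) {
    m <- random_table(sample(2:6, 1), sample(2:11, 1))
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    r <- pearson_chi2(m)
    expect_equal(unname(r$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(r$p.value, ref$p.value, tolerance = 1e-12)
    # brute-force double loop over cells
    rs <- rowSums(m); cs <- colSums(m); N <- sum(m); acc <- 0
    for (a in seq_len(nrow(m))) for (b in seq_len(ncol(m))) {
      e <- rs[a] * cs[b] / N
      acc <- acc + (m[a, b] - e)^2 / e
    }
    expect_equal(unname(r$statistic), unname(acc), tolerance = 1e-12)
  }
})

test_that("chi-squared is invariant under row and column permutation", {
  set.seed(7)
  m <- random_table(4, 5)
  s0 <- unname(pearson_chi2(m)$statistic)
  expect_equal(unname(pearson_chi2(m[sample(4), sample(5)])$statistic), s0)
})

test_that("linear-by-linear trend reproduces the published values", {
  expect_equal(unname(linear_by_linear(cow_printed_table("T6"))$statistic),
               13.340, tolerance = 0.0005)
  s34 <- rbind(c(295, 1317), c(70, 263), c(41, 165), c(32, 63))
  r <- linear_by_linear(s34, row_scores = 1:4, col_scores = c(0, 1))
  expect_equal(unname(r$statistic), 9.188, tolerance = 0.005)
  expect_equal(unname(r$parameter), 1)
  expect_lt(r$p.value, 0.0025)
})

test_that("trend statistic matches the expansion-correlation oracle", {
  set.seed(13)
  for (i in 1:10) {
    m <- random_table(sample(2:5, 1), sample(2:6, 1), lambda = 8)
    rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m)) - 1
    # independent oracle: expand to observations and correlate the scores
    u <- rep(rep(rs, times = ncol(m)), as.vector(m))
    v <- rep(rep(cs, each = nrow(m)), as.vector(m))
    expect_equal(unname(linear_by_linear(m, rs, cs)$statistic),
                 (sum(m) - 1) * stats::cor(u, v)^2, tolerance = 1e-12)
  }
})

test_that("on 2x2 tables the trend equals chi-squared scaled by (N-1)/N", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_table(2, 2)
    N <- sum(m)
    expect_equal(unname(linear_by_linear(m)$statistic),
                 unname(pearson_chi2(m)$statistic) * (N - 1) / N,
                 tolerance = 1e-12)
  }
})

test_that("trend is invariant under affine rescaling of scores", {
  m <- cow_printed_table("T6")
  s0 <- unname(linear_by_linear(m)$statistic)
  expect_equal(unname(linear_by_linear(m, row_scores = 3 * (1:4) - 7,
                                       col_scores = 10 * (0:4) + 2)$statistic),
               s0, tolerance = 1e-12)
})

test_that("degenerate scores are rejected", {
  m <- rbind(c(5, 7), c(3, 2))
  expect_error(linear_by_linear(m, row_scores = c(1, 1)), "degenerate")
  # a single nonzero row leaves no row-score variation
  expect_error(linear_by_linear(rbind(c(5, 7), c(0, 0))), "degenerate|empty")
})

test_that("tie-corrected rank-sum reproduces the published A1 side comparison", {
  r <- ranksum_ordered(c(2041, 135, 56, 14), c(1817, 198, 150, 81))
  expect_equal(unname(r$statistic), 9.944, tolerance = 0.0005)
  expect_equal(unname(r$estimate), c(2130.10, 2362.90), tolerance = 1e-5)
  expect_lt(r$p.value, 0.0005)
})

test_that("P1 side comparison matches the reference normal approximation", {
  # frozen from the tie-corrected oracle; see the packaged discrepancies
  # table for why this differs from the published 2.576
  r <- ranksum_ordered(c(2073, 71, 102), c(2025, 106, 115))
  expect_equal(unname(r$statistic), 2.466776, tolerance = 1e-6)
  x <- rep(1:3, c(2073, 71, 102)); y <- rep(1:3, c(2025, 106, 115))
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))
  expect_equal(r$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("rank-sum symmetry and degenerate cases", {
  r <- ranksum_ordered(c(10, 5, 2), c(10, 5, 2))
  expect_equal(unname(r$statistic), 0)
  expect_equal(unname(r$estimate[1]), unname(r$estimate[2]))
  # all observations in one category: zero variance, Z = 0
  expect_equal(unname(ranksum_ordered(c(8, 0), c(5, 0))$statistic), 0)
  expect_error(ranksum_ordered(c(0, 0), c(1, 2)), "empty group")
})

test_that("group mean ranks average to (N + 1) / 2", {
  set.seed(31)
  for (i in 1:10) {
    g1 <- stats::rpois(5, 6); g2 <- stats::rpois(5, 6)
    if (sum(g1) == 0 || sum(g2) == 0) next
    r <- ranksum_ordered(g1, g2)
    N <- sum(g1) + sum(g2)
    expect_equal((sum(g1) * r$estimate[[1]] + sum(g2) * r$estimate[[2]]) / N,
                 (N + 1) / 2, tolerance = 1e-12)
  }
  # the published A1 table: (2130.10 + 2362.90) / 2 = 2246.5
  r <- ranksum_ordered(c(2041, 135, 56, 14), c(1817, 198, 150, 81))
  expect_equal(mean(r$estimate), 2246.5, tolerance = 1e-9)
})

test_that("rank-sum agrees with wilcox.test across random ordered data", {
  set.seed(77)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    g1 <- stats::rpois(k, 10) + c(1, rep(0, k - 1))
    g2 <- stats::rpois(k, 10) + c(1, rep(0, k - 1))
    r <- ranksum_ordered(g1, g2)
    x <- rep(seq_len(k), g1); y <- rep(seq_len(k), g2)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
    expect_equal(r$p.value, ref$p.value, tolerance = 1e-9)
  }
})
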