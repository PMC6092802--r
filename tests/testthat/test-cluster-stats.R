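# per-cluster Above/Below counts for the MCM5-shaped example used
# throughout: clusters (9/6, 16/7, 11/11, 4/16)
mcm5_counts <- data.frame(cluster = 1:4,
                          above = c(9, 16, 11, 4),
                          below = c(6, 7, 11, 16))

test_that("pooling sums per-cluster counts under the chosen partition", {
  tab <- pool_contingency(mcm5_counts)
  expect_equal(unclass(tab)[1:4], c(25L, 15L, 13L, 27L))  # column-major

  tab2 <- pool_contingency(mcm5_counts, grouping = list(1, 2:4))
  expect_equal(unclass(tab2)[1:4], c(9L, 31L, 6L, 34L))

  zero <- data.frame(cluster = 1:4, above = 0, below = 0)
  expect_error(pool_contingency(zero), "empty")
  expect_error(pool_contingency(mcm5_counts[-2, ]), "missing: 2")
})

test_that("two-tailed Fisher matches enumeration, conventions and fixtures", {
  # full hypergeometric enumeration for [[2,1],[1,2]]: probabilities
  # 0.05/0.45/0.45/0.05 are all <= the observed 0.45, so p = 1
  expect_equal(fisher_exact_two_tailed(contingency_table(2, 1, 1, 2))$p_value,
               1.0)

  p_mcm5 <- fisher_exact_two_tailed(contingency_table(25, 13, 15, 27))$p_value
  expect_equal(round(p_mcm5, 4), 0.0133)

  deg <- fisher_exact_two_tailed(contingency_table(0, 5, 0, 7))
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
})

test_that("Fisher p is invariant under transposition and row/column swap", {
  set.seed(8)
  for (i in 1:50) {
    x <- as.integer(rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    p <- fisher_exact_two_tailed(contingency_table(x[1], x[2], x[3], x[4]))$p_value
    pt <- fisher_exact_two_tailed(contingency_table(x[1], x[3], x[2], x[4]))$p_value
    ps <- fisher_exact_two_tailed(contingency_table(x[4], x[3], x[2], x[1]))$p_value
    expect_equal(pt, p, tolerance = 1e-12)
    expect_equal(ps, p, tolerance = 1e-12)
  }
})

test_that("for fixed margins the modal table has the largest two-tailed p", {
  for (margins in list(c(8, 6, 7), c(10, 10, 5), c(12, 4, 9))) {
    r1 <- margins[1]; r2 <- margins[2]; c1 <- margins[3]
    ks <- max(0, c1 - r2):min(r1, c1)
    probs <- dhyper(ks, r1, r2, c1)
    ps <- vapply(ks, function(a)
      fisher_exact_two_tailed(
        contingency_table(a, r1 - a, c1 - a, r2 - c1 + a))$p_value,
      numeric(1))
    expect_equal(which.max(ps), which.max(probs))
    expect_equal(max(ps), 1)
  }
})

test_that("Pearson chi-square uses no continuity correction", {
  res <- pearson_chisq(contingency_table(0, 22, 4, 18))
  expect_equal(res$statistic, 4.4)
  expect_equal(round(res$p_value, 4), 0.0359)
  expect_equal(res$df, 1L)

  indep <- pearson_chisq(contingency_table(10, 10, 10, 10))
  expect_equal(indep$statistic, 0)
  expect_equal(indep$p_value, 1)

  expect_error(pearson_chisq(contingency_table(0, 0, 4, 18)), "[Ff]isher")

  set.seed(4)
  for (i in 1:30) {
    x <- as.integer(rmultinom(1, sample(8:60, 1), rep(0.25, 4))) + 1L
    tab <- contingency_table(x[1], x[2], x[3], x[4])
    mine <- pearson_chisq(tab)
    ref <- suppressWarnings(
      chisq.test(matrix(x, 2, byrow = TRUE), correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
    # transposition invariance
    tr <- pearson_chisq(contingency_table(x[1], x[3], x[2], x[4]))
    expect_equal(tr$statistic, mine$statistic, tolerance = 1e-12)
  }
})

test_that("summary rows format counts, half-up percentages and totals", {
  mcm2 <- data.frame(cluster = 1:4, above = c(12, 20, 3, 5),
                     below = c(3, 3, 19, 15))
  row <- gene_summary_row("MCM2", mcm2, c(15, 23, 22, 20),
                          fisher_p = 1e-5, logrank_p = 0.0001,
                          worse_group = "Below")
  expect_equal(row$cluster1, "12/3 (80/20)")
  expect_equal(row$total_above, 40)
  expect_equal(row$total_below, 40)
  expect_equal(row$worse_survival, "Below")

  # 7/15 of 22 -> 31.8/68.2 rounds half-up to 32/68
  mcm3 <- data.frame(cluster = 1:4, above = c(7, 10, 7, 12),
                     below = c(8, 13, 15, 8))
  r3 <- gene_summary_row("MCM3", mcm3, c(15, 23, 22, 20), 1)
  expect_equal(r3$cluster3, "7/15 (32/68)")

  # 10/22 -> 45.45/54.55 rounds to 45/55 (exact halves go up)
  msh6 <- data.frame(cluster = 1:4, above = c(4, 13, 10, 16),
                     below = c(11, 10, 12, 4))
  r6 <- gene_summary_row("MSH6", msh6, c(15, 23, 22, 20), 1)
  expect_equal(r6$cluster3, "10/12 (45/55)")

  # non-significant log-rank blanks the worse-survival call
  ns <- gene_summary_row("MCM2", mcm2, c(15, 23, 22, 20), 1,
                         logrank_p = 0.3, worse_group = "Below")
  expect_true(is.na(ns$worse_survival))

  expect_error(gene_summary_row("MCM2", mcm2, c(15, 23, 22, 21), 1),
               "inconsistent")
})
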