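test_that("log2 transform handles the pseudocount and preserves order", {
  expect_equal(log2_transform(0, 1), 0)
  expect_equal(log2_transform(7, 1), 3)
  expect_error(log2_transform(-0.1), "non-negative")
  expect_error(log2_transform(1, 0), "positive")

  set.seed(5)
  x <- runif(1000, 0, 1e4)
  y <- runif(1000, 0, 1e4)
  expect_true(all(sign(log2_transform(x, 0.5) - log2_transform(y, 0.5)) ==
                  sign(x - y)))
})

test_that("cohort-referenced Z-scores standardize every non-degenerate row", {
  ex <- make_gene_exons("G", n_exons = 3)
  keys <- format_exon_key(ex$chromosome, ex$start, ex$stop, ex$strand)
  # log2 rows: constant; (0,1,2) hand case; random
  l <- rbind(c(1, 1, 1), c(0, 1, 2), c(0.3, 2.5, 1.1))
  dimnames(l) <- list(keys, c("S1", "S2", "S3"))
  em <- expr_matrix(2^l - 1 + 1e-12)  # log2(x + 1) recovers l up to eps
  zm <- relative_zscores(em, pseudocount = 1)
  expect_equal(unname(zm$z[1, ]), c(0, 0, 0))
  expect_equal(unname(zm$z[2, ]), c(-1, 0, 1), tolerance = 1e-9)

  expect_error(relative_zscores(expr_matrix(l[, 1, drop = FALSE] + 2)),
               "at least 2 cases")

  b <- generate_cohort(synthetic_config(seed = 3))
  zc <- relative_zscores(subset_cohort(b$expression, b$meta))
  nondeg <- zc$scale > 0
  expect_true(all(abs(rowMeans(zc$z[nondeg, ])) < 1e-9))
  expect_true(all(abs(apply(zc$z[nondeg, ], 1, sd) - 1) < 1e-9))
})

test_that("Z-scores are invariant to column permutation and per-row scaling", {
  ex <- make_gene_exons("G", n_exons = 6)
  em <- make_expr(ex, sprintf("S%d", 1:10), seed = 9)
  zm <- relative_zscores(em)

  set.seed(1)
  perm <- sample(10)
  zp <- relative_zscores(expr_matrix(em$values[, perm]))
  expect_equal(zp$z, zm$z[, perm])

  # multiplying one exon's RPKM by a constant is a location shift in log2,
  # hence invisible after standardization; the pseudocount must be
  # negligible relative to the abundances for the identity to be exact
  v <- em$values
  z1 <- relative_zscores(expr_matrix(v), pseudocount = 1e-12)
  v[2, ] <- v[2, ] * 8
  z2 <- relative_zscores(expr_matrix(v), pseudocount = 1e-12)
  expect_equal(z2$z[2, ], z1$z[2, ], tolerance = 1e-9)
})

test_that("diploid-referenced Z-scores shift monosomic cases Below", {
  arms <- c(GENE3 = "3q")
  # noisy gene (exon SD 2) so the -1 monosomy shift does not saturate the
  # classification under either reference; the cohort mean sits below the
  # diploid mean, so the diploid reference pushes more monosomic cases
  # Below, on average over seeds
  extra <- vapply(21:25, function(s) {
    b <- generate_cohort(one_gene_config("GENE3", arm = "3q",
                                         chromosome = "chr3",
                                         exon_sd = 2, seed = s))
    em <- subset_cohort(b$expression, b$meta)
    pr <- gene_average_z(relative_zscores(em), b$exons, "GENE3")
    pd <- gene_average_z(differential_zscores(em, b$meta, b$exons, arms),
                         b$exons, "GENE3")
    mono <- b$meta$cluster %in% c(3, 4)
    sum(dichotomize(pd)[mono] == "Below") -
      sum(dichotomize(pr)[mono] == "Below")
  }, numeric(1))
  expect_gt(mean(extra), 0)

  b <- generate_cohort(one_gene_config("GENE3", arm = "3q",
                                       chromosome = "chr3", seed = 21))
  em <- subset_cohort(b$expression, b$meta)

  # with every case diploid the two references coincide exactly
  cfg0 <- one_gene_config("GENE3", arm = "3q", chromosome = "chr3",
                          seed = 21,
                          cn_by_cluster = rep(list(character(0)), 4))
  b0 <- generate_cohort(cfg0)
  em0 <- subset_cohort(b0$expression, b0$meta)
  z0d <- differential_zscores(em0, b0$meta, b0$exons, arms)
  z0r <- relative_zscores(em0)
  expect_equal(z0d$z, z0r$z)

  # fewer than 2 diploid reference cases is an error naming the gene
  all_loss <- case_meta(as.data.frame(b$meta)[, c("case_id", "cluster")],
                        copy_number = rep(list(c(`3q` = "loss")), 80))
  expect_error(differential_zscores(em, all_loss, b$exons, arms),
               "GENE3.*diploid")
})

test_that("gene averaging and dichotomization follow the strict-zero rule", {
  ex <- make_gene_exons("G", n_exons = 2)
  keys <- format_exon_key(ex$chromosome, ex$start, ex$stop, ex$strand)
  z <- matrix(c(1, -1, 0.5, 0.5, -2, 1), 2,
              dimnames = list(keys, c("S1", "S2", "S3")))
  zm <- structure(list(z = z, reference_label = "cohort_average",
                       center = c(0, 0), scale = c(1, 1), pseudocount = 1),
                  class = "zscore_matrix")
  prof <- gene_average_z(zm, ex, "G")
  expect_equal(prof$average_z, c(0, 0.5, -0.5))
  expect_equal(prof$group, c("Below", "Above", "Below"))
  expect_equal(prof$n_exons_used, rep(2L, 3))

  g <- dichotomize(prof)
  expect_equal(unname(g["S1"]), "Below")  # exact zero tie goes Below
  expect_equal(sum(g == "Above") + sum(g == "Below"), 3L)

  one <- ex[1, , drop = FALSE]
  attr(one, "genome_build") <- "hg19"
  class(one) <- c("exon_table", "data.frame")
  p1 <- gene_average_z(zm, one, "G")
  expect_equal(p1$average_z, unname(z[1, ]))

  expect_error(gene_average_z(zm, ex, "MISSING"), "no exon rows")
})

test_that("gene average equals a brute-force exon mean on a 16-exon gene", {
  ex <- make_gene_exons("MCM2", chrom = "chr3", n_exons = 16)
  em <- make_expr(ex, sprintf("S%02d", 1:20), seed = 13)
  zm <- relative_zscores(em)
  prof <- gene_average_z(zm, ex, "MCM2")
  brute <- apply(zm$z, 2, mean)  # all rows belong to the gene
  expect_equal(prof$average_z, unname(brute), tolerance = 1e-12)
})

test_that("heatmap matrices are cluster-ordered and tri-level binned", {
  cfg <- one_gene_config("GENE8", arm = "8q", chromosome = "chr8", seed = 5)
  b <- generate_cohort(cfg)
  zm <- relative_zscores(subset_cohort(b$expression, b$meta))
  hm <- heatmap_matrix(zm, b$exons, "GENE8", b$meta)
  expect_identical(colnames(hm$z),
                   b$meta$case_id[order(b$meta$cluster)])
  expect_true(all(hm$bins %in% c("high", "low", "no_change")))
  # only cluster 4 carries the 8q gain: its columns skew high
  frac_high_c4 <- mean(hm$bins[, hm$clusters == 4] == "high")
  frac_high_c12 <- mean(hm$bins[, hm$clusters %in% c(1, 2)] == "high")
  expect_gt(frac_high_c4, frac_high_c12)

  zm$z[] <- 0
  hm0 <- heatmap_matrix(zm, b$exons, "GENE8", b$meta)
  expect_true(all(hm0$bins == "no_change"))

  expect_error(heatmap_matrix(zm, b$exons, "NOPE", b$meta), "unknown gene")
})
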