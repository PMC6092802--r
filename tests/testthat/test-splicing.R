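# 16-exon plus-strand gene; exon i spans [1e6 + (i-1)*1000, +149]
plus_exons <- make_gene_exons("CIZ1", chrom = "chr9", strand = "+",
                              n_exons = 16)
ex_stop <- function(ex, i) ex$stop[match(i, ex$exon_index)]
ex_start <- function(ex, i) ex$start[match(i, ex$exon_index)]

test_that("junction evidence calls skips above the coverage threshold", {
  j <- junction_records(
    case_id = c("c1", "c2", "c3", "c4"),
    chromosome = "chr9",
    donor_end = c(ex_stop(plus_exons, 3), ex_stop(plus_exons, 3),
                  ex_stop(plus_exons, 3), ex_stop(plus_exons, 4)),
    acceptor_start = c(ex_start(plus_exons, 5), ex_start(plus_exons, 5),
                       ex_start(plus_exons, 4), ex_start(plus_exons, 8)),
    read_count = c(5, 3, 100, 6))
  ev <- detect_exon_skipping(j, plus_exons, min_coverage = 4)
  expect_equal(nrow(ev), 2L)
  # exon3 -> exon5 with 5 reads: exon 4 skipped
  expect_equal(ev$skipped_exons[ev$case_id == "c1"], "4")
  expect_equal(ev$supporting_reads[ev$case_id == "c1"], 5L)
  # same junction at 3 reads (c2) is below the screening threshold
  expect_false("c2" %in% ev$case_id)
  # canonical exon3 -> exon4 splice (c3) is not a skip at any coverage
  expect_false("c3" %in% ev$case_id)
  # exon4 -> exon8: multi-exon skip
  expect_equal(ev$skipped_exons[ev$case_id == "c4"], "5,6,7")
  expect_equal(ev$flank_upstream[ev$case_id == "c4"], 4L)
  expect_equal(ev$flank_downstream[ev$case_id == "c4"], 8L)
})

test_that("skipped exons are reported in transcript order on minus strands", {
  neg <- make_gene_exons("MLH3", chrom = "chr14", strand = "-", n_exons = 9)
  # transcript exon 1 is the genomically last exon; a skip of transcript
  # exon 5 joins transcript exons 4 and 6, i.e. genomic exon 6 -> exon 4
  j <- junction_records("c1", "chr14",
                        donor_end = ex_stop(neg, 6),
                        acceptor_start = ex_start(neg, 4),
                        read_count = 10)
  ev <- detect_exon_skipping(j, neg, min_coverage = 4)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$skipped_exons, "5")
  expect_equal(ev$flank_upstream, 4L)
  expect_equal(ev$flank_downstream, 6L)

  # a junction running against transcript direction matches nothing
  j_bad <- junction_records("c1", "chr14",
                            donor_end = ex_stop(neg, 4),
                            acceptor_start = ex_start(neg, 4) + 5000L,
                            read_count = 10)
  ev_bad <- detect_exon_skipping(j_bad, neg, min_coverage = 4)
  expect_equal(nrow(ev_bad), 0L)
  expect_equal(attr(ev_bad, "unmatched"), 1L)
})

test_that("detection is order-independent and anti-monotone in threshold", {
  set.seed(2)
  j <- junction_records(
    case_id = sprintf("c%d", 1:12),
    chromosome = "chr9",
    donor_end = ex_stop(plus_exons, sample(1:6, 12, replace = TRUE)),
    acceptor_start = ex_start(plus_exons,
                              sample(8:14, 12, replace = TRUE)),
    read_count = sample(1:10, 12, replace = TRUE))
  ev1 <- detect_exon_skipping(j, plus_exons, min_coverage = 4)
  ev2 <- detect_exon_skipping(j[sample(nrow(j)), ], plus_exons,
                              min_coverage = 4)
  expect_identical(as.data.frame(ev1), as.data.frame(ev2))

  sizes <- vapply(1:10, function(th)
    nrow(detect_exon_skipping(j, plus_exons, min_coverage = th)),
    integer(1))
  expect_true(all(diff(sizes) <= 0))
  for (th in c(2, 5, 8)) {
    ev <- detect_exon_skipping(j, plus_exons, min_coverage = th)
    expect_true(all(ev$supporting_reads >= th))
  }
})

test_that("co-occurring skips per case are reported with phase unknown", {
  j <- junction_records(
    case_id = c("c1", "c1"), chromosome = "chr9",
    donor_end = c(ex_stop(plus_exons, 4), ex_stop(plus_exons, 6)),
    acceptor_start = c(ex_start(plus_exons, 6), ex_start(plus_exons, 8)),
    read_count = c(9, 8))
  ev <- detect_exon_skipping(j, plus_exons)
  co <- attr(ev, "cooccurring")
  expect_equal(nrow(co), 1L)
  expect_equal(co$n_events, 2L)
  expect_equal(co$phase, "unknown")
})

test_that("junction serialization round-trips through TSV and intron BED", {
  j <- junction_records(c("c1", "c2"), c("chr9", "chr9"),
                        donor_end = c(1000L, 2500L),
                        acceptor_start = c(2001L, 4001L),
                        read_count = c(7L, 12L))
  f <- tempfile()
  write_junctions(j, f, format = "tsv")
  expect_identical(as.data.frame(read_junctions(f, "tsv")),
                   as.data.frame(j))
  write_junctions(j, f, format = "bed")
  expect_identical(as.data.frame(read_junctions(f, "bed")),
                   as.data.frame(j))

  expect_error(junction_records("c", "chr1", 10, 10, 5), "donor_end")
  expect_error(junction_records("c", "chr1", 10, 20, -1), "non-negative")
})
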