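# Fixture builders shared across the suite. Everything is generated in
# code; files go to tempdir().

# 16-exon single-gene table, + or - strand, ~150 bp exons 1 kb apart
make_gene_exons <- function(gene = "CIZ1", chrom = "chr9", strand = "+",
                            n_exons = 16, origin = 1e6) {
  starts <- origin + (seq_len(n_exons) - 1L) * 1000L
  exon_table(data.frame(
    gene = gene, chromosome = chrom, start = as.integer(starts),
    stop = as.integer(starts + 149L), strand = strand,
    stringsAsFactors = FALSE))
}

# expression matrix over the exons of a table, log2 values supplied or drawn
make_expr <- function(exons, cases, log2_values = NULL, seed = 1) {
  keys <- format_exon_key(exons$chromosome, exons$start, exons$stop,
                          exons$strand)
  if (is.null(log2_values)) {
    set.seed(seed)
    log2_values <- matrix(rnorm(length(keys) * length(cases), 5, 1),
                          length(keys), length(cases))
  }
  v <- 2^log2_values
  dimnames(v) <- list(keys, cases)
  expr_matrix(v)
}

make_meta <- function(n = 12, clusters = rep(1:4, each = n / 4),
                      cn = NULL) {
  ids <- sprintf("CASE-%03d", seq_len(n))
  if (is.null(cn)) cn <- rep(list(character(0)), n)
  case_meta(data.frame(case_id = ids, cluster = clusters,
                       stringsAsFactors = FALSE), copy_number = cn)
}

# tiny single-gene synthetic config; cn/effects as in the default cohort
one_gene_config <- function(symbol = "GENE1", arm = "19q",
                            chromosome = "chr19", strand = "+",
                            n_exons = 10, exon_sd = 0.5, seed = 1,
                            hazards = c(2e-4, 2e-4, 2e-4, 2e-4),
                            cn_by_cluster = NULL) {
  if (is.null(cn_by_cluster))
    cn_by_cluster <- list(character(0), character(0),
                          c(`3p` = "loss", `3q` = "loss"),
                          c(`3p` = "loss", `3q` = "loss", `8q` = "gain"))
  synthetic_config(
    genes = data.frame(symbol = symbol, arm = arm, chromosome = chromosome,
                       strand = strand, n_exons = as.integer(n_exons),
                       baseline_log2 = 5, exon_sd = exon_sd,
                       stringsAsFactors = FALSE),
    effects = data.frame(gene = character(0),
                         clusters = I(list()), log2fc = numeric(0)),
    cn_by_cluster = cn_by_cluster,
    hazards = hazards,
    skip_spec = data.frame(gene = character(0), exon = integer(0),
                           fraction = numeric(0), min_reads = integer(0),
                           max_reads = integer(0)),
    seed = seed)
}

# naive product-limit estimate at each event time (independent oracle)
naive_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_at_risk)
    out[i] <- s
  }
  list(times = ts, surv = out)
}

# hand Mantel-Cox tabulation over pooled event times (independent oracle)
naive_logrank_stat <- function(t1, e1, t2, e2) {
  time <- c(t1, t2); event <- c(e1, e2)
  g1 <- c(rep(TRUE, length(t1)), rep(FALSE, length(t2)))
  O1 <- 0; E1 <- 0; V <- 0
  for (ts in sort(unique(time[event == 1]))) {
    n <- sum(time >= ts); n1 <- sum(time >= ts & g1)
    d <- sum(time == ts & event == 1)
    d1 <- sum(time == ts & event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}
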