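#' Default gene panel for the synthetic cohort
#'
#' A compact panel shaped like the replication/repair genes the analysis
#' targets: chromosome-3 genes feel the monosomy-3 of clusters 3&4, an
#' 8q gene feels the cluster-4 gain, and genes elsewhere act as
#' copy-neutral or null controls. Exon counts follow the real transcripts
#' where the analysis cares (16 exons for MCM2, exon 4 of CIZ1, exons
#' 5 and 7 of MLH3).
#'
#' @return Data frame: `symbol`, `arm`, `chromosome`, `strand`, `n_exons`,
#'   `baseline_log2` (cohort-average log2 RPKM), `exon_sd` (log2 noise SD).
#' @export
default_gene_panel <- function() {
  data.frame(
    symbol   = c("MCM2", "BAP1", "ATRIP", "MCM4", "MCM5", "CIZ1", "PCNA",
                 "MLH3", "RPS19"),
    arm      = c("3q", "3p", "3p", "8q", "22q", "9q", "20p", "14q", "19q"),
    chromosome = c("chr3", "chr3", "chr3", "chr8", "chr22", "chr9", "chr20",
                   "chr14", "chr19"),
    strand   = c("+", "-", "-", "+", "+", "+", "+", "-", "+"),
    n_exons  = c(16L, 17L, 13L, 16L, 17L, 18L, 7L, 13L, 6L),
    baseline_log2 = c(5, 5, 4.5, 5, 5, 4, 6, 3.5, 7),
    exon_sd  = rep(0.5, 9),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic SCNA-subtyped cohort
#'
#' Defaults emulate the TCGA uveal-melanoma cohort structure: 80 tumors in
#' SCNA clusters of sizes 15/23/22/20; clusters 3 and 4 monosomic for
#' chromosome 3 (both arms, -1 in log2), cluster 4 additionally carrying a
#' single-copy 8q gain (+0.585 in log2, i.e. 3/2 dosage); log-normal exon
#' RPKM noise; exponential disease-specific survival with higher hazards
#' in the monosomy-3 clusters; and injected exon-skipping junctions (CIZ1
#' exon 4, MLH3 exons 5 and 7) over a coverage-4 detection threshold.
#'
#' @param cluster_sizes Four positive integers, default `c(15, 23, 22, 20)`.
#' @param genes Gene panel as in [default_gene_panel()].
#' @param effects Data frame `gene`, `clusters` (list column of integer
#'   vectors), `log2fc`: copy-number-independent transcriptional shifts.
#'   The default gives PCNA a +0.8 log2 increase in clusters 3&4 (the
#'   replisome up-regulation motif that occurs without SCNA).
#' @param cn_by_cluster List of 4 named character vectors mapping arm to
#'   `loss`/`gain` for every case of that cluster.
#' @param dosage_damping Fraction in \[0, 1\] by which the copy-number term
#'   is shrunk (0 = expression follows dosage fully; expression does not
#'   always simply track SCNA).
#' @param hazards Four positive per-day event hazards.
#' @param weibull_shape Shape of the event-time distribution (1 =
#'   exponential).
#' @param censor_horizon Censoring times drawn uniformly on
#'   `(0, censor_horizon)` days.
#' @param skip_spec Data frame `gene`, `exon`, `fraction` (of cases
#'   carrying the skip), `min_reads`, `max_reads`.
#' @param seed Integer RNG seed; the whole bundle is deterministic given it.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(cluster_sizes = c(15L, 23L, 22L, 20L),
                             genes = default_gene_panel(),
                             effects = data.frame(
                               gene = "PCNA",
                               clusters = I(list(c(3L, 4L))),
                               log2fc = 0.8,
                               stringsAsFactors = FALSE),
                             cn_by_cluster = list(
                               character(0),
                               character(0),
                               c(`3p` = "loss", `3q` = "loss"),
                               c(`3p` = "loss", `3q` = "loss",
                                 `8q` = "gain")),
                             dosage_damping = 0,
                             hazards = c(1.5e-4, 1.5e-4, 6e-4, 8e-4),
                             weibull_shape = 1,
                             censor_horizon = 3650,
                             skip_spec = data.frame(
                               gene = c("CIZ1", "MLH3", "MLH3"),
                               exon = c(4L, 5L, 7L),
                               fraction = c(0.5, 0.15, 0.15),
                               min_reads = c(4L, 4L, 4L),
                               max_reads = c(30L, 20L, 20L),
                               stringsAsFactors = FALSE),
                             seed = 1L) {
  if (length(cluster_sizes) != 4 || any(cluster_sizes < 1))
    stop("cluster_sizes must be four positive integers")
  if (!all(c("symbol", "arm", "chromosome", "strand", "n_exons",
             "baseline_log2", "exon_sd") %in% names(genes)))
    stop("gene panel lacks required columns")
  if (anyDuplicated(genes$symbol)) stop("duplicate gene symbols in panel")
  if (nrow(effects) && (!all(effects$gene %in% genes$symbol) ||
                        any(!is.finite(effects$log2fc))))
    stop("effects must target panel genes with finite log2 fold changes")
  if (length(cn_by_cluster) != 4)
    stop("cn_by_cluster must list states for the four clusters")
  if (any(hazards <= 0) || length(hazards) != 4)
    stop("hazards must be four positive rates")
  if (dosage_damping < 0 || dosage_damping > 1)
    stop("dosage_damping must lie in [0, 1]")
  if (nrow(skip_spec)) {
    ne <- genes$n_exons[match(skip_spec$gene, genes$symbol)]
    if (any(skip_spec$fraction < 0) || any(skip_spec$fraction > 1) ||
        any(skip_spec$min_reads < 0) ||
        any(is.na(ne)) || any(skip_spec$exon < 2) ||
        any(skip_spec$exon > ne - 1))
      stop("invalid skip_spec (skipped exons must be interior panel exons)")
  }
  structure(list(cluster_sizes = as.integer(cluster_sizes), genes = genes,
                 effects = effects, cn_by_cluster = cn_by_cluster,
                 dosage_damping = dosage_damping, hazards = hazards,
                 weibull_shape = weibull_shape,
                 censor_horizon = censor_horizon, skip_spec = skip_spec,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# deterministic exon coordinates: exons of ~150 bp spaced 1 kb apart,
# genes offset along their chromosome
synthetic_exon_table <- function(genes) {
  rec <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    starts <- 1e6 * i + (seq_len(g$n_exons) - 1L) * 1000L
    data.frame(gene = g$symbol, chromosome = g$chromosome,
               start = as.integer(starts),
               stop = as.integer(starts + 149L),
               strand = g$strand, stringsAsFactors = FALSE)
  })
  exon_table(do.call(rbind, rec))
}

#' Generate a complete synthetic cohort bundle
#'
#' Draws exon RPKM log-normally — `log2 RPKM = baseline + copy-number term
#' + effect term + Normal(0, exon_sd)` with -1 for a lost copy and +0.585
#' for a single-copy gain at the gene's arm — plus cluster-hazard survival
#' times with uniform censoring and skip-supporting junction reads, and
#' records every injected effect in a ground-truth ledger. Byte-identical
#' for a fixed config (the seed covers all randomness).
#'
#' @param config A [synthetic_config()].
#' @return List of class `uvm_cohort`: `exons` ([exon_table()]),
#'   `expression` ([expr_matrix()], full aliquot barcodes as columns),
#'   `meta` ([case_meta()]), `clinical` ([survival_records()]),
#'   `junctions` ([junction_records()]), `truth` (ledger: per-gene
#'   per-cluster total log2 shift, hazards, injected skips), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  sizes <- config$cluster_sizes
  n <- sum(sizes)
  cluster <- rep(1:4, times = sizes)
  case_id <- sprintf("TCGA-SY-%04d", seq_len(n))
  aliquot <- sprintf("%s-01A-11R-A10%d-07", case_id, cluster)
  meta <- case_meta(
    data.frame(case_id = case_id, cluster = cluster,
               stringsAsFactors = FALSE),
    copy_number = lapply(cluster, function(k) config$cn_by_cluster[[k]]))

  exons <- synthetic_exon_table(config$genes)
  genes <- config$genes

  # per-gene per-case log2 shift = damped copy-number dosage + effects
  shift <- matrix(0, nrow(genes), n,
                  dimnames = list(genes$symbol, case_id))
  for (i in seq_len(nrow(genes))) {
    st <- arm_state(meta, genes$arm[i])
    cn <- ifelse(st == "loss", -1, ifelse(st == "gain", log2(3 / 2), 0))
    shift[i, ] <- cn * (1 - config$dosage_damping)
  }
  if (nrow(config$effects)) for (j in seq_len(nrow(config$effects))) {
    e <- config$effects[j, ]
    shift[e$gene, cluster %in% e$clusters[[1]]] <-
      shift[e$gene, cluster %in% e$clusters[[1]]] + e$log2fc
  }

  keys <- format_exon_key(exons$chromosome, exons$start, exons$stop,
                          exons$strand)
  vals <- matrix(0, nrow(exons), n, dimnames = list(keys, aliquot))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    rows <- which(exons$gene == g$symbol)
    lg <- g$baseline_log2 +
      matrix(shift[i, ], length(rows), n, byrow = TRUE) +
      matrix(stats::rnorm(length(rows) * n, 0, g$exon_sd), length(rows), n)
    vals[rows, ] <- 2^lg
  }
  expression <- expr_matrix(vals, quantification_label = "RPKM")

  haz <- config$hazards[cluster]
  t_event <- stats::rweibull(n, shape = config$weibull_shape,
                             scale = 1 / haz)
  t_cens <- stats::runif(n, 0, config$censor_horizon)
  clinical <- survival_records(case_id,
                               time = pmin(t_event, t_cens),
                               event = as.integer(t_event <= t_cens))

  junctions <- synthetic_junctions(config, exons, meta)

  truth_effects <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    data.frame(gene = genes$symbol[i], cluster = 1:4,
               log2_shift = vapply(1:4, function(k)
                 mean(shift[i, cluster == k]), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  structure(list(exons = exons, expression = expression, meta = meta,
                 clinical = clinical, junctions = junctions$records,
                 truth = list(effects = truth_effects,
                              hazards = config$hazards,
                              skips = junctions$truth),
                 config = config),
            class = "uvm_cohort")
}

# canonical junctions for every case/gene, injected skips per skip_spec,
# plus sub-threshold (1-3 read) skip noise in a few cases
synthetic_junctions <- function(config, exons, meta) {
  n <- nrow(meta)
  recs <- list()
  truth <- list()
  for (g in unique(exons$gene)) {
    ex <- exons[exons$gene == g, ]
    ex <- ex[order(ex$exon_index), ]
    plus <- ex$strand[1] == "+"
    # transcript-adjacent pairs in genomic orientation
    gord <- ex[order(ex$start), ]
    for (ci in seq_len(n)) {
      recs[[length(recs) + 1L]] <- data.frame(
        case_id = meta$case_id[ci], chromosome = gord$chromosome[1],
        donor_end = gord$stop[-nrow(gord)],
        acceptor_start = gord$start[-1],
        read_count = 20L + as.integer(stats::runif(nrow(gord) - 1, 0, 40)),
        stringsAsFactors = FALSE)
    }
    spec <- config$skip_spec[config$skip_spec$gene == g, , drop = FALSE]
    for (si in seq_len(nrow(spec))) {
      sp <- spec[si, ]
      carriers <- sort(sample.int(n, size = round(sp$fraction * n)))
      lo <- ex[ex$exon_index == sp$exon - 1L, ]
      hi <- ex[ex$exon_index == sp$exon + 1L, ]
      # skip junction spans the skipped exon in genomic coordinates
      de <- if (plus) lo$stop else hi$stop
      as_ <- if (plus) hi$start else lo$start
      for (ci in carriers) {
        reads <- as.integer(sample(seq(sp$min_reads, sp$max_reads), 1))
        recs[[length(recs) + 1L]] <- data.frame(
          case_id = meta$case_id[ci], chromosome = ex$chromosome[1],
          donor_end = de, acceptor_start = as_, read_count = reads,
          stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        gene = g, exon = sp$exon, n_carriers = length(carriers),
        cases = paste(meta$case_id[carriers], collapse = ","),
        stringsAsFactors = FALSE)
      # sub-threshold evidence in two non-carrier cases
      others <- setdiff(seq_len(n), carriers)
      if (length(others) >= 2) {
        for (ci in sort(sample(others, 2))) {
          recs[[length(recs) + 1L]] <- data.frame(
            case_id = meta$case_id[ci], chromosome = ex$chromosome[1],
            donor_end = de, acceptor_start = as_,
            read_count = as.integer(sample(1:3, 1)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  all <- do.call(rbind, recs)
  list(records = junction_records(all$case_id, all$chromosome,
                                  all$donor_end, all$acceptor_start,
                                  all$read_count),
       truth = if (length(truth)) do.call(rbind, truth)
               else data.frame(gene = character(0), exon = integer(0),
                               n_carriers = integer(0),
                               cases = character(0)))
}

#' Write a cohort bundle to disk in the dialects the readers accept
#'
#' Emits the exon table, expression matrix (simple wide TSV), case
#' metadata, clinical table, junction TSV and the ground-truth ledger as
#' JSON.
#'
#' @param bundle A `uvm_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    exons = file.path(dir, "exon_start_stop.tsv"),
    expression = file.path(dir, "exon_quantification.tsv"),
    meta = file.path(dir, "case_clusters.tsv"),
    clinical = file.path(dir, "clinical_dss.tsv"),
    junctions = file.path(dir, "junctions.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  write_exon_table(bundle$exons, paths[["exons"]])
  write_exon_quantification(bundle$expression, paths[["expression"]])
  write_case_meta(bundle$meta, paths[["meta"]])
  write_clinical(bundle$clinical, paths[["clinical"]])
  write_junctions(bundle$junctions, paths[["junctions"]])
  jsonlite::write_json(bundle$truth, paths[["truth"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Score the analysis against the generator's ground truth
#'
#' Re-derives the Above/Below grouping from the bundle, tests the pooled
#' 1&2-vs-3&4 contingency per gene, and joins the outcome to the injected
#' shifts: a gene is `detected` when its Fisher P clears `alpha` with
#' enrichment in the direction of the injected shift contrast. The
#' survival contrast between pooled clusters 1&2 and 3&4 is scored by
#' log-rank P and O/E hazard ratio.
#'
#' @param bundle A `uvm_cohort`.
#' @param alpha Detection significance level, default 0.05.
#' @param pseudocount Offset for the log2 transform.
#' @return List of class `recovery_report`: `genes` (per gene: injected
#'   shift contrast, Fisher P, direction correctness, `detected`) and
#'   `survival` (log-rank P, hazard ratio of clusters 3&4 vs 1&2).
#' @export
evaluate_recovery <- function(bundle, alpha = 0.05, pseudocount = 1) {
  em <- subset_cohort(bundle$expression, bundle$meta)
  zm <- relative_zscores(em, pseudocount)
  fx <- bundle$truth$effects
  genes <- unique(bundle$exons$gene)
  if (!setequal(genes, unique(fx$gene)))
    stop("ground-truth ledger does not match the analyzed genes")
  rows <- lapply(genes, function(g) {
    prof <- gene_average_z(zm, bundle$exons, g)
    cc <- cluster_counts(prof, bundle$meta)
    ft <- fisher_exact_two_tailed(pool_contingency(cc))
    sh <- fx$log2_shift[fx$gene == g]
    # injected contrast: mean shift in clusters 3&4 minus clusters 1&2
    contrast <- mean(sh[3:4]) - mean(sh[1:2])
    frac_below_34 <- sum(cc$below[3:4]) / sum(cc$above[3:4] + cc$below[3:4])
    frac_below_12 <- sum(cc$below[1:2]) / sum(cc$above[1:2] + cc$below[1:2])
    dir_ok <- if (contrast == 0) NA
              else if (contrast < 0) frac_below_34 > frac_below_12
              else frac_below_34 < frac_below_12
    data.frame(gene = g, injected_contrast = contrast,
               fisher_p = ft$p_value, direction_correct = dir_ok,
               detected = ft$p_value < alpha &&
                 (is.na(dir_ok) || isTRUE(dir_ok)),
               stringsAsFactors = FALSE)
  })
  cl <- bundle$meta$cluster[match(bundle$clinical$case_id,
                                  bundle$meta$case_id)]
  g12 <- bundle$clinical[cl %in% c(1, 2), ]
  g34 <- bundle$clinical[cl %in% c(3, 4), ]
  lr <- logrank_test(g34, g12)
  hr <- hazard_ratio(g34, g12)
  structure(list(genes = do.call(rbind, rows),
                 survival = list(logrank_p = lr$p_value, hr = hr$hr,
                                 hr_conf = c(hr$conf_low, hr$conf_high))),
            class = "recovery_report")
}
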