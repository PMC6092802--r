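#' Log2 transform with pseudocount
#'
#' Abundances are shifted by a pseudocount before the log so zero RPKM maps
#' to a finite value; the transform is strictly monotone in the abundance.
#'
#' @param rpkm Non-negative numeric vector.
#' @param pseudocount Positive offset, default 1 (so 0 RPKM -> 0).
#' @return `log2(rpkm + pseudocount)`.
#' @export
log2_transform <- function(rpkm, pseudocount = 1) {
  if (any(!is.finite(rpkm)) || any(rpkm < 0))
    stop("rpkm values must be finite and non-negative")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  log2(rpkm + pseudocount)
}

new_zscore_matrix <- function(z, reference_label, center, scale, pseudocount) {
  structure(list(z = z, reference_label = reference_label,
                 center = center, scale = scale, pseudocount = pseudocount),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat(sprintf("zscore_matrix: %d exons x %d cases, reference = %s\n",
              nrow(x$z), ncol(x$z), x$reference_label))
  invisible(x)
}

#' Cohort-centered ("relative") exon Z-scores
#'
#' For each exon row, log2-transformed abundances are mean-centered at the
#' whole-cohort average — the "average alteration level" — and divided by
#' the cohort sample standard deviation (n-1 denominator). Rows with zero
#' variance (no change / no expression everywhere) are set to all-zero Z.
#'
#' @param em An [expr_matrix()] restricted to the tumor cohort.
#' @param pseudocount Offset for [log2_transform()].
#' @return A `zscore_matrix` with `reference_label = "cohort_average"`;
#'   `center` and `scale` hold the per-exon log2 mean and SD.
#' @export
relative_zscores <- function(em, pseudocount = 1) {
  v <- em$values
  if (ncol(v) < 2L)
    stop("cohort Z-scores need at least 2 cases")
  l <- log2_transform(v, pseudocount)
  dim(l) <- dim(v); dimnames(l) <- dimnames(v)
  m <- rowMeans(l)
  s <- apply(l, 1L, stats::sd)
  z <- (l - m) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  new_zscore_matrix(z, "cohort_average", m, s, pseudocount)
}

#' Diploid-referenced ("differential") exon Z-scores
#'
#' Emulates the cBioPortal convention: each gene's exons are standardized
#' against the expression distribution of the tumors that are copy-number
#' diploid at the gene's locus, and that reference is applied to every
#' case. Used here at arm resolution: a case is in the reference set for a
#' gene when its state at the gene's chromosome arm is `diploid`.
#'
#' @param em An [expr_matrix()] aligned to `meta` (same columns, same
#'   order; see [subset_cohort()]).
#' @param meta A [case_meta()] carrying per-case arm states.
#' @param exons An [exon_table()] mapping matrix rows to genes.
#' @param gene_arms Named character vector, gene symbol -> chromosome arm.
#' @param pseudocount Offset for [log2_transform()].
#' @return A `zscore_matrix` (`reference_label = "diploid_fraction"`)
#'   covering the matrix rows that map to an annotated gene.
#' @export
differential_zscores <- function(em, meta, exons, gene_arms, pseudocount = 1) {
  v <- em$values
  if (!identical(colnames(v), meta$case_id))
    stop("expression columns must be aligned to metadata (see subset_cohort)")
  genes <- unique(exons$gene)
  if (any(!genes %in% names(gene_arms)))
    stop("gene_arms lacks an arm for: ",
         paste(setdiff(genes, names(gene_arms)), collapse = ", "))
  row_map <- map_gene_rows(exons, rownames(v))
  rows_used <- unlist(row_map, use.names = FALSE)
  l <- log2_transform(v[rows_used, , drop = FALSE], pseudocount)
  dim(l) <- c(length(rows_used), ncol(v))
  dimnames(l) <- list(rownames(v)[rows_used], colnames(v))

  m <- numeric(nrow(l)); s <- numeric(nrow(l))
  at <- 0L
  for (g in genes) {
    k <- length(row_map[[g]])
    dip <- arm_state(meta, gene_arms[[g]]) == "diploid"
    if (sum(dip) < 2L)
      stop(sprintf("gene %s: fewer than 2 diploid reference cases", g))
    sub <- l[at + seq_len(k), dip, drop = FALSE]
    m[at + seq_len(k)] <- rowMeans(sub)
    s[at + seq_len(k)] <- apply(sub, 1L, stats::sd)
    at <- at + k
  }
  z <- (l - m) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  names(m) <- names(s) <- rownames(l)
  new_zscore_matrix(z, "diploid_fraction", m, s, pseudocount)
}

# gene -> integer vector of matrix row indices (transcript order), matching
# annotation coordinates to composite row keys on the normalized form.
map_gene_rows <- function(exons, matrix_keys) {
  mk <- norm_key(matrix_keys)
  tk <- norm_key(format_exon_key(exons$chromosome, exons$start, exons$stop,
                                 exons$strand))
  pos <- match(tk, mk)
  out <- list()
  for (g in unique(exons$gene)) {
    i <- which(exons$gene == g)
    i <- i[order(exons$exon_index[i])]
    p <- pos[i]
    out[[g]] <- p[!is.na(p)]
  }
  out
}

#' Per-case gene-level average Z-score and Above/Below placement
#'
#' The gene score is the unweighted arithmetic mean of the gene's exon-row
#' Z-scores — defensible because structural variation within these genes is
#' rare, so exons move together. Cases with a positive average sit `Above`
#' the average alteration level, all others (ties at exactly zero
#' included) `Below`.
#'
#' @param zm A `zscore_matrix`.
#' @param exons An [exon_table()].
#' @param gene Gene symbol.
#' @return Data frame of class `gene_z_profile`: `case_id`, `gene`,
#'   `average_z`, `group`, `n_exons_used`.
#' @export
gene_average_z <- function(zm, exons, gene) {
  rows <- map_gene_rows(exons[exons$gene == gene, , drop = FALSE],
                        rownames(zm$z))[[gene]]
  if (is.null(rows) || !length(rows))
    stop(sprintf("gene %s has no exon rows in the Z-score matrix", gene))
  avg <- colMeans(zm$z[rows, , drop = FALSE])
  out <- data.frame(case_id = colnames(zm$z), gene = gene,
                    average_z = unname(avg),
                    group = ifelse(avg > 0, "Above", "Below"),
                    n_exons_used = length(rows),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_z_profile", "data.frame")
  out
}

#' Above/Below group mapping from gene profiles
#'
#' @param profiles A `gene_z_profile` (one gene).
#' @return Named character vector, case id -> `"Above"` (average Z strictly
#'   positive) or `"Below"`.
#' @export
dichotomize <- function(profiles) {
  stats::setNames(ifelse(profiles$average_z > 0, "Above", "Below"),
                  profiles$case_id)
}

#' Above/Below counts per cluster for one gene
#'
#' @param profiles A `gene_z_profile`.
#' @param meta A [case_meta()] covering the profiled cases.
#' @return Data frame with one row per cluster 1–4: `cluster`, `above`,
#'   `below`.
#' @export
cluster_counts <- function(profiles, meta) {
  grp <- dichotomize(profiles)
  cl <- meta$cluster[match(names(grp), meta$case_id)]
  if (anyNA(cl))
    stop("profiled case missing from metadata: ",
         names(grp)[which(is.na(cl))[1]])
  data.frame(
    cluster = 1:4,
    above = vapply(1:4, function(k) sum(grp == "Above" & cl == k), integer(1)),
    below = vapply(1:4, function(k) sum(grp == "Below" & cl == k), integer(1))
  )
}

#' Cluster-ordered exon-by-case matrix with tri-level heatmap bins
#'
#' Columns are arranged by SCNA cluster 1–4 (stable within cluster by
#' metadata order); each cell is binned `high` (z above the threshold),
#' `low` (below its negative) or `no_change`, the red/white/blue scheme of
#' the expression heat maps.
#'
#' @param zm A `zscore_matrix`.
#' @param exons An [exon_table()].
#' @param gene Gene symbol.
#' @param meta A [case_meta()].
#' @param bin_threshold Positive bin half-width in Z units, default 1.
#' @return List of class `heatmap_matrix`: `z` (exon x case, transcript
#'   order rows, cluster-ordered columns), `bins` (character matrix),
#'   `clusters` (per ordered column), `gene`.
#' @export
heatmap_matrix <- function(zm, exons, gene, meta, bin_threshold = 1) {
  if (!gene %in% exons$gene) stop("unknown gene: ", gene)
  rows <- map_gene_rows(exons[exons$gene == gene, , drop = FALSE],
                        rownames(zm$z))[[gene]]
  if (!length(rows))
    stop(sprintf("gene %s has no exon rows in the Z-score matrix", gene))
  ord <- order(meta$cluster)   # stable: ties keep metadata order
  cases <- meta$case_id[ord]
  z <- zm$z[rows, cases, drop = FALSE]
  bins <- matrix("no_change", nrow(z), ncol(z), dimnames = dimnames(z))
  bins[z > bin_threshold] <- "high"
  bins[z < -bin_threshold] <- "low"
  structure(list(z = z, bins = bins, clusters = meta$cluster[ord],
                 gene = gene),
            class = "heatmap_matrix")
}

#' Write a heatmap matrix as TSV (6 significant digits)
#' @param hm A `heatmap_matrix`.
#' @param path Output path.
#' @export
write_heatmap_matrix <- function(hm, path) {
  header <- paste(c("exon", colnames(hm$z)), collapse = "\t")
  body <- vapply(seq_len(nrow(hm$z)), function(i)
    paste(c(rownames(hm$z)[i], sprintf("%.6g", hm$z[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Render a heatmap matrix
#'
#' Simple image rendering of the tri-level binning: low = blue, no change =
#' white, high = red, columns in cluster order.
#'
#' @param x A `heatmap_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.heatmap_matrix <- function(x, ...) {
  lv <- matrix(match(x$bins, c("low", "no_change", "high")),
               nrow(x$bins), ncol(x$bins))
  graphics::image(t(lv[rev(seq_len(nrow(lv))), , drop = FALSE]),
                  col = c("#2166AC", "#FFFFFF", "#B2182B"),
                  zlim = c(1, 3), axes = FALSE,
                  main = x$gene, ...)
  invisible(x)
}

#' Write a Z-score matrix as TSV (6 significant digits)
#' @param zm A `zscore_matrix`.
#' @param path Output path.
#' @export
write_zscore_matrix <- function(zm, path) {
  header <- paste(c("exon", colnames(zm$z)), collapse = "\t")
  body <- vapply(seq_len(nrow(zm$z)), function(i)
    paste(c(rownames(zm$z)[i], sprintf("%.6g", zm$z[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
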