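#' Construct a 2x2 contingency table
#'
#' Rows are the pooled cluster groups, columns the Above/Below expression
#' groups, laid out `[[a, b], [c, d]]`.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param row_labels,col_labels Dimension labels.
#' @return Integer matrix of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d,
                              row_labels = c("clusters 1&2", "clusters 3&4"),
                              col_labels = c("Above", "Below")) {
  x <- c(a, b, c, d)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("contingency counts must be non-negative integers")
  m <- matrix(as.integer(x), nrow = 2, byrow = TRUE,
              dimnames = list(row_labels, col_labels))
  class(m) <- c("contingency_table", class(m))
  m
}

#' Pool per-cluster Above/Below counts into a 2x2 table
#'
#' The default grouping contrasts the disomy-3 clusters 1&2 with the
#' monosomy-3 clusters 3&4.
#'
#' @param per_cluster_counts Data frame with columns `cluster`, `above`,
#'   `below` covering clusters 1–4 (see [cluster_counts()]).
#' @param grouping List of two integer vectors partitioning `1:4`.
#' @return A [contingency_table()].
#' @export
pool_contingency <- function(per_cluster_counts,
                             grouping = list(c(1, 2), c(3, 4))) {
  cc <- per_cluster_counts
  if (!all(1:4 %in% cc$cluster))
    stop("counts must cover clusters 1..4; missing: ",
         paste(setdiff(1:4, cc$cluster), collapse = ", "))
  if (length(grouping) != 2 || !setequal(unlist(grouping), 1:4))
    stop("grouping must be a 2-part partition of clusters 1..4")
  s <- function(cl, col) sum(cc[[col]][cc$cluster %in% cl])
  tab <- contingency_table(
    s(grouping[[1]], "above"), s(grouping[[1]], "below"),
    s(grouping[[2]], "above"), s(grouping[[2]], "below"),
    row_labels = vapply(grouping, function(g)
      paste0("clusters ", paste(g, collapse = "&")), character(1)))
  if (sum(tab) == 0) stop("pooled contingency table is empty")
  tab
}

assoc_test <- function(method, p_value, statistic = NA_real_,
                       df = NA_integer_, degenerate = FALSE) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, degenerate = degenerate),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s: p = %.6g", x$method, x$p_value))
  if (!is.na(x$statistic)) cat(sprintf(" (statistic %.6g, df %d)",
                                       x$statistic, x$df))
  if (x$degenerate) cat(" [degenerate]")
  cat("\n")
  invisible(x)
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' The two-tailed P is the sum, over all tables with the observed margins,
#' of the hypergeometric probabilities no greater than the observed
#' table's. Probabilities are compared with a relative slack of 1e-7 so
#' floating-point ties count as ties — the convention of the GraphPad-style
#' calculators these cohort tables were historically run through. A table
#' with an empty row or column margin is degenerate: P = 1 by convention.
#'
#' @param table A [contingency_table()] (any 2x2 count matrix works).
#' @return An `assoc_test` with `method = "fisher_two_tailed"`.
#' @export
fisher_exact_two_tailed <- function(table) {
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  if (sum(table) < 1) stop("empty table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(assoc_test("fisher_two_tailed", 1, degenerate = TRUE))
  # support of the (1,1) cell given the margins
  k <- max(0, c1 - r2):min(r1, c1)
  logp <- stats::dhyper(k, r1, r2, c1, log = TRUE)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(exp(logp)[exp(logp) <= p_obs * (1 + 1e-7)])
  assoc_test("fisher_two_tailed", min(p, 1))
}

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' Statistic computed in the margin form
#' `N * (ad - bc)^2 / (r1 * r2 * c1 * c2)`, algebraically identical to
#' `sum((obs - exp)^2 / exp)` but exact for integer tables. No Yates
#' correction is applied; df = 1.
#'
#' @param table A 2x2 count matrix.
#' @return An `assoc_test` with `method = "pearson_chisq"`, the statistic
#'   and the upper-tail chi-square P.
#' @export
pearson_chisq <- function(table) {
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c + d
  if (n < 1) stop("empty table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0))
    stop("zero expected cell (empty margin); use fisher_exact_two_tailed")
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  assoc_test("pearson_chisq",
             stats::pchisq(stat, df = 1, lower.tail = FALSE),
             statistic = stat, df = 1L)
}

# integer-percentage rounding, half away from zero (printed-table style;
# base round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

#' Per-gene summary row in the printed-table layout
#'
#' Formats one gene's per-cluster counts as `above/below (p%/q%)` cells
#' plus pooled Fisher P, cohort totals, and the Kaplan–Meier annotation:
#' which expression group has worse survival (`NA` when the log-rank P is
#' not significant).
#'
#' @param gene Gene symbol.
#' @param per_cluster_counts Data frame `cluster`, `above`, `below`.
#' @param cluster_sizes Integer vector of the four cluster sizes.
#' @param fisher_p Pooled two-tailed Fisher P.
#' @param logrank_p Above-vs-Below log-rank P (or `NA`).
#' @param worse_group `"Above"`, `"Below"` or `NA`; ignored (forced `NA`)
#'   when `logrank_p >= alpha`.
#' @param alpha Significance level for the survival annotation.
#' @return One-row data frame: `gene`, `cluster1`..`cluster4` formatted
#'   cells, `fisher_p`, `total_above`, `total_below`, `worse_survival`,
#'   `logrank_p`.
#' @export
gene_summary_row <- function(gene, per_cluster_counts, cluster_sizes,
                             fisher_p, logrank_p = NA_real_,
                             worse_group = NA_character_, alpha = 0.05) {
  cc <- per_cluster_counts[order(per_cluster_counts$cluster), ]
  tot <- cc$above + cc$below
  if (!identical(as.integer(tot), as.integer(cluster_sizes)))
    stop(sprintf("gene %s: above+below (%s) inconsistent with cluster sizes (%s)",
                 gene, paste(tot, collapse = ","),
                 paste(cluster_sizes, collapse = ",")))
  cells <- sprintf("%d/%d (%d/%d)", cc$above, cc$below,
                   round_half_up(100 * cc$above / tot),
                   round_half_up(100 * cc$below / tot))
  worse <- if (is.na(logrank_p) || logrank_p >= alpha) NA_character_
           else worse_group
  out <- data.frame(gene = gene,
                    cluster1 = cells[1], cluster2 = cells[2],
                    cluster3 = cells[3], cluster4 = cells[4],
                    fisher_p = fisher_p,
                    total_above = sum(cc$above), total_below = sum(cc$below),
                    worse_survival = worse, logrank_p = logrank_p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
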