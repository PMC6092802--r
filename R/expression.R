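#' Construct an expression matrix
#'
#' @param values Numeric matrix, exons (rows, named by composite key) by
#'   cases (columns, named). All values must be finite and non-negative.
#' @param quantification_label Abundance unit label, e.g. `"RPKM"`.
#' @return A list of class `expr_matrix` with elements `values` and
#'   `quantification_label`.
#' @export
expr_matrix <- function(values, quantification_label = "RPKM") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs row (exon key) and column (case) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate exon row keys in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate case columns in expression matrix")
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(values))
    stop(sprintf("invalid abundance at row '%s', column '%s': %s",
                 rownames(values)[rc[1]], colnames(values)[rc[2]],
                 format(values[bad[1]])))
  }
  structure(list(values = values,
                 quantification_label = quantification_label),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d exons x %d cases (%s)\n",
              nrow(x$values), ncol(x$values), x$quantification_label))
  invisible(x)
}

#' Read a TCGA-style exon quantification matrix
#'
#' Accepts two tab-separated dialects, auto-detected from the header:
#' \describe{
#'   \item{simple wide}{first column composite exon keys, one numeric
#'     column per case, single header row of case identifiers.}
#'   \item{TCGA Level-3 triplet}{two header rows — barcodes repeated three
#'     times, then a row of value types (`raw_counts`,
#'     `median_length_normalized`, `RPKM`) — from which only the RPKM
#'     columns are retained.}
#' }
#'
#' @param path File path.
#' @return An [expr_matrix()] with full barcodes as column labels.
#' @export
read_exon_quantification <- function(path) {
  head2 <- readLines(path, n = 2L)
  if (length(head2) < 2L) stop("exon quantification file too short: ", path)
  h1 <- strsplit(head2[1], "\t", fixed = TRUE)[[1]]
  h2 <- strsplit(head2[2], "\t", fixed = TRUE)[[1]]
  triplet_types <- c("raw_counts", "median_length_normalized", "RPKM")
  triplet <- length(h2) > 1L && all(h2[-1] %in% triplet_types)

  if (triplet) {
    dat <- utils::read.delim(path, header = FALSE, skip = 2L,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             colClasses = "character")
    if (ncol(dat) != length(h1))
      stop("ragged triplet-dialect file: data rows have ", ncol(dat),
           " fields, header has ", length(h1))
    keep <- which(h2[-1] == "RPKM") + 1L
    cases <- h1[keep]
    vals <- dat[, keep, drop = FALSE]
  } else {
    dat <- utils::read.delim(path, header = FALSE, skip = 1L,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             colClasses = "character")
    if (ncol(dat) != length(h1))
      stop("ragged file: data rows have ", ncol(dat),
           " fields, header has ", length(h1))
    cases <- h1[-1]
    vals <- dat[, -1, drop = FALSE]
  }
  keys <- dat[[1]]
  num <- suppressWarnings(
    vapply(vals, function(col) as.numeric(col), numeric(nrow(vals))))
  num <- matrix(num, nrow = nrow(vals),
                dimnames = list(keys, cases))
  nn <- which(is.na(num))
  if (length(nn)) {
    rc <- arrayInd(nn[1], dim(num))
    stop(sprintf("non-numeric cell at row '%s', column '%s'",
                 keys[rc[1]], cases[rc[2]]))
  }
  neg <- which(num < 0)
  if (length(neg)) {
    rc <- arrayInd(neg[1], dim(num))
    stop(sprintf("negative abundance at row '%s', column '%s': %s",
                 keys[rc[1]], cases[rc[2]], format(num[neg[1]])))
  }
  expr_matrix(num, quantification_label = "RPKM")
}

#' Write an expression matrix in the simple wide dialect
#'
#' Floats are serialized with 17 significant digits so a read-back
#' reproduces the values bit-exactly.
#'
#' @param em An `expr_matrix`.
#' @param path Output path.
#' @export
write_exon_quantification <- function(em, path) {
  v <- em$values
  header <- paste(c("exon", colnames(v)), collapse = "\t")
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Split a TCGA sample barcode
#'
#' @param barcode A TCGA aliquot barcode, `TCGA-XX-XXXX-TTx-...` with at
#'   least four dash-separated fields.
#' @return List with `participant` (first three fields),
#'   `sample_type_code` (leading two digits of field 4) and `is_tumor`
#'   (`TRUE` for codes 01–09, the TCGA tumor range).
#' @export
parse_barcode <- function(barcode) {
  f <- strsplit(barcode, "-", fixed = TRUE)[[1]]
  if (length(f) < 4L)
    stop(sprintf("barcode '%s' has fewer than 4 dash-separated fields",
                 barcode))
  code <- substr(f[4], 1, 2)
  structure(list(
    participant = paste(f[1:3], collapse = "-"),
    sample_type_code = code,
    is_tumor = code %in% sprintf("%02d", 1:9)
  ), class = "tcga_barcode")
}

#' Read case metadata (cluster assignments and copy-number states)
#'
#' Dialect: `case_id<TAB>cluster[<TAB>arm=state,arm=state,...]`, header
#' optional, `#` comments ignored. States are `loss`, `diploid` or `gain`;
#' arms absent from a case's list are taken as diploid.
#'
#' @param path File path.
#' @return A data frame of class `case_meta` with columns `case_id`,
#'   `cluster` (integer 1–4) and list column `copy_number` (named character
#'   vector of arm states per case).
#' @export
read_case_meta <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (suppressWarnings(is.na(as.integer(fields[[1]][2]))))
    fields <- fields[-1]
  case_id <- vapply(fields, `[[`, character(1), 1)
  cluster <- vapply(fields, function(f) as.integer(f[[2]]), integer(1))
  cn <- lapply(fields, function(f) {
    if (length(f) < 3 || !nzchar(f[[3]])) return(character(0))
    kv <- strsplit(strsplit(f[[3]], ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(vapply(kv, `[[`, character(1), 2),
                    vapply(kv, `[[`, character(1), 1))
  })
  case_meta(data.frame(case_id = case_id, cluster = cluster,
                       stringsAsFactors = FALSE),
            copy_number = cn)
}

#' Construct case metadata
#'
#' @param df Data frame with columns `case_id` and `cluster`.
#' @param copy_number List (one element per case) of named character
#'   vectors mapping chromosome arm to `loss` / `diploid` / `gain`.
#' @return Data frame of class `case_meta`.
#' @export
case_meta <- function(df, copy_number = NULL) {
  if (!all(c("case_id", "cluster") %in% names(df)))
    stop("case metadata needs case_id and cluster columns")
  if (anyDuplicated(df$case_id))
    stop("duplicate case_id in metadata: ",
         df$case_id[which(duplicated(df$case_id))[1]])
  if (any(!df$cluster %in% 1:4))
    stop("cluster labels must be in 1..4")
  if (is.null(copy_number))
    copy_number <- rep(list(character(0)), nrow(df))
  if (length(copy_number) != nrow(df))
    stop("copy_number list length differs from case count")
  bad <- unlist(lapply(copy_number, function(x)
    x[!x %in% c("loss", "diploid", "gain")]))
  if (length(bad))
    stop("unknown copy-number state: ", bad[1])
  df$copy_number <- copy_number
  class(df) <- c("case_meta", "data.frame")
  df
}

#' Copy-number state of a case at a chromosome arm
#'
#' @param meta A `case_meta`.
#' @param arm Chromosome arm label, e.g. `"3p"`.
#' @return Character vector of states, one per case; arms not listed for a
#'   case are `"diploid"`.
#' @export
arm_state <- function(meta, arm) {
  vapply(meta$copy_number, function(cn) {
    if (arm %in% names(cn)) unname(cn[[arm]]) else "diploid"
  }, character(1))
}

#' Write case metadata in the dialect [read_case_meta()] accepts
#' @param meta A `case_meta`.
#' @param path Output path.
#' @export
write_case_meta <- function(meta, path) {
  cn <- vapply(meta$copy_number, function(x)
    paste(names(x), x, sep = "=", collapse = ","), character(1))
  writeLines(c("case_id\tcluster\tcopy_number",
               paste(meta$case_id, meta$cluster, cn, sep = "\t")),
             path)
  invisible(path)
}

#' Project an expression matrix onto a case cohort
#'
#' Resolves each metadata case to exactly one matrix column (by full column
#' label or by TCGA participant barcode) and returns the columns in
#' metadata order, relabelled by participant-level case id. A pure
#' projection: values are never modified.
#'
#' @param em An `expr_matrix` with full barcodes (or case ids) as columns.
#' @param meta A `case_meta`.
#' @param tumor_only Drop non-tumor aliquots (sample type codes outside
#'   01–09) before matching; default `TRUE`.
#' @return An `expr_matrix` with `ncol == nrow(meta)`.
#' @export
subset_cohort <- function(em, meta, tumor_only = TRUE) {
  cols <- colnames(em$values)
  parseable <- vapply(cols, function(x)
    length(strsplit(x, "-", fixed = TRUE)[[1]]) >= 4L, logical(1))
  participant <- cols
  is_tumor <- rep(TRUE, length(cols))
  for (i in which(parseable)) {
    b <- parse_barcode(cols[i])
    participant[i] <- b$participant
    is_tumor[i] <- b$is_tumor
  }
  keep <- if (tumor_only) which(is_tumor | !parseable) else seq_along(cols)

  sel <- integer(nrow(meta))
  problems <- character(0)
  for (j in seq_len(nrow(meta))) {
    id <- meta$case_id[j]
    hits <- keep[cols[keep] == id | participant[keep] == id]
    if (length(hits) == 0L)
      problems <- c(problems, sprintf("case '%s': no matching column", id))
    else if (length(hits) > 1L)
      problems <- c(problems,
                    sprintf("case '%s': ambiguous columns (%s)", id,
                            paste(cols[hits], collapse = ", ")))
    else sel[j] <- hits
  }
  if (length(problems))
    stop("cohort subsetting failed:\n  ", paste(problems, collapse = "\n  "))
  out <- em$values[, sel, drop = FALSE]
  colnames(out) <- meta$case_id
  expr_matrix(out, quantification_label = em$quantification_label)
}
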