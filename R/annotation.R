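#' Parse a composite exon key
#'
#' Exon quantification matrices key rows as `chr:start-stop:strand`
#' (e.g. `"chr9:130950210-130950372:+"`). Coordinates are 1-based and
#' inclusive on both ends, the convention of TCGA GAF-derived files and of
#' genome-browser coordinate strings. Thousands separators (commas) inside
#' the coordinates are tolerated and stripped.
#'
#' @param key Character scalar, `<chrom>:<start>-<stop>:<strand>`.
#' @return A list of class `exon_key` with elements `chromosome`, `start`,
#'   `stop`, `strand`. Gene fields are unset; see [load_exon_table()] for
#'   gene-annotated records.
#' @examples
#' parse_exon_key("chr9:130,950,210-130,950,372:+")
#' @seealso [format_exon_key()]
#' @export
parse_exon_key <- function(key) {
  if (!is.character(key) || length(key) != 1L || is.na(key))
    stop("exon key must be a single character string")
  raw <- key
  key <- gsub(",", "", key, fixed = TRUE)
  m <- regmatches(key, regexec("^([^:]+):([0-9]+)-([0-9]+):(.+)$", key))[[1]]
  if (length(m) == 0L)
    stop(sprintf("malformed exon key: '%s'", raw))
  chrom <- m[2]
  start <- as.integer(m[3])
  stop_ <- as.integer(m[4])
  strand <- m[5]
  if (is.na(start) || is.na(stop_))
    stop(sprintf("malformed exon key '%s': non-integer coordinate", raw))
  if (!strand %in% c("+", "-"))
    stop(sprintf("malformed exon key '%s': unknown strand symbol '%s'",
                 raw, strand))
  if (start > stop_)
    stop(sprintf("malformed exon key '%s': start %d > stop %d",
                 raw, start, stop_))
  structure(list(chromosome = chrom, start = start, stop = stop_,
                 strand = strand),
            class = "exon_key")
}

#' Format an exon composite key
#'
#' Inverse of [parse_exon_key()]; emits the canonical form without
#' thousands separators, so `format_exon_key(parse_exon_key(k))` is the
#' canonical spelling of `k`.
#'
#' @param x An `exon_key`, or a chromosome name when the remaining
#'   components are given separately.
#' @param start,stop,strand Components when `x` is a chromosome name.
#' @return Character vector of canonical keys.
#' @export
format_exon_key <- function(x, start = NULL, stop = NULL, strand = NULL) {
  if (inherits(x, "exon_key"))
    return(sprintf("%s:%d-%d:%s", x$chromosome, x$start, x$stop, x$strand))
  sprintf("%s:%d-%d:%s", x, as.integer(start), as.integer(stop), strand)
}

# Comparable form of a chromosome name: "chr" prefix stripped, for matching
# annotation against matrix keys only; stored names stay verbatim.
norm_chrom <- function(chrom) sub("^chr", "", chrom)

# Comparable form of a composite key (normalized chromosome, no separators).
norm_key <- function(keys) {
  vapply(keys, function(k) {
    p <- parse_exon_key(k)
    format_exon_key(norm_chrom(p$chromosome), p$start, p$stop, p$strand)
  }, character(1), USE.NAMES = FALSE)
}

#' Construct an exon coordinate table
#'
#' @param records A data frame with columns `gene`, `chromosome`, `start`,
#'   `stop`, `strand` and optionally `exon_index`. Coordinates are 1-based
#'   inclusive. When `exon_index` is absent it is assigned in transcription
#'   order within each gene: ascending genomic coordinate on `+` strands,
#'   descending on `-`.
#' @param genome_build Label recorded with the table (default `"hg19"`).
#' @return A data frame of class `exon_table`, sorted by
#'   `(gene, exon_index)`, with a `genome_build` attribute.
#' @export
exon_table <- function(records, genome_build = "hg19") {
  req <- c("gene", "chromosome", "start", "stop", "strand")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("exon table lacks columns: ", paste(missing_cols, collapse = ", "))
  records$start <- as.integer(records$start)
  records$stop <- as.integer(records$stop)
  if (any(records$start > records$stop))
    stop("exon with start > stop: ",
         records$gene[which(records$start > records$stop)[1]])
  if (any(!records$strand %in% c("+", "-")))
    stop("unknown strand symbol in exon table")

  if (!"exon_index" %in% names(records) || all(is.na(records$exon_index))) {
    records$exon_index <- NA_integer_
    for (g in unique(records$gene)) {
      i <- which(records$gene == g)
      asc <- order(records$start[i], records$stop[i])
      if (records$strand[i[1]] == "-") asc <- rev(asc)
      records$exon_index[i[asc]] <- seq_along(i)
    }
  }
  records$exon_index <- as.integer(records$exon_index)

  key4 <- paste(records$chromosome, records$start, records$stop,
                records$strand)
  if (anyDuplicated(key4))
    stop("duplicate exon coordinates: ", key4[which(duplicated(key4))[1]])
  gi <- paste(records$gene, records$exon_index)
  if (anyDuplicated(gi))
    stop("duplicate (gene, exon_index): ", gi[which(duplicated(gi))[1]])
  for (g in unique(records$gene)) {
    idx <- sort(records$exon_index[records$gene == g])
    if (!identical(idx, seq_along(idx)))
      stop(sprintf("exon_index for gene %s is not consecutive from 1", g))
  }

  records <- records[order(records$gene, records$exon_index), , drop = FALSE]
  rownames(records) <- NULL
  structure(records, genome_build = genome_build,
            class = c("exon_table", "data.frame"))
}

#' Read an exon coordinate table from a TSV file
#'
#' The dialect is one exon per line:
#' `gene<TAB>chr:start-stop:strand[<TAB>exon_index]`, an optional header
#' line, `#` comment lines ignored. This is the per-gene exon start/stop
#' extract conventionally derived from a TCGA gene annotation (GAF) file.
#'
#' @param path File path.
#' @param gene_filter Optional character vector; only these genes are kept.
#' @param genome_build Label recorded with the table.
#' @return An [exon_table()].
#' @export
load_exon_table <- function(path, gene_filter = NULL, genome_build = "hg19") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty exon table file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 2L))
    stop(sprintf("line %d of %s has fewer than 2 tab-separated fields",
                 which(n < 2L)[1], path))
  # header line: second field is not a parseable composite key
  is_key <- function(s) grepl("^[^:]+:[0-9,]+-[0-9,]+:[+-]$", gsub(",", "", s))
  if (!is_key(fields[[1]][2])) fields <- fields[-1]
  if (!length(fields)) stop("exon table file holds only a header: ", path)

  gene <- vapply(fields, `[[`, character(1), 1)
  keys <- lapply(fields, function(f) parse_exon_key(f[[2]]))
  idx <- vapply(fields, function(f)
    if (length(f) >= 3 && nzchar(f[[3]])) as.integer(f[[3]]) else NA_integer_,
    integer(1))
  records <- data.frame(
    gene = gene,
    chromosome = vapply(keys, `[[`, character(1), "chromosome"),
    start = vapply(keys, `[[`, integer(1), "start"),
    stop = vapply(keys, `[[`, integer(1), "stop"),
    strand = vapply(keys, `[[`, character(1), "strand"),
    exon_index = idx,
    stringsAsFactors = FALSE
  )
  if (!is.null(gene_filter)) {
    records <- records[records$gene %in% gene_filter, , drop = FALSE]
    if (!nrow(records))
      stop("no exons left after gene filter: ",
           paste(gene_filter, collapse = ", "))
  }
  exon_table(records, genome_build = genome_build)
}

#' Write an exon coordinate table
#'
#' Serializes in the dialect [load_exon_table()] reads; round-trips
#' identically.
#'
#' @param table An `exon_table`.
#' @param path Output file path.
#' @export
write_exon_table <- function(table, path) {
  keys <- format_exon_key(table$chromosome, table$start, table$stop,
                          table$strand)
  writeLines(c("gene\texon_key\texon_index",
               paste(table$gene, keys, table$exon_index, sep = "\t")),
             path)
  invisible(path)
}

#' Export an exon table as BED6
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention, for genome-browser inspection.
#'
#' @param table An `exon_table`.
#' @param path Optional path; when given the BED lines are written there.
#' @return Invisibly (or visibly when `path` is `NULL`) a data frame with
#'   BED6 columns.
#' @export
exon_table_to_bed <- function(table, path = NULL) {
  bed <- data.frame(
    chrom = table$chromosome,
    chromStart = table$start - 1L,
    chromEnd = table$stop,
    name = paste0(table$gene, ":exon", table$exon_index),
    score = 0L,
    strand = table$strand,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}

#' Check an exon table against the row keys of a quantification matrix
#'
#' Verification step run before any Z-score computation: confirms every
#' annotated exon has a row in the expression matrix. Matching normalizes
#' the `chr` prefix away; stored names are untouched.
#'
#' @param table An `exon_table`.
#' @param matrix_keys Character vector of composite row keys.
#' @return A list of class `verification_report`: `matched`, `missing`,
#'   `extra` counts plus `missing_keys` identities. `matched + missing`
#'   equals `nrow(table)`; the report is clean iff `missing == 0`.
#' @export
verify_annotation <- function(table, matrix_keys) {
  tab_keys <- norm_key(format_exon_key(table$chromosome, table$start,
                                       table$stop, table$strand))
  mat_keys <- norm_key(matrix_keys)
  hit <- tab_keys %in% mat_keys
  structure(list(
    matched = sum(hit),
    missing = sum(!hit),
    extra = sum(!mat_keys %in% tab_keys),
    missing_keys = format_exon_key(table$chromosome, table$start,
                                   table$stop, table$strand)[!hit]
  ), class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("annotation verification: %d matched, %d missing, %d extra\n",
              x$matched, x$missing, x$extra))
  if (x$missing > 0)
    cat("missing keys:", paste(utils::head(x$missing_keys, 10),
                               collapse = ", "), "\n")
  invisible(x)
}
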