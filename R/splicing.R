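#' Construct splice-junction records
#'
#' A junction joins the last base of a genomically upstream exon
#' (`donor_end`) to the first base of a downstream exon
#' (`acceptor_start`), both 1-based; `donor_end < acceptor_start`.
#'
#' @param case_id,chromosome Character vectors.
#' @param donor_end,acceptor_start Integer positions.
#' @param read_count Non-negative integer read support.
#' @return Data frame of class `junction_records`.
#' @export
junction_records <- function(case_id, chromosome, donor_end, acceptor_start,
                             read_count) {
  donor_end <- as.integer(donor_end)
  acceptor_start <- as.integer(acceptor_start)
  read_count <- as.integer(read_count)
  if (any(is.na(donor_end)) || any(is.na(acceptor_start)))
    stop("malformed junction coordinates")
  if (any(donor_end >= acceptor_start))
    stop("junction with donor_end >= acceptor_start at record ",
         which(donor_end >= acceptor_start)[1])
  if (any(is.na(read_count)) || any(read_count < 0))
    stop("junction read counts must be non-negative integers")
  out <- data.frame(case_id = case_id, chromosome = chromosome,
                    donor_end = donor_end, acceptor_start = acceptor_start,
                    read_count = read_count, stringsAsFactors = FALSE)
  class(out) <- c("junction_records", "data.frame")
  out
}

#' Read a junction table
#'
#' Two dialects:
#' \describe{
#'   \item{`tsv`}{`case_id<TAB>chrom<TAB>donor_end<TAB>acceptor_start<TAB>reads`,
#'     1-based coordinates as stored internally; header optional.}
#'   \item{`bed`}{TopHat/STAR-style intron BED6: 0-based half-open span of
#'     the intron, `name` = case id, `score` = read count. Converted so
#'     `donor_end = chromStart` and `acceptor_start = chromEnd + 1`
#'     (both 1-based exonic bases); the conversion round-trips through
#'     [write_junctions()].}
#' }
#'
#' @param path File path.
#' @param format `"tsv"` or `"bed"`.
#' @return A [junction_records()] data frame.
#' @export
read_junctions <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|track)", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "tsv") {
    if (suppressWarnings(is.na(as.integer(fields[[1]][3]))))
      fields <- fields[-1]
    junction_records(
      case_id = vapply(fields, `[[`, character(1), 1),
      chromosome = vapply(fields, `[[`, character(1), 2),
      donor_end = vapply(fields, function(f) as.integer(f[[3]]), integer(1)),
      acceptor_start = vapply(fields, function(f) as.integer(f[[4]]),
                              integer(1)),
      read_count = vapply(fields, function(f) as.integer(f[[5]]), integer(1)))
  } else {
    cs <- vapply(fields, function(f) as.integer(f[[2]]), integer(1))
    ce <- vapply(fields, function(f) as.integer(f[[3]]), integer(1))
    junction_records(
      case_id = vapply(fields, `[[`, character(1), 4),
      chromosome = vapply(fields, `[[`, character(1), 1),
      donor_end = cs,            # 0-based intron start = last exonic base
      acceptor_start = ce + 1L,  # half-open intron end + 1 = next exon start
      read_count = vapply(fields, function(f) as.integer(f[[5]]), integer(1)))
  }
}

#' Write a junction table
#' @param junctions A [junction_records()] data frame.
#' @param path Output path.
#' @param format `"tsv"` (internal 1-based dialect) or `"bed"` (0-based
#'   half-open intron BED6).
#' @export
write_junctions <- function(junctions, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  j <- junctions
  if (format == "tsv") {
    writeLines(c("case_id\tchrom\tdonor_end\tacceptor_start\treads",
                 paste(j$case_id, j$chromosome, j$donor_end,
                       j$acceptor_start, j$read_count, sep = "\t")),
               path)
  } else {
    writeLines(paste(j$chromosome, j$donor_end, j$acceptor_start - 1L,
                     j$case_id, j$read_count, ".", sep = "\t"),
               path)
  }
  invisible(path)
}

#' Detect exon skipping from junction evidence
#'
#' A junction whose ends land on the boundaries of two non-adjacent exons
#' of the same gene, with read support at or above `min_coverage`, is
#' called a skipping event covering every exon strictly between the two.
#' Exon indices are strand-aware transcript ordinals, so "exon 4" is the
#' fourth transcribed exon on either strand. Junctions joining adjacent
#' exons are canonical splices; junctions matching no exon-boundary pair
#' are ignored and tallied in the `unmatched` attribute. Whether two skips
#' in the same case lie on one molecule is not inferable from junction
#' counts, so co-occurring events per case are summarized in the
#' `cooccurring` attribute with phase flagged unknown.
#'
#' @param junctions A [junction_records()] data frame.
#' @param exons An [exon_table()].
#' @param min_coverage Minimum junction read support, default 4 (the
#'   routine Sashimi-plot screening threshold).
#' @param slack Integer tolerance for boundary matching, default 0.
#' @return Data frame of class `skipping_events`: `case_id`, `gene`,
#'   `skipped_exons` (comma-joined indices), `supporting_reads`,
#'   `flank_upstream`, `flank_downstream` (transcript order); attributes
#'   `unmatched` (count) and `cooccurring` (per case/gene with > 1 event,
#'   `phase = "unknown"`).
#' @export
detect_exon_skipping <- function(junctions, exons, min_coverage = 4,
                                 slack = 0) {
  if (min_coverage < 1) stop("min_coverage must be >= 1")
  ex_chrom <- norm_chrom(exons$chromosome)
  rows <- list()
  unmatched <- 0L
  for (i in seq_len(nrow(junctions))) {
    jn <- junctions[i, ]
    if (jn$read_count < min_coverage) next
    on_chrom <- which(ex_chrom == norm_chrom(jn$chromosome))
    u <- on_chrom[abs(exons$stop[on_chrom] - jn$donor_end) <= slack]
    d <- on_chrom[abs(exons$start[on_chrom] - jn$acceptor_start) <= slack]
    hit <- FALSE
    for (iu in u) for (id in d) {
      if (exons$gene[iu] != exons$gene[id]) next
      tu <- exons$exon_index[iu]   # exon ending at the donor side
      td <- exons$exon_index[id]   # exon starting at the acceptor side
      # on '+' transcript order follows the genome; on '-' it is reversed,
      # so the acceptor-side exon is the transcript-upstream flank
      first <- if (exons$strand[iu] == "+") tu else td
      second <- if (exons$strand[iu] == "+") td else tu
      if (second <= first) next         # direction inconsistent with strand
      hit <- TRUE
      if (second == first + 1L) next    # canonical splice
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = jn$case_id, gene = exons$gene[iu],
        skipped_exons = paste(seq(first + 1L, second - 1L), collapse = ","),
        supporting_reads = jn$read_count,
        flank_upstream = first, flank_downstream = second,
        stringsAsFactors = FALSE)
    }
    if (!hit) unmatched <- unmatched + 1L
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(case_id = character(0), gene = character(0),
                         skipped_exons = character(0),
                         supporting_reads = integer(0),
                         flank_upstream = integer(0),
                         flank_downstream = integer(0),
                         stringsAsFactors = FALSE)
  out <- out[order(out$case_id, out$gene, out$flank_upstream,
                   out$flank_downstream), , drop = FALSE]
  rownames(out) <- NULL
  co <- unique(out[, c("case_id", "gene")])
  co$n_events <- mapply(function(cs, g)
    sum(out$case_id == cs & out$gene == g), co$case_id, co$gene)
  co <- co[co$n_events > 1, , drop = FALSE]
  if (nrow(co)) co$phase <- "unknown"
  rownames(co) <- NULL
  structure(out, unmatched = unmatched, cooccurring = co,
            class = c("skipping_events", "data.frame"))
}

#' Write a skipping-event report
#' @param events A `skipping_events` data frame.
#' @param path Output path.
#' @export
write_skipping_report <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
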