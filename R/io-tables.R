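# GFF-like ORF tables and the truth ledger: plain tab-separated text,
# Unix newlines, bit-stable writers.

#' Write an ORF table (GFF-like TSV)
#'
#' Columns: seqid, source, type=CDS, start, end, score, strand, frame,
#' attributes.  Only `locus_tag=` (and `product=` when present) is written
#' into the attribute column; coordinates are 1-based inclusive.
#'
#' @param orfs data.frame with contig_id, locus_tag, start, end, strand,
#'   optionally product
#' @param path output path
#' @return `path`, invisibly
#' @export
write_orf_table <- function(orfs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(orfs)) {
    attrs <- paste0("locus_tag=", orfs$locus_tag)
    if (!is.null(orfs$product))
      attrs <- paste0(attrs, ";product=", gsub("[;\t]", " ", orfs$product))
    writeLines(paste(orfs$contig_id, "ventcomp", "CDS",
                     orfs$start, orfs$end, ".", orfs$strand, "0", attrs,
                     sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read an ORF table written by [write_orf_table()]
#'
#' @param path file path
#' @return data.frame with contig_id, locus_tag, start, end, strand,
#'   product (NA when absent)
#' @export
read_orf_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(contig_id = character(0), locus_tag = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), product = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad))
    stop(sprintf("%s:%d: expected 9 tab-separated columns", path, bad[1L]))
  m <- do.call(rbind, parts)
  tag <- sub(".*locus_tag=([^;]+).*", "\\1", m[, 9L])
  prod <- ifelse(grepl("product=", m[, 9L]),
                 sub(".*product=([^;]+).*", "\\1", m[, 9L]), NA_character_)
  data.frame(
    contig_id = m[, 1L], locus_tag = tag,
    start = as.integer(m[, 4L]), end = as.integer(m[, 5L]),
    strand = m[, 7L], product = prod, stringsAsFactors = FALSE
  )
}

LEDGER_COLUMNS <- c("kind", "locus_tag", "ref_start", "ref_end",
                    "query_start", "query_end", "strand", "aa_identity",
                    "note")

#' Write a truth ledger (TSV with a header of # key=value lines)
#'
#' Coordinates are 1-based inclusive in the file (0-based half-open
#' arithmetic is internal only).
#'
#' @param ledger data.frame in the ledger layout
#' @param path output path
#' @param seed the simulation seed recorded in the header
#' @return `path`, invisibly
#' @export
write_ledger <- function(ledger, path, seed = NA_integer_) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# seed=%s", seed),
               paste0("# ", paste(LEDGER_COLUMNS, collapse = "\t"))),
             con, sep = "\n")
  if (nrow(ledger)) {
    fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
    writeLines(paste(fmt(ledger$kind), fmt(ledger$locus_tag),
                     fmt(ledger$ref_start), fmt(ledger$ref_end),
                     fmt(ledger$query_start), fmt(ledger$query_end),
                     fmt(ledger$strand),
                     ifelse(is.na(ledger$aa_identity), ".",
                            sprintf("%.4f", ledger$aa_identity)),
                     fmt(ledger$note), sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read a truth ledger written by [write_ledger()]
#' @param path file path
#' @return data.frame in the ledger layout with a `seed` attribute
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  seed <- NA_integer_
  sl <- grep("^# seed=", lines, value = TRUE)
  if (length(sl)) seed <- suppressWarnings(as.integer(sub("^# seed=", "", sl[1L])))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    df <- empty_ledger()
    attr(df, "seed") <- seed
    return(df)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(LEDGER_COLUMNS))
  if (length(bad))
    stop(sprintf("%s:%d: malformed ledger row", path, bad[1L]))
  m <- do.call(rbind, parts)
  num <- function(x) suppressWarnings(as.integer(ifelse(x == ".", NA, x)))
  df <- data.frame(
    kind = m[, 1L],
    locus_tag = ifelse(m[, 2L] == ".", NA_character_, m[, 2L]),
    ref_start = num(m[, 3L]), ref_end = num(m[, 4L]),
    query_start = num(m[, 5L]), query_end = num(m[, 6L]),
    strand = ifelse(m[, 7L] == ".", NA_character_, m[, 7L]),
    aa_identity = suppressWarnings(as.numeric(ifelse(m[, 8L] == ".", NA, m[, 8L]))),
    note = ifelse(m[, 9L] == ".", NA_character_, m[, 9L]),
    stringsAsFactors = FALSE
  )
  attr(df, "seed") <- seed
  df
}

#' @rdname read_ledger
#' @export
empty_ledger <- function() {
  data.frame(kind = character(0), locus_tag = character(0),
             ref_start = integer(0), ref_end = integer(0),
             query_start = integer(0), query_end = integer(0),
             strand = character(0), aa_identity = numeric(0),
             note = character(0), stringsAsFactors = FALSE)
}

# generic TSV writer used by report stages (deterministic bytes)
.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col))
        ifelse(is.na(col), "NA", format(col, digits = 10, scientific = TRUE,
                                        trim = TRUE))
      else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}
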