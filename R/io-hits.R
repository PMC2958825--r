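# The 12/13-column tabular alignment-hit dialect (BLAST -outfmt 6 plus an
# optional frame column), the lingua franca between search and every
# downstream stage.

HIT_COLUMNS <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_openings",
                 "q_start", "q_end", "s_start", "s_end",
                 "e_value", "bit_score")

#' An empty alignment-hit table
#' @param frame include the 13th (frame) column
#' @return zero-row data.frame in the tabular hit layout
#' @export
empty_hits <- function(frame = FALSE) {
  df <- data.frame(
    query_id = character(0), subject_id = character(0),
    percent_identity = numeric(0), alignment_length = integer(0),
    mismatches = integer(0), gap_openings = integer(0),
    q_start = integer(0), q_end = integer(0),
    s_start = integer(0), s_end = integer(0),
    e_value = numeric(0), bit_score = numeric(0),
    stringsAsFactors = FALSE
  )
  if (frame) df$frame <- integer(0)
  df
}

.validate_hits <- function(df, where = "hits") {
  if (nrow(df) == 0L) return(df)
  if (any(df$percent_identity < 0 | df$percent_identity > 100))
    stop(where, ": percent_identity outside [0, 100]")
  if (any(df$alignment_length < 1L)) stop(where, ": alignment_length < 1")
  if (any(df$e_value < 0)) stop(where, ": negative e_value")
  df
}

#' Read a tabular alignment-hit file
#'
#' Accepts 12 or 13 tab-separated columns (13th = frame for translated
#' hits).  E-values in scientific notation are parsed, including the bare
#' `e-100` shorthand some tools emit.  A wrong column count is an error
#' carrying the file and line number.
#'
#' @param path file path
#' @return data.frame in the tabular hit layout
#' @export
read_hits_tabular <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  bad <- which(ncols != 12L & ncols != 13L)
  if (length(bad))
    stop(sprintf("%s:%d: expected 12 or 13 tab-separated columns, found %d",
                 path, bad[1L], ncols[bad[1L]]))
  has_frame <- any(ncols == 13L)
  m <- matrix("", nrow = length(parts), ncol = max(ncols))
  for (i in seq_along(parts)) m[i, seq_len(ncols[i])] <- parts[[i]]
  ev <- m[, 11L]
  ev[grepl("^e", ev)] <- paste0("1", ev[grepl("^e", ev)]) # bare "e-100"
  num <- function(j, what) {
    x <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(x))
      stop(sprintf("%s:%d: non-numeric %s", path, which(is.na(x))[1L], what))
    x
  }
  df <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    percent_identity = num(3L, "percent identity"),
    alignment_length = as.integer(num(4L, "alignment length")),
    mismatches = as.integer(num(5L, "mismatch count")),
    gap_openings = as.integer(num(6L, "gap openings")),
    q_start = as.integer(num(7L, "q_start")),
    q_end = as.integer(num(8L, "q_end")),
    s_start = as.integer(num(9L, "s_start")),
    s_end = as.integer(num(10L, "s_end")),
    e_value = { x <- suppressWarnings(as.numeric(ev))
                if (anyNA(x)) stop(sprintf("%s:%d: unparseable E-value",
                                           path, which(is.na(x))[1L]))
                x },
    bit_score = num(12L, "bit score"),
    stringsAsFactors = FALSE
  )
  if (has_frame) {
    fr <- suppressWarnings(as.integer(m[, 13L]))
    fr[ncols == 12L] <- NA_integer_
    df$frame <- fr
  }
  .validate_hits(df, path)
}

#' Write a tabular alignment-hit file
#'
#' Identities are written with two decimals, bit scores with one, and
#' E-values with two significant digits, matching common tabular output.
#'
#' @param hits data.frame in the tabular hit layout
#' @param path output path
#' @return `path`, invisibly
#' @export
write_hits_tabular <- function(hits, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(hits) == 0L) return(invisible(path))
  fields <- cbind(
    hits$query_id, hits$subject_id,
    sprintf("%.2f", hits$percent_identity),
    format(hits$alignment_length, scientific = FALSE, trim = TRUE),
    format(hits$mismatches, scientific = FALSE, trim = TRUE),
    format(hits$gap_openings, scientific = FALSE, trim = TRUE),
    format(hits$q_start, scientific = FALSE, trim = TRUE),
    format(hits$q_end, scientific = FALSE, trim = TRUE),
    format(hits$s_start, scientific = FALSE, trim = TRUE),
    format(hits$s_end, scientific = FALSE, trim = TRUE),
    .format_evalue(hits$e_value),
    sprintf("%.1f", hits$bit_score)
  )
  if (!is.null(hits$frame)) fields <- cbind(fields, as.character(hits$frame))
  writeLines(apply(fields, 1L, paste, collapse = "\t"), con, sep = "\n")
  invisible(path)
}

.format_evalue <- function(e) {
  out <- sprintf("%.1e", e)
  out[e == 0] <- "0.0e+00"
  out
}
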