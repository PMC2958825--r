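# FASTA reading and writing with strict validation.
#
# Sequence sets travel through the package as named uppercase character
# vectors (names = record ids) with a "descriptions" attribute holding any
# free text after the id.  Files at the scale this package targets (a few
# Mb of Sanger-style data) read comfortably through readLines().

#' Read a FASTA file
#'
#' Ids must be unique; sequence characters must be IUPAC nucleotide or
#' amino-acid codes (either alphabet is accepted, validation is per
#' character).  Lowercase input is normalized to uppercase.  Malformed
#' lines raise an error naming the file and line number.  An empty file
#' yields an empty vector.
#'
#' @param path file path
#' @return named character vector of sequences, with a `descriptions`
#'   attribute
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L)
    return(structure(character(0), descriptions = character(0)))
  hdr <- startsWith(lines, ">")
  if (!hdr[1L] && any(nzchar(trimws(lines))))
    stop(sprintf("%s:1: expected a '>' header line", path))
  bad <- which(!hdr & grepl("[^A-Za-z*.-]", lines))
  if (length(bad))
    stop(sprintf("%s:%d: illegal sequence character", path, bad[1L]))
  ids_raw <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids_raw)
  desc <- ifelse(grepl("\\s", ids_raw),
                 sub("^\\S+\\s+", "", ids_raw), "")
  empty_id <- which(!nzchar(ids))
  if (length(empty_id))
    stop(sprintf("%s:%d: empty record id", path, which(hdr)[empty_id[1L]]))
  if (anyDuplicated(ids))
    stop(path, ": duplicate record id: ", ids[duplicated(ids)][1L])
  grp <- cumsum(hdr)
  body <- !hdr
  seqs <- vapply(seq_along(ids), function(i) {
    .collapse(lines[body & grp == i])
  }, character(1))
  seqs <- toupper(gsub("[ \t]", "", seqs))
  structure(stats::setNames(seqs, ids), descriptions = stats::setNames(desc, ids))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences (uppercase enforced)
#' @param path output path
#' @param wrap line width for sequence lines (default 60)
#' @param descriptions optional named character vector of header free text
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, wrap = 60L, descriptions = NULL) {
  stopifnot(is.character(seqs))
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("write_fasta() requires non-empty names on `seqs`")
  if (anyDuplicated(ids)) stop("duplicate record id: ", ids[duplicated(ids)][1L])
  if (is.null(descriptions)) descriptions <- attr(seqs, "descriptions")
  con <- file(path, open = "wb") # binary: byte-stable Unix newlines
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    d <- if (!is.null(descriptions)) descriptions[[ids[i]]] %||% "" else ""
    hdr <- if (nzchar(d)) paste0(">", ids[i], " ", d) else paste0(">", ids[i])
    s <- toupper(seqs[[i]])
    n <- nchar(s)
    starts <- if (n > 0L) seq.int(1L, n, by = wrap) else integer(0)
    writeLines(c(hdr, substring(s, starts, pmin(starts + wrap - 1L, n))),
               con, sep = "\n")
  }
  invisible(path)
}
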