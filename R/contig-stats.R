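# Per-contig characterization: length, fold coverage from assembly read
# membership, GC, and best reference-protein hit class.

EVALUE_TIERS <- c(1e-100, 1e-50, 1e-10)

.evalue_class <- function(e) {
  ifelse(is.na(e), "none",
  ifelse(e < 1e-100, "<1e-100",
  ifelse(e < 1e-50, "<1e-50",
  ifelse(e < 1e-10, "<1e-10", "none"))))
}

#' Per-contig statistics table
#'
#' One row per contig: length, GC, fold coverage (summed member-read bp
#' divided by contig length -- the assembly-membership definition, not
#' alignment depth), member read count, and best reference-protein E-value
#' with its tier class under strict thresholds 1e-100 / 1e-50 / 1e-10.
#'
#' @param contigs named character vector of contig sequences
#' @param membership data.frame with `read_id`, `contig_id` (NA for
#'   unassembled reads) and `read_length`; may be NULL, in which case
#'   coverage is NA
#' @param hits data.frame of translated-search hits of reference proteins
#'   vs contigs (`subject_id` = contig id); may be NULL
#' @return data.frame of class `contig_stats`
#' @export
contig_table <- function(contigs, membership = NULL, hits = NULL) {
  ids <- names(contigs)
  stopifnot(!is.null(ids))
  len <- nchar(contigs)
  gc <- vapply(contigs, function(s) gc_content(s)$gc_fraction, numeric(1))
  n_reads <- rep(NA_integer_, length(ids))
  cov <- rep(NA_real_, length(ids))
  if (!is.null(membership) && nrow(membership)) {
    if (is.null(membership$read_length) || anyNA(membership$read_length))
      stop("membership table must carry read_length for every member read")
    mm <- membership[!is.na(membership$contig_id), , drop = FALSE]
    cnt <- tapply(mm$read_id, mm$contig_id, length)
    bp <- tapply(mm$read_length, mm$contig_id, sum)
    n_reads <- as.integer(cnt[ids]); n_reads[is.na(n_reads)] <- 0L
    bp_v <- as.numeric(bp[ids]); bp_v[is.na(bp_v)] <- 0
    cov <- bp_v / len
  }
  best_e <- rep(NA_real_, length(ids))
  if (!is.null(hits) && nrow(hits)) {
    be <- tapply(hits$e_value, hits$subject_id, min)
    best_e <- as.numeric(be[ids])
  }
  out <- data.frame(
    contig_id = ids, length = unname(len), coverage = unname(cov),
    gc = unname(gc), n_member_reads = unname(n_reads),
    best_evalue = unname(best_e),
    evalue_class = .evalue_class(unname(best_e)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("contig_stats", "data.frame")
  out
}

#' Count contigs above size thresholds
#'
#' Strict greater-than, as in "contigs >7 kb".
#'
#' @param stats a [contig_table()] result (or any frame with `length`)
#' @param thresholds bp thresholds (default 7000 and 10000)
#' @return named integer vector of counts
#' @export
size_filter_report <- function(stats, thresholds = c(7000L, 10000L)) {
  vapply(thresholds, function(t) sum(stats$length > t), integer(1)) |>
    setNames(paste0(">", thresholds))
}
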