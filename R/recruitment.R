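# Fragment-recruitment profiling: reads vs reference genome, binned by
# percent identity, coverage = aligned bp per bin / reference length.

#' Build a fragment-recruitment profile
#'
#' Each read contributes only its best hit (lowest E-value, ties broken by
#' highest bit score).  Hits with alignment length not exceeding
#' `min_alignment_length` are excluded (strictly greater-than, so a hit of
#' exactly the threshold length is dropped).  The surviving read is binned
#' by its hit's percent identity into 1-point bins `[k, k+1)` over
#' `range_pct`, with 100% falling in the top bin, and the bin's aligned bp
#' is incremented by the alignment length.
#'
#' @param hits data.frame in the tabular hit layout (reads vs reference)
#' @param reference_length reference genome length in bp
#' @param min_alignment_length exclusion threshold in bp (default 500,
#'   strict)
#' @param n_reads_total total reads searched; defaults to the number of
#'   distinct query ids in `hits`
#' @param bin_width identity bin width in percentage points (default 1)
#' @param range_pct identity range covered by the bins (default c(50, 100))
#' @param read_manifest optional character vector of all read ids; hits
#'   naming unknown reads raise a consistency error
#' @return object of class `recruitment_profile`: a list with `bins`
#'   (data.frame: bin_lo, bin_hi, aligned_bp, coverage), counts and
#'   parameters
#' @export
recruit <- function(hits, reference_length, min_alignment_length = 500L,
                    n_reads_total = NULL, bin_width = 1,
                    range_pct = c(50, 100), read_manifest = NULL) {
  stopifnot(reference_length > 0)
  if (!is.null(read_manifest)) {
    unknown <- setdiff(unique(hits$query_id), read_manifest)
    if (length(unknown))
      stop("hits reference unknown reads: ", paste(head(unknown, 3), collapse = ", "))
    n_reads_total <- n_reads_total %||% length(read_manifest)
  }
  n_reads_total <- n_reads_total %||% length(unique(hits$query_id))
  edges <- seq(range_pct[1L], range_pct[2L], by = bin_width)
  bins <- data.frame(bin_lo = head(edges, -1L), bin_hi = edges[-1L],
                     aligned_bp = 0, coverage = 0)
  kept <- hits[hits$alignment_length > min_alignment_length, , drop = FALSE]
  n_recruited <- 0L
  if (nrow(kept)) {
    ord <- order(kept$e_value, -kept$bit_score)
    kept <- kept[ord, , drop = FALSE]
    best <- kept[!duplicated(kept$query_id), , drop = FALSE]
    n_recruited <- nrow(best)
    idx <- findInterval(best$percent_identity, edges,
                        rightmost.closed = TRUE) # 100% -> top bin
    ok <- idx >= 1L & idx <= nrow(bins)
    agg <- tapply(best$alignment_length[ok], idx[ok], sum)
    bins$aligned_bp[as.integer(names(agg))] <- as.numeric(agg)
    bins$coverage <- bins$aligned_bp / reference_length
  }
  structure(list(
    bins = bins,
    reference_length = reference_length,
    min_alignment_length = min_alignment_length,
    n_reads_recruited = n_recruited,
    n_reads_total = n_reads_total
  ), class = "recruitment_profile")
}

#' Fraction of reads recruited, as a percentage
#' @param profile a [recruit()] result
#' @return percentage of total reads with a qualifying alignment
#' @export
recruited_fraction <- function(profile) {
  stopifnot(inherits(profile, "recruitment_profile"))
  if (profile$n_reads_total == 0L)
    stop("recruited fraction undefined: zero total reads")
  100 * profile$n_reads_recruited / profile$n_reads_total
}

#' Identity bin with the most aligned bp
#' @param profile a [recruit()] result
#' @return named numeric: lower and upper edge of the modal bin
#' @export
modal_bin <- function(profile) {
  b <- profile$bins
  i <- which.max(b$aligned_bp)
  c(bin_lo = b$bin_lo[i], bin_hi = b$bin_hi[i])
}

#' @export
print.recruitment_profile <- function(x, ...) {
  cat("Fragment-recruitment profile\n")
  cat(sprintf("  reference length: %d bp\n", x$reference_length))
  cat(sprintf("  reads recruited:  %d / %d (%.1f%%), alignments > %d bp\n",
              x$n_reads_recruited, x$n_reads_total,
              if (x$n_reads_total) 100 * x$n_reads_recruited / x$n_reads_total else 0,
              x$min_alignment_length))
  nz <- x$bins[x$bins$aligned_bp > 0, ]
  if (nrow(nz)) {
    m <- modal_bin(x)
    cat(sprintf("  occupied bins:    %d (identity %.0f-%.0f%%), modal bin [%g,%g) at %.3fx\n",
                nrow(nz), min(nz$bin_lo), max(nz$bin_hi), m[1L], m[2L],
                max(x$bins$coverage)))
  }
  invisible(x)
}

#' Write a recruitment profile as TSV
#' @param profile a [recruit()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_recruitment_profile <- function(profile, path) {
  .write_tsv(profile$bins, path)
}

#' Plot a recruitment profile (identity vs coverage bars)
#' @param x a [recruit()] result
#' @param ... passed to [graphics::barplot()]
#' @export
plot.recruitment_profile <- function(x, ...) {
  b <- x$bins
  graphics::barplot(b$coverage, names.arg = b$bin_lo, space = 0,
                    xlab = "nucleotide identity (%)",
                    ylab = "coverage (aligned bp / reference bp)", ...)
}
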