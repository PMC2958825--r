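# Mate-pair linkage of large contigs to transposase-bearing sequences,
# and transposase spacing estimates.

#' Flag sequences carrying a transposase
#'
#' A read or contig is flagged when any hit of the transposase protein
#' set against it meets the E-value cutoff.
#'
#' @param seq_ids ids of the sequences that were searched
#' @param transposase_hits translated-search hit table (transposase
#'   proteins vs the sequences; `subject_id` = sequence id)
#' @param evalue_cutoff strict threshold (default 1e-10)
#' @return character vector of flagged ids
#' @export
classify_transposase_sequences <- function(seq_ids, transposase_hits,
                                           evalue_cutoff = 1e-10) {
  if (is.null(transposase_hits) || nrow(transposase_hits) == 0L)
    return(character(0))
  flagged <- unique(transposase_hits$subject_id[
    transposase_hits$e_value < evalue_cutoff])
  intersect(seq_ids, flagged)
}

#' Mate-pair linkage of large contigs to transposase sequences
#'
#' For each contig longer than `threshold` (strict), a member read is
#' "linked" when its clone mate is a flagged transposase-bearing sequence
#' (the mate may be unassembled or belong to any contig, including the
#' same one); a contig is linked when at least one member read is linked.
#' Mates absent from the read universe count as unlinked.
#'
#' @param membership data.frame with `read_id`, `contig_id` (NA =
#'   unassembled), `read_length`
#' @param clone_pairs the `pairs` data.frame from [pair_reads()]
#' @param flagged_ids ids (reads and/or contigs) carrying a transposase,
#'   from [classify_transposase_sequences()]; a contig id in this set
#'   marks the contig as itself encoding a transposase
#' @param stats a [contig_table()] result (for contig lengths)
#' @param threshold large-contig size in bp (default 10000, strict)
#' @param count_same_contig_mates count a flagged mate lying in the same
#'   large contig (default TRUE)
#' @return object of class `linkage_report`
#' @export
link_contigs <- function(membership, clone_pairs, flagged_ids, stats,
                         threshold = 10000L, count_same_contig_mates = TRUE) {
  mates <- mate_map(clone_pairs)
  large <- stats[stats$length > threshold, , drop = FALSE]
  contig_of <- setNames(membership$contig_id, membership$read_id)
  per <- lapply(seq_len(nrow(large)), function(i) {
    cid <- large$contig_id[i]
    members <- membership$read_id[!is.na(membership$contig_id) &
                                    membership$contig_id == cid]
    mt <- mates[members]
    linked <- !is.na(mt) & mt %in% flagged_ids
    if (!count_same_contig_mates) {
      same <- !is.na(mt) & !is.na(contig_of[mt]) & contig_of[mt] == cid
      linked <- linked & !same
    }
    data.frame(contig_id = cid, length = large$length[i],
               n_member_reads = length(members),
               n_linked_reads = sum(linked),
               encodes_transposase = cid %in% flagged_ids,
               stringsAsFactors = FALSE)
  })
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(contig_id = character(0), length = integer(0),
               n_member_reads = integer(0), n_linked_reads = integer(0),
               encodes_transposase = logical(0), stringsAsFactors = FALSE)
  n_member_total <- sum(per$n_member_reads)
  n_linked_total <- sum(per$n_linked_reads)
  structure(list(
    per_contig = per,
    large_contig_threshold = threshold,
    n_large_contigs = nrow(per),
    n_linked_contigs = sum(per$n_linked_reads > 0L),
    n_member_reads_total = n_member_total,
    n_linked_reads_total = n_linked_total,
    linked_read_percent = if (n_member_total > 0L)
      round(100 * n_linked_total / n_member_total, 1L) else NA_real_
  ), class = "linkage_report")
}

#' Transposase spacing estimate from a linkage report
#'
#' Under the conservative one-transposase-per-linked-contig assumption,
#' the spacing is the summed length of linked contigs (kb) divided by the
#' number of linked contigs, rounded to integer kb (the unrounded value is
#' kept alongside).  Supplying a reference transposase count and genome
#' length adds the reference spacing for comparison.
#'
#' @param report a [link_contigs()] result
#' @param reference_length_bp,reference_transposase_count optional
#'   reference genome figures
#' @return list with `kb_per_transposase`, `kb_per_transposase_unrounded`,
#'   `n_linked_contigs`, `linked_kb`, and (when supplied)
#'   `reference_kb_per_transposase`
#' @export
density_estimate <- function(report, reference_length_bp = NULL,
                             reference_transposase_count = NULL) {
  stopifnot(inherits(report, "linkage_report"))
  linked <- report$per_contig[report$per_contig$n_linked_reads > 0L, , drop = FALSE]
  if (nrow(linked) == 0L)
    stop("density undefined: no linked contigs")
  kb <- sum(linked$length) / 1000
  out <- list(
    kb_per_transposase = round(kb / nrow(linked)),
    kb_per_transposase_unrounded = kb / nrow(linked),
    n_linked_contigs = nrow(linked),
    linked_kb = kb
  )
  if (!is.null(reference_length_bp) && !is.null(reference_transposase_count)) {
    out$reference_kb_per_transposase <-
      round(reference_length_bp / 1000 / reference_transposase_count)
  }
  out
}

#' @export
print.linkage_report <- function(x, ...) {
  cat("Mate-pair transposase linkage\n")
  cat(sprintf("  large contigs (> %d bp): %d, of which linked: %d\n",
              x$large_contig_threshold, x$n_large_contigs, x$n_linked_contigs))
  cat(sprintf("  member reads: %d, linked to a transposase sequence: %d (%.1f%%)\n",
              x$n_member_reads_total, x$n_linked_reads_total,
              x$linked_read_percent))
  invisible(x)
}
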