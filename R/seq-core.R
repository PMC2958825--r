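# Elementary sequence computations: GC content, translation, ORF finding.

#' GC content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T).  IUPAC ambiguity codes (N and
#' friends) are excluded from both numerator and denominator.  An empty or
#' all-ambiguous sequence yields `gc_fraction = NA` with
#' `counted_bases = 0` rather than an error.
#'
#' @param seq a single nucleotide string
#' @return a list with `gc_fraction` and `counted_bases`
#' @export
#' @examples
#' gc_content("ATGC")$gc_fraction # 0.5
#' gc_content("ANGC")             # 2/3 over 3 counted bases
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!.is_nucleotide(seq))
    stop("gc_content() expects a nucleotide sequence (IUPAC codes)")
  codes <- .dna_lookup()[as.integer(charToRaw(seq)) + 1L]
  n_gc <- sum(codes == 1L | codes == 2L)
  n_at <- sum(codes == 0L | codes == 3L)
  counted <- n_gc + n_at
  list(
    gc_fraction = if (counted == 0L) NA_real_ else n_gc / counted,
    counted_bases = counted
  )
}

#' Translate a nucleotide sequence in a given frame
#'
#' Standard genetic code; stops are rendered `*`; start codons are not
#' special-cased (M only for ATG).  Frames -1..-3 translate the reverse
#' complement.  A trailing partial codon is dropped; codons containing
#' ambiguity codes translate to `X`.
#'
#' @param seq a single nucleotide string
#' @param frame integer in -3..-1, 1..3
#' @return the amino-acid string
#' @export
#' @examples
#' translate("ATGAAATAG")            # "MK*"
#' translate("ATGAAATAG", frame = -1)
translate <- function(seq, frame = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  frame <- as.integer(frame)
  if (is.na(frame) || frame == 0L || frame > 3L || frame < -3L)
    stop("frame must be in -3..-1 or 1..3")
  seq <- toupper(seq)
  if (frame < 0L) {
    seq <- revcomp(seq)
    frame <- -frame
  }
  n <- nchar(seq)
  if (n < frame + 2L) return("")
  s <- substr(seq, frame, n)
  ncod <- nchar(s) %/% 3L
  if (ncod == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = ncod)
  codons <- substring(s, starts, starts + 2L)
  aa <- .genetic_code()[codons]
  aa[is.na(aa)] <- "X"
  .collapse(aa)
}

#' Find open reading frames on both strands
#'
#' Maximal ATG-to-stop spans in all six frames with span length (including
#' the stop codon) at least `min_length_bp`.  Calls on the same strand
#' whose spans overlap by more than `max_overlap_bp` are resolved by
#' keeping the longer call (ties keep the leftmost start).  Coordinates
#' are 1-based inclusive on the forward strand.
#'
#' @param seq a single nucleotide string
#' @param min_length_bp minimum ORF span in bp (default 300)
#' @param contig_id sequence id recorded in the output
#' @param max_overlap_bp same-strand overlap tolerated before the shorter
#'   call is dropped (default 30)
#' @return a data.frame with columns `contig_id`, `locus_tag`, `start`,
#'   `end`, `strand`, `translation`
#' @export
find_orfs <- function(seq, min_length_bp = 300L, contig_id = "seq",
                      max_overlap_bp = 30L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- list()
  stops_set <- c("TAA", "TAG", "TGA")

  scan_strand <- function(s, strand) {
    ns <- nchar(s)
    res <- list()
    for (frame in 1:3) {
      ncod <- (ns - frame + 1L) %/% 3L
      if (ncod < 2L) next
      starts <- seq.int(frame, by = 3L, length.out = ncod)
      codons <- substring(s, starts, starts + 2L)
      is_stop <- codons %in% stops_set
      is_atg <- codons == "ATG"
      # segment boundaries: positions after each stop start a fresh segment
      seg <- cumsum(c(TRUE, utils::head(is_stop, -1L)))
      for (g in split(seq_len(ncod), seg)) {
        last <- g[length(g)]
        if (!is_stop[last]) next           # open segment, no stop: skip
        atg <- g[is_atg[g]]
        atg <- atg[atg < last]
        if (length(atg) == 0L) next
        a <- atg[1L]                       # maximal span: first ATG
        span_start <- starts[a]
        span_end <- starts[last] + 2L
        if (span_end - span_start + 1L < min_length_bp) next
        res[[length(res) + 1L]] <- c(span_start, span_end)
      }
    }
    if (length(res) == 0L) return(NULL)
    m <- do.call(rbind, res)
    data.frame(start = m[, 1L], end = m[, 2L], strand = strand)
  }

  fwd <- scan_strand(seq, "+")
  rc <- revcomp(seq)
  rev_ <- scan_strand(rc, "-")
  if (!is.null(rev_) && nrow(rev_)) {
    # map reverse-strand coordinates back to the forward strand
    s2 <- n - rev_$end + 1L
    e2 <- n - rev_$start + 1L
    rev_$start <- s2
    rev_$end <- e2
  }
  orfs <- rbind(fwd, rev_)
  if (is.null(orfs) || nrow(orfs) == 0L) {
    return(data.frame(contig_id = character(0), locus_tag = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), translation = character(0),
                      stringsAsFactors = FALSE))
  }
  # same-strand overlap resolution: keep the longer (tie -> leftmost)
  keep <- rep(TRUE, nrow(orfs))
  len <- orfs$end - orfs$start + 1L
  ord <- order(-len, orfs$start)
  for (strand in c("+", "-")) {
    idx <- ord[orfs$strand[ord] == strand]
    taken <- matrix(numeric(0), ncol = 2L)
    for (i in idx) {
      if (nrow(taken)) {
        ov <- pmin(taken[, 2L], orfs$end[i]) - pmax(taken[, 1L], orfs$start[i]) + 1L
        if (any(ov > max_overlap_bp)) { keep[i] <- FALSE; next }
      }
      taken <- rbind(taken, c(orfs$start[i], orfs$end[i]))
    }
  }
  orfs <- orfs[keep, , drop = FALSE]
  orfs <- orfs[order(orfs$start, orfs$end), , drop = FALSE]
  tr <- vapply(seq_len(nrow(orfs)), function(i) {
    sub <- substr(seq, orfs$start[i], orfs$end[i])
    if (orfs$strand[i] == "-") sub <- revcomp(sub)
    p <- translate(sub, 1L)
    sub("\\*$", "", p)
  }, character(1))
  data.frame(
    contig_id = contig_id,
    locus_tag = sprintf("%s_orf%04d", contig_id, seq_len(nrow(orfs))),
    start = orfs$start, end = orfs$end, strand = orfs$strand,
    translation = tr, stringsAsFactors = FALSE, row.names = NULL
  )
}
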