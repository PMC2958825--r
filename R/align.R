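# Self-contained seeded local alignment: exact word seeds, ungapped X-drop
# triage, then banded affine-gap Smith-Waterman around the surviving seed
# diagonals.  All results are emitted in the tabular hit layout so an
# external aligner's tabular output can be substituted anywhere downstream.

.align_defaults <- list(
  nucleotide = list(word = 11L, band_pad = 16L, xdrop = 20L, min_ungapped = 16L),
  translated = list(word = 3L, band_pad = 12L, xdrop = 18L, min_ungapped = 40L)
)

# Cluster seeds (matrix qpos, spos) into diagonal bands and run one banded
# alignment per cluster.  Returns raw alignments (list of lists).
.align_encoded <- function(qi, si, scheme, word_size, band_pad, xdrop,
                           min_ungapped, max_sep = NULL) {
  max_sep <- max_sep %||% (length(qi) + 3000L)
  clusters <- cpp_seed_clusters(qi, si, word_size, scheme$alphabet_size,
                                scheme$matrix, band_pad, max_sep, xdrop,
                                min_ungapped)
  out <- list()
  for (k in seq_len(nrow(clusters))) {
    aln <- cpp_banded_sw(qi, si, scheme$matrix, scheme$gap_open,
                         scheme$gap_extend,
                         clusters$dlo[k] - band_pad,
                         clusters$dhi[k] + band_pad)
    if (aln$score > 0L) out[[length(out) + 1L]] <- aln
  }
  out
}

.aln_to_hit <- function(aln, qid, sid, scheme, search_space) {
  bits <- bit_score(aln$score, scheme)
  data.frame(
    query_id = qid, subject_id = sid,
    percent_identity = 100 * aln$matches / aln$columns,
    alignment_length = aln$columns,
    mismatches = aln$mismatches,
    gap_openings = aln$gap_openings,
    q_start = aln$q_start, q_end = aln$q_end,
    s_start = aln$s_start, s_end = aln$s_end,
    e_value = evalue(bits, search_space),
    bit_score = bits,
    raw_score = aln$score,
    stringsAsFactors = FALSE
  )
}

# drop lower-scoring hits whose query AND subject spans substantially
# overlap a better hit (same-diagonal duplicates from adjacent bands)
.dedupe_hits <- function(df, max_frac = 0.5) {
  if (nrow(df) <= 1L) return(df)
  ord <- order(-df$bit_score, pmin(df$s_start, df$s_end), df$q_start)
  df <- df[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  qs <- df$q_start; qe <- df$q_end
  ss <- pmin(df$s_start, df$s_end); se <- pmax(df$s_start, df$s_end)
  for (i in seq_len(nrow(df))[-1L]) {
    prev <- which(keep[seq_len(i - 1L)])
    qov <- pmin(qe[prev], qe[i]) - pmax(qs[prev], qs[i]) + 1L
    sov <- pmin(se[prev], se[i]) - pmax(ss[prev], ss[i]) + 1L
    qlen <- qe[i] - qs[i] + 1L
    slen <- se[i] - ss[i] + 1L
    if (any(qov > max_frac * qlen & sov > max_frac * slen)) keep[i] <- FALSE
  }
  df[keep, , drop = FALSE]
}

#' Seeded local alignment of two sequences
#'
#' Exact word seeds, ungapped X-drop extension, then gapped Smith-Waterman
#' restricted to a band around the surviving seed diagonals.  Nucleotide
#' mode searches both strands; a minus-strand hit is reported with
#' `s_start > s_end`.  Percent identity is computed over alignment columns
#' including gap columns.  Hits with E-value above `evalue_max` are
#' discarded.
#'
#' @param query,subject single sequences (character), or length-1 named
#'   vectors whose names become the reported ids
#' @param scheme a [scoring_scheme()]; defaults to the mode's standard
#'   costs
#' @param word_size exact-seed word length (default 11 nucleotide,
#'   3 translated/protein)
#' @param evalue_max report threshold (default 10)
#' @param search_space effective m x n product; defaults to
#'   `nchar(query) * nchar(subject)`
#' @param mode "nucleotide" or "protein" (protein-vs-protein under the
#'   translated scoring scheme)
#' @return data.frame in the tabular hit layout (plus `raw_score`)
#' @export
seed_extend_align <- function(query, subject, mode = c("nucleotide", "protein"),
                              scheme = NULL, word_size = NULL,
                              evalue_max = 10, search_space = NULL) {
  mode <- match.arg(mode)
  qid <- names(query) %||% "query"
  sid <- names(subject) %||% "subject"
  query <- unname(query); subject <- unname(subject)
  if (nchar(query) == 0L || nchar(subject) == 0L) return(empty_hits())
  if (mode == "nucleotide") {
    scheme <- scheme %||% scoring_scheme("nucleotide")
    defs <- .align_defaults$nucleotide
    word_size <- word_size %||% defs$word
    if (word_size < 4L) stop("nucleotide word_size must be >= 4")
    search_space <- search_space %||% (nchar(query) * nchar(subject))
    qi <- encode_dna(query)
    hits <- list()
    for (strand in c("+", "-")) {
      s <- if (strand == "+") subject else revcomp(subject)
      alns <- .align_encoded(qi, encode_dna(s), scheme, word_size,
                             defs$band_pad, defs$xdrop, defs$min_ungapped)
      n <- nchar(subject)
      for (a in alns) {
        h <- .aln_to_hit(a, qid, sid, scheme, search_space)
        if (strand == "-") {
          h$s_start <- n - a$s_start + 1L
          h$s_end <- n - a$s_end + 1L
        }
        hits[[length(hits) + 1L]] <- h
      }
    }
  } else {
    scheme <- scheme %||% scoring_scheme("translated")
    defs <- .align_defaults$translated
    word_size <- word_size %||% defs$word
    if (word_size < 2L) stop("protein word_size must be >= 2")
    search_space <- search_space %||% (nchar(query) * nchar(subject))
    alns <- .align_encoded(encode_protein(query), encode_protein(subject),
                           scheme, word_size, defs$band_pad, defs$xdrop,
                           defs$min_ungapped)
    hits <- lapply(alns, .aln_to_hit, qid = qid, sid = sid, scheme = scheme,
                   search_space = search_space)
  }
  if (length(hits) == 0L) return(empty_hits())
  df <- do.call(rbind, hits)
  df <- .dedupe_hits(df)
  df <- df[df$e_value <= evalue_max, , drop = FALSE]
  df <- df[order(df$e_value, -df$bit_score, pmin(df$s_start, df$s_end),
                 df$q_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Translated homology search of a protein against a nucleotide sequence
#'
#' The protein is aligned against all six translation frames of the
#' nucleotide subject (BLOSUM62, gap 11/1 by default).  Query coordinates
#' are protein residues; subject coordinates are nucleotides, 1-based,
#' with `s_start > s_end` on minus-strand frames; the frame is recorded in
#' a 13th column.
#'
#' @inheritParams seed_extend_align
#' @param protein single amino-acid sequence (optionally named)
#' @param nucleotide single nucleotide sequence (optionally named)
#' @return data.frame in the 13-column tabular hit layout
#' @export
translated_search <- function(protein, nucleotide, scheme = NULL,
                              word_size = 3L, evalue_max = 10,
                              search_space = NULL) {
  qid <- names(protein) %||% "query"
  sid <- names(nucleotide) %||% "subject"
  protein <- unname(protein); nucleotide <- unname(nucleotide)
  if (.is_nucleotide(protein) && nchar(protein) > 20L)
    warning("query looks like a nucleotide sequence")
  if (nchar(protein) == 0L || nchar(nucleotide) == 0L) return(empty_hits(frame = TRUE))
  scheme <- scheme %||% scoring_scheme("translated")
  defs <- .align_defaults$translated
  search_space <- search_space %||% (nchar(protein) * nchar(nucleotide))
  qi <- encode_protein(protein)
  n <- nchar(nucleotide)
  hits <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    tr <- translate(nucleotide, frame)
    if (nchar(tr) < word_size) next
    alns <- .align_encoded(qi, encode_protein(tr), scheme, word_size,
                           defs$band_pad, defs$xdrop, defs$min_ungapped)
    for (a in alns) {
      h <- .aln_to_hit(a, qid, sid, scheme, search_space)
      f <- abs(frame)
      p1 <- f + 3L * (a$s_start - 1L)
      p2 <- f + 3L * a$s_end - 1L
      if (frame > 0L) {
        h$s_start <- p1; h$s_end <- p2
      } else {
        h$s_start <- n - p1 + 1L
        h$s_end <- n - p2 + 1L
      }
      h$frame <- frame
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0L) return(empty_hits(frame = TRUE))
  df <- do.call(rbind, hits)
  df <- .dedupe_hits(df)
  df <- df[df$e_value <= evalue_max, , drop = FALSE]
  df <- df[order(df$e_value, -df$bit_score, pmin(df$s_start, df$s_end),
                 df$q_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Search a query set against a subject set
#'
#' Batch wrapper emitting one combined hit table.  The search space for
#' E-values is each query's length times the summed subject length, so
#' E-values are comparable across subjects of one database.
#'
#' @param queries,subjects named character vectors of sequences
#' @param mode "nucleotide" (blastn-like), "tblastn" (protein queries vs
#'   six-frame subjects) or "protein" (blastp-like)
#' @param evalue_max report threshold (default 10)
#' @param word_size optional seed word length override
#' @return data.frame in the tabular hit layout
#' @export
search_hits <- function(queries, subjects,
                        mode = c("nucleotide", "tblastn", "protein"),
                        evalue_max = 10, word_size = NULL) {
  mode <- match.arg(mode)
  db_len <- sum(nchar(subjects))
  out <- vector("list", length(queries) * length(subjects))
  k <- 0L
  for (qi in seq_along(queries)) {
    space <- nchar(queries[[qi]]) * db_len
    for (si in seq_along(subjects)) {
      h <- switch(mode,
        nucleotide = seed_extend_align(queries[qi], subjects[si],
                                       mode = "nucleotide",
                                       evalue_max = evalue_max,
                                       word_size = word_size,
                                       search_space = space),
        tblastn = translated_search(queries[qi], subjects[si],
                                    evalue_max = evalue_max,
                                    word_size = word_size %||% 3L,
                                    search_space = space),
        protein = seed_extend_align(queries[qi], subjects[si],
                                    mode = "protein",
                                    evalue_max = evalue_max,
                                    word_size = word_size,
                                    search_space = space))
      if (nrow(h)) { k <- k + 1L; out[[k]] <- h }
    }
  }
  if (k == 0L) return(empty_hits(frame = (mode == "tblastn")))
  df <- do.call(rbind, out[seq_len(k)])
  rownames(df) <- NULL
  df
}

#' Local alignment of two short sequences over the full dynamic-programming
#' matrix
#'
#' Unrestricted (full-band) affine-gap Smith-Waterman; used for
#' direct-repeat searches in flanking windows, where sequences are short
#' and no seed is required.
#'
#' @inheritParams seed_extend_align
#' @return one-row data.frame in the tabular hit layout (plus
#'   `raw_score`), or a zero-row frame when no positive-scoring local
#'   alignment exists
#' @export
local_align <- function(query, subject, mode = c("nucleotide", "protein"),
                        scheme = NULL) {
  mode <- match.arg(mode)
  qid <- names(query) %||% "query"
  sid <- names(subject) %||% "subject"
  query <- unname(query); subject <- unname(subject)
  if (nchar(query) == 0L || nchar(subject) == 0L) return(empty_hits())
  if (mode == "nucleotide") {
    scheme <- scheme %||% scoring_scheme("nucleotide")
    qi <- encode_dna(query); si <- encode_dna(subject)
  } else {
    scheme <- scheme %||% scoring_scheme("translated")
    qi <- encode_protein(query); si <- encode_protein(subject)
  }
  aln <- cpp_banded_sw(qi, si, scheme$matrix, scheme$gap_open,
                       scheme$gap_extend, -(length(qi) - 1L),
                       length(si) - 1L)
  if (is.null(aln$columns) || aln$score <= 0L) return(empty_hits())
  .aln_to_hit(aln, qid, sid, scheme, nchar(query) * nchar(subject))
}
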