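# Synteny anchoring, collinear block segmentation, rearrangement breaks,
# gene-fusion calls, and reverse-orientation foreign-ORF flags.

#' Anchor query ORFs to reference ORFs by best protein hit
#'
#' Each query ORF is anchored to its best reference hit (lowest E-value,
#' ties by highest bit score then lowest reference coordinate); anchors
#' with E-value above `evalue_max` are discarded and the ORFs listed as
#' unanchored.  `orientation_concordant` compares the query ORF's strand
#' (relative to the contig's consensus orientation against the reference)
#' with the reference ORF's strand.
#'
#' @param query_orfs,reference_orfs ORF data.frames (contig_id, locus_tag,
#'   start, end, strand)
#' @param hits protein-protein hit table, `query_id` = query locus tag,
#'   `subject_id` = reference locus tag
#' @param evalue_max anchor threshold (default 1e-5)
#' @return list with `anchors` (data.frame) and `unanchored` (character);
#'   anchors are sorted by query contig and coordinate
#' @export
anchor_orfs <- function(query_orfs, reference_orfs, hits, evalue_max = 1e-5) {
  unknown_q <- setdiff(unique(hits$query_id), query_orfs$locus_tag)
  if (length(unknown_q))
    stop("hits name unknown query loci: ", paste(head(unknown_q, 3), collapse = ", "))
  unknown_s <- setdiff(unique(hits$subject_id), reference_orfs$locus_tag)
  if (length(unknown_s))
    stop("hits name unknown reference loci: ", paste(head(unknown_s, 3), collapse = ", "))
  h <- hits[hits$e_value <= evalue_max, , drop = FALSE]
  qi <- match(h$query_id, query_orfs$locus_tag)
  ri <- match(h$subject_id, reference_orfs$locus_tag)
  ord <- order(h$e_value, -h$bit_score, reference_orfs$start[ri])
  h <- h[ord, , drop = FALSE]; qi <- qi[ord]; ri <- ri[ord]
  best <- !duplicated(h$query_id)
  h <- h[best, , drop = FALSE]; qi <- qi[best]; ri <- ri[best]
  anchors <- data.frame(
    contig_id = query_orfs$contig_id[qi],
    query_orf = h$query_id,
    reference_orf = h$subject_id,
    percent_identity = h$percent_identity,
    alignment_length = h$alignment_length,
    e_value = h$e_value, bit_score = h$bit_score,
    q_start = query_orfs$start[qi], q_end = query_orfs$end[qi],
    q_strand = query_orfs$strand[qi],
    r_start = reference_orfs$start[ri], r_end = reference_orfs$end[ri],
    r_strand = reference_orfs$strand[ri],
    hit_q_start = h$q_start, hit_q_end = h$q_end,
    hit_s_start = h$s_start, hit_s_end = h$s_end,
    stringsAsFactors = FALSE
  )
  anchors <- anchors[order(anchors$contig_id, anchors$q_start), , drop = FALSE]
  rownames(anchors) <- NULL
  # contig consensus orientation: majority strand agreement with reference
  concord <- anchors$q_strand == anchors$r_strand
  flip <- tapply(concord, anchors$contig_id, function(z) mean(z) < 0.5)
  anchors$orientation_concordant <-
    concord != unname(flip[anchors$contig_id])
  list(anchors = anchors,
       unanchored = setdiff(query_orfs$locus_tag, anchors$query_orf))
}

#' Segment anchors into collinear synteny blocks
#'
#' Anchors are walked in query coordinate order per contig; consecutive
#' anchors whose reference midpoints advance by at most
#' `max_reference_jump_bp` in a consistent direction extend the current
#' block.  A larger jump, or a flip of the reference direction, closes the
#' block and records a break with the reference distance between the
#' flanking anchors.  Blocks need >= 2 anchors; singletons are reported
#' separately.
#'
#' @param anchors anchor data.frame from [anchor_orfs()]
#' @param max_reference_jump_bp jump tolerance (default 20000)
#' @return list with `blocks`, `breaks`, `singletons`
#' @export
build_blocks <- function(anchors, max_reference_jump_bp = 20000L) {
  blocks <- list(); breaks <- list(); singles <- list()
  for (cid in unique(anchors$contig_id)) {
    a <- anchors[anchors$contig_id == cid, , drop = FALSE]
    a <- a[order(a$q_start), , drop = FALSE]
    rmid <- (a$r_start + a$r_end) / 2
    i0 <- 1L
    sense <- 0L
    flush <- function(i0, i1) {
      idx <- i0:i1
      if (length(idx) >= 2L) {
        blocks[[length(blocks) + 1L]] <<- data.frame(
          contig_id = cid,
          n_anchors = length(idx),
          q_start = min(a$q_start[idx]), q_end = max(a$q_end[idx]),
          r_start = min(a$r_start[idx]), r_end = max(a$r_end[idx]),
          sense = if (sum(sign(diff(rmid[idx]))) >= 0) "colinear" else "inverted",
          first_anchor = a$query_orf[idx[1L]],
          last_anchor = a$query_orf[idx[length(idx)]],
          anchor_tags = paste(a$query_orf[idx], collapse = ","),
          stringsAsFactors = FALSE)
      } else {
        singles[[length(singles) + 1L]] <<- a[idx, , drop = FALSE]
      }
    }
    if (nrow(a) == 0L) next
    for (i in seq_len(nrow(a))[-1L]) {
      jump <- rmid[i] - rmid[i - 1L]
      dir <- sign(jump)
      sense_flip <- sense != 0L && dir != 0L && dir != sense
      too_far <- abs(jump) > max_reference_jump_bp
      if (too_far || sense_flip) {
        flush(i0, i - 1L)
        breaks[[length(breaks) + 1L]] <- data.frame(
          contig_id = cid,
          left_anchor = a$query_orf[i - 1L], right_anchor = a$query_orf[i],
          left_reference_orf = a$reference_orf[i - 1L],
          right_reference_orf = a$reference_orf[i],
          query_position = a$q_end[i - 1L],
          reference_distance_bp = abs(a$r_start[i] - a$r_end[i - 1L]),
          reason = if (too_far) "jump" else "sense-flip",
          stringsAsFactors = FALSE)
        i0 <- i
        sense <- 0L
      } else if (dir != 0L) {
        sense <- dir
      }
    }
    flush(i0, nrow(a))
  }
  bind <- function(x, empty) if (length(x)) do.call(rbind, x) else empty
  list(
    blocks = bind(blocks, data.frame(contig_id = character(0),
                                     n_anchors = integer(0))),
    breaks = bind(breaks, data.frame(contig_id = character(0),
                                     reason = character(0))),
    singletons = bind(singles, anchors[0, , drop = FALSE])
  )
}

#' Call gene fusions: one reference ORF covered by two adjacent query ORFs
#'
#' A reference ORF is a fusion candidate (relative to the query lineage)
#' when two query ORFs that are consecutive in query coordinate order on
#' one contig both hit it, each covering at least `min_cov_each` of its
#' protein length, with the covered reference spans overlapping at most
#' `max_overlap_res` residues and appearing in consistent order.
#'
#' @param anchors anchor data.frame from [anchor_orfs()] (uses the per-hit
#'   reference spans `hit_s_start`/`hit_s_end` in residues)
#' @param reference_orfs reference ORF table (for protein lengths)
#' @param min_cov_each minimum coverage fraction per partner (default 0.25)
#' @param max_overlap_res maximum covered-span overlap (default 30)
#' @return data.frame of fusion calls
#' @export
call_fusions <- function(anchors, reference_orfs, min_cov_each = 0.25,
                         max_overlap_res = 30L) {
  out <- list()
  ref_len_aa <- setNames((reference_orfs$end - reference_orfs$start + 1L) %/% 3L - 1L,
                         reference_orfs$locus_tag)
  for (cid in unique(anchors$contig_id)) {
    a <- anchors[anchors$contig_id == cid, , drop = FALSE]
    a <- a[order(a$q_start), , drop = FALSE]
    if (nrow(a) < 2L) next
    for (i in seq_len(nrow(a) - 1L)) {
      if (a$reference_orf[i] != a$reference_orf[i + 1L]) next
      rlen <- ref_len_aa[[a$reference_orf[i]]]
      s1 <- sort(c(a$hit_s_start[i], a$hit_s_end[i]))
      s2 <- sort(c(a$hit_s_start[i + 1L], a$hit_s_end[i + 1L]))
      cov1 <- (s1[2L] - s1[1L] + 1L) / rlen
      cov2 <- (s2[2L] - s2[1L] + 1L) / rlen
      if (cov1 < min_cov_each || cov2 < min_cov_each) next
      overlap <- min(s1[2L], s2[2L]) - max(s1[1L], s2[1L]) + 1L
      if (overlap > max_overlap_res) next
      out[[length(out) + 1L]] <- data.frame(
        contig_id = cid,
        reference_orf = a$reference_orf[i],
        query_orf_1 = a$query_orf[i], query_orf_2 = a$query_orf[i + 1L],
        coverage_1 = cov1, coverage_2 = cov2,
        gap_res = max(s1[1L], s2[1L]) - min(s1[2L], s2[2L]) - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(contig_id = character(0), reference_orf = character(0),
                      query_orf_1 = character(0), query_orf_2 = character(0),
                      coverage_1 = numeric(0), coverage_2 = numeric(0),
                      gap_res = integer(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Flag reverse-orientation foreign ORF candidates
#'
#' Flags query ORFs that are (a) unanchored against the reference (or
#' better-hit to a secondary "other taxa" protein set when one is given)
#' and (b) strand-discordant with both flanking ORFs on their contig.
#' When per-read contig spans are supplied, each flag is annotated with
#' the number of reads covering both the flagged ORF and an anchored
#' neighbor -- the read-level check against assembly error; flags with at
#' least `min_support_reads` such reads are marked `assembly_supported`.
#'
#' @param anchors anchor data.frame from [anchor_orfs()]
#' @param query_orfs full query ORF table
#' @param secondary_hits optional hit table of query ORFs vs another
#'   protein set; without it, flags are orientation-only (a caveat is
#'   attached as an attribute)
#' @param read_spans optional data.frame (read_id, contig_id, start, end)
#'   of read placements in contig coordinates
#' @param min_support_reads support threshold (default 3)
#' @return data.frame of flagged loci with support counts
#' @export
flag_discordant_orfs <- function(anchors, query_orfs, secondary_hits = NULL,
                                 read_spans = NULL, min_support_reads = 3L) {
  anchored <- anchors$query_orf
  better_foreign <- character(0)
  if (!is.null(secondary_hits) && nrow(secondary_hits)) {
    sec_best <- tapply(secondary_hits$bit_score, secondary_hits$query_id, max)
    ref_best <- setNames(anchors$bit_score, anchors$query_orf)
    cand <- names(sec_best)
    better_foreign <- cand[is.na(ref_best[cand]) |
                             sec_best[cand] > ref_best[cand]]
  }
  out <- list()
  for (cid in unique(query_orfs$contig_id)) {
    o <- query_orfs[query_orfs$contig_id == cid, , drop = FALSE]
    o <- o[order(o$start), , drop = FALSE]
    if (nrow(o) < 3L) next
    for (i in 2:(nrow(o) - 1L)) {
      tag <- o$locus_tag[i]
      foreign <- !(tag %in% anchored) || tag %in% better_foreign
      if (!foreign) next
      discordant <- o$strand[i] != o$strand[i - 1L] &&
        o$strand[i] != o$strand[i + 1L]
      if (!discordant) next
      support <- NA_integer_
      if (!is.null(read_spans)) {
        rs <- read_spans[read_spans$contig_id == cid, , drop = FALSE]
        covers <- function(j) rs$start <= o$end[j] & rs$end >= o$start[j]
        nb <- c(i - 1L, i + 1L)
        nb <- nb[o$locus_tag[nb] %in% anchored]
        support <- if (length(nb))
          sum(covers(i) & Reduce(`|`, lapply(nb, covers))) else 0L
      }
      out[[length(out) + 1L]] <- data.frame(
        contig_id = cid, locus_tag = tag, strand = o$strand[i],
        spanning_reads = support,
        assembly_supported = !is.na(support) && support >= min_support_reads,
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(contig_id = character(0), locus_tag = character(0),
               strand = character(0), spanning_reads = integer(0),
               assembly_supported = logical(0), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (is.null(secondary_hits))
    attr(df, "caveat") <- "orientation-only flags: no secondary protein set supplied"
  df
}
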