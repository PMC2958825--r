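# Per-reference-protein homolog census over tiered E-value thresholds,
# and the missing-gene report.

#' Tiered homolog census of reference proteins
#'
#' One row per reference protein with the best hit against contigs and
#' against unassembled reads (singlets), the overall best E-value, and the
#' most stringent tier strictly exceeded ("better than 1e-X" is strict
#' less-than).  Tier tallies are cumulative: a protein with a 1e-100 hit
#' counts in the 1e-100, 1e-50 and 1e-10 tallies alike.
#'
#' @param reference_proteins character vector of reference locus tags (or
#'   a named vector of protein sequences, whose names are used)
#' @param hits_vs_contigs,hits_vs_singlets hit tables keyed by reference
#'   protein in `query_id`; either may be NULL
#' @return data.frame of class `census` with one row per protein
#' @export
census <- function(reference_proteins, hits_vs_contigs,
                   hits_vs_singlets = NULL) {
  loci <- if (!is.null(names(reference_proteins))) names(reference_proteins)
          else reference_proteins
  best_of <- function(hits) {
    if (is.null(hits) || nrow(hits) == 0L)
      return(data.frame(query_id = character(0), subject_id = character(0),
                        e_value = numeric(0), bit_score = numeric(0),
                        percent_identity = numeric(0)))
    h <- hits[order(hits$e_value, -hits$bit_score), , drop = FALSE]
    h[!duplicated(h$query_id), , drop = FALSE]
  }
  bc <- best_of(hits_vs_contigs)
  bs <- best_of(hits_vs_singlets)
  ic <- match(loci, bc$query_id)
  is_ <- match(loci, bs$query_id)
  best_overall <- pmin(bc$e_value[ic], bs$e_value[is_], na.rm = TRUE)
  best_overall[is.na(ic) & is.na(is_)] <- NA_real_
  out <- data.frame(
    reference_protein = loci,
    best_contig_id = bc$subject_id[ic],
    best_contig_evalue = bc$e_value[ic],
    best_contig_identity = bc$percent_identity[ic],
    best_singlet_id = bs$subject_id[is_],
    best_singlet_evalue = bs$e_value[is_],
    best_singlet_identity = bs$percent_identity[is_],
    best_evalue_overall = best_overall,
    tier = .evalue_class(best_overall),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("census", "data.frame")
  out
}

#' Cumulative tier tallies of a census
#'
#' @param census_rows a [census()] result
#' @return named integer vector: proteins with best E strictly better than
#'   1e-100, 1e-50 and 1e-10 (cumulative), plus `none` and `total`
#' @export
census_tier_counts <- function(census_rows) {
  e <- census_rows$best_evalue_overall
  c(`1e-100` = sum(!is.na(e) & e < 1e-100),
    `1e-50` = sum(!is.na(e) & e < 1e-50),
    `1e-10` = sum(!is.na(e) & e < 1e-10),
    none = sum(is.na(e) | e >= 1e-10),
    total = nrow(census_rows))
}

#' Missing-gene report: reference proteins without a close homolog
#'
#' Lists tier-none proteins, counts those annotated as hypothetical, and
#' groups the remainder by a crude annotation keyword (the first
#' informative word of the product) to surface missing operons or
#' transporter families.
#'
#' @param census_rows a [census()] result
#' @param annotations data.frame with `locus_tag` and `product`
#' @return list with `missing` (data.frame), `n_missing`,
#'   `n_hypothetical`, `by_keyword` (table)
#' @export
missing_gene_report <- function(census_rows, annotations) {
  miss <- census_rows[census_rows$tier == "none", , drop = FALSE]
  prod <- annotations$product[match(miss$reference_protein,
                                    annotations$locus_tag)]
  prod[is.na(prod)] <- "unannotated"
  hyp <- grepl("hypothetical", prod, ignore.case = TRUE)
  keyword <- vapply(strsplit(tolower(prod[!hyp]), "[^a-z0-9-]+"), function(w) {
    w <- w[nchar(w) > 3L]
    if (length(w)) w[1L] else "other"
  }, character(1))
  list(
    missing = data.frame(reference_protein = miss$reference_protein,
                         product = prod, hypothetical = hyp,
                         stringsAsFactors = FALSE, row.names = NULL),
    n_missing = nrow(miss),
    n_hypothetical = sum(hyp),
    by_keyword = if (length(keyword)) sort(table(keyword), decreasing = TRUE)
                 else table(character(0))
  )
}
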