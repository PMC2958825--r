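# Simulation configuration: the study conditions under which the
# synthetic reference and diverged query lineage are generated.

#' Simulation configuration
#'
#' Defaults mirror the study system this package models: a ~43% GC
#' reference genome, a query lineage diverged to ~70% nucleotide identity
#' with GC drifted to ~38%, a large translocation joining two reference
#' regions separated by a wide gap, two gene-fusion events, a prophage
#' with a 26 bp flanking direct repeat present in the reference lineage
#' only, multi-copy transposases in the query, a few reverse-orientation
#' foreign ORFs, and Sanger-style paired-end reads of ~755 bp mean length
#' at ~6x coverage from ~3 kb clone inserts.
#'
#' @param seed integer RNG seed; stage streams are derived from it
#' @param genome_length reference genome length in bp (prophage included)
#' @param n_orfs backbone ORF count (prophage ORFs are extra)
#' @param gc_reference,gc_query GC fractions in (0,1)
#' @param nt_divergence planted per-site substitution rate in (0,1)
#' @param syn_nonsyn_ratio synonymous:nonsynonymous site-rate ratio
#'   (default 3)
#' @param translocation NULL, or list(regionA = c(start, end),
#'   regionB = c(start, end)) in reference coordinates; NULL regions are
#'   derived from `gap_bp`
#' @param gap_bp reference distance separating the translocated regions
#'   when regions are derived (default 50000)
#' @param n_fusions reference ORFs split into two adjacent query ORFs
#' @param prophage NULL, or list(length_bp, insertion_site (NULL = auto),
#'   repeat_length)
#' @param n_transposase_copies transposase copies scattered in the query
#' @param transposase_length_bp transposase ORF length (default 960)
#' @param n_foreign_orfs reverse-orientation foreign ORFs in the query
#' @param foreign_orf_length_bp foreign ORF length (default 900)
#' @param read_length_mean,read_length_sd Sanger read length model (bp)
#' @param insert_size_mean,insert_size_sd clone insert model (bp)
#' @param coverage_target fold sequencing coverage
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 150000L,
                       n_orfs = 100L,
                       gc_reference = 0.43,
                       gc_query = 0.38,
                       nt_divergence = 0.30,
                       syn_nonsyn_ratio = 3,
                       translocation = list(regionA = NULL, regionB = NULL),
                       gap_bp = 50000L,
                       n_fusions = 2L,
                       prophage = list(length_bp = 8000L,
                                       insertion_site = NULL,
                                       repeat_length = 26L),
                       n_transposase_copies = 10L,
                       transposase_length_bp = 960L,
                       n_foreign_orfs = 3L,
                       foreign_orf_length_bp = 900L,
                       read_length_mean = 755,
                       read_length_sd = 100,
                       insert_size_mean = 3000,
                       insert_size_sd = 300,
                       coverage_target = 6) {
  stopifnot(
    genome_length >= 1000L, n_orfs >= 0L,
    gc_reference > 0 && gc_reference < 1,
    gc_query > 0 && gc_query < 1,
    nt_divergence >= 0 && nt_divergence < 1,
    syn_nonsyn_ratio > 0,
    n_fusions >= 0L, n_transposase_copies >= 0L, n_foreign_orfs >= 0L,
    read_length_mean > 0, insert_size_mean > 0, coverage_target > 0
  )
  if (!is.null(prophage)) {
    prophage$repeat_length <- prophage$repeat_length %||% 26L
    stopifnot(prophage$length_bp >= 1000L, prophage$repeat_length >= 15L)
  }
  if (!is.null(translocation)) {
    a <- translocation$regionA; b <- translocation$regionB
    if (is.null(a) || is.null(b)) {
      # derive regions: A ends at ~25% of the genome, B starts gap_bp later
      span <- round(genome_length * 0.1)
      endA <- round(genome_length * 0.25)
      a <- c(endA - span + 1L, endA)
      b <- c(endA + gap_bp + 1L, endA + gap_bp + span)
      if (b[2L] > genome_length - 1000L)
        stop("translocation regions with gap_bp=", gap_bp,
             " do not fit in genome_length=", genome_length)
    }
    stopifnot(length(a) == 2L, length(b) == 2L, a[1L] < a[2L], b[1L] < b[2L])
    if (max(a[1L], b[1L]) <= min(a[2L], b[2L]))
      stop("translocation regions must be disjoint")
    if (a[1L] > b[1L]) { tmp <- a; a <- b; b <- tmp }
    translocation <- list(regionA = as.integer(a), regionB = as.integer(b))
  }
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_orfs = as.integer(n_orfs), gc_reference = gc_reference,
    gc_query = gc_query, nt_divergence = nt_divergence,
    syn_nonsyn_ratio = syn_nonsyn_ratio,
    translocation = translocation, gap_bp = as.integer(gap_bp),
    n_fusions = as.integer(n_fusions), prophage = prophage,
    n_transposase_copies = as.integer(n_transposase_copies),
    transposase_length_bp = as.integer(transposase_length_bp),
    n_foreign_orfs = as.integer(n_foreign_orfs),
    foreign_orf_length_bp = as.integer(foreign_orf_length_bp),
    read_length_mean = read_length_mean, read_length_sd = read_length_sd,
    insert_size_mean = insert_size_mean, insert_size_sd = insert_size_sd,
    coverage_target = coverage_target
  ), class = "sim_config")
}
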