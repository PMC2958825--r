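# Sanger-style paired-end read simulation from clone inserts, and
# window-based contig fixtures standing in for an assembly.

#' Simulate paired-end Sanger-style reads
#'
#' Clone inserts are placed uniformly on the genome with
#' Normal(insert_size_mean, insert_size_sd) lengths; the two reads of a
#' clone come from opposite ends and opposite strands, with
#' Normal(read_length_mean, read_length_sd) lengths clamped to the insert.
#' Read names follow the clone-stem naming convention (`.b1`/`.g1`).
#' Pairs are emitted until total read bp reaches
#' `coverage_target * genome length` (within one clone).  Inserts smaller
#' than twice the read length are clamped with a warning.
#'
#' @param genome an `annotated_genome` (or any list with `seq`)
#' @param config a [sim_config()]
#' @param stem_prefix clone stem prefix (default "LCC")
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: read_id, clone_stem, start, end, strand, read_length)
#' @export
simulate_reads <- function(genome, config, stem_prefix = "LCC") {
  stopifnot(nchar(genome$seq) > 0)
  set.seed(config$seed + 2L)
  L <- nchar(genome$seq)
  target_bp <- config$coverage_target * L
  if (config$insert_size_mean < 2 * config$read_length_mean)
    warning("insert size mean below twice the read length mean; ",
            "read lengths will be clamped to the insert")
  reads <- character(0); truth <- list()
  total <- 0; clone <- 0L
  while (total < target_bp) {
    clone <- clone + 1L
    ins <- max(600L, round(rnorm(1, config$insert_size_mean,
                                 config$insert_size_sd)))
    ins <- min(ins, L)
    a <- sample.int(L - ins + 1L, 1L)
    b <- a + ins - 1L
    rl <- pmax(200L, round(rnorm(2, config$read_length_mean,
                                 config$read_length_sd)))
    rl <- pmin(rl, ins)
    stem <- sprintf("%s%05d", stem_prefix, clone)
    fwd_id <- paste0(stem, ".b1"); rev_id <- paste0(stem, ".g1")
    fwd <- substr(genome$seq, a, a + rl[1L] - 1L)
    rev_ <- revcomp(substr(genome$seq, b - rl[2L] + 1L, b))
    reads[fwd_id] <- fwd
    reads[rev_id] <- rev_
    truth[[length(truth) + 1L]] <- data.frame(
      read_id = c(fwd_id, rev_id), clone_stem = stem,
      start = c(a, b - rl[2L] + 1L), end = c(a + rl[1L] - 1L, b),
      strand = c("+", "-"), read_length = rl, stringsAsFactors = FALSE)
    total <- total + sum(rl)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(reads = reads, truth = truth)
}

#' Build window-based contig fixtures
#'
#' Assembly is simulated, not performed: contigs are windows tiling the
#' genome, with sizes drawn from a mixture so that a few exceed 10 kb and
#' most stay below ~2.5 kb.  A fraction of the small windows is withheld
#' from the contig set, so reads falling there stay unassembled
#' (singlets).  Each read is assigned to the contig containing its source
#' midpoint.
#'
#' @param genome the sampled `annotated_genome`
#' @param reads a [simulate_reads()] result
#' @param config a [sim_config()]
#' @param p_large probability of drawing a large (10-18 kb) window
#'   (default 0.12)
#' @param singlet_every withhold every k-th small window from assembly
#'   (default 6; 0 disables)
#' @return list with `contigs` (named character vector), `windows`
#'   (data.frame: contig_id, start, end, assembled), `membership`
#'   (data.frame: read_id, contig_id (NA = singlet), read_length,
#'   start_in_contig, end_in_contig)
#' @export
make_contig_fixtures <- function(genome, reads, config, p_large = 0.12,
                                 singlet_every = 6L) {
  set.seed(config$seed + 3L)
  L <- nchar(genome$seq)
  # window boundaries snap forward into intergenic space: the fixture
  # emulates an assembly that breaks between genes, not inside them.
  # Excision junctions (with their flanking genes) are protected too, so
  # the junction locus stays on one contig as in the observed data.
  iv <- genome$orfs[, c("start", "end")]
  prot <- genome$protected %||% data.frame(start = integer(0), end = integer(0))
  if (nrow(prot)) iv <- rbind(iv, prot)
  snap <- function(pos) {
    if (pos >= L) return(L)
    repeat {
      hit <- which(iv$start - 4L <= pos & iv$end + 4L >= pos)
      if (length(hit) == 0L) return(pos)
      pos <- max(iv$end[hit]) + 5L
      if (pos >= L) return(L)
    }
  }
  ends <- integer(0); pos <- 0L
  while (pos < L) {
    sz <- if (runif(1) < p_large) sample(10000:18000, 1L)
          else sample(600:2500, 1L)
    e <- snap(min(pos + sz, L))
    ends <- c(ends, e)
    pos <- e
  }
  sizes <- diff(c(0L, ends))
  windows <- data.frame(
    contig_id = sprintf("C%04d", seq_along(sizes)),
    start = c(1L, head(ends, -1L) + 1L), end = ends,
    stringsAsFactors = FALSE)
  small <- which(sizes < 10000L)
  withheld <- if (singlet_every > 0L && length(small))
    small[seq_along(small) %% singlet_every == 0L] else integer(0)
  # never withhold a window carrying a protected locus
  if (nrow(prot))
    for (k in seq_len(nrow(prot)))
      withheld <- setdiff(withheld,
                          which(windows$start <= prot$end[k] &
                                  windows$end >= prot$start[k]))
  windows$assembled <- !(seq_along(sizes) %in% withheld)

  truth <- reads$truth
  mid <- (truth$start + truth$end) %/% 2L
  w_idx <- findInterval(mid, c(1L, ends + 1L))
  assembled_w <- windows$assembled[w_idx]
  cid <- ifelse(assembled_w, windows$contig_id[w_idx], NA_character_)
  membership <- data.frame(
    read_id = truth$read_id, contig_id = cid,
    read_length = truth$read_length,
    start_in_contig = ifelse(is.na(cid), NA_integer_,
                             pmax(1L, truth$start - windows$start[w_idx] + 1L)),
    end_in_contig = ifelse(is.na(cid), NA_integer_,
                           pmin(windows$end[w_idx] - windows$start[w_idx] + 1L,
                                truth$end - windows$start[w_idx] + 1L)),
    stringsAsFactors = FALSE)
  asm <- windows[windows$assembled, , drop = FALSE]
  contigs <- if (nrow(asm))
    setNames(substring(genome$seq, asm$start, asm$end), asm$contig_id)
  else setNames(character(0), character(0))
  list(contigs = contigs, windows = windows, membership = membership)
}

#' Run the full simulation and write its artifacts
#'
#' Builds the reference, evolves the query lineage, simulates reads from
#' the query genome, cuts contig fixtures, and (optionally) writes every
#' artifact: reference/query FASTA and ORF tables, reads FASTA, contigs
#' FASTA, membership TSV, truth ledger TSV, and the reference protein and
#' transposase protein FASTA files.
#'
#' @param config a [sim_config()]
#' @param outdir output directory, or NULL to skip writing
#' @return list with `reference`, `query`, `ledger`, `reads`, `fixtures`
#' @export
simulate_metagenome <- function(config, outdir = NULL) {
  ref <- build_reference(config)
  ev <- evolve_query(ref, config)
  rd <- simulate_reads(ev$genome, config)
  fx <- make_contig_fixtures(ev$genome, rd, config)
  out <- list(reference = ref, query = ev$genome, ledger = ev$ledger,
              reads = rd, fixtures = fx)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_fasta(setNames(ref$seq, ref$id), p("reference.fasta"))
    write_orf_table(ref$orfs, p("reference_orfs.tsv"))
    write_fasta(setNames(ref$orfs$translation, ref$orfs$locus_tag),
                p("reference_proteins.faa"))
    write_fasta(setNames(ev$genome$seq, ev$genome$id), p("query.fasta"))
    write_orf_table(ev$genome$orfs, p("query_orfs.tsv"))
    write_fasta(rd$reads, p("reads.fasta"))
    .write_tsv(rd$truth, p("read_truth.tsv"))
    write_fasta(fx$contigs, p("contigs.fasta"))
    .write_tsv(fx$membership, p("membership.tsv"))
    .write_tsv(fx$windows, p("contig_windows.tsv"))
    write_ledger(ev$ledger, p("truth_ledger.tsv"), seed = config$seed)
    if (!is.null(ev$genome$transposase_protein))
      write_fasta(c(transposase1 = ev$genome$transposase_protein),
                  p("transposase.faa"))
  }
  out
}
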