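# Shared fixtures: random-sequence helpers, constructed linkage tallies,
# and a memoised full synthetic pipeline run reused across test files.

.fixture_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linkage fixtures: contigs, membership and clone pairs constructed to a
# prescribed tally.
linkage_fixture <- function(n_contigs = 17, reads_per_contig = NULL,
                            linked_per_contig = NULL, contig_kb = NULL) {
  reads_per_contig <- reads_per_contig %||% rep(76, n_contigs)
  linked_per_contig <- linked_per_contig %||% rep(0, n_contigs)
  contig_kb <- contig_kb %||% rep(15, n_contigs)
  membership <- list(); pairs <- list(); flagged <- character(0)
  for (i in seq_len(n_contigs)) {
    ids <- sprintf("CL%02d_%04d", i, seq_len(reads_per_contig[i]))
    fwd <- paste0(ids, ".b1"); rev_ <- paste0(ids, ".g1")
    membership[[i]] <- data.frame(
      read_id = fwd, contig_id = sprintf("big%02d", i),
      read_length = 755L, stringsAsFactors = FALSE)
    pairs[[i]] <- data.frame(stem = ids, forward_read_id = fwd,
                             reverse_read_id = rev_, stringsAsFactors = FALSE)
    if (linked_per_contig[i] > 0)
      flagged <- c(flagged, rev_[seq_len(linked_per_contig[i])])
  }
  membership <- do.call(rbind, membership)
  # mates are unassembled singlets
  membership <- rbind(membership, data.frame(
    read_id = unlist(lapply(pairs, `[[`, "reverse_read_id")),
    contig_id = NA_character_, read_length = 755L, stringsAsFactors = FALSE))
  stats <- data.frame(
    contig_id = sprintf("big%02d", seq_len(n_contigs)),
    length = contig_kb * 1000L, stringsAsFactors = FALSE)
  list(membership = membership, pairs = do.call(rbind, pairs),
       flagged = flagged, stats = stats)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitute a fraction of positions with a different base
mutate_dna <- function(seq, rate) {
  x <- strsplit(seq, "")[[1]]
  i <- which(runif(length(x)) < rate)
  x[i] <- vapply(x[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                 character(1))
  paste(x, collapse = "")
}

# one full default-conditions pipeline run, computed once per test session
sim_run <- function() {
  if (!is.null(.fixture_env$run)) return(.fixture_env$run)
  dir <- file.path(tempdir(), "ventcomp-simrun")
  cfg <- sim_config(seed = 42L)
  run_pipeline(cfg, dir, quiet = TRUE)
  .fixture_env$run <- list(
    dir = dir, config = cfg,
    ledger = read_ledger(file.path(dir, "truth_ledger.tsv")),
    tsv = function(f) utils::read.delim(file.path(dir, f))
  )
  .fixture_env$run
}

# a small simulated dataset (no pipeline) for simulator-level tests
sim_small <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  cfg <- sim_config(seed = 7L, genome_length = 60000L, n_orfs = 40L,
                    gap_bp = 18000L,
                    prophage = list(length_bp = 5000L, insertion_site = NULL,
                                    repeat_length = 26L),
                    n_transposase_copies = 4L, n_foreign_orfs = 2L,
                    coverage_target = 4)
  ref <- build_reference(cfg)
  ev <- evolve_query(ref, cfg)
  rd <- simulate_reads(ev$genome, cfg)
  fx <- make_contig_fixtures(ev$genome, rd, cfg)
  .fixture_env$small <- list(cfg = cfg, ref = ref, query = ev$genome,
                             ledger = ev$ledger, reads = rd, fixtures = fx)
  .fixture_env$small
}
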