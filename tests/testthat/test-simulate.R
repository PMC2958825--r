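test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(gc_reference = 1.2))
  expect_error(sim_config(coverage_target = 0))
  expect_error(sim_config(prophage = list(length_bp = 5000,
                                          repeat_length = 10)))
  expect_error(sim_config(translocation = list(regionA = c(1000, 5000),
                                               regionB = c(4000, 9000))),
               "disjoint")
  expect_error(sim_config(genome_length = 60000, gap_bp = 50000), "fit")
})

test_that("the reference genome hits its GC target and composition contract", {
  s <- sim_small()
  ref <- s$ref
  expect_equal(nchar(ref$seq), s$cfg$genome_length)
  gc <- gc_content(ref$seq)
  sd3 <- 3 * sqrt(0.43 * 0.57 / gc$counted_bases)
  expect_lt(abs(gc$gc_fraction - 0.43), sd3)
  # ORFs: non-overlapping per strand, ATG starts, in-frame stops at the end
  orfs <- ref$orfs
  expect_gte(nrow(orfs), s$cfg$n_orfs) # backbone + prophage ORFs
  for (i in sample(nrow(orfs), 10)) {
    cds <- substr(ref$seq, orfs$start[i], orfs$end[i])
    if (orfs$strand[i] == "-") cds <- revcomp(cds)
    expect_equal(substr(cds, 1, 3), "ATG")
    p <- translate(cds)
    expect_equal(substr(p, nchar(p), nchar(p)), "*")
    expect_false(grepl("\\*", substr(p, 1, nchar(p) - 1)))
  }
  ord <- orfs[order(orfs$start), ]
  expect_true(all(diff(ord$start) > 0))
  expect_true(all(head(ord$end, -1) < tail(ord$start, -1)))
})

test_that("a zero-ORF, prophage-free configuration yields a bare genome", {
  cfg <- sim_config(seed = 5, genome_length = 20000, n_orfs = 0,
                    gc_reference = 0.5, prophage = NULL,
                    translocation = NULL, n_fusions = 0)
  ref <- build_reference(cfg)
  expect_equal(nrow(ref$orfs), 0L)
  expect_equal(nrow(ref$elements), 0L)
  expect_equal(nchar(ref$seq), 20000L)
})

test_that("infeasible ORF packing fails naming the limiting parameters", {
  expect_error(build_reference(sim_config(genome_length = 30000,
                                          n_orfs = 200, prophage = NULL,
                                          translocation = NULL)),
               "n_orfs")
})

test_that("the same seed reproduces byte-identical artifacts", {
  cfg <- sim_config(seed = 99, genome_length = 40000, n_orfs = 25,
                    gap_bp = 12000,
                    prophage = list(length_bp = 4000, insertion_site = NULL,
                                    repeat_length = 26),
                    n_transposase_copies = 2, n_foreign_orfs = 1,
                    coverage_target = 2)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  r1 <- build_reference(cfg); e1 <- evolve_query(r1, cfg)
  rd1 <- simulate_reads(e1$genome, cfg)
  r2 <- build_reference(cfg); e2 <- evolve_query(r2, cfg)
  rd2 <- simulate_reads(e2$genome, cfg)
  expect_identical(r1$seq, r2$seq)
  expect_identical(e1$genome$seq, e2$genome$seq)
  expect_identical(e1$ledger, e2$ledger)
  expect_identical(rd1$reads, rd2$reads)
  write_fasta(setNames(r1$seq, "ref"), file.path(tempdir(), "a.fasta"))
  write_fasta(setNames(r2$seq, "ref"), file.path(tempdir(), "b.fasta"))
  expect_identical(readBin(file.path(tempdir(), "a.fasta"), "raw", 99999),
                   readBin(file.path(tempdir(), "b.fasta"), "raw", 99999))
})

test_that("the prophage and its direct repeat exist only in the reference", {
  s <- sim_small()
  el <- s$ref$elements
  expect_equal(el$kind, "prophage")
  rep_seq <- el$repeat_seq
  expect_equal(nchar(rep_seq), 26L)
  # exact string search: two copies in the reference, zero in the query
  count <- function(hay, needle)
    sum(gregexpr(needle, hay, fixed = TRUE)[[1]] > 0)
  expect_equal(count(s$ref$seq, rep_seq), 2)
  expect_equal(count(s$query$seq, rep_seq), 0)
  expect_equal(substr(s$ref$seq, el$repeat_left_start, el$repeat_left_end),
               rep_seq)
  expect_equal(substr(s$ref$seq, el$repeat_right_start, el$repeat_right_end),
               rep_seq)
})

test_that("query length bookkeeping matches the planted events", {
  cfg <- sim_config(seed = 13, genome_length = 60000, n_orfs = 30,
                    gap_bp = 15000, nt_divergence = 0,
                    prophage = list(length_bp = 5000, insertion_site = NULL,
                                    repeat_length = 26),
                    n_transposase_copies = 0, n_foreign_orfs = 0,
                    n_fusions = 0)
  ref <- build_reference(cfg)
  ev <- evolve_query(ref, cfg)
  # prophage + both repeat copies removed; nothing inserted
  expect_equal(nchar(ev$genome$seq), 60000 - 5000 - 2 * 26)
})

test_that("a null evolution returns the reference verbatim", {
  cfg <- sim_config(seed = 14, genome_length = 30000, n_orfs = 15,
                    nt_divergence = 0, prophage = NULL, translocation = NULL,
                    n_fusions = 0, n_transposase_copies = 0,
                    n_foreign_orfs = 0)
  ref <- build_reference(cfg)
  ev <- evolve_query(ref, cfg)
  expect_identical(ev$genome$seq, ref$seq)
  expect_equal(ev$ledger$kind, "substitution-rate")
})

test_that("planted divergence is recovered from ortholog alignments", {
  s <- sim_small()
  orth <- s$ledger[s$ledger$kind == "ortholog", ]
  ident <- vapply(seq_len(nrow(orth)), function(i) {
    a <- substr(s$ref$seq, orth$ref_start[i], orth$ref_end[i])
    b <- substr(s$query$seq, orth$query_start[i], orth$query_end[i])
    if (nchar(a) != nchar(b)) return(NA_real_)
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }, numeric(1))
  expect_lt(abs(median(ident, na.rm = TRUE) - 0.70), 0.03)
  expect_true(all(orth$aa_identity > 0.55 & orth$aa_identity < 0.95,
                  na.rm = TRUE))
})

test_that("query GC drifts to its target within binomial error", {
  s <- sim_small()
  gc <- gc_content(s$query$seq)
  sd3 <- 3 * sqrt(0.38 * 0.62 / gc$counted_bases)
  expect_lt(abs(gc$gc_fraction - 0.38), sd3)
})

test_that("every structural event is present in the ledger with valid coords", {
  s <- sim_small()
  led <- s$ledger
  cfg <- s$cfg
  expect_equal(sum(led$kind == "prophage"), 1L)
  expect_equal(sum(led$kind == "translocation"), 1L)
  expect_equal(sum(led$kind == "fusion"), cfg$n_fusions)
  expect_equal(sum(led$kind == "transposase-copy"), cfg$n_transposase_copies)
  expect_equal(sum(led$kind == "foreign-orf"), cfg$n_foreign_orfs)
  qlen <- nchar(s$query$seq)
  qcoords <- led[!is.na(led$query_start) & led$kind != "prophage", ]
  expect_true(all(qcoords$query_start >= 1 & qcoords$query_end <= qlen))
  # transposase copies really sit at their recorded coordinates
  for (i in which(led$kind == "transposase-copy")) {
    cds <- substr(s$query$seq, led$query_start[i], led$query_end[i])
    if (led$strand[i] == "-") cds <- revcomp(cds)
    expect_equal(substr(cds, 1, 3), "ATG")
    p <- translate(cds)
    expect_false(grepl("\\*", substr(p, 1, nchar(p) - 1)))
  }
  # foreign ORFs are strand-discordant with both neighbors
  orfs <- s$query$orfs[order(s$query$orfs$start), ]
  for (i in which(led$kind == "foreign-orf")) {
    j <- which(orfs$start == led$query_start[i])
    expect_length(j, 1)
    expect_true(orfs$strand[j] != orfs$strand[j - 1] &&
                  orfs$strand[j] != orfs$strand[j + 1])
  }
})

test_that("reads respect the pairing, length and coverage contracts", {
  s <- sim_small()
  reads <- s$reads$reads
  truth <- s$reads$truth
  L <- nchar(s$query$seq)
  total <- sum(nchar(reads))
  expect_lt(abs(total - s$cfg$coverage_target * L),
            0.05 * s$cfg$coverage_target * L + 2000)
  # every clone stem appears exactly twice
  stems <- sub("\\..*$", "", names(reads))
  expect_true(all(table(stems) == 2L))
  pr <- pair_reads(names(reads))
  expect_equal(nrow(pr$pairs), length(reads) / 2)
  expect_length(pr$unpaired, 0)
  # emitted sequences match their truth intervals
  for (i in sample(nrow(truth), 20)) {
    src <- substr(s$query$seq, truth$start[i], truth$end[i])
    if (truth$strand[i] == "-") src <- revcomp(src)
    expect_identical(unname(reads[truth$read_id[i]]), src)
  }
})

test_that("read lengths track the Sanger model mean", {
  cfg <- sim_config(seed = 21, genome_length = 100000, n_orfs = 50,
                    gap_bp = 30000, read_length_sd = 50, coverage_target = 10)
  ref <- build_reference(cfg)
  ev <- evolve_query(ref, cfg)
  rd <- simulate_reads(ev$genome, cfg)
  expect_gte(length(rd$reads), 1000)
  expect_lt(abs(mean(nchar(rd$reads)) - 755), 10)
})

test_that("contig fixtures partition reads consistently", {
  s <- sim_small()
  fx <- s$fixtures
  m <- fx$membership
  # each read is assigned to at most one contig; windows tile the genome
  expect_equal(anyDuplicated(m$read_id), 0L)
  expect_equal(fx$windows$start[1], 1L)
  expect_equal(max(fx$windows$end), nchar(s$query$seq))
  expect_true(all(diff(fx$windows$start) > 0))
  # membership bp of a window ~ coverage * window length
  big <- fx$windows[fx$windows$end - fx$windows$start > 10000 &
                      fx$windows$assembled, ][1, ]
  bp <- sum(m$read_length[!is.na(m$contig_id) &
                            m$contig_id == big$contig_id])
  expected <- s$cfg$coverage_target * (big$end - big$start + 1)
  expect_lt(abs(bp - expected) / expected, 0.35)
  # no assembled windows -> everything unassembled (plain genome without
  # protected loci, so every window may be withheld)
  cfg0 <- sim_config(seed = 2, genome_length = 20000, n_orfs = 10,
                     nt_divergence = 0, prophage = NULL,
                     translocation = NULL, n_fusions = 0,
                     n_transposase_copies = 0, n_foreign_orfs = 0,
                     coverage_target = 1)
  ref0 <- build_reference(cfg0)
  ev0 <- evolve_query(ref0, cfg0)
  rd0 <- simulate_reads(ev0$genome, cfg0)
  none <- make_contig_fixtures(ev0$genome, rd0, cfg0,
                               p_large = 0, singlet_every = 1)
  expect_true(all(is.na(none$membership$contig_id)))
})
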