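test_that("the published linkage tallies reproduce 3.8% and 16/17", {
  # 17 contigs > 10 kb, 1294 member reads, 49 of them mate-linked,
  # spread so 16 contigs get at least one link
  reads_per <- c(rep(76, 16), 78); stopifnot(sum(reads_per) == 1294)
  linked_per <- c(rep(3, 15), 4, 0); stopifnot(sum(linked_per) == 49)
  fx <- linkage_fixture(17, reads_per, linked_per)
  rep_ <- link_contigs(fx$membership, fx$pairs, fx$flagged, fx$stats)
  expect_equal(rep_$n_large_contigs, 17L)
  expect_equal(rep_$n_linked_contigs, 16L)
  expect_equal(rep_$n_member_reads_total, 1294L)
  expect_equal(rep_$n_linked_reads_total, 49L)
  expect_equal(rep_$linked_read_percent, 3.8)
})

test_that("density arithmetic matches the published spacing figures", {
  # 16 linked contigs totaling 244 kb -> one transposase per 15 kb
  kb <- c(rep(15, 12), rep(16, 4), 12); stopifnot(sum(kb[1:16]) == 244)
  fx <- linkage_fixture(17, linked_per_contig = c(rep(1, 16), 0),
                        contig_kb = kb)
  rep_ <- link_contigs(fx$membership, fx$pairs, fx$flagged, fx$stats)
  dens <- density_estimate(rep_, reference_length_bp = 2400000,
                           reference_transposase_count = 20)
  expect_equal(dens$kb_per_transposase, 15)
  expect_equal(dens$n_linked_contigs, 16L)
  expect_equal(dens$linked_kb, 244)
  expect_equal(dens$reference_kb_per_transposase, 120)

  one <- linkage_fixture(1, linked_per_contig = 1, contig_kb = 15)
  r1 <- link_contigs(one$membership, one$pairs, one$flagged, one$stats)
  expect_equal(density_estimate(r1)$kb_per_transposase, 15)
})

test_that("no flagged sequences means zero linkage, and density is undefined", {
  fx <- linkage_fixture(5)
  rep_ <- link_contigs(fx$membership, fx$pairs, character(0), fx$stats)
  expect_equal(rep_$n_linked_contigs, 0L)
  expect_equal(rep_$n_linked_reads_total, 0L)
  expect_error(density_estimate(rep_), "no linked contigs")
})

test_that("linkage is invariant to swapping pair roles and renaming reads", {
  fx <- linkage_fixture(4, linked_per_contig = c(2, 0, 1, 0))
  rep1 <- link_contigs(fx$membership, fx$pairs, fx$flagged, fx$stats)
  swapped <- fx$pairs
  names(swapped)[2:3] <- c("reverse_read_id", "forward_read_id")
  rep2 <- link_contigs(fx$membership, swapped, fx$flagged, fx$stats)
  expect_equal(rep1$linked_read_percent, rep2$linked_read_percent)
  expect_equal(rep1$n_linked_contigs, rep2$n_linked_contigs)

  ren <- function(x) chartr("CL", "XY", x)
  m3 <- fx$membership; m3$read_id <- ren(m3$read_id)
  p3 <- fx$pairs
  p3$forward_read_id <- ren(p3$forward_read_id)
  p3$reverse_read_id <- ren(p3$reverse_read_id)
  rep3 <- link_contigs(m3, p3, ren(fx$flagged), fx$stats)
  expect_equal(rep3$linked_read_percent, rep1$linked_read_percent)
})

test_that("transposase classification respects the strict E cutoff", {
  hits <- data.frame(query_id = "tp", subject_id = c("r1", "r2"),
                     percent_identity = 90, alignment_length = 100L,
                     mismatches = 0L, gap_openings = 0L,
                     q_start = 1L, q_end = 1L, s_start = 1L, s_end = 1L,
                     e_value = c(1e-5, 1e-12), bit_score = 80,
                     stringsAsFactors = FALSE)
  expect_equal(classify_transposase_sequences(c("r1", "r2"), hits), "r2")
  expect_equal(classify_transposase_sequences(c("r1"), empty_hits()),
               character(0))
})

test_that("a contig can be both transposase-encoding and linked", {
  fx <- linkage_fixture(2, linked_per_contig = c(1, 0))
  flagged <- c(fx$flagged, "big01")
  rep_ <- link_contigs(fx$membership, fx$pairs, flagged, fx$stats)
  pc <- rep_$per_contig
  expect_true(pc$encodes_transposase[pc$contig_id == "big01"])
  expect_gte(pc$n_linked_reads[pc$contig_id == "big01"], 1L)
})
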