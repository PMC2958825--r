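# Insertion detection and the direct-repeat decision logic, on genomes
# constructed base by base.

build_insertion_toy <- function(repeat_in_ref = TRUE, repeat_in_query = FALSE,
                                repeat_identity = 1) {
  set.seed(60)
  rep_seq <- random_dna(26)
  flankL <- random_dna(1200) # carries the left anchor ORF
  flankR <- random_dna(1200)
  element <- random_dna(4000)
  rep_right <- if (repeat_identity < 1) mutate_dna(rep_seq, 1 - repeat_identity)
               else rep_seq
  ref_seq <- if (repeat_in_ref)
    paste0(flankL, rep_seq, element, rep_right, flankR)
  else paste0(flankL, element, flankR)
  query_seq <- if (repeat_in_query)
    paste0(flankL, rep_seq, flankR) else paste0(flankL, flankR)

  rl <- if (repeat_in_ref) 26L else 0L
  el_start <- nchar(flankL) + rl + 1L
  el_end <- el_start + 4000L - 1L
  ref_orfs <- data.frame(
    contig_id = "ref", locus_tag = c("RL", "RR"),
    start = c(101L, el_end + rl + 101L),
    end = c(1000L, el_end + rl + 1000L),
    strand = "+", stringsAsFactors = FALSE)
  anchors <- data.frame(
    contig_id = "c1", query_orf = c("QL", "QR"),
    reference_orf = c("RL", "RR"),
    percent_identity = 70, alignment_length = 300L,
    e_value = 1e-40, bit_score = 150,
    q_start = c(101L, nchar(flankL) + 101L),
    q_end = c(1000L, nchar(flankL) + 1000L),
    q_strand = "+",
    r_start = ref_orfs$start, r_end = ref_orfs$end, r_strand = "+",
    hit_q_start = 1L, hit_q_end = 300L, hit_s_start = 1L, hit_s_end = 300L,
    orientation_concordant = TRUE, stringsAsFactors = FALSE)
  if (repeat_in_query) {
    shift <- 26L
    anchors$q_start[2] <- anchors$q_start[2] + shift
    anchors$q_end[2] <- anchors$q_end[2] + shift
  }
  list(ref_seq = ref_seq, query_seq = query_seq, ref_orfs = ref_orfs,
       anchors = anchors,
       elements = data.frame(element_id = "el1", start = el_start,
                             end = el_end, stringsAsFactors = FALSE),
       rep_seq = rep_seq, flankL_len = nchar(flankL))
}

test_that("an annotated element flanked by query-adjacent anchors is called", {
  toy <- build_insertion_toy()
  calls <- find_insertions(toy$anchors, toy$ref_orfs,
                           element_annotations = toy$elements)
  expect_equal(nrow(calls), 1L)
  expect_true(calls$flanks_adjacent)
  expect_false(calls$interior_anchored)
  expect_equal(calls$query_junction, 1001L)
})

test_that("de novo gap scanning finds the same candidate, and a null run is quiet", {
  toy <- build_insertion_toy()
  calls <- find_insertions(toy$anchors, toy$ref_orfs, min_gap = 3000)
  expect_equal(nrow(calls), 1L)
  expect_true(calls$flanks_adjacent)
  # colinear anchors with a small reference gap: no candidates
  none <- toy$anchors
  none$r_start[2] <- none$r_end[1] + 200L
  none$r_end[2] <- none$r_start[2] + 899L
  expect_equal(nrow(find_insertions(none, toy$ref_orfs, min_gap = 3000)), 0L)
})

test_that("a missing flank downgrades the call to indeterminate", {
  toy <- build_insertion_toy()
  calls <- find_insertions(toy$anchors[1, ], toy$ref_orfs,
                           element_annotations = toy$elements)
  expect_equal(calls$verdict, "indeterminate")
  expect_false(calls$flanks_adjacent)
})

test_that("repeat verdict logic covers the full decision table", {
  # repeat in reference, absent from query: inserted after divergence
  toy <- build_insertion_toy(repeat_in_ref = TRUE, repeat_in_query = FALSE)
  call <- find_insertions(toy$anchors, toy$ref_orfs,
                          element_annotations = toy$elements)
  res <- repeat_test(call, toy$ref_seq, toy$query_seq)
  expect_equal(res$verdict, "inserted-after-divergence")
  expect_equal(res$repeat_length, 26L)
  expect_equal(res$repeat_identity, 100)
  expect_equal(res$repeat_seq, toy$rep_seq)
  # exact coordinates of both planted copies
  expect_equal(res$repeat_left_start, toy$flankL_len + 1L)
  expect_equal(res$repeat_left_end, toy$flankL_len + 26L)
  expect_equal(res$repeat_right_start, toy$elements$end + 1L)
  expect_equal(res$repeat_right_end, toy$elements$end + 26L)

  # repeat surviving in the query: the element was deleted from the query
  toy2 <- build_insertion_toy(repeat_in_query = TRUE)
  call2 <- find_insertions(toy2$anchors, toy2$ref_orfs,
                           element_annotations = toy2$elements)
  res2 <- repeat_test(call2, toy2$ref_seq, toy2$query_seq)
  expect_equal(res2$verdict, "deleted-from-query")
  expect_true(res2$repeat_in_query)

  # no reference repeat: indeterminate regardless of the query
  toy3 <- build_insertion_toy(repeat_in_ref = FALSE)
  call3 <- find_insertions(toy3$anchors, toy3$ref_orfs,
                           element_annotations = toy3$elements)
  res3 <- repeat_test(call3, toy3$ref_seq, toy3$query_seq)
  expect_equal(res3$verdict, "indeterminate")

  # degraded repeat below the identity floor: indeterminate
  toy4 <- build_insertion_toy(repeat_identity = 0.65)
  call4 <- find_insertions(toy4$anchors, toy4$ref_orfs,
                           element_annotations = toy4$elements)
  res4 <- repeat_test(call4, toy4$ref_seq, toy4$query_seq,
                      min_identity = 80)
  expect_equal(res4$verdict, "indeterminate")
})

test_that("windows beyond the sequence bounds are clipped with a warning", {
  toy <- build_insertion_toy()
  call <- find_insertions(toy$anchors, toy$ref_orfs,
                          element_annotations = toy$elements)
  short_ref <- substr(toy$ref_seq, 1, toy$elements$end + 200)
  expect_warning(repeat_test(call, short_ref, toy$query_seq, window = 500),
                 "clipped")
})
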