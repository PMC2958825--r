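census_hit <- function(protein, subject, e) {
  data.frame(query_id = protein, subject_id = subject,
             percent_identity = 70, alignment_length = 200L,
             mismatches = 0L, gap_openings = 0L, q_start = 1L, q_end = 200L,
             s_start = 1L, s_end = 600L, e_value = e, bit_score = 300,
             stringsAsFactors = FALSE)
}

test_that("tiers nest cumulatively and use strict thresholds", {
  prot <- paste0("P", 1:5)
  hc <- rbind(census_hit("P1", "c1", 1e-101),
              census_hit("P2", "c2", 1e-60),
              census_hit("P3", "c3", 1e-20),
              census_hit("P4", "c4", 1e-10)) # not < 1e-10
  rows <- census(prot, hc)
  expect_equal(rows$tier, c("<1e-100", "<1e-50", "<1e-10", "none", "none"))
  counts <- census_tier_counts(rows)
  expect_equal(unname(counts["1e-100"]), 1L)
  expect_equal(unname(counts["1e-50"]), 2L) # the 1e-101 hit counts here too
  expect_equal(unname(counts["1e-10"]), 3L)
  expect_equal(unname(counts["none"]), 2L)
})

test_that("contig and singlet hits merge into the overall best", {
  hc <- census_hit("P1", "c1", 1e-30)
  hs <- census_hit("P1", "read9.g1", 1e-70)
  rows <- census("P1", hc, hs)
  expect_equal(rows$best_evalue_overall, 1e-70)
  expect_equal(rows$best_contig_id, "c1")
  expect_equal(rows$best_singlet_id, "read9.g1")
  expect_equal(rows$tier, "<1e-50")
})

test_that("the published tier tallies imply 358 missing genes", {
  # 2200 proteins; 652 better than 1e-100, 1217 than 1e-50, 1842 than 1e-10
  e <- c(rep(1e-150, 652), rep(1e-60, 1217 - 652), rep(1e-20, 1842 - 1217))
  prot <- sprintf("Tcr_%04d", seq_len(2200))
  hc <- do.call(rbind, lapply(seq_along(e), function(i)
    census_hit(prot[i], paste0("c", i), e[i])))
  rows <- census(prot, hc)
  counts <- census_tier_counts(rows)
  expect_equal(unname(counts["1e-100"]), 652L)
  expect_equal(unname(counts["1e-50"]), 1217L)
  expect_equal(unname(counts["1e-10"]), 1842L)
  expect_equal(unname(counts["none"]), 358L)
  expect_equal(unname(counts["total"] - counts["1e-10"]), unname(counts["none"]))
})

test_that("tier tallies are monotone for random censuses", {
  set.seed(50)
  for (i in 1:10) {
    n <- 200
    e <- 10^runif(n, -150, 5)
    e[sample.int(n, 40)] <- NA # no hit at all
    prot <- paste0("P", seq_len(n))
    hc <- do.call(rbind, lapply(which(!is.na(e)), function(j)
      census_hit(prot[j], "c", e[j])))
    counts <- census_tier_counts(census(prot, hc))
    expect_true(counts["1e-100"] <= counts["1e-50"])
    expect_true(counts["1e-50"] <= counts["1e-10"])
    expect_true(counts["1e-10"] + counts["none"] == counts["total"])
  }
})

test_that("missing-gene report counts hypothetical annotations", {
  prot <- paste0("P", 1:8)
  hc <- do.call(rbind, lapply(1:3, function(i)
    census_hit(paste0("P", i), "c", 1e-40)))
  rows <- census(prot, hc)
  ann <- data.frame(
    locus_tag = prot,
    product = c(rep("ATPase", 3), rep("hypothetical protein", 3),
                "phosphonate ABC transporter", "sulfonate transporter"),
    stringsAsFactors = FALSE)
  rep_ <- missing_gene_report(rows, ann)
  expect_equal(rep_$n_missing, 5L)
  expect_equal(rep_$n_hypothetical, 3L)
  expect_setequal(rep_$missing$reference_protein, paste0("P", 4:8))
  expect_true("phosphonate" %in% names(rep_$by_keyword))

  empty <- missing_gene_report(census(character(0), NULL), ann)
  expect_equal(empty$n_missing, 0L)
})
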