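# Constructed ORF sets and hit tables exercising anchoring, block
# segmentation, fusion calls and orientation flags.

orf_row <- function(contig, tag, start, len = 900, strand = "+") {
  data.frame(contig_id = contig, locus_tag = tag, start = start,
             end = start + len - 1L, strand = strand,
             stringsAsFactors = FALSE)
}

pp_hit <- function(q, s, e = 1e-40, bits = 150, id = 80,
                   qs = 1L, qe = 250L, ss = 1L, se = 250L) {
  data.frame(query_id = q, subject_id = s, percent_identity = id,
             alignment_length = qe - qs + 1L, mismatches = 0L,
             gap_openings = 0L, q_start = qs, q_end = qe,
             s_start = ss, s_end = se, e_value = e, bit_score = bits,
             stringsAsFactors = FALSE)
}

test_that("identical ORF sets anchor 1:1 at 100% identity", {
  ref <- do.call(rbind, lapply(1:5, function(i)
    orf_row("ref", paste0("R", i), 1000 * i)))
  qry <- do.call(rbind, lapply(1:5, function(i)
    orf_row("c1", paste0("Q", i), 1000 * i)))
  hits <- do.call(rbind, lapply(1:5, function(i)
    pp_hit(paste0("Q", i), paste0("R", i), id = 100)))
  an <- anchor_orfs(qry, ref, hits)
  expect_equal(nrow(an$anchors), 5L)
  expect_equal(an$anchors$reference_orf, paste0("R", 1:5))
  expect_true(all(an$anchors$percent_identity == 100))
  expect_length(an$unanchored, 0)
})

test_that("weak hits leave ORFs unanchored; unknown loci are errors", {
  ref <- orf_row("ref", "R1", 1000)
  qry <- rbind(orf_row("c1", "Q1", 1000), orf_row("c1", "Q2", 2000))
  hits <- rbind(pp_hit("Q1", "R1", e = 1e-40), pp_hit("Q2", "R1", e = 1e-3))
  an <- anchor_orfs(qry, ref, hits)
  expect_equal(an$anchors$query_orf, "Q1")
  expect_equal(an$unanchored, "Q2")
  expect_error(anchor_orfs(qry, ref, pp_hit("ghost", "R1")), "unknown query")
  expect_error(anchor_orfs(qry, ref, pp_hit("Q1", "ghost")), "unknown reference")
})

test_that("colinear anchors form one block; a large jump breaks it", {
  ref <- do.call(rbind, lapply(1:8, function(i)
    orf_row("ref", paste0("R", i),
            ifelse(i <= 4, 1000 * i, 1000 * i + 50000))))
  qry <- do.call(rbind, lapply(1:8, function(i)
    orf_row("c1", paste0("Q", i), 1000 * i)))
  hits <- do.call(rbind, lapply(1:8, function(i)
    pp_hit(paste0("Q", i), paste0("R", i))))
  an <- anchor_orfs(qry, ref, hits)

  colinear <- build_blocks(an$anchors[1:4, ])
  expect_equal(nrow(colinear$blocks), 1L)
  expect_equal(nrow(colinear$breaks), 0L)
  expect_equal(colinear$blocks$n_anchors, 4L)

  split <- build_blocks(an$anchors)
  expect_equal(nrow(split$blocks), 2L)
  expect_equal(nrow(split$breaks), 1L)
  expect_equal(split$breaks$reason, "jump")
  # recorded distance ~ 50 kb between the flanking anchors:
  # |r_start(R5) - r_end(R4)| = |55000 - 4899|
  expect_equal(split$breaks$reference_distance_bp, 50101)
})

test_that("a sense flip mid-contig records a sense-flip break", {
  ref <- do.call(rbind, lapply(1:6, function(i)
    orf_row("ref", paste0("R", i), c(1, 2, 3, 9, 8, 7)[i] * 1000)))
  qry <- do.call(rbind, lapply(1:6, function(i)
    orf_row("c1", paste0("Q", i), 1000 * i)))
  hits <- do.call(rbind, lapply(1:6, function(i)
    pp_hit(paste0("Q", i), paste0("R", i))))
  an <- anchor_orfs(qry, ref, hits)
  bl <- build_blocks(an$anchors)
  expect_true("sense-flip" %in% bl$breaks$reason)
  expect_setequal(bl$blocks$sense, c("colinear", "inverted"))
})

test_that("every anchor lands in exactly one block or the singleton list", {
  s <- sim_run()
  anchors <- s$tsv("anchors.tsv")
  bl <- build_blocks(anchors)
  in_blocks <- sum(bl$blocks$n_anchors)
  expect_equal(in_blocks + nrow(bl$singletons), nrow(anchors))
})

test_that("fusion calls need two adjacent partners covering disjoint halves", {
  ref <- orf_row("ref", "RF", 10000, len = 1500)
  qry <- rbind(orf_row("c1", "QA", 1000, len = 750),
               orf_row("c1", "QB", 1800, len = 750))
  # each query ORF covers one half of the 499-residue reference protein
  good <- rbind(
    pp_hit("QA", "RF", qs = 1, qe = 245, ss = 1, se = 245),
    pp_hit("QB", "RF", qs = 1, qe = 245, ss = 250, se = 494))
  an <- anchor_orfs(qry, ref, good)
  calls <- call_fusions(an$anchors, ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$reference_orf, "RF")
  expect_equal(calls$query_orf_1, "QA")
  expect_equal(calls$query_orf_2, "QB")

  # both partners covering the same half: overlap exceeds the cap
  same_half <- rbind(
    pp_hit("QA", "RF", qs = 1, qe = 245, ss = 1, se = 245),
    pp_hit("QB", "RF", qs = 1, qe = 245, ss = 5, se = 249))
  an2 <- anchor_orfs(qry, ref, same_half)
  expect_equal(nrow(call_fusions(an2$anchors, ref)), 0L)

  # a single ORF covering everything is not a fusion
  single <- pp_hit("QA", "RF", qs = 1, qe = 494, ss = 1, se = 494)
  an3 <- anchor_orfs(rbind(qry[1, ]), ref, single)
  expect_equal(nrow(call_fusions(an3$anchors, ref)), 0L)

  # marginal coverage by one partner: below min_cov_each
  shallow <- rbind(
    pp_hit("QA", "RF", qs = 1, qe = 90, ss = 1, se = 90),
    pp_hit("QB", "RF", qs = 1, qe = 245, ss = 250, se = 494))
  an4 <- anchor_orfs(qry, ref, shallow)
  expect_equal(nrow(call_fusions(an4$anchors, ref)), 0L)
})

test_that("planted reverse-orientation foreign ORFs are all flagged", {
  s <- sim_run()
  led <- s$ledger
  disc <- s$tsv("discordant_orfs.tsv")
  win <- s$tsv("contig_windows.tsv")
  co <- read_orf_table(file.path(s$dir, "contig_orfs.tsv"))
  foreign <- led[led$kind == "foreign-orf", ]
  for (i in seq_len(nrow(foreign))) {
    w <- win[win$start <= foreign$query_start[i] &
               win$end >= foreign$query_end[i], ]
    expect_equal(nrow(w), 1L)
    expect_true(w$assembled)
    cs <- foreign$query_start[i] - w$start + 1L
    ce <- foreign$query_end[i] - w$start + 1L
    hit <- co[co$contig_id == w$contig_id & co$start <= ce & co$end >= cs &
                co$strand == foreign$strand[i], ]
    # the overlapping call for this locus carries a discordance flag
    expect_true(any(hit$locus_tag %in% disc$locus_tag))
  }
})

test_that("orientation flags need both discordance and missing anchors", {
  ref <- do.call(rbind, lapply(1:4, function(i)
    orf_row("ref", paste0("R", i), 1000 * i)))
  qry <- rbind(orf_row("c1", "Q1", 1000), orf_row("c1", "Q2", 2000),
               orf_row("c1", "QX", 3000, strand = "-"),
               orf_row("c1", "Q3", 4000))
  hits <- do.call(rbind, lapply(1:3, function(i)
    pp_hit(paste0("Q", i), paste0("R", i))))
  an <- anchor_orfs(qry, ref, hits)
  flags <- flag_discordant_orfs(an$anchors, qry)
  expect_equal(flags$locus_tag, "QX")

  # same ORF, concordant strand: not flagged
  qry2 <- qry; qry2$strand[qry2$locus_tag == "QX"] <- "+"
  expect_equal(nrow(flag_discordant_orfs(an$anchors, qry2)), 0L)

  # spanning-read support annotation
  spans <- data.frame(read_id = paste0("rd", 1:4), contig_id = "c1",
                      start = c(2500, 2600, 2700, 100),
                      end = c(3400, 3500, 3600, 700),
                      stringsAsFactors = FALSE)
  flags2 <- flag_discordant_orfs(an$anchors, qry, read_spans = spans)
  expect_equal(flags2$spanning_reads, 3L)
  expect_true(flags2$assembly_supported)
})
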