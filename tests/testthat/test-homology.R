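test_that("evalue follows the closed Karlin-Altschul form", {
  # bit score with 2^(-S) * mn = 1
  expect_equal(evalue(log2(1e6), 1e6), 1.0)
  # +10 bits divides E by 1024
  expect_equal(evalue(60, 1e6) * 1024, evalue(50, 1e6))
  expect_equal(evalue(50, 1e6), 1e6 * 2^-50)
  expect_equal(evalue(50, 1e6), 8.88e-10, tolerance = 1e-2)
  # monotone in score and search space
  expect_true(evalue(100, 1e6) < evalue(99, 1e6))
  expect_true(evalue(50, 2e6) > evalue(50, 1e6))
})

test_that("E-value doubles (approximately) when subject length doubles", {
  set.seed(20)
  prot <- paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 80,
                       replace = TRUE), collapse = "")
  bt <- paste(vapply(strsplit(prot, "")[[1]], function(a) {
    cands <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
    cands[1]
  }, character(1)), collapse = "")
  nt1 <- paste0(bt, random_dna(760))
  nt2 <- paste0(nt1, random_dna(1000))
  h1 <- translated_search(c(p = prot), c(s = nt1))[1, ]
  h2 <- translated_search(c(p = prot), c(s = nt2))[1, ]
  expect_equal(h2$bit_score, h1$bit_score)
  expect_equal(h2$e_value / h1$e_value, nchar(nt2) / nchar(nt1))
})

test_that("self-alignment is a single full-span 100% hit", {
  set.seed(21)
  s <- random_dna(1000)
  h <- seed_extend_align(c(q = s), c(s = s))
  expect_equal(nrow(h), 1L)
  expect_equal(h$percent_identity, 100)
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end), c(1, 1000, 1, 1000))
  expect_equal(h$mismatches + h$gap_openings, 0L)
})

test_that("a planted diverged segment is found and scored like full Smith-Waterman", {
  skip_if_not_installed("Biostrings")
  set.seed(22)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  # divergence kept within the 11-mer seeding regime (a ~30% diverged
  # plant occasionally carries no exact 11-mer at all, as with blastn)
  for (div in c(0.1, 0.2, 0.25)) {
    seg <- random_dna(600)
    subj <- paste0(random_dna(5000), mutate_dna(seg, div), random_dna(4400))
    h <- seed_extend_align(c(q = seg), c(s = subj))
    expect_gte(nrow(h), 1L)
    ora <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seg), Biostrings::DNAString(subj),
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    expect_equal(h$raw_score[1], Biostrings::score(ora))
    if (div <= 0.1) { # mild divergence: alignment covers the whole plant
      expect_gte(h$q_end[1] - h$q_start[1] + 1, 0.9 * 600)
      expect_true(h$s_start[1] >= 4900 && h$s_end[1] <= 10100)
    }
  }
})

test_that("reverse-complement plants are reported with s_start > s_end", {
  set.seed(23)
  seg <- random_dna(400)
  subj <- paste0(random_dna(2000), revcomp(seg), random_dna(1500))
  h <- seed_extend_align(c(q = seg), c(s = subj))
  expect_gte(nrow(h), 1L)
  expect_true(h$s_start[1] > h$s_end[1])
  expect_true(h$s_end[1] >= 1990 && h$s_start[1] <= 2420)
  expect_equal(h$percent_identity[1], 100)
})

test_that("nucleotide scoring is symmetric", {
  set.seed(24)
  for (i in 1:5) {
    a <- random_dna(500)
    b <- paste0(random_dna(100), mutate_dna(a, 0.2), random_dna(80))
    h1 <- seed_extend_align(c(q = a), c(s = b))
    h2 <- seed_extend_align(c(q = b), c(s = a))
    expect_equal(h1$raw_score[1], h2$raw_score[1])
  }
})

test_that("translated search reports frames and nucleotide coordinates", {
  set.seed(25)
  # back-translate a protein, then verify a frame +1 perfect hit
  prot <- paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 120,
                       replace = TRUE), collapse = "")
  bt <- paste(vapply(strsplit(prot, "")[[1]], function(a) {
    cands <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
    cands[sample.int(length(cands), 1)]
  }, character(1)), collapse = "")
  h <- translated_search(c(p = prot), c(s = bt))
  expect_equal(h$percent_identity[1], 100)
  expect_equal(h$frame[1], 1L)
  expect_equal(c(h$s_start[1], h$s_end[1]), c(1L, 360L))

  # synonymous recoding is invisible at the protein level
  bt2 <- paste(vapply(strsplit(prot, "")[[1]], function(a) {
    cands <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
    cands[sample.int(length(cands), 1)]
  }, character(1)), collapse = "")
  h2 <- translated_search(c(p = prot), c(s = bt2))
  expect_equal(h2$percent_identity[1], 100)

  # reverse strand: frame negative, coordinates strand-encoded
  h3 <- translated_search(c(p = prot), c(s = revcomp(bt)))
  expect_equal(h3$percent_identity[1], 100)
  expect_true(h3$frame[1] < 0)
  expect_true(h3$s_start[1] > h3$s_end[1])
  expect_equal(c(h3$s_start[1], h3$s_end[1]), c(360L, 1L))
})

test_that("local_align recovers a shared exact substring between windows", {
  set.seed(26)
  core <- random_dna(26)
  a <- paste0(random_dna(300), core)
  b <- paste0(core, random_dna(300))
  h <- local_align(c(L = a), c(R = b))
  expect_equal(h$alignment_length, 26L)
  expect_equal(h$percent_identity, 100)
  expect_equal(h$q_start, 301L)
  expect_equal(h$s_end, 26L)
})
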