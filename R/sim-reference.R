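# Mock reference genome builder: random backbone at a GC target with
# non-overlapping ORFs on strand runs, plus a prophage flanked by an exact
# direct repeat.
#
# Each planted ORF is preceded (in its own frame) by an in-frame stop
# codon planted in the intergenic spacer, so a naive maximal-ORF scan
# recovers the planted coordinates exactly.

PRODUCT_VOCABULARY <- c(
  "ABC transporter permease", "sulfate transporter", "carbonic anhydrase",
  "RuBisCO large subunit", "carboxysome shell protein",
  "sulfur oxidation protein SoxA", "sulfur oxidation protein SoxB",
  "DNA polymerase III subunit", "ribosomal protein", "elongation factor",
  "phosphonate ABC transporter", "sulfonate transporter",
  "outer membrane porin", "two-component sensor kinase",
  "flagellar motor protein", "cytochrome c oxidase subunit",
  "NADH dehydrogenase subunit", "signal peptidase", "chaperonin GroEL",
  "sodium/proton antiporter"
)

PHAGE_PRODUCTS <- c("phage integrase", "phage capsid protein",
                    "phage terminase large subunit", "phage tail fiber",
                    "phage portal protein")

# sample one ORF: ATG + non-stop codons at a GC target + stop codon
.random_orf <- function(len_bp, gc) {
  stopifnot(len_bp %% 3L == 0L, len_bp >= 9L)
  ncod <- len_bp %/% 3L
  cods <- .codons_by_aa()
  sense <- setdiff(unlist(cods, use.names = FALSE), cods[["*"]])
  w <- .gc_weights(gc)
  codon_w <- vapply(sense, function(cd) {
    prod(w[strsplit(cd, "")[[1]]])
  }, numeric(1))
  mid <- sample(sense, ncod - 2L, replace = TRUE, prob = codon_w)
  stop_w <- vapply(cods[["*"]], function(cd) prod(w[strsplit(cd, "")[[1]]]),
                   numeric(1))
  stop_c <- sample(cods[["*"]], 1L, prob = stop_w)
  paste0("ATG", .collapse(mid), stop_c)
}

# partition `extra` bp over n gaps of minimum size min_gap
.random_gaps <- function(n, total, min_gap = 40L) {
  if (n == 0L) return(integer(0))
  extra <- total - n * min_gap
  stopifnot(extra >= 0L)
  if (extra == 0L) return(rep(min_gap, n))
  cuts <- sort(sample.int(extra + n - 1L, n - 1L))
  parts <- diff(c(0L, cuts, extra + n)) - 1L
  min_gap + parts
}

# build a gene-bearing segment; returns list(seq, orfs) with local coords
.build_segment <- function(orf_lens, gap_total, gc, strand_switch_prob = 0.15,
                           products = NULL) {
  n <- length(orf_lens)
  gaps <- .random_gaps(n + 1L, gap_total)
  strands <- character(n)
  if (n > 0L) {
    strands[1L] <- sample(c("+", "-"), 1L)
    for (i in seq_len(n - 1L))
      strands[i + 1L] <- if (runif(1) < strand_switch_prob)
        setdiff(c("+", "-"), strands[i]) else strands[i]
  }
  pieces <- character(2L * n + 1L)
  starts <- integer(n); ends <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    g <- .collapse(.random_bases(gaps[i], gc))
    orf <- .random_orf(orf_lens[i], gc)
    if (strands[i] == "-") orf <- revcomp(orf)
    pieces[2L * i - 1L] <- g
    pieces[2L * i] <- orf
    pos <- pos + gaps[i]
    starts[i] <- pos + 1L
    ends[i] <- pos + orf_lens[i]
    pos <- pos + orf_lens[i]
  }
  pieces[2L * n + 1L] <- .collapse(.random_bases(gaps[n + 1L], gc))
  seq <- .collapse(pieces)
  # plant an in-frame stop guard flush against each ORF in the spacer
  if (n > 0L) {
    ch <- strsplit(seq, "")[[1]]
    for (i in seq_len(n)) {
      if (strands[i] == "+") ch[(starts[i] - 3L):(starts[i] - 1L)] <- c("T", "A", "A")
      else ch[(ends[i] + 1L):(ends[i] + 3L)] <- c("T", "T", "A")
    }
    seq <- .collapse(ch)
  }
  orfs <- data.frame(start = starts, end = ends, strand = strands,
                     stringsAsFactors = FALSE)
  if (!is.null(products) && n > 0L) orfs$product <- rep_len(products, n)
  list(seq = seq, orfs = orfs)
}

# adjust intergenic bases so that the global G+C count hits the target
.calibrate_gc <- function(seq, orfs, gc_target, protect = integer(0)) {
  ch <- strsplit(seq, "")[[1]]
  target <- round(gc_target * length(ch))
  current <- sum(ch == "G" | ch == "C")
  delta <- target - current
  if (delta == 0L) return(seq)
  in_orf <- rep(FALSE, length(ch))
  for (i in seq_len(nrow(orfs))) {
    lo <- max(1L, orfs$start[i] - 3L)   # keep the stop guards intact
    hi <- min(length(ch), orfs$end[i] + 3L)
    in_orf[lo:hi] <- TRUE
  }
  if (length(protect)) in_orf[protect] <- TRUE
  free <- which(!in_orf)
  if (delta > 0L) {
    pool <- free[ch[free] %in% c("A", "T")]
    pick <- pool[sample.int(length(pool), min(delta, length(pool)))]
    ch[pick] <- sample(c("G", "C"), length(pick), replace = TRUE)
  } else {
    pool <- free[ch[free] %in% c("G", "C")]
    pick <- pool[sample.int(length(pool), min(-delta, length(pool)))]
    ch[pick] <- sample(c("A", "T"), length(pick), replace = TRUE)
  }
  .collapse(ch)
}

.add_translations <- function(orfs, seq) {
  if (nrow(orfs) == 0L) { orfs$translation <- character(0); return(orfs) }
  orfs$translation <- vapply(seq_len(nrow(orfs)), function(i) {
    s <- substr(seq, orfs$start[i], orfs$end[i])
    if (orfs$strand[i] == "-") s <- revcomp(s)
    sub("\\*$", "", translate(s, 1L))
  }, character(1))
  orfs
}

#' Build the mock annotated reference genome
#'
#' A random genome of the requested length at the GC target, carrying
#' `n_orfs` non-overlapping backbone ORFs (lengths 300-3000 bp, both
#' strands, arranged in operon-like strand runs) and, when configured, a
#' prophage segment with its own ORFs and an exact direct repeat
#' duplicated flush at both boundaries.  Base composition is calibrated
#' on the intergenic spacers to hit the GC target exactly.  Deterministic
#' under a fixed seed.
#'
#' @param config a [sim_config()]
#' @return object of class `annotated_genome`: list with `id`, `seq`,
#'   `orfs` (contig_id, locus_tag, start, end, strand, product,
#'   translation), `elements` (prophage span and repeat coordinates)
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rl <- if (!is.null(config$prophage)) config$prophage$repeat_length else 0L
  ph_len <- if (!is.null(config$prophage)) config$prophage$length_bp else 0L
  backbone_len <- config$genome_length - ph_len - 2L * rl
  n <- config$n_orfs

  # ORF length mix: mostly 300-1500 bp with a long tail to 3000 bp
  n_long <- round(0.15 * n)
  lens <- c(
    3L * sample(500:1000, n_long, replace = TRUE),
    3L * sample(100:500, n - n_long, replace = TRUE)
  )
  lens <- sample(lens)
  min_gap_total <- 40L * (n + 1L)
  if (sum(lens) + min_gap_total > backbone_len) {
    scale <- (backbone_len - min_gap_total) / sum(lens)
    lens <- pmax(300L, 3L * floor(lens * scale / 3L))
    if (sum(lens) + min_gap_total > backbone_len)
      stop("cannot place ", n, " non-overlapping ORFs in a ",
           config$genome_length, " bp genome: reduce n_orfs or increase ",
           "genome_length")
  }
  seg <- .build_segment(lens, backbone_len - sum(lens), config$gc_reference,
                        products = NULL)
  orfs <- seg$orfs
  seq <- seg$seq
  if (nrow(orfs)) {
    hyp <- runif(nrow(orfs)) < 0.4
    orfs$product <- ifelse(hyp, "hypothetical protein",
                           sample(PRODUCT_VOCABULARY, nrow(orfs), replace = TRUE))
  } else orfs$product <- character(0)

  elements <- data.frame(
    element_id = character(0), kind = character(0),
    start = integer(0), end = integer(0),
    repeat_left_start = integer(0), repeat_left_end = integer(0),
    repeat_right_start = integer(0), repeat_right_end = integer(0),
    repeat_seq = character(0), stringsAsFactors = FALSE)

  if (!is.null(config$prophage)) {
    n_ph <- max(1L, ph_len %/% 2000L)
    ph_lens <- rep(3L * as.integer(floor((ph_len / n_ph) * 2 / 9)), n_ph)
    ph_lens <- pmin(ph_lens, 3000L)
    seg_ph <- .build_segment(ph_lens, ph_len - sum(ph_lens),
                             config$gc_reference,
                             products = PHAGE_PRODUCTS)
    rep_seq <- .collapse(.random_bases(rl, config$gc_reference))
    site <- config$prophage$insertion_site
    if (is.null(site)) {
      # auto: an intergenic point in the last quarter of the backbone,
      # clear of the translocation regions
      cand <- round(0.85 * backbone_len)
      in_orf <- orfs$start <= cand & orfs$end >= cand
      while (any(in_orf)) {
        cand <- max(orfs$end[in_orf]) + 10L
        in_orf <- orfs$start <= cand & orfs$end >= cand
      }
      site <- cand
    }
    if (any(orfs$start <= site & orfs$end >= site))
      stop("prophage insertion_site falls inside a backbone ORF")
    insert <- paste0(rep_seq, seg_ph$seq, rep_seq)
    seq <- paste0(substr(seq, 1L, site - 1L), insert,
                  substr(seq, site, nchar(seq)))
    shift <- nchar(insert)
    after <- orfs$start >= site
    orfs$start[after] <- orfs$start[after] + shift
    orfs$end[after] <- orfs$end[after] + shift
    ph_orfs <- seg_ph$orfs
    ph_orfs$start <- ph_orfs$start + site - 1L + rl
    ph_orfs$end <- ph_orfs$end + site - 1L + rl
    orfs <- rbind(orfs[, c("start", "end", "strand", "product")],
                  ph_orfs[, c("start", "end", "strand", "product")])
    elements <- rbind(elements, data.frame(
      element_id = "prophage1", kind = "prophage",
      start = site + rl, end = site + rl + ph_len - 1L,
      repeat_left_start = site, repeat_left_end = site + rl - 1L,
      repeat_right_start = site + rl + ph_len,
      repeat_right_end = site + rl + ph_len + rl - 1L,
      repeat_seq = rep_seq, stringsAsFactors = FALSE))
  }

  orfs <- orfs[order(orfs$start), , drop = FALSE]
  protect <- if (nrow(elements))
    c(elements$repeat_left_start:elements$repeat_left_end,
      elements$repeat_right_start:elements$repeat_right_end) else integer(0)
  seq <- .calibrate_gc(seq, orfs, config$gc_reference, protect)
  orfs <- data.frame(
    contig_id = rep("ref", nrow(orfs)),
    locus_tag = sprintf("REF_%04d", seq_len(nrow(orfs))),
    orfs, stringsAsFactors = FALSE, row.names = NULL)
  orfs <- .add_translations(orfs, seq)
  structure(list(id = "ref", seq = seq, orfs = orfs, elements = elements),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  gcv <- gc_content(x$seq)$gc_fraction
  cat(sprintf("Annotated genome '%s': %d bp, GC %.1f%%, %d ORFs, %d elements\n",
              x$id, nchar(x$seq), 100 * gcv, nrow(x$orfs), nrow(x$elements)))
  invisible(x)
}
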