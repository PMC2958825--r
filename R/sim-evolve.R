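# Evolve the diverged query lineage from the reference: prophage + repeat
# removal, translocation, ORF splits (reference-side fusions), mobile
# element and foreign ORF insertions, and codon-aware substitutions with
# GC drift.  Every planted event is recorded in a truth ledger.

# shift stored query coordinates in ORF table and event list after an
# insertion of `len` bp at position `at` (1-based; bases at >= at move up)
.shift_after <- function(x, at, len) {
  ifelse(!is.na(x) & x >= at, x + len, x)
}

.new_event <- function(kind, locus_tag = NA, ref_start = NA, ref_end = NA,
                       query_start = NA, query_end = NA, strand = NA,
                       aa_identity = NA, note = NA) {
  data.frame(kind = kind, locus_tag = as.character(locus_tag),
             ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
             query_start = as.integer(query_start),
             query_end = as.integer(query_end),
             strand = as.character(strand),
             aa_identity = as.numeric(aa_identity),
             note = as.character(note), stringsAsFactors = FALSE)
}

# codon-aware mutation of one coding sequence (given on its coding strand).
# Exact per-ORF site counts: third positions carry `ratio` times the
# per-site rate of first/second positions; replacements drift toward the
# target base weights.  First and last codons are left intact.
#
# `drift_env`, when given, holds a genome-wide counter `need`: the number
# of G+C bases still to be shed (positive) or gained (negative) to hit
# the query GC target.  Synonymous third-position changes are then chosen
# preferentially in the needed direction, which is how the planted
# divergence and the GC drift coexist without extra substitutions.
.mutate_coding <- function(orf_seq, d, ratio, drift_w, drift_env = NULL) {
  ncod <- nchar(orf_seq) %/% 3L
  if (ncod <= 2L || d <= 0) return(orf_seq)
  ch <- strsplit(orf_seq, "")[[1]]
  interior <- 2:(ncod - 1L)
  n_int <- length(interior)
  r <- 3 * d / (2 + ratio) # per-site pos1/2 rate; pos3 rate = ratio * r
  c3 <- min(n_int, round(ratio * r * n_int))
  c12 <- round(r * 2L * n_int)
  gcode <- .genetic_code()
  GC <- c("G", "C"); AT <- c("A", "T")
  bump <- function(old, new) {
    if (!is.null(drift_env)) # need = current GC excess; track every change
      drift_env$need <- drift_env$need + ((new %in% GC) - (old %in% GC))
  }
  codon_at <- function(k) .collapse(ch[(3L * k - 2L):(3L * k)])
  # third-position synonymous changes
  cand3 <- sample(interior)
  if (!is.null(drift_env) && drift_env$need != 0L) {
    # handle drift-capable codons first while the counter is open
    from <- if (drift_env$need > 0L) GC else AT
    capable <- ch[3L * cand3] %in% from
    cand3 <- c(cand3[capable], cand3[!capable])
  }
  done3 <- 0L
  for (k in cand3) {
    if (done3 >= c3) break
    cod <- codon_at(k)
    aa <- gcode[[cod]]
    old <- substr(cod, 3L, 3L)
    alts <- setdiff(c("A", "C", "G", "T"), old)
    alt_cods <- paste0(substr(cod, 1L, 2L), alts)
    keep <- alts[gcode[alt_cods] == aa]
    if (length(keep) == 0L) next
    pick <- NULL
    if (!is.null(drift_env) && drift_env$need > 0L && old %in% GC) {
      to <- intersect(keep, AT)
      if (length(to)) pick <- if (length(to) == 1L) to else sample(to, 1L)
    } else if (!is.null(drift_env) && drift_env$need < 0L && old %in% AT) {
      to <- intersect(keep, GC)
      if (length(to)) pick <- if (length(to) == 1L) to else sample(to, 1L)
    }
    if (is.null(pick))
      pick <- if (length(keep) == 1L) keep else
        sample(keep, 1L, prob = drift_w[keep])
    ch[3L * k] <- pick
    bump(old, pick)
    done3 <- done3 + 1L
  }
  # first/second-position changes (any base, never creating a stop)
  pos12 <- c(3L * interior - 2L, 3L * interior - 1L)
  sel <- sample(pos12, min(c12, length(pos12)))
  for (p in sel) {
    k <- (p + 2L) %/% 3L
    cod <- codon_at(k)
    off <- p - (3L * k - 3L) # 1 or 2 within codon
    alts <- setdiff(c("A", "C", "G", "T"), ch[p])
    new_cods <- vapply(alts, function(b) {
      cc <- strsplit(cod, "")[[1]]; cc[off] <- b; .collapse(cc)
    }, character(1))
    ok <- alts[gcode[new_cods] != "*"]
    if (length(ok) == 0L) next
    old <- ch[p]
    ch[p] <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = drift_w[ok])
    bump(old, ch[p])
  }
  .collapse(ch)
}

.aa_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(NA_real_)
  mean(strsplit(substr(a, 1L, n), "")[[1]] == strsplit(substr(b, 1L, n), "")[[1]])
}

#' Evolve the diverged query lineage
#'
#' Starting from the reference, the query lineage (a) loses the prophage
#' together with both copies of its direct repeat, (b) undergoes the
#' configured translocation so regionB becomes adjacent to regionA (the
#' intervening segment is relocated behind regionB's former neighbors),
#' (c) has `n_fusions` long reference ORFs split into two adjacent query
#' ORFs sharing the reference span (so the reference ORF looks like a
#' fusion of two query ORFs), (d) gains transposase copies and
#' reverse-orientation foreign ORFs in intergenic spacers, and (e)
#' accumulates codon-aware substitutions at the planted rate with
#' synonymous sites mutated `syn_nonsyn_ratio` times faster and base
#' replacements drifted toward the query GC target.  Every event is
#' recorded in the truth ledger with final query coordinates.
#'
#' @param ref an [build_reference()] result
#' @param config the same [sim_config()]
#' @return list with `genome` (query `annotated_genome`) and `ledger`
#'   (data.frame in the ledger layout)
#' @export
evolve_query <- function(ref, config) {
  stopifnot(inherits(ref, "annotated_genome"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  seq <- ref$seq
  orfs <- ref$orfs
  orfs$ref_locus <- orfs$locus_tag
  orfs$ref_start <- orfs$start
  orfs$ref_end <- orfs$end
  events <- list()
  shift_events <- function(at, len) {
    for (i in seq_along(events)) {
      events[[i]]$query_start <<- .shift_after(events[[i]]$query_start, at, len)
      events[[i]]$query_end <<- .shift_after(events[[i]]$query_end, at, len)
    }
  }

  ## (a) prophage + both direct-repeat copies removed
  if (!is.null(config$prophage)) {
    el <- ref$elements[ref$elements$kind == "prophage", ]
    if (nrow(el) != 1L)
      stop("reference does not carry a prophage annotation")
    cut_lo <- el$repeat_left_start
    cut_hi <- el$repeat_right_end
    removed <- cut_hi - cut_lo + 1L
    inside <- orfs$start >= cut_lo & orfs$end <= cut_hi
    lost <- orfs$locus_tag[inside]
    orfs <- orfs[!inside, , drop = FALSE]
    seq <- paste0(substr(seq, 1L, cut_lo - 1L),
                  substr(seq, cut_hi + 1L, nchar(seq)))
    after <- orfs$start > cut_hi
    orfs$start[after] <- orfs$start[after] - removed
    orfs$end[after] <- orfs$end[after] - removed
    events[[length(events) + 1L]] <- .new_event(
      "prophage", locus_tag = el$element_id,
      ref_start = cut_lo, ref_end = cut_hi,
      query_start = cut_lo, query_end = cut_lo,
      note = paste0("repeat=", el$repeat_seq, ";lost_loci=",
                    paste(lost, collapse = "|")))
    ph_removed_before <- function(x) ifelse(x > cut_hi, x - removed, x)
  } else {
    ph_removed_before <- identity
  }

  ## (b) translocation: regionB spliced in right after regionA
  if (!is.null(config$translocation)) {
    a <- ph_removed_before(config$translocation$regionA)
    b <- ph_removed_before(config$translocation$regionB)
    # snap region bounds outward to whole ORFs
    snap <- function(pos, is_start) {
      hit <- which(orfs$start <= pos & orfs$end >= pos)
      if (length(hit) == 0L) return(pos)
      if (is_start) min(orfs$start[hit]) - 4L else max(orfs$end[hit]) + 4L
    }
    a <- c(snap(a[1L], TRUE), snap(a[2L], FALSE))
    b <- c(snap(b[1L], TRUE), snap(b[2L], FALSE))
    n0 <- nchar(seq)
    stopifnot(a[2L] < b[1L], b[2L] <= n0)
    piece <- function(lo, hi) if (hi >= lo) substr(seq, lo, hi) else ""
    seq <- paste0(piece(1L, a[2L]), piece(b[1L], b[2L]),
                  piece(a[2L] + 1L, b[1L] - 1L), piece(b[2L] + 1L, n0))
    lenB <- b[2L] - b[1L] + 1L
    lenGap <- b[1L] - 1L - a[2L]
    remap <- function(x) {
      ifelse(x <= a[2L], x,
      ifelse(x >= b[1L] & x <= b[2L], x - lenGap,
      ifelse(x > a[2L] & x < b[1L], x + lenB, x)))
    }
    spanning <- (orfs$start <= a[2L] & orfs$end > a[2L]) |
      (orfs$start < b[1L] & orfs$end >= b[1L]) |
      (orfs$start <= b[2L] & orfs$end > b[2L])
    if (any(spanning)) stop("translocation boundary splits an ORF")
    orfs$start <- remap(orfs$start)
    orfs$end <- remap(orfs$end)
    events[[length(events) + 1L]] <- .new_event(
      "translocation",
      ref_start = config$translocation$regionA[1L],
      ref_end = config$translocation$regionB[2L],
      query_start = a[1L], query_end = a[2L] + lenB,
      note = sprintf("junction=%d;gap_bp=%d", a[2L] + 1L,
                     b[1L] - a[2L] - 1L))
  }

  ## (c) fusions: split a long reference ORF into two adjacent query ORFs
  if (config$n_fusions > 0L) {
    elig <- which(orfs$end - orfs$start + 1L >= 900L)
    if (length(elig) < config$n_fusions)
      stop("not enough ORFs >= 900 bp to plant ", config$n_fusions, " fusions")
    chosen <- sample(elig, config$n_fusions)
    new_rows <- list()
    drop <- integer(0)
    for (i in chosen) {
      len <- orfs$end[i] - orfs$start[i] + 1L
      ncod <- len %/% 3L
      k <- ncod %/% 2L # ORF1 = codons 1..k (codon k becomes its stop)
      ch <- strsplit(seq, "")[[1]]
      if (orfs$strand[i] == "+") {
        stop_at <- orfs$start[i] + 3L * (k - 1L)
        ch[stop_at:(stop_at + 2L)] <- c("T", "A", "A")
        ch[(stop_at + 3L):(stop_at + 5L)] <- c("A", "T", "G")
        half1 <- c(orfs$start[i], stop_at + 2L)
        half2 <- c(stop_at + 3L, orfs$end[i])
      } else {
        stop_at <- orfs$end[i] - 3L * k + 1L # codon k on minus strand
        ch[stop_at:(stop_at + 2L)] <- c("T", "T", "A") # revcomp(TAA)
        ch[(stop_at - 3L):(stop_at - 1L)] <- c("C", "A", "T") # revcomp(ATG)
        half1 <- c(stop_at, orfs$end[i])
        half2 <- c(orfs$start[i], stop_at - 1L)
      }
      seq <- .collapse(ch)
      for (h in list(half1, half2)) {
        row <- orfs[i, , drop = FALSE]
        row$start <- h[1L]; row$end <- h[2L]
        new_rows[[length(new_rows) + 1L]] <- row
      }
      drop <- c(drop, i)
      events[[length(events) + 1L]] <- .new_event(
        "fusion", locus_tag = orfs$ref_locus[i],
        ref_start = orfs$ref_start[i], ref_end = orfs$ref_end[i],
        query_start = orfs$start[i], query_end = orfs$end[i],
        strand = orfs$strand[i],
        note = sprintf("split_codon=%d;n_codons=%d", k, ncod))
    }
    orfs <- rbind(orfs[-drop, , drop = FALSE], do.call(rbind, new_rows))
    orfs <- orfs[order(orfs$start), , drop = FALSE]
  }

  ## (d) insertions: transposase copies, then reverse-orientation foreign ORFs
  junction_pos <- function() {
    for (e in events) if (e$kind == "prophage") return(e$query_start)
    NA_integer_
  }
  insert_orf <- function(orf_seq, strand, product, kind, require_same_strand_flanks = FALSE) {
    # fragment carries stop guards on both sides in both frames
    frag <- paste0("TAA", if (strand == "-") revcomp(orf_seq) else orf_seq, "TTA")
    for (attempt in 1:50) {
      ord <- order(orfs$start)
      gaps_lo <- c(1L, orfs$end[ord] + 8L)
      gaps_hi <- c(orfs$start[ord] - 8L, nchar(seq))
      wide <- which(gaps_hi - gaps_lo > 10L)
      # keep the prophage excision junction clean: its flanking genes must
      # stay adjacent for the downstream insertion logic to see the locus
      j <- junction_pos()
      if (!is.na(j))
        wide <- wide[gaps_hi[wide] < j - 50L | gaps_lo[wide] > j + 50L]
      if (length(wide) == 0L) stop("no intergenic space left for insertions")
      g <- wide[sample.int(length(wide), 1L)]
      if (require_same_strand_flanks) {
        if (g == 1L || g > nrow(orfs)) next
        s_prev <- orfs$strand[ord][g - 1L]
        s_next <- orfs$strand[ord][g]
        if (s_prev != s_next) next
        if (s_prev == strand) strand <- setdiff(c("+", "-"), s_prev)
        frag <- paste0("TAA", if (strand == "-") revcomp(orf_seq) else orf_seq, "TTA")
      }
      at <- (gaps_lo[g] + gaps_hi[g]) %/% 2L
      seq <<- paste0(substr(seq, 1L, at - 1L), frag,
                     substr(seq, at, nchar(seq)))
      flen <- nchar(frag)
      orfs$start <<- .shift_after(orfs$start, at, flen)
      orfs$end <<- .shift_after(orfs$end, at, flen)
      shift_events(at, flen)
      o_start <- at + 3L
      o_end <- at + 3L + nchar(orf_seq) - 1L
      orfs <<- rbind(orfs, data.frame(
        contig_id = "query", locus_tag = NA_character_,
        start = o_start, end = o_end, strand = strand, product = product,
        translation = NA_character_, ref_locus = NA_character_,
        ref_start = NA_integer_, ref_end = NA_integer_,
        stringsAsFactors = FALSE))
      orfs <<- orfs[order(orfs$start), , drop = FALSE]
      events[[length(events) + 1L]] <<- .new_event(
        kind, query_start = o_start, query_end = o_end, strand = strand,
        note = product)
      return(invisible(TRUE))
    }
    stop("could not place ", kind, " after bounded retries")
  }

  transposase_protein <- NULL
  if (config$n_transposase_copies > 0L) {
    tp <- .random_orf(config$transposase_length_bp, config$gc_query)
    transposase_protein <- sub("\\*$", "", translate(tp, 1L))
    for (i in seq_len(config$n_transposase_copies)) {
      copy <- .mutate_coding(tp, 0.02, config$syn_nonsyn_ratio,
                             .gc_weights(config$gc_query))
      insert_orf(copy, sample(c("+", "-"), 1L), "transposase",
                 "transposase-copy")
    }
  }
  if (config$n_foreign_orfs > 0L) {
    for (i in seq_len(config$n_foreign_orfs)) {
      fo <- .random_orf(config$foreign_orf_length_bp, 0.45)
      insert_orf(fo, "-", "foreign protein", "foreign-orf",
                 require_same_strand_flanks = TRUE)
    }
  }

  ## (e) codon-aware substitutions with GC drift
  d <- config$nt_divergence
  realized_changes <- 0L
  if (d > 0) {
    gcr <- config$gc_reference; gcq <- config$gc_query
    g_new <- min(0.95, max(0.05, (gcq - (1 - d) * gcr) / d))
    drift_w <- .gc_weights(g_new)
    ch <- strsplit(seq, "")[[1]]
    is_ortholog <- !is.na(orfs$ref_locus)
    orfs$aa_identity <- NA_real_
    # intergenic first: exact site count at rate d, drifted replacements
    in_orf <- rep(FALSE, length(ch))
    for (i in seq_len(nrow(orfs))) in_orf[orfs$start[i]:orfs$end[i]] <- TRUE
    inter <- which(!in_orf)
    n_mut <- round(d * length(inter))
    sites <- sample(inter, n_mut)
    bases <- c("A", "C", "G", "T")
    for (p in sites) {
      alts <- setdiff(bases, ch[p])
      ch[p] <- sample(alts, 1L, prob = .gc_weights(g_new)[alts])
    }
    realized_changes <- realized_changes + n_mut
    # coding next, with the genome-wide GC countdown steering synonymous
    # third-position choices toward the query GC target
    drift_env <- new.env(parent = emptyenv())
    drift_env$need <- as.integer(sum(ch == "G" | ch == "C") -
                                   round(gcq * length(ch)))
    for (i in which(is_ortholog)) {
      span <- orfs$start[i]:orfs$end[i]
      cds <- .collapse(ch[span])
      if (orfs$strand[i] == "-") cds <- revcomp(cds)
      before <- sub("\\*$", "", translate(cds, 1L))
      mut <- .mutate_coding(cds, d, config$syn_nonsyn_ratio, drift_w,
                            drift_env)
      after <- sub("\\*$", "", translate(mut, 1L))
      realized_changes <- realized_changes +
        sum(strsplit(cds, "")[[1]] != strsplit(mut, "")[[1]])
      if (orfs$strand[i] == "-") mut <- revcomp(mut)
      ch[span] <- strsplit(mut, "")[[1]]
      orfs$aa_identity[i] <- .aa_identity(before, after)
    }
    ## residual GC calibration on mutated intergenic sites (swap the
    ## replacement base within the non-original set; divergence unchanged)
    target <- round(gcq * length(ch))
    delta <- target - sum(ch == "G" | ch == "C")
    if (delta != 0L) {
      want_gc <- delta > 0L
      pool <- sites[if (want_gc) ch[sites] %in% c("A", "T")
                    else ch[sites] %in% c("G", "C")]
      pick <- pool[sample.int(length(pool), min(abs(delta), length(pool)))]
      for (p in pick) {
        alts <- setdiff(if (want_gc) c("G", "C") else c("A", "T"), ch[p])
        ch[p] <- if (length(alts) == 1L) alts else sample(alts, 1L)
      }
    }
    seq <- .collapse(ch)
  } else {
    orfs$aa_identity <- ifelse(is.na(orfs$ref_locus), NA_real_, 1)
  }
  events[[length(events) + 1L]] <- .new_event(
    "substitution-rate", aa_identity = d,
    note = sprintf("planted=%.4f;realized=%.4f", d,
                   realized_changes / nchar(seq)))

  ## finalize: renumber query loci, translations, ortholog ledger rows
  orfs <- orfs[order(orfs$start), , drop = FALSE]
  orfs$contig_id <- "query"
  orfs$locus_tag <- sprintf("LC_%04d", seq_len(nrow(orfs)))
  orfs <- .add_translations(orfs, seq)
  if (d > 0) for (i in which(!is.na(orfs$ref_locus))) {
    events[[length(events) + 1L]] <- .new_event(
      "ortholog", locus_tag = orfs$locus_tag[i],
      ref_start = orfs$ref_start[i], ref_end = orfs$ref_end[i],
      query_start = orfs$start[i], query_end = orfs$end[i],
      strand = orfs$strand[i], aa_identity = orfs$aa_identity[i],
      note = orfs$ref_locus[i])
  }
  ledger <- do.call(rbind, events)
  rownames(ledger) <- NULL
  # loci whose recovery the fixtures must not destroy: the excision
  # junction with its flanks, fusion spans, and foreign ORFs with their
  # neighborhoods (an assembly fixture that withheld them would test the
  # fixture, not the method)
  jx <- ledger$query_start[ledger$kind == "prophage"]
  prot <- rbind(
    if (length(jx)) data.frame(start = jx - 1500L, end = jx + 1500L),
    if (any(ledger$kind == "fusion"))
      data.frame(start = ledger$query_start[ledger$kind == "fusion"],
                 end = ledger$query_end[ledger$kind == "fusion"]),
    if (any(ledger$kind == "foreign-orf"))
      data.frame(start = ledger$query_start[ledger$kind == "foreign-orf"] - 1200L,
                 end = ledger$query_end[ledger$kind == "foreign-orf"] + 1200L)
  )
  genome <- structure(list(
    id = "query", seq = seq,
    orfs = orfs[, c("contig_id", "locus_tag", "start", "end", "strand",
                    "product", "translation", "ref_locus")],
    elements = ref$elements[0, , drop = FALSE],
    junctions = if (length(jx)) jx else integer(0),
    protected = if (is.null(prot)) data.frame(start = integer(0),
                                              end = integer(0)) else prot,
    transposase_protein = transposase_protein
  ), class = "annotated_genome")
  list(genome = genome, ledger = ledger)
}
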