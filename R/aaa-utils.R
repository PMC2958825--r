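# Internal constants and low-level sequence utilities.

.vc <- new.env(parent = emptyenv())

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes are complemented; case is preserved on the
#' complement table but sequences handled by this package are uppercase.
#'
#' @param x a single nucleotide string
#' @return the reverse complement string
#' @export
#' @examples
#' revcomp("ATGC")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return("")
  y <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
              "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  rawToChar(rev(charToRaw(y)))
}

# byte lookup tables: map characters to integer codes used by the C++ core
.dna_lookup <- function() {
  if (!is.null(.vc$dna_lut)) return(.vc$dna_lut)
  lut <- rep.int(4L, 256L) # everything else = ambiguity code 4
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  .vc$dna_lut <- lut
  lut
}

.blosum62 <- function() {
  if (is.null(.vc$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .vc$blosum62 <- e$BLOSUM62
  }
  .vc$blosum62
}

.protein_alphabet <- function() rownames(.blosum62())

.protein_lookup <- function() {
  if (!is.null(.vc$prot_lut)) return(.vc$prot_lut)
  ab <- .protein_alphabet()
  lut <- rep.int(match("X", ab) - 1L, 256L) # unknown residues -> X
  lut[utf8ToInt(paste(ab, collapse = "")) + 1L] <- seq_along(ab) - 1L
  .vc$prot_lut <- lut
  lut
}

encode_dna <- function(x) .dna_lookup()[as.integer(charToRaw(x)) + 1L]

encode_protein <- function(x) .protein_lookup()[as.integer(charToRaw(x)) + 1L]

# nucleotide scoring matrix over codes {A,C,G,T,ambiguous}
.dna_score_matrix <- function(match = 1L, mismatch = -2L) {
  m <- matrix(as.integer(mismatch), 5L, 5L)
  diag(m)[1:4] <- as.integer(match)
  m[5L, 5L] <- as.integer(mismatch) # ambiguity never rewarded
  m
}

.blosum62_int <- function() {
  if (is.null(.vc$blosum62_int)) .vc$blosum62_int <- {
    m <- .blosum62()
    storage.mode(m) <- "integer"
    m
  }
  .vc$blosum62_int
}

.genetic_code <- function() {
  if (is.null(.vc$gcode)) {
    gc <- Biostrings::GENETIC_CODE
    .vc$gcode <- stats::setNames(as.character(gc), names(gc))
  }
  .vc$gcode
}

# codons grouped by encoded amino acid (stops under "*")
.codons_by_aa <- function() {
  if (is.null(.vc$codons_by_aa))
    .vc$codons_by_aa <- split(names(.genetic_code()), .genetic_code())
  .vc$codons_by_aa
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.is_nucleotide <- function(seq) {
  !grepl("[^ACGTRYSWKMBDHVN]", seq)
}

.gc_weights <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# sample n bases at a GC target
.random_bases <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(DNA_ALPHABET, n, replace = TRUE, prob = .gc_weights(gc)[DNA_ALPHABET])
}

.collapse <- function(x) paste0(x, collapse = "")
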