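# Scoring schemes and Karlin-Altschul statistics.

# Published Karlin-Altschul parameters for the default scoring schemes.
# Gapped values correspond to the stated gap costs (a gap of length L costs
# open + L * extend).
KA_PARAMS <- data.frame(
  scheme = c("nt+1/-2,gap5/2", "blosum62,gap11/1", "blosum62,ungapped"),
  lambda = c(1.28, 0.267, 0.3176),
  K = c(0.46, 0.041, 0.134),
  stringsAsFactors = FALSE
)

#' Construct a scoring scheme
#'
#' Nucleotide mode scores +1/-2 with gap costs 5/2 by default; translated
#' (and protein) mode uses BLOSUM62 with gap costs 11/1.  The
#' Karlin-Altschul `lambda` and `K` are taken from the published values
#' for those schemes; supplying custom match/mismatch or gap costs
#' requires supplying `lambda` and `K` as well.
#'
#' @param mode "nucleotide" or "translated"
#' @param match,mismatch integer scores (nucleotide mode)
#' @param gap_open,gap_extend non-negative integer gap costs
#' @param lambda,K Karlin-Altschul parameters; defaults looked up for the
#'   default costs
#' @return an object of class `scoring_scheme`
#' @export
scoring_scheme <- function(mode = c("nucleotide", "translated"),
                           match = 1L, mismatch = -2L,
                           gap_open = NULL, gap_extend = NULL,
                           lambda = NULL, K = NULL) {
  mode <- match.arg(mode)
  if (mode == "nucleotide") {
    gap_open <- gap_open %||% 5L
    gap_extend <- gap_extend %||% 2L
    default <- match == 1L && mismatch == -2L && gap_open == 5L && gap_extend == 2L
    if (is.null(lambda) || is.null(K)) {
      if (!default)
        stop("custom nucleotide costs need explicit lambda and K")
      lambda <- KA_PARAMS$lambda[1L]; K <- KA_PARAMS$K[1L]
    }
    mat <- .dna_score_matrix(match, mismatch)
    alpha <- 4L
  } else {
    gap_open <- gap_open %||% 11L
    gap_extend <- gap_extend %||% 1L
    if (is.null(lambda) || is.null(K)) {
      if (!(gap_open == 11L && gap_extend == 1L))
        stop("custom translated gap costs need explicit lambda and K")
      lambda <- KA_PARAMS$lambda[2L]; K <- KA_PARAMS$K[2L]
    }
    mat <- .blosum62_int()
    alpha <- 20L
  }
  stopifnot(lambda > 0, K > 0, gap_open >= 0, gap_extend >= 0)
  structure(list(mode = mode, matrix = mat, alphabet_size = alpha,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Bit score from a raw alignment score
#' @param raw_score raw (matrix-sum) score
#' @param scheme a [scoring_scheme()]
#' @return bit score
#' @export
bit_score <- function(raw_score, scheme) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' Karlin-Altschul expectation from a bit score
#'
#' `E = search_space * 2^(-bit_score)` with search space the raw m x n
#' product (no length correction); monotone decreasing in the score.
#'
#' @param bit_score bit score
#' @param search_space effective m x n product
#' @return expected chance-alignment count
#' @export
#' @examples
#' evalue(50, 1e6) # ~8.9e-10
evalue <- function(bit_score, search_space) {
  stopifnot(is.finite(bit_score), search_space >= 0)
  search_space * 2^(-bit_score)
}
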