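# Clone mate-pair naming: the two Sanger reads from opposite ends of one
# cloned insert share a name stem and differ only in suffix
# (FNHG1000.b1 / FNHG1000.g1; FOSS3464.x1 / FOSS3464.y1).

DEFAULT_SUFFIX_FAMILIES <- list(c(".b1", ".g1"), c(".x1", ".y1"))

#' Pair reads by clone naming convention
#'
#' Ids sharing a stem before a known suffix pair are mated; the suffix
#' family must be consistent within a pair.  Ids with unknown suffixes, or
#' with a lone mate, are returned unpaired.  Three or more ids on one stem
#' is an ambiguity error listing the ids.
#'
#' @param read_ids character vector of read ids
#' @param suffix_families list of length-2 character vectors
#'   (forward suffix, reverse suffix)
#' @return list with `pairs` (data.frame: stem, forward_read_id,
#'   reverse_read_id) and `unpaired` (character)
#' @export
#' @examples
#' pair_reads(c("FNHG1000.b1", "FNHG1000.g1", "A.b1"))
pair_reads <- function(read_ids, suffix_families = DEFAULT_SUFFIX_FAMILIES) {
  stopifnot(is.character(read_ids))
  suffixes <- unlist(suffix_families)
  sfx <- rep(NA_character_, length(read_ids))
  for (s in suffixes) {
    m <- endsWith(read_ids, s) & is.na(sfx)
    sfx[m] <- s
  }
  known <- !is.na(sfx)
  stems <- ifelse(known,
                  substr(read_ids, 1L, nchar(read_ids) - nchar(sfx)),
                  NA_character_)
  counts <- table(stems[known])
  over <- names(counts)[counts > 2L]
  if (length(over))
    stop("ambiguous clone stem '", over[1L], "': ",
         paste(read_ids[!is.na(stems) & stems == over[1L]], collapse = ", "))
  pairs <- list()
  unpaired <- read_ids[!known]
  for (stem in names(counts)) {
    ids <- read_ids[!is.na(stems) & stems == stem]
    if (length(ids) == 1L) { unpaired <- c(unpaired, ids); next }
    sx <- sort(sfx[match(ids, read_ids)])
    fam <- Filter(function(f) setequal(sx, f), suffix_families)
    if (length(fam) == 0L) { unpaired <- c(unpaired, ids); next }
    f <- fam[[1L]]
    pairs[[length(pairs) + 1L]] <- data.frame(
      stem = stem,
      forward_read_id = ids[sfx[match(ids, read_ids)] == f[1L]],
      reverse_read_id = ids[sfx[match(ids, read_ids)] == f[2L]],
      stringsAsFactors = FALSE
    )
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(stem = character(0), forward_read_id = character(0),
               reverse_read_id = character(0), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$stem), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, unpaired = unname(unpaired))
}

#' Map each read id to its mate
#'
#' @param pairs the `pairs` data.frame from [pair_reads()]
#' @return named character vector: read id -> mate id
#' @export
mate_map <- function(pairs) {
  stats::setNames(
    c(pairs$reverse_read_id, pairs$forward_read_id),
    c(pairs$forward_read_id, pairs$reverse_read_id)
  )
}
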