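# Cross-panel comparison: shared loci and target-length surplus.

#' Find overlapping loci between two bait panels
#'
#' Every locus pair is compared by seed-and-extend ungapped local alignment;
#' a pair is recorded when the aligned span exceeds `min_overlap_frac` of
#' the shorter target and identity over the span reaches `min_identity`
#' (the identity floor stands in for an alignment-significance test so
#' unrelated loci never "overlap"). Each locus of panel A reports at most
#' its best partner (most matches; ties lexicographic).
#'
#' @param panel_a,panel_b Named character vectors of per-locus target
#'   sequences.
#' @param min_overlap_frac Minimum aligned span as a fraction of the shorter
#'   target (strict).
#' @param min_identity Minimum identity over the aligned span.
#' @param k Seed k-mer size for the local search.
#' @return data.frame with `locus_a`, `locus_b`, `overlap_len`,
#'   `overlap_frac`, `identity` and `surplus_bases`
#'   (`len_a - len_b`, signed).
#' @export
find_overlaps <- function(panel_a, panel_b, min_overlap_frac = 0.05,
                          min_identity = 0.70, k = 21L) {
  stopifnot(length(panel_a) > 0L, length(panel_b) > 0L,
            !is.null(names(panel_a)), !is.null(names(panel_b)))
  rows <- list()
  for (a in sort(names(panel_a))) {
    best <- NULL
    for (b in sort(names(panel_b))) {
      hit <- local_search(panel_a[[a]], panel_b[[b]], k = k)
      if (is.null(hit)) next
      shorter <- min(nchar(panel_a[[a]]), nchar(panel_b[[b]]))
      frac <- hit$len / shorter
      if (frac <= min_overlap_frac || hit$identity < min_identity) next
      if (is.null(best) || hit$matches > best$matches)
        best <- list(b = b, len = hit$len, frac = frac,
                     identity = hit$identity, matches = hit$matches)
    }
    if (!is.null(best))
      rows[[length(rows) + 1L]] <- data.frame(
        locus_a = a, locus_b = best$b, overlap_len = best$len,
        overlap_frac = best$frac, identity = best$identity,
        surplus_bases = nchar(panel_a[[a]]) - nchar(panel_b[[best$b]]),
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(locus_a = character(0), locus_b = character(0),
                      overlap_len = integer(0), overlap_frac = numeric(0),
                      identity = numeric(0), surplus_bases = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Target-length surplus over overlapping loci
#'
#' @param records Overlap records from [find_overlaps()].
#' @return List with `total` (sum of signed surplus bases) and
#'   `mean_per_locus` (total over record count, rounded to the nearest
#'   integer).
#' @export
surplus_summary <- function(records) {
  if (nrow(records) == 0L) stop("no overlap records")
  total <- sum(records$surplus_bases)
  list(total = total, mean_per_locus = round(total / nrow(records)))
}
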