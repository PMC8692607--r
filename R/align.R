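#' Canonical k-mer set of a sequence
#'
#' Canonical form is the lexicographic minimum of a k-mer and its reverse
#' complement; k-mers containing ambiguity codes are skipped.
#'
#' @param seq Nucleotide string.
#' @param k k-mer size.
#' @return Character vector of distinct canonical k-mers.
#' @export
canonical_kmer_set <- function(seq, k) {
  unique(canonical_kmers_cpp(seq, as.integer(k)))
}

#' Shared-k-mer similarity of two sequences
#'
#' The count of shared canonical k-mers normalised by the k-mer count of the
#' smaller set, so an exact substring relationship scores 1.
#'
#' @param ka,kb Canonical k-mer sets (from [canonical_kmer_set()]).
#' @return Similarity in `[0, 1]`; 0 if either set is empty.
#' @export
kmer_similarity <- function(ka, kb) {
  if (length(ka) == 0L || length(kb) == 0L) return(0)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Global pairwise alignment (match +1, mismatch -1, gap -2)
#'
#' Deterministic Needleman-Wunsch with fixed scoring; traceback ties resolve
#' diagonal > gap-in-second > gap-in-first.
#'
#' @param a,b Nucleotide strings.
#' @return Character vector of the two gapped sequences.
#' @export
nw_align <- function(a, b) {
  nw_align_cpp(a, b, 1L, -1L, -2L)
}

#' Best ungapped local hit between two sequences
#'
#' Seed-and-extend: shared forward k-mers seed diagonals, each diagonal's
#' first seed is extended ungapped in both directions with an X-drop rule,
#' and the highest-scoring extension is returned. Both inputs are taken as
#' sense strand.
#'
#' @param query,subject Nucleotide strings.
#' @param k Seed k-mer size.
#' @param xdrop X-drop threshold for the extension.
#' @return `NULL` if no seed is shared, else a list with `q_start`, `s_start`
#'   (0-based), `len`, `matches`, `identity` and `query_coverage`
#'   (`len / nchar(query)`).
#' @export
local_search <- function(query, subject, k = 21L, xdrop = 12L) {
  qk <- forward_kmers_cpp(query, as.integer(k))
  sk <- forward_kmers_cpp(subject, as.integer(k))
  if (length(qk) == 0L || length(sk) == 0L) return(NULL)
  hit <- match(qk, sk)
  qpos <- which(!is.na(hit))
  if (length(qpos) == 0L) return(NULL)
  spos <- hit[qpos]
  diag <- spos - qpos
  first <- !duplicated(diag)
  qpos <- qpos[first]; spos <- spos[first]
  best <- NULL
  for (i in seq_along(qpos)) {
    ext <- ungapped_extend_cpp(query, subject, qpos[i] - 1L, spos[i] - 1L,
                               as.integer(k), 1L, -2L, as.integer(xdrop))
    if (is.null(best) || ext[4L] > best[4L]) best <- ext
  }
  list(q_start = best[1L], s_start = best[2L], len = best[3L],
       matches = best[4L], identity = best[4L] / best[3L],
       query_coverage = best[3L] / nchar(query))
}
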