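# High-level selection pipeline: cluster -> rescue -> annotate -> trim ->
# filter, plus helpers to turn kept loci into panel reference targets.

#' Select bait-ready loci from per-species transcript sets
#'
#' Runs the full locus-selection pipeline: ortholog clustering, exclusion of
#' multi-copy groups, rescue of species missing from a group (searching the
#' missing species' unassigned transcripts), reference matching and exon
#' annotation, end trimming, and the locus filters.
#'
#' @param transcript_sets Named list (species -> named transcript sequences).
#' @param reference Named character vector of annotated reference sequences
#'   (one per reference locus).
#' @param reference_exons Named list of [exon_map()]s parallel to
#'   `reference`.
#' @param params A [selection_params()] object.
#' @return List with `kept`, `rejected` (locus candidates), `report`
#'   (filter report), `groups` (all ortholog groups) and `multi_copy`
#'   (locus ids excluded as multi-copy).
#' @export
select_loci <- function(transcript_sets, reference, reference_exons,
                        params = selection_params()) {
  groups <- cluster_orthologs(transcript_sets, params)
  multi <- names(groups)[!vapply(groups, is_low_copy, TRUE)]
  groups_lc <- groups[setdiff(names(groups), multi)]

  # transcripts only reachable through singleton groups are the rescue pool
  multi_member <- names(groups_lc)[vapply(groups_lc, function(g)
    length(g$members) >= 2L, TRUE)]
  singletons <- setdiff(names(groups_lc), multi_member)
  pool <- list()
  for (gid in singletons) {
    g <- groups_lc[[gid]]
    sp <- names(g$members)[1L]
    pool[[sp]] <- c(pool[[sp]],
                    setNames(g$members[[1L]], g$member_ids[[1L]]))
  }
  species <- sort(names(transcript_sets))
  for (gid in multi_member) {
    g <- groups_lc[[gid]]
    for (sp in setdiff(species, names(g$members))) {
      if (is.null(pool[[sp]]) || length(pool[[sp]]) == 0L) next
      g2 <- rescue_missing(g, pool[[sp]], sp, params)
      if (sp %in% names(g2$members)) {
        rid <- g2$member_ids[[sp]]
        pool[[sp]] <- pool[[sp]][setdiff(names(pool[[sp]]), rid)]
        # drop the singleton group the rescued transcript came from
        gone <- vapply(groups_lc[singletons], function(s)
          identical(unname(s$member_ids), rid), TRUE)
        groups_lc[names(gone)[gone]] <- NULL
        singletons <- setdiff(singletons, names(gone)[gone])
        groups_lc[[gid]] <- g2
      }
    }
  }

  ref_kmers <- lapply(reference, canonical_kmer_set, k = params$k_ref)
  candidates <- vector("list", length(groups_lc))
  for (i in seq_along(groups_lc)) {
    g <- groups_lc[[i]]
    gk <- canonical_kmer_set(g$members[[1L]], params$k_ref)
    sims <- vapply(ref_kmers, kmer_similarity, 0, ka = gk)
    if (length(sims) == 0L || max(sims) <= 0) {
      candidates[[i]] <- list(locus_id = g$locus_id, group = g,
                              alignment = NULL, exon_map = NULL,
                              exon_presence = NULL,
                              snp_density = NA_real_, verdict = "fail",
                              reasons = "no_alignable_region")
      next
    }
    best_ref <- sort(names(sims)[sims == max(sims)])[1L]
    cand <- annotate_exons(g, reference[[best_ref]],
                           reference_exons[[best_ref]], params)
    cand$reference_locus <- best_ref
    candidates[[i]] <- trim_to_overlap(cand)
  }
  # name candidates after their matched reference locus (the annotation
  # donor's gene id), as capture workflows conventionally do; collisions
  # get a numeric suffix, unmatched candidates keep their group id
  taken <- character(0)
  for (i in seq_along(candidates)) {
    ref_id <- candidates[[i]]$reference_locus
    if (is.null(ref_id)) next
    id <- ref_id
    n_try <- 1L
    while (id %in% taken) {
      n_try <- n_try + 1L
      id <- paste0(ref_id, "_", n_try)
    }
    taken <- c(taken, id)
    candidates[[i]]$locus_id <- id
  }
  res <- apply_locus_filters(candidates, params)
  res$groups <- groups
  res$multi_copy <- multi
  res
}

#' Panel reference targets of kept loci
#'
#' Per kept locus, the ungapped trimmed per-species sequences - the set a
#' HybPiper-style target file is written from ([write_target_file()]).
#'
#' @param kept Named list of passing candidates from [select_loci()] /
#'   [apply_locus_filters()].
#' @return Named list (locus id -> named character vector keyed by species).
#' @export
panel_targets <- function(kept) {
  lapply(kept, function(cand) {
    vapply(cand$alignment, function(row) gsub("-", "", row, fixed = TRUE),
           "", USE.NAMES = TRUE)
  })
}

#' Flatten panel targets to a named sequence vector
#'
#' @param targets Output of [panel_targets()].
#' @return Character vector named `"Species-locus"`.
#' @export
flatten_targets <- function(targets) {
  out <- character(0)
  for (locus in names(targets)) {
    v <- targets[[locus]]
    out[paste0(names(v), "-", locus)] <- unname(v)
  }
  out
}
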