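# Ortholog group detection across congeneric transcript sets.
#
# MarkerMiner-style classification is approximated by reciprocal best match
# under a shared canonical k-mer similarity: self-contained, deterministic
# and adequate for grouping transcripts into putative single- to low-copy
# loci at desk scale.

sim_matrix <- function(ks_a, ks_b) {
  m <- matrix(0, length(ks_a), length(ks_b),
              dimnames = list(names(ks_a), names(ks_b)))
  for (i in seq_along(ks_a))
    for (j in seq_along(ks_b))
      m[i, j] <- kmer_similarity(ks_a[[i]], ks_b[[j]])
  m
}

#' Cluster transcripts into putative ortholog groups
#'
#' Groups are seeded from the lexicographically first species and grown by
#' reciprocal best match under shared-canonical-k-mer similarity (count of
#' shared k-mers over the smaller sequence's k-mer count). Each other species
#' contributes its best-matching transcript; `copy_counts` record how many of
#' that species' transcripts score within 95% of the chosen member's
#' within-species best - its self-similarity - so only near-identical
#' copies count as multi-copy. Transcripts never join two groups, and ties
#' break by
#' lexicographic transcript id, so the result is invariant to input order.
#'
#' @param transcript_sets Named list (species -> named character vector of
#'   transcript sequences).
#' @param params A [selection_params()] object (uses `k_cluster`).
#' @return A named list of ortholog groups (by locus id). Each group is a
#'   list with `locus_id`, `members` (species -> sequence), `member_ids`
#'   (species -> transcript id) and `copy_counts` (species -> integer).
#' @export
cluster_orthologs <- function(transcript_sets, params = selection_params()) {
  stopifnot(is.list(transcript_sets), length(transcript_sets) >= 2L,
            !is.null(names(transcript_sets)))
  for (sp in names(transcript_sets)) {
    ts <- transcript_sets[[sp]]
    if (length(ts) == 0L) stop("empty transcript set for species ", sp)
    if (anyDuplicated(names(ts)))
      stop("duplicate transcript ids in species ", sp)
  }
  k <- params$k_cluster
  species <- sort(names(transcript_sets))
  # canonical order: transcripts sorted by id within each species
  sets <- lapply(transcript_sets[species], function(ts) ts[order(names(ts))])
  kmers <- lapply(sets, function(ts)
    lapply(ts, canonical_kmer_set, k = k))

  simw <- lapply(species, function(sp) sim_matrix(kmers[[sp]], kmers[[sp]]))
  names(simw) <- species
  # cross-species similarity matrices, computed once per unordered pair
  xcache <- new.env(parent = emptyenv())
  cross_sim <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "|")
    if (is.null(xcache[[key]]))
      xcache[[key]] <- sim_matrix(kmers[[sort(c(a, b))[1L]]],
                                  kmers[[sort(c(a, b))[2L]]])
    m <- xcache[[key]]
    if (a == sort(c(a, b))[1L]) m else t(m)
  }

  used <- lapply(sets, function(ts) setNames(rep(FALSE, length(ts)), names(ts)))
  groups <- list()
  # successive anchor passes so that a locus absent from earlier species
  # still forms one group from the remaining species
  for (ai in seq_along(species)) {
    anchor <- species[ai]
    for (t_id in names(sets[[anchor]])[!used[[anchor]]]) {
      members <- setNames(sets[[anchor]][t_id], anchor)
      member_ids <- setNames(t_id, anchor)
      within <- setNames(simw[[anchor]][t_id, ], colnames(simw[[anchor]]))
      copy_counts <- setNames(sum(within >= 0.95 * within[t_id]), anchor)
      used[[anchor]][t_id] <- TRUE
      for (sp in setdiff(species, anchor)) {
        m <- cross_sim(anchor, sp)
        sims <- setNames(m[t_id, ], colnames(m))
        free <- !used[[sp]][names(sims)]
        if (!any(free) || max(sims[free]) <= 0) next
        best <- max(sims[free])
        u_id <- sort(names(sims)[free & sims == best])[1L]
        # relaxed reciprocity: t must score at least half of u's best match
        # in the anchor species. Same-locus scores dwarf cross-locus ones
        # (which are ~0), so the slack only tolerates sampling noise among
        # same-locus copies - shared-k-mer counts are noisy at outer-clade
        # divergence - while still blocking cross-locus attachment.
        if (m[t_id, u_id] < 0.5 * max(m[, u_id])) next
        members[sp] <- sets[[sp]][[u_id]]
        member_ids[sp] <- u_id
        # multi-copy detection on the within-species score (self-similarity
        # of the chosen member = 1), as for the anchor: cross-species
        # scores are too noisy at outgroup divergence to rank copies
        wsp <- setNames(simw[[sp]][u_id, ], colnames(simw[[sp]]))
        copy_counts[sp] <- sum(wsp >= 0.95 * wsp[u_id])
        used[[sp]][u_id] <- TRUE
      }
      groups[[length(groups) + 1L]] <- list(
        locus_id = NA_character_, members = members,
        member_ids = member_ids, copy_counts = copy_counts)
    }
  }
  ids <- sprintf("OG%04d", seq_along(groups))
  for (i in seq_along(groups)) groups[[i]]$locus_id <- ids[i]
  names(groups) <- ids
  groups
}

#' Is a group single/low-copy in every species?
#'
#' @param group An ortholog group from [cluster_orthologs()].
#' @return `TRUE` iff every species' copy count is 1.
#' @export
is_low_copy <- function(group) all(group$copy_counts <= 1L)

# Majority-rule consensus of group members, anchored on the first member.
group_consensus <- function(group) {
  members <- group$members
  if (length(members) == 1L) return(unname(members[[1L]]))
  merged <- merge_on_reference(members[[1L]], members[-1L])
  rows <- c(setNames(merged$reference_row, names(members)[1L]), merged$rows)
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  cons <- apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    if (length(col) * 2L < nrow(mat)) return(NA_character_)
    tab <- sort(table(col), decreasing = TRUE)
    # alphabetical tie-break
    cand <- names(tab)[tab == tab[1L]]
    sort(cand)[1L]
  })
  paste(cons[!is.na(cons)], collapse = "")
}

#' Rescue a locus from the transcriptome of a missing species
#'
#' Runs a seed-and-extend ungapped local search of the group consensus
#' against every transcript of the missing species and adds the best hit if
#' its identity and consensus coverage clear the rescue thresholds;
#' otherwise the group is returned unchanged (no hit is a valid outcome).
#'
#' @param group Ortholog group lacking `species`.
#' @param transcript_set Named character vector: the missing species'
#'   transcripts.
#' @param species Name of the missing species.
#' @param params A [selection_params()] object.
#' @return The (possibly extended) group; a rescued member is recorded in
#'   `rescued`.
#' @export
rescue_missing <- function(group, transcript_set, species,
                           params = selection_params()) {
  if (species %in% names(group$members))
    stop("species ", species, " already present in group ", group$locus_id)
  if (length(transcript_set) == 0L) {
    warning("empty transcript set for species ", species, "; group unchanged")
    return(group)
  }
  cons <- group_consensus(group)
  best_hit <- NULL
  best_id <- NULL
  for (t_id in sort(names(transcript_set))) {
    hit <- local_search(cons, transcript_set[[t_id]], k = params$k_cluster)
    if (is.null(hit)) next
    if (hit$identity < params$rescue_min_identity) next
    if (hit$query_coverage < params$rescue_min_coverage) next
    if (is.null(best_hit) || hit$matches > best_hit$matches) {
      best_hit <- hit
      best_id <- t_id
    }
  }
  if (is.null(best_hit)) return(group)
  group$members[species] <- transcript_set[[best_id]]
  group$member_ids[species] <- best_id
  group$copy_counts[species] <- 1L
  group$rescued <- c(group$rescued, setNames(best_hit$identity, species))
  group
}
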