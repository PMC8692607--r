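# Exon annotation, end trimming, SNP density and the locus filters.

# Align each member to the reference pairwise (match 1 / mismatch -1 /
# gap -2) and merge the pairwise alignments on reference coordinates:
# insertion blocks between consecutive reference positions are widened to
# the longest insertion observed at that junction, members' insertions are
# left-justified inside the block, and everything else is gap-padded.
# Deterministic. Returns the gapped member rows, the gapped reference row and
# the per-junction insertion widths used for exon projection.
merge_on_reference <- function(reference, members) {
  nref <- nchar(reference)
  per <- lapply(members, function(m) {
    al <- nw_align(reference, m)
    gr <- strsplit(al[1L], "")[[1L]]
    gm <- strsplit(al[2L], "")[[1L]]
    # ins[[j + 1]]: member characters inserted before reference position j
    # (0-based); slot nref + 1 holds the tail insertion.
    ins <- vector("list", nref + 1L)
    at <- character(nref)            # member char aligned to each ref position
    j <- 0L
    buf <- character(0)
    for (c in seq_along(gr)) {
      if (gr[c] == "-") {
        buf <- c(buf, gm[c])
      } else {
        ins[[j + 1L]] <- buf
        buf <- character(0)
        j <- j + 1L
        at[j] <- gm[c]
      }
    }
    ins[[nref + 1L]] <- buf
    list(ins = ins, at = at)
  })
  ins_max <- vapply(seq_len(nref + 1L), function(j)
    max(vapply(per, function(p) length(p$ins[[j]]), 0L)), 0L)
  ref_chars <- strsplit(reference, "")[[1L]]
  build_row <- function(at, ins) {
    parts <- character(0)
    for (j in seq_len(nref)) {
      block <- ins[[j]]
      pad <- strrep("-", ins_max[j] - length(block))
      parts <- c(parts, paste0(paste(block, collapse = ""), pad), at[j])
    }
    tail <- ins[[nref + 1L]]
    c(parts, paste0(paste(tail, collapse = ""),
                    strrep("-", ins_max[nref + 1L] - length(tail))))
  }
  rows <- vapply(per, function(p)
    paste(build_row(p$at, p$ins), collapse = ""), "")
  ref_row <- paste(vapply(seq_len(nref), function(j)
    paste0(strrep("-", ins_max[j]), ref_chars[j]), ""), collapse = "")
  ref_row <- paste0(ref_row, strrep("-", ins_max[nref + 1L]))
  list(rows = rows, reference_row = ref_row, ins_max = ins_max, nref = nref)
}

# 0-based alignment column at which reference position p starts; p = nref
# maps past the last reference column, excluding any tail insertion block.
ref_col0 <- function(p, ins_max, nref) {
  if (p < nref) p + sum(ins_max[seq_len(p + 1L)])
  else nref + sum(ins_max[seq_len(nref)])
}

#' Annotate a locus with exon boundaries from an annotated reference
#'
#' Group members are aligned together with the reference (pairwise global
#' alignments merged on reference coordinates) and the reference's exon
#' boundaries are projected through the alignment columns onto the locus.
#' The reference row is then dropped and columns gapped in every member are
#' compacted; a boundary landing on a removed or gapped column moves to the
#' nearest following retained column.
#'
#' @param group Ortholog group from [cluster_orthologs()].
#' @param reference Reference transcript sequence (annotated, e.g. from a
#'   model-organism genome).
#' @param ref_exons [exon_map()] of the reference transcript.
#' @param params A [selection_params()] object (seed k-mer size for the
#'   alignability pre-check).
#' @return A locus candidate: list with `locus_id`, `group`, `alignment`
#'   (gapped member rows), `exon_map` (0-based half-open alignment-column
#'   intervals), `exon_presence` (members x exons logical matrix; `TRUE`
#'   when at least 10% of the exon's columns are non-gap for that member),
#'   `snp_density` (`NA` until filtering), `verdict` and `reasons`. If no
#'   member shares a seed k-mer with the reference the candidate is rejected
#'   with reason `"no_alignable_region"`.
#' @export
annotate_exons <- function(group, reference, ref_exons,
                           params = selection_params()) {
  cand <- list(locus_id = group$locus_id, group = group,
               alignment = NULL, exon_map = NULL, exon_presence = NULL,
               snp_density = NA_real_, verdict = "unfiltered",
               reasons = character(0))
  alignable <- any(vapply(group$members, function(m)
    !is.null(local_search(reference, m, k = params$k_ref)), TRUE))
  if (!alignable) {
    cand$verdict <- "fail"
    cand$reasons <- "no_alignable_region"
    return(cand)
  }
  merged <- merge_on_reference(reference, group$members)
  nref <- merged$nref
  cols0 <- vapply(0:nref, ref_col0, 0, ins_max = merged$ins_max, nref = nref)
  ex_start <- cols0[ref_exons$start + 1L]
  ex_end <- cols0[ref_exons$end + 1L]

  rows <- merged$rows
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(mat) <- names(rows)
  keep <- colSums(mat != "-") > 0L
  kept_before <- c(0L, cumsum(keep))    # kept columns among the first c
  new_start <- kept_before[ex_start + 1L]
  new_end <- kept_before[ex_end + 1L]
  ok <- new_end > new_start
  mat <- mat[, keep, drop = FALSE]
  cand$alignment <- setNames(apply(mat, 1L, paste, collapse = ""),
                             names(rows))
  cand$exon_map <- data.frame(start = as.integer(new_start[ok]),
                              end = as.integer(new_end[ok]))
  n_ex <- nrow(cand$exon_map)
  pres <- matrix(FALSE, length(rows), n_ex,
                 dimnames = list(names(rows), NULL))
  for (e in seq_len(n_ex)) {
    cols <- (cand$exon_map$start[e] + 1L):cand$exon_map$end[e]
    # a member carries an exon when a meaningful fraction of it aligns;
    # the 10% floor keeps single straggler bases from end-of-alignment
    # ties out of the presence call
    need <- max(1L, ceiling(0.1 * length(cols)))
    pres[, e] <- rowSums(mat[, cols, drop = FALSE] != "-") >= need
  }
  cand$exon_presence <- pres
  cand
}

#' Trim a locus alignment to the fully overlapping span
#'
#' Removes leading columns before the first column at which every row is
#' non-gap and trailing columns after the last such column, re-indexing the
#' exon map. A candidate with no common non-gap column fails with reason
#' `"no_overlap"`.
#'
#' @param candidate A locus candidate from [annotate_exons()].
#' @return The trimmed candidate.
#' @export
trim_to_overlap <- function(candidate) {
  if (is.null(candidate$alignment)) return(candidate)
  mat <- do.call(rbind, strsplit(unname(candidate$alignment), ""))
  full <- which(colSums(mat == "-") == 0L)
  if (length(full) == 0L) {
    candidate$verdict <- "fail"
    candidate$reasons <- union(candidate$reasons, "no_overlap")
    candidate$alignment <- NULL
    candidate$exon_map <- candidate$exon_map[0, ]
    return(candidate)
  }
  first0 <- full[1L] - 1L                  # 0-based window start
  last0 <- full[length(full)]              # 0-based half-open window end
  width <- last0 - first0
  mat <- mat[, (first0 + 1L):last0, drop = FALSE]
  candidate$alignment <- setNames(apply(mat, 1L, paste, collapse = ""),
                                  names(candidate$alignment))
  em <- candidate$exon_map
  new_start <- pmax(em$start - first0, 0L)
  new_end <- pmin(em$end - first0, width)
  ok <- new_end > new_start
  candidate$exon_map <- data.frame(start = as.integer(new_start[ok]),
                                   end = as.integer(new_end[ok]))
  candidate$exon_presence <-
    candidate$exon_presence[, ok, drop = FALSE]
  candidate
}

#' SNP density of a locus alignment
#'
#' A column is polymorphic when it holds at least two distinct bases among
#' `{A,C,G,T}`; gaps and `N` never contribute. Density is polymorphic
#' columns per 1,000 alignment columns.
#'
#' @param alignment Named character vector of gapped rows.
#' @return SNPs per 1,000 bp.
#' @export
count_snp_density <- function(alignment) {
  len <- unique(nchar(alignment))
  stopifnot(length(len) == 1L)
  if (len == 0L) stop("zero-length alignment")
  mat <- do.call(rbind, strsplit(unname(alignment), ""))
  poly <- apply(mat, 2L, function(col) {
    b <- unique(col[col %in% c("A", "C", "G", "T")])
    length(b) >= 2L
  })
  1000 * sum(poly) / len
}

#' Apply the locus filters
#'
#' A candidate fails iff (a) fewer than `min_presence` focal-clade species
#' are present, (b) any internal (mid-locus) exon is shorter than
#' `min_exon_len` - short terminal exons are retained but later receive no
#' baits - or (c) its SNP density is strictly below `min_snp_density`.
#' Reasons accumulate; input order is preserved.
#'
#' @param candidates List of trimmed locus candidates.
#' @param params A [selection_params()] object.
#' @return List with `kept` and `rejected` candidate lists (partitioning the
#'   input) and a `report` data.frame (locus id, presence, shortest internal
#'   exon, SNP density, verdict, comma-separated reasons).
#' @export
apply_locus_filters <- function(candidates, params = selection_params()) {
  kept <- list(); rejected <- list()
  rep_rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    reasons <- setdiff(cand$reasons,
                       c("absent_species", "short_internal_exon",
                         "low_snp_density"))
    present <- names(cand$group$members)
    if (!is.null(params$focal_species))
      present <- intersect(present, params$focal_species)
    n_present <- length(present)
    if (n_present < params$min_presence)
      reasons <- c(reasons, "absent_species")
    min_internal <- NA_integer_
    if (!is.null(cand$alignment) && nrow(cand$exon_map) >= 3L) {
      lens <- cand$exon_map$end - cand$exon_map$start
      internal <- lens[-c(1L, length(lens))]
      min_internal <- min(internal)
      if (any(internal < params$min_exon_len))
        reasons <- c(reasons, "short_internal_exon")
    }
    dens <- NA_real_
    if (!is.null(cand$alignment) && length(cand$alignment) >= 2L) {
      dens <- count_snp_density(cand$alignment)
      if (dens < params$min_snp_density)
        reasons <- c(reasons, "low_snp_density")
    }
    cand$snp_density <- dens
    cand$verdict <- if (length(reasons)) "fail" else "pass"
    cand$reasons <- reasons
    if (cand$verdict == "pass") kept[[length(kept) + 1L]] <- cand
    else rejected[[length(rejected) + 1L]] <- cand
    rep_rows[[i]] <- data.frame(
      locus_id = cand$locus_id, presence = n_present,
      min_internal_exon = min_internal, snp_density = dens,
      verdict = cand$verdict,
      reasons = paste(reasons, collapse = ","),
      stringsAsFactors = FALSE)
  }
  names(kept) <- vapply(kept, `[[`, "", "locus_id")
  names(rejected) <- vapply(rejected, `[[`, "", "locus_id")
  list(kept = kept, rejected = rejected, report = do.call(rbind, rep_rows))
}
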