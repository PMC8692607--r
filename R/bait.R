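# Bait tiling and the panel screens (low complexity, blacklist, GC/Tm,
# redundancy).

#' Tile an exon with bait start offsets
#'
#' Starts form a ladder at step `round(B / d)` from 0 while `start <= E - B`;
#' if the last ladder start falls short of `E - B`, a flush-right bait at
#' `E - B` is appended so every exon position is covered. Baits never cross
#' exon boundaries, so exons shorter than the bait receive none.
#'
#' @param exon_len Exon length E in bases.
#' @param params A [design_params()] object (uses `bait_len`, `tiling_depth`).
#' @return Integer vector of 0-based start offsets (empty when `E < B`).
#' @export
tile_exon <- function(exon_len, params = design_params()) {
  B <- params$bait_len
  if (exon_len < B) return(integer(0))
  s <- as.integer(round(B / params$tiling_depth))
  starts <- seq.int(0L, exon_len - B, by = s)
  if (starts[length(starts)] < exon_len - B)
    starts <- c(starts, exon_len - B)
  as.integer(starts)
}

#' GC content of a sequence, in percent
#' @param seq Nucleotide string over `{A,C,G,T}`.
#' @export
compute_gc <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  if (any(!chars %in% c("A", "C", "G", "T")))
    stop("ambiguity code in sequence: GC/Tm are defined over {A,C,G,T} only")
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Melting temperature by the basic long-oligo formula
#'
#' `Tm = 81.5 + 0.41 * GC% - 675 / L` (degrees Celsius). This is the
#' documented salt-free long-oligonucleotide approximation; vendor
#' hybridization models differ in scale, which is why the Tm cutoff is
#' disabled by default in [design_params()].
#'
#' @param seq Nucleotide string over `{A,C,G,T}`.
#' @export
compute_tm <- function(seq) {
  81.5 + 0.41 * compute_gc(seq) - 675 / nchar(seq)
}

#' Build a canonical k-mer index of blacklist sequences
#'
#' @param blacklist Named character vector of high-copy sequences (plastome,
#'   repeats, ...).
#' @param k k-mer size.
#' @return Character vector of distinct canonical k-mers.
#' @export
blacklist_index <- function(blacklist, k = 24L) {
  unique(unlist(lapply(blacklist, canonical_kmer_set, k = k),
                use.names = FALSE))
}

#' Screen a bait against a blacklist k-mer index
#'
#' Canonical k-mers make the screen strand-insensitive: a bait matching the
#' blacklist only in reverse complement still fails.
#'
#' @param bait_seq Bait sequence.
#' @param index From [blacklist_index()].
#' @param k The k used to build the index.
#' @return `TRUE` if the bait passes (shares no canonical k-mer).
#' @export
screen_blacklist <- function(bait_seq, index, k = 24L) {
  if (k > nchar(bait_seq)) stop("blacklist k exceeds bait length")
  if (length(index) == 0L) return(TRUE)
  !any(canonical_kmers_cpp(bait_seq, as.integer(k)) %in% index)
}

#' Is a sequence low-complexity?
#'
#' `TRUE` iff an exact tandem repeat of period `<= low_complexity_max_period`
#' spans at least `low_complexity_min_span` of the sequence.
#'
#' @param seq Nucleotide string.
#' @param params A [design_params()] object.
#' @export
is_low_complexity <- function(seq, params = design_params()) {
  span <- max_tandem_span_cpp(seq, params$low_complexity_max_period)
  span >= params$low_complexity_min_span * nchar(seq)
}

# Redundancy predicate shared by the greedy pass: TRUE if at the best
# ungapped relative offset the overlap reaches ceil(coverage * B) bases and
# identity over the overlap strictly exceeds the identity threshold.
bait_redundant <- function(a, b, params = design_params()) {
  min_ov <- as.integer(ceiling(params$redundancy_coverage * params$bait_len))
  baits_redundant_cpp(a, b, min_ov, params$redundancy_identity)
}

#' Remove redundant baits
#'
#' Greedy single pass over baits in canonical order (locus, exon, start,
#' species): a bait is kept iff it is not redundant with any already-kept
#' bait, where redundancy means identity above `redundancy_identity` over an
#' ungapped overlap of at least `redundancy_coverage * bait_len` bases at
#' some relative offset.
#'
#' @param baits A bait data.frame (see [build_panel()]) or a character vector
#'   of bait sequences.
#' @param params A [design_params()] object.
#' @return List with `kept` and `dropped` (same type as the input).
#' @export
dedupe_baits <- function(baits, params = design_params()) {
  seqs <- if (is.data.frame(baits)) baits$seq else baits
  n <- length(seqs)
  # lossless prefilter: identity > 0.95 over >= 0.83*B forces <= 3
  # mismatches in the overlap, so by pigeonhole a redundant pair shares an
  # exact 16-mer; only baits sharing one need the all-offsets test
  min_ov <- ceiling(params$redundancy_coverage * params$bait_len)
  mism_max <- ceiling(min_ov * (1 - params$redundancy_identity))
  kpre <- max(4L, as.integer(floor((min_ov - mism_max) / (mism_max + 1L))))
  kmap <- new.env(parent = emptyenv(), size = 4L * n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    kms <- unique(forward_kmers_cpp(seqs[i], kpre))
    kms <- kms[!is.na(kms)]
    cand <- unique(unlist(lapply(kms, function(k) kmap[[k]]),
                          use.names = FALSE))
    red <- FALSE
    for (j in cand) {
      if (bait_redundant(seqs[j], seqs[i], params)) { red <- TRUE; break }
    }
    if (!red) {
      keep[i] <- TRUE
      for (k in kms) kmap[[k]] <- c(kmap[[k]], i)
    }
  }
  if (is.data.frame(baits))
    list(kept = baits[keep, , drop = FALSE],
         dropped = baits[!keep, , drop = FALSE])
  else
    list(kept = seqs[keep], dropped = seqs[!keep])
}

# Ungapped exon sequence of one member of a locus candidate.
member_exon_seq <- function(candidate, species, exon_idx) {
  em <- candidate$exon_map
  row <- candidate$alignment[[species]]
  sub <- substr(row, em$start[exon_idx] + 1L, em$end[exon_idx])
  gsub("-", "", sub, fixed = TRUE)
}

#' Build a filtered, tiled bait panel from kept loci
#'
#' Every exon of length at least `bait_len` is tiled per source species
#' ([tile_exon()] on the species' ungapped exon sequence); candidate baits
#' then pass through the screens in order low-complexity, blacklist, GC (and
#' Tm when enabled), redundancy. Baits containing `N` are dropped up front
#' (`ambiguous`). The manifest records per-locus retained/dropped counts and
#' the per-exon average tiling depth (sum of retained bait lengths over exon
#' length); the ledger records every dropped bait with its reason.
#'
#' @param kept_loci Named list of passing locus candidates (from
#'   [apply_locus_filters()]).
#' @param blacklist Named character vector of blacklist sequences (may be
#'   empty).
#' @param params A [design_params()] object.
#' @return List of class `"bait_panel"` with `baits` (data.frame: bait_id,
#'   locus_id, source_species, exon_index, start, seq, gc_pct, tm_c),
#'   `dropped` (same columns plus `drop_reason`), `manifest` (per-locus
#'   counts) and `exon_depth` (per locus and exon average tiling depth).
#' @export
build_panel <- function(kept_loci, blacklist = character(0),
                        params = design_params()) {
  B <- params$bait_len
  idx <- blacklist_index(blacklist, params$blacklist_k)
  rows <- list()
  for (locus_id in sort(names(kept_loci))) {
    cand <- kept_loci[[locus_id]]
    n_ex <- nrow(cand$exon_map)
    if (n_ex == 0L) next
    for (sp in sort(names(cand$alignment))) {
      for (e in seq_len(n_ex)) {
        if (!is.null(cand$exon_presence) && !cand$exon_presence[sp, e]) next
        eseq <- member_exon_seq(cand, sp, e)
        E <- nchar(eseq)
        if (E < B) next
        for (st in tile_exon(E, params)) {
          rows[[length(rows) + 1L]] <- data.frame(
            locus_id = locus_id, source_species = sp, exon_index = e,
            start = st, exon_len = E,
            seq = substr(eseq, st + 1L, st + B),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    empty <- data.frame(bait_id = character(0), locus_id = character(0),
                        source_species = character(0),
                        exon_index = integer(0), start = integer(0),
                        exon_len = integer(0), seq = character(0),
                        gc_pct = numeric(0), tm_c = numeric(0),
                        stringsAsFactors = FALSE)
    return(structure(list(baits = empty,
                          dropped = cbind(empty, drop_reason = character(0)),
                          manifest = NULL, exon_depth = NULL),
                     class = "bait_panel"))
  }
  baits <- do.call(rbind, rows)
  # canonical order
  baits <- baits[order(baits$locus_id, baits$exon_index, baits$start,
                       baits$source_species), , drop = FALSE]
  baits$bait_id <- sprintf("%s_%s_e%d_p%d", baits$locus_id,
                           baits$source_species, baits$exon_index,
                           baits$start)
  reason <- rep(NA_character_, nrow(baits))
  has_n <- grepl("N", baits$seq, fixed = TRUE)
  reason[has_n] <- "ambiguous"
  todo <- which(is.na(reason))
  lc <- vapply(baits$seq[todo], is_low_complexity, TRUE, params = params)
  reason[todo[lc]] <- "low_complexity"
  todo <- which(is.na(reason))
  bl <- !vapply(baits$seq[todo], screen_blacklist, TRUE,
                index = idx, k = params$blacklist_k)
  reason[todo[bl]] <- "blacklist"
  baits$gc_pct <- NA_real_
  baits$tm_c <- NA_real_
  todo <- which(is.na(reason))
  baits$gc_pct[todo] <- vapply(baits$seq[todo], compute_gc, 0)
  baits$tm_c[todo] <- vapply(baits$seq[todo], compute_tm, 0)
  gc_fail <- !is.na(baits$gc_pct) & baits$gc_pct > params$gc_max
  reason[is.na(reason) & gc_fail] <- "gc"
  if (!is.null(params$tm_max)) {
    tm_fail <- !is.na(baits$tm_c) & baits$tm_c > params$tm_max
    reason[is.na(reason) & tm_fail] <- "tm"
  }
  surv <- baits[is.na(reason), , drop = FALSE]
  dd <- dedupe_baits(surv, params)
  reason[match(dd$dropped$bait_id, baits$bait_id)] <- "redundant"
  kept <- dd$kept
  dropped <- baits[!is.na(reason), , drop = FALSE]
  dropped$drop_reason <- reason[!is.na(reason)]

  ex_info <- unique(baits[, c("locus_id", "exon_index", "exon_len")])
  # reference exon length for depth: longest species copy of that exon
  agg_len <- stats::aggregate(exon_len ~ locus_id + exon_index,
                              data = ex_info, FUN = max)
  kept_bases <- if (nrow(kept)) {
    stats::aggregate(list(bait_bases = rep(params$bait_len, nrow(kept))),
                     by = list(locus_id = kept$locus_id,
                               exon_index = kept$exon_index), FUN = sum)
  } else {
    data.frame(locus_id = character(0), exon_index = integer(0),
               bait_bases = numeric(0))
  }
  exon_depth <- merge(agg_len, kept_bases, all.x = TRUE)
  exon_depth$bait_bases[is.na(exon_depth$bait_bases)] <- 0
  exon_depth$avg_depth <- exon_depth$bait_bases / exon_depth$exon_len
  exon_depth <- exon_depth[order(exon_depth$locus_id,
                                 exon_depth$exon_index), , drop = FALSE]

  manifest <- data.frame(
    locus_id = sort(unique(baits$locus_id)), stringsAsFactors = FALSE)
  manifest$n_designed <- as.integer(table(baits$locus_id)[manifest$locus_id])
  tk <- table(kept$locus_id)
  manifest$n_retained <- as.integer(ifelse(manifest$locus_id %in% names(tk),
                                           tk[manifest$locus_id], 0L))
  manifest$n_dropped <- manifest$n_designed - manifest$n_retained

  cols <- c("bait_id", "locus_id", "source_species", "exon_index", "start",
            "exon_len", "seq", "gc_pct", "tm_c")
  structure(list(baits = kept[, cols],
                 dropped = dropped[, c(cols, "drop_reason")],
                 manifest = manifest, exon_depth = exon_depth),
            class = "bait_panel")
}

#' Write a bait panel FASTA
#'
#' Headers carry provenance:
#' `"<bait_id> locus=<L> exon=<i> start=<s> gc=<g> tm=<t>"`.
#'
#' @param panel A `"bait_panel"` from [build_panel()].
#' @param path Output path.
#' @export
write_bait_fasta <- function(panel, path) {
  b <- panel$baits
  headers <- sprintf("%s locus=%s exon=%d start=%d gc=%.2f tm=%.2f",
                     b$bait_id, b$locus_id, b$exon_index, b$start,
                     b$gc_pct, b$tm_c)
  lines <- as.vector(rbind(paste0(">", headers), b$seq))
  writeLines(lines, path)
  invisible(path)
}
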