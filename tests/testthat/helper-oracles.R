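# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately written without reusing the package's internal machinery so
# the tests cross-check two routes to the same answer.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force redundancy oracle: all ungapped offsets, integer-coded strings
oracle_redundant <- function(a, b, min_ov = 67L, min_id = 0.95) {
  ai <- utf8ToInt(a); bi <- utf8ToInt(b)
  na <- length(ai); nb <- length(bi)
  for (off in seq(-(nb - min_ov), na - min_ov)) {
    a0 <- max(1L, off + 1L); a1 <- min(na, off + nb)
    span <- a1 - a0 + 1L
    if (span < min_ov) next
    m <- sum(ai[a0:a1] == bi[(a0 - off):(a1 - off)])
    if (m / span > min_id) return(TRUE)
  }
  FALSE
}

# brute-force re-check of the three locus filters, independent of
# apply_locus_filters' internals
oracle_filter <- function(cand, params) {
  reasons <- character(0)
  present <- names(cand$group$members)
  if (!is.null(params$focal_species))
    present <- present[present %in% params$focal_species]
  if (length(present) < params$min_presence)
    reasons <- c(reasons, "absent_species")
  n_ex <- nrow(cand$exon_map)
  if (!is.null(cand$alignment) && n_ex >= 3L) {
    for (e in 2:(n_ex - 1L)) {
      if (cand$exon_map$end[e] - cand$exon_map$start[e] < params$min_exon_len) {
        reasons <- c(reasons, "short_internal_exon")
        break
      }
    }
  }
  if (!is.null(cand$alignment) && length(cand$alignment) >= 2L) {
    rows <- lapply(unname(cand$alignment), function(r) strsplit(r, "")[[1L]])
    len <- length(rows[[1L]])
    poly <- 0L
    for (i in seq_len(len)) {
      col <- vapply(rows, `[[`, "", i)
      col <- col[col %in% c("A", "C", "G", "T")]
      if (length(unique(col)) >= 2L) poly <- poly + 1L
    }
    if (1000 * poly / len < params$min_snp_density)
      reasons <- c(reasons, "low_snp_density")
  }
  if (length(reasons)) sort(reasons) else character(0)
}

# random locus candidate spanning the filter boundaries: 2-4 species rows,
# 1-5 exons (some short), per-column polymorphism rate 0-6%
make_random_candidate <- function(id, species_pool = c("SpA", "SpB", "SpC",
                                                       "SpD")) {
  n_sp <- sample(2:4, 1L)
  sp <- sort(sample(species_pool, n_sp))
  n_ex <- sample(1:5, 1L)
  ex_len <- sample(40:300, n_ex, replace = TRUE)
  len <- sum(ex_len)
  q <- runif(1L, 0, 0.06)
  base <- strsplit(rand_seq(len), "")[[1L]]
  rows <- lapply(seq_len(n_sp), function(i) base)
  for (i in which(runif(len) < q)) {
    r <- sample(n_sp, 1L)
    rows[[r]][i] <- sample(setdiff(c("A", "C", "G", "T"), rows[[r]][i]), 1L)
  }
  aln <- setNames(vapply(rows, paste, "", collapse = ""), sp)
  ends <- cumsum(ex_len)
  list(locus_id = id,
       group = list(locus_id = id,
                    members = setNames(as.list(aln), sp),
                    member_ids = setNames(paste0(sp, "_", id), sp),
                    copy_counts = setNames(rep(1L, n_sp), sp)),
       alignment = aln,
       exon_map = data.frame(start = c(0L, ends[-n_ex]), end = ends),
       exon_presence = matrix(TRUE, n_sp, n_ex, dimnames = list(sp, NULL)),
       snp_density = NA_real_, verdict = "unfiltered",
       reasons = character(0))
}

# mismatch fraction between two equal-length sequences
mismatch_frac <- function(a, b) {
  mean(utf8ToInt(a) != utf8ToInt(b))
}
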