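# Capture-experiment evaluation: pseudo-mapping, on-target statistics,
# recovery and paralog flags.

as_target_df <- function(targets) {
  if (is.data.frame(targets)) return(targets)
  stopifnot(is.character(targets), !is.null(names(targets)))
  ids <- names(targets)
  data.frame(ref = ids, species = sub("-[^-]*$", "", ids),
             locus = sub("^.*-", "", ids), seq = unname(targets),
             len = nchar(unname(targets)), stringsAsFactors = FALSE)
}

#' Map reads onto panel reference targets
#'
#' A deterministic seed-and-extend pseudo-mapper: a read maps to the
#' reference maximizing ungapped identity at a diagonal implied by a shared
#' 31-mer seed (both strands are tried), provided the overlap spans at least
#' `min(min_span, read length)` bases at identity `>= min_identity`. Each
#' read is counted for exactly one (locus, reference); ties break by plus
#' strand first, then lexicographic reference id. Reads with no shared seed
#' are off-target. The per-locus figure is the maximum count across that
#' locus's references.
#'
#' @param reads Named character vector of read sequences.
#' @param targets Target reference set: a `"Species-locus"`-named character
#'   vector or a data.frame from [read_target_file()].
#' @param seed_k Seed k-mer size.
#' @param min_identity Minimum overlap identity for a mapping.
#' @param min_span Minimum overlap span in bases (capped at the read length).
#' @return A mapping result: list with `per_ref` (counts per reference),
#'   `locus_counts` (per-locus max count and the length of the reference
#'   achieving it), `assignments` (per mapped read), `total_reads` and
#'   `reads_mapped`.
#' @export
map_reads <- function(reads, targets, seed_k = 31L, min_identity = 0.90,
                      min_span = 100L) {
  targets <- as_target_df(targets)
  stopifnot(length(reads) > 0L, nrow(targets) > 0L)
  if (any(nchar(reads) < seed_k))
    stop("read(s) shorter than the seed k-mer size")
  ord <- order(targets$ref)
  ref_rank <- integer(nrow(targets)); ref_rank[ord] <- seq_along(ord)
  assigned_ref <- map_reads_cpp(targets$seq, unname(reads), ref_rank,
                                as.integer(seed_k), min_identity,
                                as.integer(min_span))
  mapped <- !is.na(assigned_ref)
  per_ref <- targets[, c("ref", "species", "locus", "len")]
  per_ref$count <- as.integer(tabulate(assigned_ref[mapped],
                                       nbins = nrow(targets)))
  locus_counts <- do.call(rbind, lapply(split(per_ref, per_ref$locus),
    function(d) {
      d <- d[order(-d$count, d$ref), , drop = FALSE]
      data.frame(locus = d$locus[1L], count = d$count[1L],
                 ref = d$ref[1L], ref_len = d$len[1L],
                 stringsAsFactors = FALSE)
    }))
  locus_counts <- locus_counts[order(locus_counts$locus), , drop = FALSE]
  rownames(locus_counts) <- NULL
  assignments <- data.frame(
    read_id = names(reads)[mapped],
    ref = targets$ref[assigned_ref[mapped]],
    locus = targets$locus[assigned_ref[mapped]],
    stringsAsFactors = FALSE)
  list(per_ref = per_ref, locus_counts = locus_counts,
       assignments = assignments,
       total_reads = length(reads), reads_mapped = sum(mapped))
}

#' Percentage of reads on target
#'
#' @param reads_mapped,reads_total Read counts; `reads_total` must be > 0.
#' @return `100 * reads_mapped / reads_total`, reported to one decimal.
#' @export
pct_on_target <- function(reads_mapped, reads_total) {
  if (reads_total <= 0) stop("reads_total must be positive")
  round(100 * reads_mapped / reads_total, 1)
}

#' Per-locus read coverage
#'
#' Coverage is the per-locus read count times the read length divided by the
#' reference length of the locus (the reference that yielded the maximal
#' count).
#'
#' @param locus_count Reads counted for the locus.
#' @param read_len Read length in bases (e.g. 300 for MiSeq, 150 for HiSeq).
#' @param locus_ref_len Reference length of the locus.
#' @return Coverage in x.
#' @export
locus_coverage <- function(locus_count, read_len, locus_ref_len) {
  if (any(locus_ref_len <= 0)) stop("zero reference length")
  locus_count * read_len / locus_ref_len
}

#' Recovery statistics and recovery matrix
#'
#' Per sample: the total assembled target length, the number of loci with
#' any sequence, and the percentage of the total reference target length
#' recovered. The matrix holds per-locus recovery fractions
#' (assembled length / reference length); entries above 1 (assemblies longer
#' than the reference) are retained and reported separately.
#'
#' The reference target length of a locus is the longest reference among the
#' panel's source species.
#'
#' @param assemblies Named list (sample -> named vector keyed by locus id,
#'   holding assembled sequences or assembled lengths).
#' @param targets Target reference set (see [map_reads()]).
#' @return List with `stats` (per-sample data.frame), `matrix` (loci x
#'   samples recovery fractions) and `over_reference` (entries > 1).
#' @export
recovery_stats <- function(assemblies, targets) {
  targets <- as_target_df(targets)
  ref_len <- vapply(split(targets$len, targets$locus), max, 0)
  loci <- sort(names(ref_len))
  ref_len <- ref_len[loci]
  samples <- names(assemblies)
  stopifnot(!is.null(samples))
  mat <- matrix(0, length(loci), length(samples),
                dimnames = list(loci, samples))
  stats <- vector("list", length(samples))
  for (s in samples) {
    a <- assemblies[[s]]
    lens <- if (is.character(a)) nchar(a) else as.numeric(a)
    names(lens) <- names(a)
    unknown <- setdiff(names(lens), loci)
    if (length(unknown))
      stop("assembly for unknown locus id: ",
           paste(unknown, collapse = ", "))
    mat[names(lens), s] <- lens / ref_len[names(lens)]
    stats[[match(s, samples)]] <- data.frame(
      sample = s,
      total_assembled_target_len = sum(lens),
      loci_with_sequence = sum(lens > 0),
      pct_target_recovered = round(100 * sum(lens) / sum(ref_len), 1),
      stringsAsFactors = FALSE)
  }
  over <- which(mat > 1, arr.ind = TRUE)
  over_df <- data.frame(sample = colnames(mat)[over[, 2L]],
                        locus = rownames(mat)[over[, 1L]],
                        recovery_frac = mat[over],
                        stringsAsFactors = FALSE)
  list(stats = do.call(rbind, stats), matrix = mat, over_reference = over_df)
}

#' Flag potential paralogs
#'
#' A (sample, locus) pair is flagged when at least two competing contigs
#' each cover at least `paralog_min_frac` of the locus reference length,
#' mirroring the warning criterion of standard target-capture assemblers.
#'
#' @param contig_sets Named list (sample -> named list keyed by locus id of
#'   numeric contig lengths).
#' @param ref_len Named numeric vector of per-locus reference lengths.
#' @param paralog_min_frac Minimum reference coverage per competing contig.
#' @return data.frame with `sample`, `locus`, `n_competing` and the
#'   competing contigs' coverage fractions (comma-separated).
#' @export
flag_paralogs <- function(contig_sets, ref_len, paralog_min_frac = 0.85) {
  rows <- list()
  for (s in names(contig_sets)) {
    for (locus in names(contig_sets[[s]])) {
      lens <- contig_sets[[s]][[locus]]
      if (!locus %in% names(ref_len))
        stop("unknown locus in contig set: ", locus)
      frac <- lens / ref_len[[locus]]
      comp <- frac[frac >= paralog_min_frac]
      if (length(comp) >= 2L)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, locus = locus, n_competing = length(comp),
          coverage_fracs = paste(sprintf("%.3f", sort(comp,
                                                      decreasing = TRUE)),
                                 collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(sample = character(0), locus = character(0),
                      n_competing = integer(0),
                      coverage_fracs = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Combine mapping and recovery into per-sample capture statistics
#'
#' @param mapping A mapping result from [map_reads()].
#' @param recovery The output of [recovery_stats()].
#' @param sample Sample id (must be a column of the recovery matrix).
#' @param read_len Read length used for per-locus coverage.
#' @return One-row data.frame with the standard per-sample statistics plus a
#'   `coverage` attribute (per-locus coverage in x).
#' @export
sample_capture_stats <- function(mapping, recovery, sample, read_len) {
  rec <- recovery$stats[recovery$stats$sample == sample, , drop = FALSE]
  stopifnot(nrow(rec) == 1L)
  out <- data.frame(
    sample = sample,
    reads_after_trimming = mapping$total_reads,
    reads_mapped = mapping$reads_mapped,
    pct_on_target = pct_on_target(mapping$reads_mapped,
                                  mapping$total_reads),
    total_assembled_target_len = rec$total_assembled_target_len,
    loci_with_sequence = rec$loci_with_sequence,
    pct_target_recovered = rec$pct_target_recovered,
    stringsAsFactors = FALSE)
  cov <- locus_coverage(mapping$locus_counts$count, read_len,
                        mapping$locus_counts$ref_len)
  attr(out, "coverage") <- setNames(cov, mapping$locus_counts$locus)
  out
}

#' Group summary of per-sample capture statistics
#'
#' Arithmetic mean of every numeric column over the samples of a group;
#' count columns are rounded to the nearest integer and percentage columns
#' to one decimal. The mean is invariant to sample order.
#'
#' @param stats Per-sample statistics data.frame (one row per sample).
#' @param group_label Label placed in the `sample` column of the summary.
#' @return One-row data.frame.
#' @export
summarize_samples <- function(stats, group_label = "average") {
  if (nrow(stats) == 0L) stop("empty sample group")
  num <- vapply(stats, is.numeric, TRUE)
  means <- lapply(names(stats)[num], function(col) {
    m <- mean(stats[[col]])
    if (startsWith(col, "pct_")) round(m, 1) else round(m)
  })
  out <- stats[1L, , drop = FALSE]
  out$sample <- group_label
  out[names(stats)[num]] <- means
  rownames(out) <- NULL
  out
}

#' Example capture statistics table
#'
#' Per-sample target-capture sequencing statistics from an Alooideae
#' bait-panel experiment (23 *Aloe* samples, one *Aloiampelos* and three
#' outgroup taxa enriched with a 189-locus clade-specific panel), bundled
#' for worked examples and arithmetic checks.
#'
#' @return data.frame with columns `sample`, `group`, `origin`,
#'   `reads_after_trimming`, `reads_mapped`, `pct_on_target` (as printed in
#'   the source experiment's report), `total_assembled_target_len`,
#'   `loci_with_sequence`, `pct_target_recovered`.
#' @export
capture_stats_table <- function() {
  path <- system.file("extdata", "alooideae_capture_stats.tsv",
                      package = "lcnbait")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             quote = "")
}
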