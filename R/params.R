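#' Parameters for locus selection
#'
#' Bundles the thresholds used when selecting bait-ready low-copy nuclear
#' loci from clustered ortholog groups.
#'
#' @param min_presence Minimum number of focal-clade species a locus must be
#'   present in (after any rescue). Default 3, matching a design built on
#'   three ingroup transcriptomes plus one outgroup.
#' @param bait_len Bait length in bases (B). Default 80.
#' @param min_exon_len Minimum length of an internal (mid-locus) exon; loci
#'   with a shorter internal exon are rejected because such exons cannot carry
#'   an intron-free bait. Defaults to `bait_len`.
#' @param min_snp_density Minimum SNP density (polymorphic alignment columns
#'   per 1,000 bp); loci strictly below this are rejected. Default 20.
#' @param rescue_min_identity Minimum ungapped identity for rescuing a locus
#'   from the transcriptome of a species it was not clustered in. Default 0.80.
#' @param rescue_min_coverage Minimum fraction of the group consensus the
#'   rescue hit must span. Default 0.50.
#' @param k_cluster k-mer size for the reciprocal-best-match clustering and
#'   seed-and-extend searches. Default 21.
#' @param k_ref Seed k-mer size when matching loci against the annotated
#'   reference gene set. Smaller than `k_cluster` because the annotation
#'   donor is typically far more divergent than the focal clade. Default 15.
#' @param focal_species Character vector of focal-clade species names used by
#'   the presence rule, or `NULL` to treat every input species as focal.
#'
#' @return A list of class `"selection_params"`.
#' @export
selection_params <- function(min_presence = 3L,
                             bait_len = 80L,
                             min_exon_len = bait_len,
                             min_snp_density = 20,
                             rescue_min_identity = 0.80,
                             rescue_min_coverage = 0.50,
                             k_cluster = 21L,
                             k_ref = 15L,
                             focal_species = NULL) {
  stopifnot(min_presence >= 1, bait_len > 0, min_exon_len >= bait_len,
            min_snp_density > 0,
            rescue_min_identity > 0, rescue_min_identity <= 1,
            rescue_min_coverage > 0, rescue_min_coverage <= 1,
            k_cluster > 0, k_ref > 0)
  structure(list(
    min_presence = as.integer(min_presence),
    bait_len = as.integer(bait_len),
    min_exon_len = as.integer(min_exon_len),
    min_snp_density = min_snp_density,
    rescue_min_identity = rescue_min_identity,
    rescue_min_coverage = rescue_min_coverage,
    k_cluster = as.integer(k_cluster),
    k_ref = as.integer(k_ref),
    focal_species = focal_species
  ), class = "selection_params")
}

#' Parameters for bait panel design
#'
#' @param bait_len Bait length in bases (B). Default 80.
#' @param tiling_depth Target average tiling depth d; bait starts are
#'   staggered by `round(bait_len / tiling_depth)` bases. Default 3.
#' @param blacklist_k k-mer size of the blacklist screen: a bait sharing any
#'   canonical k-mer of this length with the blacklist is dropped. Default 24.
#' @param redundancy_identity Identity threshold of the redundancy rule
#'   (strict: identity must exceed it). Default 0.95.
#' @param redundancy_coverage Minimum overlap, as a fraction of bait length,
#'   at which two baits are compared for redundancy. Default 0.83.
#' @param gc_max Maximum GC content in percent; baits strictly above are
#'   dropped. Default 75.
#' @param tm_max Maximum melting temperature in degrees Celsius, or `NULL` to
#'   disable the Tm screen (the default: the basic long-oligo Tm formula used
#'   here is on a different scale than vendor hybridization models, so an
#'   absolute cutoff is left to the user).
#' @param low_complexity_max_period Maximum tandem-repeat period considered by
#'   the low-complexity screen. Default 6.
#' @param low_complexity_min_span Minimum fraction of the bait that a tandem
#'   repeat must span for the bait to be dropped. Default 0.60.
#'
#' @return A list of class `"design_params"`.
#' @export
design_params <- function(bait_len = 80L,
                          tiling_depth = 3,
                          blacklist_k = 24L,
                          redundancy_identity = 0.95,
                          redundancy_coverage = 0.83,
                          gc_max = 75,
                          tm_max = NULL,
                          low_complexity_max_period = 6L,
                          low_complexity_min_span = 0.60) {
  stopifnot(bait_len > 0, tiling_depth > 0, tiling_depth <= bait_len,
            blacklist_k > 0, blacklist_k <= bait_len,
            redundancy_identity > 0, redundancy_identity <= 1,
            redundancy_coverage > 0, redundancy_coverage <= 1,
            gc_max > 0, gc_max <= 100,
            low_complexity_max_period >= 1,
            low_complexity_min_span > 0, low_complexity_min_span <= 1)
  structure(list(
    bait_len = as.integer(bait_len),
    tiling_depth = tiling_depth,
    blacklist_k = as.integer(blacklist_k),
    redundancy_identity = redundancy_identity,
    redundancy_coverage = redundancy_coverage,
    gc_max = gc_max,
    tm_max = tm_max,
    low_complexity_max_period = as.integer(low_complexity_max_period),
    low_complexity_min_span = low_complexity_min_span
  ), class = "design_params")
}
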