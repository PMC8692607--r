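# Seeded synthetic-data generator: multi-species transcript sets evolved
# under Jukes-Cantor on a fixed tree, adversarial injections with a
# ground-truth manifest, and capture read sets with a known on-target
# fraction.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the toolkit targets: four
#' congeneric transcriptomes (three focal ingroup species plus one more
#' distant congener) with divergence high enough that ordinary loci clear
#' the 20 SNPs / 1,000 bp filter by a wide margin, exon architectures of
#' 2-6 exons of 120-400 bp, and controlled fractions of adversarial loci
#' (low divergence, short internal exon, paralogous extra copy, absence in
#' one species, embedded simple repeat).
#'
#' @param seed Mandatory integer seed; every downstream draw is derived
#'   from it.
#' @param tree Newick string with branch lengths in expected
#'   substitutions/site.
#' @param focal_species Tips subject to the presence rule.
#' @param n_loci Number of loci.
#' @param exon_count_range,exon_len_range Inclusive ranges for exon
#'   architecture draws.
#' @param fraction_low_snp Fraction of loci evolved on the tree rescaled by
#'   `low_snp_tree_scale` so they fall clearly below the SNP-density
#'   threshold.
#' @param fraction_short_internal_exon Fraction of loci given one internal
#'   exon of 40-70 bp.
#' @param fraction_with_paralog Fraction of loci with an extra paralogous
#'   copy in one species at `paralog_identity_range` identity.
#' @param fraction_absent_in_one_species Fraction of loci removed from one
#'   (uniformly drawn) species' transcript set.
#' @param repeat_injection Fraction of loci with a 60 bp `AT` simple repeat
#'   embedded at identical coordinates in every species.
#' @param low_snp_tree_scale Branch-length multiplier for low-divergence
#'   loci.
#' @param paralog_identity_range Identity range of injected paralogs to
#'   their sister copy.
#' @param reference_branch Divergence of the annotated reference (the
#'   exon-model donor) from the root.
#' @param min_presence,min_snp_density,bait_len Thresholds mirrored into
#'   the truth manifest's intended verdicts.
#' @param read_len,n_reads,on_target_fraction,background_len Read-set
#'   parameters.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       tree = "((AloeA:0.03,AloeB:0.03):0.02,AloeC:0.05,Outgrp:0.10);",
                       focal_species = c("AloeA", "AloeB", "AloeC"),
                       n_loci = 30L,
                       exon_count_range = c(2L, 6L),
                       exon_len_range = c(120L, 400L),
                       fraction_low_snp = 0.15,
                       fraction_short_internal_exon = 0.15,
                       fraction_with_paralog = 0.10,
                       fraction_absent_in_one_species = 0.10,
                       repeat_injection = 0.10,
                       low_snp_tree_scale = 0.03,
                       paralog_identity_range = c(0.95, 0.99),
                       reference_branch = 0.10,
                       min_presence = 3L,
                       min_snp_density = 20,
                       bait_len = 80L,
                       read_len = 150L,
                       n_reads = 2000L,
                       on_target_fraction = 0.5,
                       background_len = 20000L) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  fr <- c(fraction_low_snp, fraction_short_internal_exon,
          fraction_with_paralog, fraction_absent_in_one_species,
          repeat_injection, on_target_fraction)
  stopifnot(all(fr >= 0), all(fr <= 1), n_loci >= 1, read_len > 0,
            n_reads > 0, reference_branch >= 0, low_snp_tree_scale > 0)
  if (exon_len_range[1L] < bait_len)
    stop("exon_len_range must start at or above bait_len so that only ",
         "injected exons are short")
  structure(as.list(environment()), class = "sim_config")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Jukes-Cantor per-site substitution probability for branch length d
# (expected substitutions/site).
jc_mismatch_prob <- function(d) 0.75 * (1 - exp(-4 * d / 3))

mutate_seq <- function(seq, p) {
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(runif(length(chars)) < p)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    cur <- match(chars[hit], bases)
    chars[hit] <- bases[((cur - 1L + sample(1:3, length(hit),
                                            replace = TRUE)) %% 4L) + 1L]
  }
  paste(chars, collapse = "")
}

#' Evolve a root sequence along a tree under Jukes-Cantor
#'
#' Each site mutates along each branch with probability
#' `3/4 * (1 - exp(-4 d / 3))` to a uniformly random different base.
#'
#' @param root_seq Root nucleotide sequence over `{A,C,G,T}`.
#' @param tree An `ape::phylo` tree or a newick string; branch lengths in
#'   expected substitutions/site.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Named character vector of tip sequences.
#' @export
evolve_on_tree <- function(root_seq, tree, seed = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- root_seq
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    seqs[[child]] <- mutate_seq(seqs[[parent]],
                                jc_mismatch_prob(ord$edge.length[e]))
  }
  setNames(unlist(seqs[seq_len(n_tip)]), tree$tip.label)
}

# SNP density computed directly from equal-length ungapped sequences
# (polymorphic site columns per 1,000 bp); this is the simulator's own
# ground-truth bookkeeping, independent of the alignment machinery.
site_snp_density <- function(seqs) {
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  poly <- apply(mat, 2L, function(col) length(unique(col)) >= 2L)
  1000 * sum(poly) / ncol(mat)
}

#' Generate a synthetic locus set with ground truth
#'
#' For each locus an exon architecture is drawn, a root sequence evolved
#' across the tree, and the configured adversarial injections applied. The
#' truth manifest records, per locus, the injections and the intended
#' filter outcome recomputed directly from the emitted sequences (species
#' presence against the focal set, internal exon lengths, site SNP
#' density), so it can be verified by an independent oracle.
#'
#' @param config A [sim_config()].
#' @return List with `transcript_sets` (species -> named sequences),
#'   `reference` (per-locus annotated reference sequences), `reference_exons`
#'   (per-locus [exon_map()]s), `truth` (manifest data.frame) and `tree`.
#' @export
make_locus_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- ape::read.tree(text = config$tree)
  tips <- sort(tree$tip.label)
  n <- config$n_loci
  draw <- function(frac) {
    k <- round(frac * n)
    if (k == 0L) integer(0) else sample(n, k)
  }
  inj_low <- draw(config$fraction_low_snp)
  inj_short <- draw(config$fraction_short_internal_exon)
  inj_para <- draw(config$fraction_with_paralog)
  inj_abs <- draw(config$fraction_absent_in_one_species)
  inj_rep <- draw(config$repeat_injection)

  transcript_sets <- setNames(replicate(length(tips), character(0),
                                        simplify = FALSE), tips)
  reference <- character(0)
  reference_exons <- list()
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    locus <- sprintf("L%03d", i)
    n_ex <- sample(config$exon_count_range[1L]:config$exon_count_range[2L], 1L)
    if (i %in% inj_short) n_ex <- max(n_ex, 3L)
    lens <- sample(config$exon_len_range[1L]:config$exon_len_range[2L],
                   n_ex, replace = TRUE)
    short_len <- NA_integer_
    if (i %in% inj_short) {
      short_len <- sample(40:70, 1L)
      lens[sample(2:(n_ex - 1L), 1L)] <- short_len
    }
    total <- sum(lens)
    root <- random_seq(total)
    tr <- tree
    if (i %in% inj_low) tr$edge.length <- tr$edge.length * config$low_snp_tree_scale
    tip_seqs <- evolve_on_tree(root, tr)

    repeat_region <- ""
    if (i %in% inj_rep) {
      cand_ex <- which(lens >= 80L)
      if (length(cand_ex)) {
        e <- cand_ex[sample.int(length(cand_ex), 1L)]
        ex_start <- c(0L, cumsum(lens))[e]
        off <- sample.int(lens[e] - 60L + 1L, 1L) - 1L
        r0 <- ex_start + off
        rep_seq <- strrep("AT", 30L)
        tip_seqs <- vapply(tip_seqs, function(s) {
          paste0(substr(s, 1L, r0), rep_seq, substr(s, r0 + 61L, total))
        }, "", USE.NAMES = TRUE)
        repeat_region <- sprintf("%d-%d", r0, r0 + 60L)
      }
    }

    absent_sp <- ""
    if (i %in% inj_abs) absent_sp <- sample(tips, 1L)
    present <- setdiff(tips, absent_sp)

    paralog_sp <- ""
    if (i %in% inj_para) {
      paralog_sp <- sample(present, 1L)
      ident <- runif(1L, config$paralog_identity_range[1L],
                     config$paralog_identity_range[2L])
      para <- mutate_seq(tip_seqs[[paralog_sp]], 1 - ident)
      transcript_sets[[paralog_sp]][paste0(paralog_sp, "_", locus, "p")] <- para
    }
    for (sp in present)
      transcript_sets[[sp]][paste0(sp, "_", locus)] <- tip_seqs[[sp]]

    ref_seq <- mutate_seq(root, jc_mismatch_prob(config$reference_branch))
    reference[locus] <- ref_seq
    reference_exons[[locus]] <- exon_map(c(0L, cumsum(lens)[-n_ex]),
                                         cumsum(lens), total)

    # intended filter outcome, recomputed from the emitted sequences
    reasons <- character(0)
    focal_present <- length(intersect(present, config$focal_species))
    if (focal_present < config$min_presence)
      reasons <- c(reasons, "absent_species")
    internal <- if (n_ex >= 3L) lens[-c(1L, n_ex)] else integer(0)
    if (length(internal) && any(internal < config$bait_len))
      reasons <- c(reasons, "short_internal_exon")
    dens <- if (length(present) >= 2L)
      site_snp_density(tip_seqs[present]) else NA_real_
    if (!is.na(dens) && dens < config$min_snp_density)
      reasons <- c(reasons, "low_snp_density")
    truth_rows[[i]] <- data.frame(
      locus = locus, n_exons = n_ex, total_len = total,
      focal_present = focal_present, absent_species = absent_sp,
      paralog_species = paralog_sp, repeat_region = repeat_region,
      min_internal_exon = if (length(internal)) min(internal) else NA_integer_,
      snp_density_true = dens,
      intended_verdict = if (length(reasons)) "fail" else "pass",
      intended_reasons = paste(reasons, collapse = ","),
      stringsAsFactors = FALSE)
  }
  list(transcript_sets = transcript_sets, reference = reference,
       reference_exons = reference_exons,
       truth = do.call(rbind, truth_rows), tree = tree)
}

#' Simulate capture reads with a known on-target fraction
#'
#' Each read is drawn, with probability `on_target_fraction`, from a
#' uniformly random position and strand of a uniformly random target, and
#' otherwise from an i.i.d.-uniform background sequence. Reads carry truth
#' labels (the target's locus id, or `"background"`). Reads are error-free:
#' the toolkit treats simulated reads as post-trimming reads.
#'
#' @param targets Named character vector of target sequences; names of the
#'   form `"Species-locus"` are labelled by their locus part.
#' @param config A [sim_config()] (uses `read_len`, `n_reads`,
#'   `on_target_fraction`, `background_len`).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return List with `reads` (named character vector), `labels`,
#'   `read_length`.
#' @export
simulate_reads <- function(targets, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rl <- config$read_len
  usable <- targets[nchar(targets) >= rl]
  if (config$on_target_fraction > 0 && length(usable) == 0L)
    stop("no target at least as long as the read length")
  labels_of <- ifelse(grepl("-", names(usable), fixed = TRUE),
                      sub("^.*-", "", names(usable)), names(usable))
  background <- random_seq(max(config$background_len, rl))
  n <- config$n_reads
  on_target <- runif(n) < config$on_target_fraction
  reads <- character(n)
  labels <- character(n)
  for (i in seq_len(n)) {
    if (on_target[i]) {
      t <- sample.int(length(usable), 1L)
      src <- usable[[t]]
      labels[i] <- labels_of[t]
    } else {
      src <- background
      labels[i] <- "background"
    }
    pos <- sample.int(nchar(src) - rl + 1L, 1L)
    rd <- substr(src, pos, pos + rl - 1L)
    if (runif(1L) < 0.5) rd <- revcomp(rd)
    reads[i] <- rd
  }
  names(reads) <- sprintf("r%06d", seq_len(n))
  list(reads = reads, labels = setNames(labels, names(reads)),
       read_length = rl)
}
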