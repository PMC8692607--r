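test_that("zero-length branches copy the parent sequence unchanged", {
  set.seed(701)
  root <- rand_seq(500)
  tips <- evolve_on_tree(root, "(A:0,B:0);")
  expect_equal(unname(tips["A"]), root)
  expect_equal(unname(tips["B"]), root)
  expect_error(evolve_on_tree(root, "(A:-0.1,B:0);"), "negative")
})

test_that("substitution counts match the Jukes-Cantor expectation", {
  root <- rand_seq(10000)
  # d = 0.1: expected mismatch fraction 3/4 (1 - exp(-4 d / 3)) = 0.09363
  p_exp <- 0.75 * (1 - exp(-0.4 / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  tips <- evolve_on_tree(root, "(A:0.1,B:0);", seed = 702)
  p_obs <- mismatch_frac(tips[["A"]], root)
  expect_lt(abs(p_obs - p_exp), 3 * se)

  # saturation: a very long branch approaches 3/4 mismatches (25% identity)
  tips_sat <- evolve_on_tree(root, "(A:50,B:0);", seed = 703)
  expect_lt(abs(mismatch_frac(tips_sat[["A"]], root) - 0.75), 0.02)
})

test_that("the locus set generator is reproducible and self-consistent", {
  sc <- sim_config(seed = 42, n_loci = 12)
  s1 <- make_locus_set(sc)
  s2 <- make_locus_set(sc)
  expect_identical(s1, s2)
  expect_error(sim_config(n_loci = 5), "seed")

  truth <- s1$truth
  # intended verdicts are recomputable from the emitted sequences
  for (i in seq_len(nrow(truth))) {
    locus <- truth$locus[i]
    reasons <- character(0)
    present <- names(s1$transcript_sets)[vapply(
      names(s1$transcript_sets), function(sp)
        paste0(sp, "_", locus) %in% names(s1$transcript_sets[[sp]]), TRUE)]
    if (length(intersect(present, sc$focal_species)) < sc$min_presence)
      reasons <- c(reasons, "absent_species")
    em <- s1$reference_exons[[locus]]
    lens <- em$end - em$start
    if (nrow(em) >= 3L && any(lens[-c(1, nrow(em))] < 80))
      reasons <- c(reasons, "short_internal_exon")
    seqs <- vapply(present, function(sp)
      s1$transcript_sets[[sp]][[paste0(sp, "_", locus)]], "")
    if (length(seqs) >= 2L) {
      m <- do.call(rbind, strsplit(unname(seqs), ""))
      dens <- 1000 * sum(apply(m, 2, function(x)
        length(unique(x)) > 1)) / ncol(m)
      if (dens < 20) reasons <- c(reasons, "low_snp_density")
      expect_equal(truth$snp_density_true[i], dens)
    }
    expect_equal(truth$intended_verdict[i],
                 if (length(reasons)) "fail" else "pass")
  }
})

test_that("simulated reads honour the configured on-target fraction", {
  sc <- sim_config(seed = 43, n_loci = 4, n_reads = 4000,
                   on_target_fraction = 1)
  sim <- make_locus_set(sc)
  targets <- setNames(
    unlist(lapply(names(sim$transcript_sets), function(sp)
      sim$transcript_sets[[sp]])),
    unlist(lapply(names(sim$transcript_sets), function(sp)
      sub("_", "-", names(sim$transcript_sets[[sp]])))))
  rs <- simulate_reads(targets, sc, seed = 1)
  expect_true(all(rs$labels != "background"))
  expect_true(all(nchar(rs$reads) == sc$read_len))

  # f = 0.5: label fraction within the 99% binomial interval
  sc2 <- sim_config(seed = 44, n_loci = 4, n_reads = 4000,
                    on_target_fraction = 0.5)
  rs2 <- simulate_reads(targets, sc2, seed = 2)
  f_obs <- mean(rs2$labels != "background")
  expect_lt(abs(f_obs - 0.5), 2.576 * sqrt(0.25 / 4000))

  # f = 0 never touches the targets
  sc3 <- sim_config(seed = 45, n_loci = 4, n_reads = 200,
                    on_target_fraction = 0)
  rs3 <- simulate_reads(targets, sc3, seed = 3)
  expect_true(all(rs3$labels == "background"))
})

test_that("injected repeats and paralogs are recorded in the manifest", {
  sc <- sim_config(seed = 46, n_loci = 20, repeat_injection = 0.3,
                   fraction_with_paralog = 0.3)
  sim <- make_locus_set(sc)
  truth <- sim$truth
  expect_equal(sum(truth$repeat_region != ""), 6L)
  expect_equal(sum(truth$paralog_species != ""), 6L)
  # a recorded repeat region really is an AT run in every species
  i <- which(truth$repeat_region != "")[1L]
  at <- as.integer(strsplit(truth$repeat_region[i], "-")[[1L]])
  for (sp in names(sim$transcript_sets)) {
    tid <- paste0(sp, "_", truth$locus[i])
    if (!tid %in% names(sim$transcript_sets[[sp]])) next
    region <- substr(sim$transcript_sets[[sp]][[tid]], at[1L] + 1L, at[2L])
    expect_equal(region, strrep("AT", 30))
  }
  # paralog copies sit inside the configured identity band
  j <- which(truth$paralog_species != "")[1L]
  sp <- truth$paralog_species[j]
  orig <- sim$transcript_sets[[sp]][[paste0(sp, "_", truth$locus[j])]]
  para <- sim$transcript_sets[[sp]][[paste0(sp, "_", truth$locus[j], "p")]]
  ident <- 1 - mismatch_frac(orig, para)
  expect_gte(ident, 0.94)   # identity drawn in [0.95, 0.99] minus jitter
  expect_lte(ident, 1.00)
})
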