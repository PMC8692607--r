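mk_group <- function(members) {
  sp <- names(members)
  list(locus_id = "OG1", members = members,
       member_ids = setNames(paste0(sp, "_t"), sp),
       copy_counts = setNames(rep(1L, length(sp)), sp))
}

test_that("exon boundaries project unchanged onto identical members", {
  set.seed(201)
  ref <- rand_seq(250)
  cand <- annotate_exons(mk_group(c(A = ref, B = ref)), ref,
                         exon_map(c(0, 100), c(100, 250), 250))
  expect_equal(cand$exon_map$start, c(0L, 100L))
  expect_equal(cand$exon_map$end, c(100L, 250L))
  expect_true(all(cand$exon_presence))
})

test_that("a member insertion widens the containing exon interval", {
  set.seed(202)
  ref <- rand_seq(250)
  ins <- paste0(substr(ref, 1, 150), rand_seq(30), substr(ref, 151, 250))
  cand <- annotate_exons(mk_group(c(A = ref, B = ins)), ref,
                         exon_map(c(0, 100), c(100, 250), 250))
  expect_equal(cand$exon_map$start, c(0L, 100L))
  expect_equal(cand$exon_map$end, c(100L, 280L))  # exon 2 widened by 30
  expect_equal(unique(nchar(cand$alignment)), 280L)
})

test_that("a truncated member is marked absent for later exons", {
  set.seed(203)
  ref <- rand_seq(250)
  cand <- annotate_exons(mk_group(c(A = ref, B = substr(ref, 1, 90))), ref,
                         exon_map(c(0, 100), c(100, 250), 250))
  expect_true(cand$exon_presence["A", 2L])
  expect_false(cand$exon_presence["B", 2L])
})

test_that("no shared seed with the reference rejects the candidate", {
  set.seed(204)
  cand <- annotate_exons(mk_group(c(A = rand_seq(300), B = rand_seq(300))),
                         rand_seq(300), exon_map(0, 300, 300))
  expect_equal(cand$verdict, "fail")
  expect_equal(cand$reasons, "no_alignable_region")
})

test_that("end trimming keeps exactly the fully overlapping window", {
  set.seed(205)
  core <- rand_seq(12)
  cand <- list(locus_id = "OG1",
               group = mk_group(c(A = "x", B = "x")),
               alignment = c(A = paste0("-----", core, "---"),
                             B = paste0(rand_seq(5), core, "---")),
               exon_map = data.frame(start = 0L, end = 20L),
               exon_presence = matrix(TRUE, 2, 1,
                                      dimnames = list(c("A", "B"), NULL)),
               snp_density = NA_real_, verdict = "unfiltered",
               reasons = character(0))
  tr <- trim_to_overlap(cand)
  expect_equal(unique(nchar(tr$alignment)), 12L)
  expect_equal(substr(tr$alignment[["A"]], 1, 12), core)
  expect_equal(tr$exon_map$start, 0L)
  expect_equal(tr$exon_map$end, 12L)

  # already fully overlapping: unchanged
  tr2 <- trim_to_overlap(tr)
  expect_equal(tr2$alignment, tr$alignment)
  expect_equal(tr2$exon_map, tr$exon_map)

  # no common non-gap column: fail verdict
  cand$alignment <- c(A = "ACGT----", B = "----ACGT")
  tr3 <- trim_to_overlap(cand)
  expect_equal(tr3$verdict, "fail")
  expect_true("no_overlap" %in% tr3$reasons)
})

test_that("SNP density counts polymorphic columns, ignoring gaps and N", {
  rows <- setNames(rep(paste(rep("A", 100), collapse = ""), 4),
                   c("a", "b", "c", "d"))
  expect_equal(count_snp_density(rows), 0)

  r2 <- rows
  substr(r2[["b"]], 10, 10) <- "C"
  substr(r2[["c"]], 60, 60) <- "G"
  expect_equal(count_snp_density(r2), 20)

  # gap-only variation is not polymorphism
  r3 <- rows
  substr(r3[["c"]], 10, 10) <- "-"
  substr(r3[["d"]], 20, 20) <- "N"
  expect_equal(count_snp_density(r3), 0)

  expect_error(count_snp_density(setNames("", "a")), "zero-length")
})

test_that("locus filters apply the documented boundary semantics", {
  set.seed(206)
  mk_cand <- function(ex_len, n_poly, sp = c("A", "B", "C")) {
    len <- sum(ex_len)
    base <- strsplit(rand_seq(len), "")[[1L]]
    rows <- lapply(seq_along(sp), function(i) base)
    for (i in seq_len(n_poly)) {
      rows[[1L]][i] <- setdiff(c("A", "C", "G", "T"), rows[[1L]][i])[1L]
    }
    aln <- setNames(vapply(rows, paste, "", collapse = ""), sp)
    ends <- cumsum(ex_len)
    list(locus_id = "L", group = mk_group(aln), alignment = aln,
         exon_map = data.frame(start = c(0L, ends[-length(ends)]),
                               end = ends),
         exon_presence = matrix(TRUE, length(sp), length(ex_len),
                                dimnames = list(sp, NULL)),
         snp_density = NA_real_, verdict = "unfiltered",
         reasons = character(0))
  }
  params <- selection_params()

  # 79 bp internal exon disqualifies; density kept high (100 SNPs / 399 bp)
  res <- apply_locus_filters(list(mk_cand(c(120, 79, 200), 100)), params)
  expect_length(res$kept, 0L)
  expect_equal(res$rejected[[1L]]$reasons, "short_internal_exon")

  # 79 bp terminal exon is tolerated (mid-locus rule)
  res <- apply_locus_filters(list(mk_cand(c(79, 200), 60)), params)
  expect_length(res$kept, 1L)

  # density boundary is strict: 19/1000 kb fails, 20/1000 passes
  res <- apply_locus_filters(list(mk_cand(c(500, 500), 19),
                                  mk_cand(c(500, 500), 20)), params)
  expect_equal(res$rejected[[1L]]$reasons, "low_snp_density")
  expect_equal(res$rejected[[1L]]$snp_density, 19)
  expect_length(res$kept, 1L)
  expect_equal(res$kept[[1L]]$snp_density, 20)

  # presence rule counts focal species only
  res <- apply_locus_filters(list(mk_cand(c(500, 500), 60, sp = c("A", "B"))),
                             selection_params(focal_species = c("A", "B", "C")))
  expect_equal(res$rejected[[1L]]$reasons, "absent_species")
})

test_that("filters agree with the brute-force oracle on random candidates", {
  params <- selection_params(focal_species = c("SpA", "SpB", "SpC"))
  for (seed in 1:3) {
    set.seed(300 + seed)
    cands <- lapply(sprintf("L%03d", 1:40), make_random_candidate)
    res <- apply_locus_filters(cands, params)
    got <- setNames(vapply(c(res$kept, res$rejected), function(c)
      paste(sort(c$reasons), collapse = ","), ""),
      vapply(c(res$kept, res$rejected), `[[`, "", "locus_id"))
    want <- setNames(vapply(cands, function(c)
      paste(oracle_filter(c, params), collapse = ","), ""),
      vapply(cands, `[[`, "", "locus_id"))
    expect_equal(got[names(want)], want)
  }
})
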