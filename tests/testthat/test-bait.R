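test_that("exon tiling follows the ladder-plus-flush rule", {
  expect_identical(tile_exon(80), 0L)
  expect_identical(tile_exon(107), c(0L, 27L))
  expect_identical(tile_exon(160), c(0L, 27L, 54L, 80L))
  expect_identical(tile_exon(79), integer(0))

  # every exon position covered by at least one bait, flush bait present
  for (E in c(80L, 81L, 107L, 133L, 160L, 500L, 2000L)) {
    starts <- tile_exon(E)
    cov <- integer(E)
    for (s in starts) cov[(s + 1):(s + 80)] <- cov[(s + 1):(s + 80)] + 1L
    expect_true(all(cov >= 1L), info = paste("E =", E))
    expect_equal(max(starts), E - 80L)
  }
})

test_that("GC and Tm follow the long-oligo formulas and reject ambiguity", {
  gc80 <- strrep("GC", 40)
  expect_equal(compute_gc(gc80), 100)
  expect_equal(compute_tm(gc80), 81.5 + 0.41 * 100 - 675 / 80)  # 114.0625
  half <- paste0(strrep("GC", 20), strrep("AT", 20))
  expect_equal(compute_gc(half), 50)
  expect_equal(compute_tm(half), 81.5 + 0.41 * 50 - 675 / 80)
  expect_error(compute_gc("ACGTN"), "ambiguity")
  expect_error(compute_tm(paste0(strrep("A", 79), "N")), "ambiguity")
})

test_that("blacklist screen is k-mer exact and strand-insensitive", {
  set.seed(401)
  plastome <- rand_seq(3000)
  idx <- blacklist_index(c(pl = plastome), k = 24)

  hit <- paste0(rand_seq(30), substr(plastome, 100, 123), rand_seq(26))
  expect_false(screen_blacklist(hit, idx, k = 24))

  rc_hit <- paste0(rand_seq(30), revcomp(substr(plastome, 100, 123)),
                   rand_seq(26))
  expect_false(screen_blacklist(rc_hit, idx, k = 24))

  expect_true(screen_blacklist(rand_seq(80), idx, k = 24))
  expect_error(screen_blacklist(rand_seq(20), idx, k = 24), "exceeds")
})

test_that("low-complexity detection is a period-bounded span rule", {
  params <- design_params()
  expect_true(is_low_complexity(strrep("AT", 40), params))
  # 47-base period-3 repeat inside an 80-mer: span below the 48-base cutoff
  set.seed(402)
  rep47 <- substr(strrep("ACG", 16), 1, 47)
  seq47 <- paste0("TTGAC", rep47, substr(rand_seq(40), 1, 28))
  expect_equal(nchar(seq47), 80L)
  expect_false(is_low_complexity(seq47, params))
  # one base more crosses the boundary
  rep48 <- substr(strrep("ACG", 16), 1, 48)
  expect_true(is_low_complexity(paste0("TTGAC", rep48,
                                       substr(rand_seq(40), 1, 27)), params))
})

test_that("dedupe drops redundant baits per the overlap-identity rule", {
  set.seed(403)
  a <- rand_seq(80)
  expect_equal(length(dedupe_baits(c(a, a))$kept), 1L)

  # identical over a 67-base overlap at offset 13: redundant (67/80 >= 0.83)
  b67 <- paste0(substr(a, 14, 80), rand_seq(13))
  expect_true(oracle_redundant(a, b67))
  dd <- dedupe_baits(c(a, b67))
  expect_equal(dd$kept, a)
  expect_equal(dd$dropped, b67)

  # 66-base overlap only: below coverage, both kept
  b66 <- paste0(substr(a, 15, 80), rand_seq(14))
  expect_false(oracle_redundant(a, b66))
  expect_equal(length(dedupe_baits(c(a, b66))$kept), 2L)
})

test_that("greedy dedupe output never violates the exhaustive oracle", {
  set.seed(404)
  originals <- vapply(rep(80, 60), rand_seq, "")
  planted <- vapply(sample(60, 15), function(j) {
    off <- sample(0:13, 1L)
    core <- substr(originals[j], off + 1, 80)
    s <- paste0(core, rand_seq(off))
    if (runif(1) < 0.5) {  # one mismatch still exceeds 0.95 identity
      i <- sample(nchar(core), 1L)
      substr(s, i, i) <- setdiff(c("A", "C", "G", "T"),
                                 substr(s, i, i))[1L]
    }
    s
  }, "")
  pool <- c(originals, planted)
  dd <- dedupe_baits(pool)
  # every planted duplicate is gone
  expect_true(all(planted %in% dd$dropped))
  # no kept pair is redundant under the brute-force all-offsets oracle
  kept <- dd$kept
  for (i in seq_along(kept)) {
    for (j in seq_len(i - 1L)) {
      expect_false(oracle_redundant(kept[i], kept[j]),
                   info = paste("pair", i, j))
    }
  }
})

test_that("build_panel tiles exons, screens baits and records drops", {
  set.seed(405)
  exon <- rand_seq(160)
  cand <- list(locus_id = "L1",
               group = list(members = list(SpA = exon)),
               alignment = c(SpA = exon),
               exon_map = data.frame(start = 0L, end = 160L),
               exon_presence = matrix(TRUE, 1, 1,
                                      dimnames = list("SpA", NULL)),
               snp_density = 50, verdict = "pass", reasons = character(0))
  panel <- build_panel(list(L1 = cand))
  expect_equal(nrow(panel$baits), 4L)
  expect_equal(panel$baits$start, c(0L, 27L, 54L, 80L))
  expect_equal(panel$exon_depth$avg_depth, 4 * 80 / 160)

  # blacklisting one tiled bait leaves 3 and a ledger entry
  bl <- substr(exon, 30, 53)  # 24-mer inside bait at start 0 and 27
  panel2 <- build_panel(list(L1 = cand), blacklist = c(b = bl))
  expect_equal(nrow(panel2$baits), 2L)
  expect_equal(unique(panel2$dropped$drop_reason), "blacklist")

  # two species with identical sequence collapse in dedupe
  cand2 <- cand
  cand2$alignment <- c(SpA = exon, SpB = exon)
  cand2$exon_presence <- matrix(TRUE, 2, 1,
                                dimnames = list(c("SpA", "SpB"), NULL))
  panel3 <- build_panel(list(L1 = cand2))
  expect_equal(nrow(panel3$baits), 4L)
  expect_true(all(panel3$dropped$drop_reason == "redundant"))
  expect_equal(nrow(panel3$dropped), 4L)
})

test_that("panel construction is deterministic", {
  set.seed(406)
  exons <- vapply(c(200, 340), rand_seq, "")
  mk <- function(locus, seqs) {
    ends <- cumsum(nchar(seqs))
    aln <- setNames(rep(paste(seqs, collapse = ""), 2), c("SpA", "SpB"))
    list(locus_id = locus, group = list(members = as.list(aln)),
         alignment = aln,
         exon_map = data.frame(start = c(0L, ends[-length(ends)]),
                               end = ends),
         exon_presence = matrix(TRUE, 2, length(seqs),
                                dimnames = list(c("SpA", "SpB"), NULL)),
         snp_density = 50, verdict = "pass", reasons = character(0))
  }
  loci <- list(L1 = mk("L1", exons[1]), L2 = mk("L2", exons))
  p1 <- build_panel(loci)
  p2 <- build_panel(rev(loci))
  expect_equal(p1$baits, p2$baits)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_bait_fasta(p1, f1); write_bait_fasta(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
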