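test_that("the pseudo-mapper assigns reads by seed and ungapped identity", {
  set.seed(501)
  t1 <- rand_seq(900); t2 <- rand_seq(700)
  targets <- c(`SpA-L1` = t1, `SpA-L2` = t2)

  reads <- c(r1 = substr(t1, 101, 250),          # exact substring
             r2 = revcomp(substr(t2, 51, 200)),  # minus strand
             r3 = rand_seq(150))                 # background, no 31-mer
  mp <- map_reads(reads, targets)
  expect_equal(mp$reads_mapped, 2L)
  expect_equal(mp$assignments$ref[mp$assignments$read_id == "r1"], "SpA-L1")
  expect_equal(mp$assignments$ref[mp$assignments$read_id == "r2"], "SpA-L2")
  expect_false("r3" %in% mp$assignments$read_id)
  expect_error(map_reads(c(r = "ACGT"), targets), "shorter than the seed")
})

test_that("ties across same-locus references count once, max rule holds", {
  set.seed(502)
  t1 <- rand_seq(600)
  targets <- c(`SpA-L1` = t1, `SpB-L1` = t1)  # duplicated reference
  reads <- setNames(vapply(1:5, function(i)
    substr(t1, i * 50, i * 50 + 149), ""), paste0("r", 1:5))
  mp <- map_reads(reads, targets)
  expect_equal(mp$reads_mapped, 5L)
  expect_equal(sum(mp$per_ref$count), 5L)            # each read counted once
  expect_equal(mp$per_ref$count[mp$per_ref$ref == "SpA-L1"], 5L)
  lc <- mp$locus_counts
  expect_equal(lc$count[lc$locus == "L1"], 5L)       # max across references
})

test_that("on-target percentage reproduces the published per-sample rows", {
  expect_equal(pct_on_target(4880245, 10785948), 45.2)
  expect_equal(pct_on_target(454810, 3050140), 14.9)
  expect_equal(pct_on_target(2318089, 3876389), 59.8)
  expect_equal(pct_on_target(0, 1000), 0)
  expect_error(pct_on_target(1, 0), "positive")
})

test_that("locus coverage is reads x read length over reference length", {
  expect_equal(locus_coverage(1000, 300, 3000), 100)
  expect_equal(locus_coverage(0, 300, 3000), 0)
  expect_equal(locus_coverage(10, 150, 1500), 1)
  expect_error(locus_coverage(10, 150, 0), "zero reference")
})

test_that("recovery statistics and matrix follow the length accounting", {
  set.seed(503)
  targets <- c(`SpA-L1` = rand_seq(600), `SpA-L2` = rand_seq(400))
  asm <- list(s1 = c(L1 = rand_seq(600), L2 = rand_seq(200)),
              s2 = c(L1 = rand_seq(300)))
  rec <- recovery_stats(asm, targets)
  s1 <- rec$stats[rec$stats$sample == "s1", ]
  expect_equal(s1$total_assembled_target_len, 800)
  expect_equal(s1$pct_target_recovered, 80)
  expect_equal(s1$loci_with_sequence, 2L)
  expect_equal(unname(rec$matrix[, "s1"]), c(1.0, 0.5))
  # missing locus gives a zero entry and a lower locus count
  expect_equal(unname(rec$matrix["L2", "s2"]), 0)
  expect_equal(rec$stats$loci_with_sequence[rec$stats$sample == "s2"], 1L)
  # conservation: matrix column total equals the assembled length total
  expect_equal(sum(rec$matrix[, "s1"] *
                     vapply(split(nchar(targets),
                                  sub("^.*-", "", names(targets))), max, 0)),
               s1$total_assembled_target_len)

  # over-length assemblies are retained above 1 and flagged
  asm$s1[["L2"]] <- rand_seq(440)
  rec2 <- recovery_stats(asm, targets)
  expect_equal(unname(rec2$matrix["L2", "s1"]), 1.1)
  expect_equal(rec2$over_reference$locus, "L2")

  expect_error(recovery_stats(list(s1 = c(LX = 100)), targets),
               "unknown locus")
})

test_that("paralog flags require two contigs above the coverage floor", {
  ref <- c(L1 = 1000)
  expect_equal(nrow(flag_paralogs(list(s = list(L1 = c(900, 860))), ref)), 1L)
  expect_equal(nrow(flag_paralogs(list(s = list(L1 = c(900, 800))), ref)), 0L)
  expect_equal(nrow(flag_paralogs(list(s = list(L1 = 1000)), ref)), 0L)
  fl <- flag_paralogs(list(s = list(L1 = c(900, 850, 880))), ref)
  expect_equal(fl$n_competing, 3L)
})

test_that("group summaries average the bundled per-sample statistics", {
  tab <- capture_stats_table()
  aloe <- tab[tab$group == "Aloe", ]
  expect_equal(nrow(aloe), 23L)
  s <- summarize_samples(aloe, "Average genus Aloe")
  expect_equal(s$reads_after_trimming, 2712317)
  expect_equal(s$reads_mapped, 1407498)

  # a one-sample group summarises to itself
  one <- summarize_samples(aloe[3, ], "solo")
  expect_equal(one$reads_after_trimming, aloe$reads_after_trimming[3])

  # sample order does not matter
  s2 <- summarize_samples(aloe[sample(nrow(aloe)), ], "Average genus Aloe")
  expect_equal(s, s2)
  expect_error(summarize_samples(aloe[0, ]), "empty")
})

test_that("per-sample stats combine mapping and recovery consistently", {
  set.seed(504)
  t1 <- rand_seq(600)
  targets <- c(`SpA-L1` = t1)
  reads <- c(r1 = substr(t1, 1, 150), r2 = substr(t1, 200, 349),
             r3 = rand_seq(150), r4 = rand_seq(150))
  mp <- map_reads(reads, targets)
  rec <- recovery_stats(list(s1 = c(L1 = substr(t1, 1, 450))), targets)
  st <- sample_capture_stats(mp, rec, "s1", read_len = 150)
  expect_equal(st$reads_after_trimming, 4L)
  expect_equal(st$reads_mapped, 2L)
  expect_equal(st$pct_on_target, 50)
  expect_equal(st$pct_target_recovered, 75)
  cov <- attr(st, "coverage")
  expect_equal(unname(cov["L1"]), 2 * 150 / 600)
})
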