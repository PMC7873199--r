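test_that("Phred conversion is exact on decade scores and rejects negatives", {
  expect_equal(phred_to_prob(20), 0.01)
  expect_equal(phred_to_prob(0), 1.0)
  expect_equal(phred_to_prob(30), 0.001)
  for (k in 1:6) expect_equal(phred_to_prob(10 * k), 10^(-k))
  expect_error(phred_to_prob(-1), ">= 0")
})

test_that("an empty alignment file yields zero counts", {
  bam <- make_fixture_bam(reads_in_target(0))
  expect_equal(count_reads(bam, toy_locus()$target_intervals[[1]]), 0L)
})

test_that("MAPQ filtering drops exactly the low-quality records", {
  reads <- reads_in_target(100)
  reads$mapq[1:5] <- 10L
  bam <- make_fixture_bam(reads)
  iv <- toy_locus()$target_intervals[[1]]
  expect_equal(count_reads(bam, iv, mapq_min = 20L), 95L)
  expect_equal(count_reads(bam, iv, mapq_min = 0L), 100L)
  # monotone in the threshold
  counts <- vapply(c(0L, 5L, 10L, 11L, 60L, 61L),
                   function(q) count_reads(bam, iv, mapq_min = q), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a single base of overlap is enough to count a record", {
  # target starts at 0-based 10000 (first covered base 1-based 10001);
  # a 100M read at pos 9902 spans 9902..10001: 1 bp of overlap
  bam <- make_fixture_bam(data.frame(pos = 9902L, mapq = 60L))
  iv <- toy_locus()$target_intervals[[1]]
  expect_equal(count_reads(bam, iv, mapq_min = 0L), 1L)
  # one base earlier: no overlap
  bam2 <- make_fixture_bam(data.frame(pos = 9901L, mapq = 60L))
  expect_equal(count_reads(bam2, iv, mapq_min = 0L), 0L)
})

test_that("ranged counting equals a naive full-file record scan", {
  set.seed(42)
  reads <- data.frame(pos = sample(5000:95000, 300, replace = TRUE),
                      mapq = sample(c(0L, 10L, 30L, 60L), 300, replace = TRUE))
  reads <- reads[order(reads$pos), ]
  bam <- make_fixture_bam(reads)
  loc <- toy_locus()
  for (iv in c(loc$target_intervals, loc$reference_intervals))
    for (q in c(0L, 20L))
      expect_equal(count_reads(bam, iv, mapq_min = q), naive_count(bam, iv, q))
})

test_that("locus counts conserve per-interval sums and compute densities", {
  # three disjoint target units, counts 200/200/200
  loc <- locus_region_def(
    "TOY3",
    target_intervals = list(genomic_interval("amytoy", 10000, 30000),
                            genomic_interval("amytoy", 32000, 52000),
                            genomic_interval("amytoy", 54000, 74000)),
    unit_length = 20000,
    reference_intervals = list(genomic_interval("amytoy", 76000, 96000)))
  reads <- data.frame(pos = c(seq(10500, 29000, length.out = 200),
                              seq(32500, 51000, length.out = 200),
                              seq(54500, 73000, length.out = 200),
                              seq(76500, 95000, length.out = 300)),
                      mapq = 60L)
  bam <- make_fixture_bam(reads)
  cr <- locus_counts(bam, loc, "s1")
  expect_equal(cr$target_count, 600L)
  expect_equal(cr$reference_count, 300L)
  expect_equal(cr$target_density, 600 / 20000)
  expect_equal(cr$reference_density, 300 / 20000)
  per_iv <- vapply(loc$target_intervals, function(iv)
    count_reads(bam, iv), integer(1))
  expect_equal(sum(per_iv), cr$target_count)
})

test_that("zero reference coverage is a hard error, not a silent zero", {
  bam <- make_fixture_bam(reads_in_target(10))
  expect_error(locus_counts(bam, toy_locus(), "s1"), "reference coverage absent")
})

test_that("alignability fractions follow the XA/SA tag composition", {
  reads <- reads_in_target(10)
  reads$xa[1:3] <- TRUE
  bam <- make_fixture_bam(reads)
  rep1 <- alignability_report(bam, toy_locus(), sample_id = "s1")
  expect_equal(rep1$frac_properly_paired_unique, 0.7)
  expect_equal(rep1$mapping_error_prob_bound, 0.01)
  expect_true(rep1$defined)
  # all proper, untagged reads -> 1.0
  bam2 <- make_fixture_bam(reads_in_target(10))
  expect_equal(alignability_report(bam2, toy_locus())$frac_properly_paired_unique, 1)
  # MAPQ fraction is strict '>'
  reads3 <- reads_in_target(10, mapq = c(rep(60L, 6), rep(20L, 4)))
  bam3 <- make_fixture_bam(reads3)
  expect_equal(alignability_report(bam3, toy_locus())$frac_mapq_gt_threshold, 0.6)
})

test_that("zero properly paired reads is flagged, not reported as 0", {
  # unpaired records only (flag 0)
  bam <- make_fixture_bam(reads_in_target(5, flag = 0L))
  expect_warning(rep0 <- alignability_report(bam, toy_locus()), "undefined")
  expect_false(rep0$defined)
  expect_true(is.na(rep0$frac_properly_paired_unique))
})

test_that("missing index, unknown chromosome and out-of-range intervals error", {
  bam <- make_fixture_bam(reads_in_target(5))
  file.remove(paste0(bam, ".bai"))
  expect_error(count_reads(bam, toy_locus()$target_intervals[[1]]), "index")
  bam2 <- make_fixture_bam(reads_in_target(5))
  expect_error(count_reads(bam2, genomic_interval("chrX", 0, 100)), "chrX")
  expect_error(count_reads(bam2, genomic_interval("amytoy", 0, 2e6)),
               "exceeds reference length")
})
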