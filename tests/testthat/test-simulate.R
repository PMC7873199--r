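test_that("cohort generation is a pure function of the seed", {
  cfg <- sim_config(seed = 81, n_samples = 200)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(a$samples, b$samples)
  expect_equal(as.matrix(a$kinship), as.matrix(b$kinship))
  expect_identical(simulate_cn(cfg, a), simulate_cn(cfg, b))
  expect_identical(simulate_phenotypes(a, simulate_cn(cfg, a), cfg),
                   simulate_phenotypes(b, simulate_cn(cfg, b), cfg))
  d1 <- simulate_ddpcr(1:5, seed = 81); d2 <- simulate_ddpcr(1:5, seed = 81)
  expect_identical(d1, d2)
  g1 <- simulate_genotype_matrix(seed = 81); g2 <- simulate_genotype_matrix(seed = 81)
  expect_identical(g1$G$dosages, g2$G$dosages)
})

test_that("pedigree families carry the expected kinship pattern", {
  cfg <- sim_config(seed = 82, n_samples = 20, family_children = 2)
  co <- simulate_cohort(cfg)
  K <- as.matrix(co$kinship)
  s <- co$samples
  sibs <- which(s$family_id == "F0001" & !is.na(s$father))
  expect_equal(K[sibs[1], sibs[2]], 0.25)
  expect_equal(K[sibs[1], which(s$sample_id == s$father[sibs[1]])], 0.25)
  # across families: zero
  expect_equal(K[1, 5], 0)
  # singleton cohort: diagonal kinship
  cfg0 <- sim_config(seed = 82, n_samples = 10, family_children = 0)
  K0 <- as.matrix(simulate_cohort(cfg0)$kinship)
  expect_equal(K0, diag(0.5, 10), ignore_attr = TRUE)
})

test_that("ages are truncated and sexes balanced", {
  cfg <- sim_config(seed = 83, n_samples = 2000)
  s <- simulate_cohort(cfg)$samples
  expect_true(all(s$age >= 18 & s$age <= 80))
  expect_lt(abs(mean(s$age) - 39.11), 1.5)
  expect_lt(abs(mean(s$sex) - 0.5), 0.05)
})

test_that("haplotype tables reproduce the target diploid means and parity", {
  tabs <- haplotype_tables()
  means <- vapply(tabs, function(t)
    c(amy1 = 2 * sum(t$amy1 * t$frequency),
      amy2a = 2 * sum(t$amy2a * t$frequency)), numeric(2))
  expect_equal(means["amy1", "Arab"], 6.92, tolerance = 1e-10)
  expect_equal(means["amy1", "Persian"], 7.60, tolerance = 1e-10)
  expect_equal(means["amy2a", "Arab"], 2.06, tolerance = 1e-10)
  expect_equal(means["amy2a", "Persian"], 2.27, tolerance = 1e-10)
  # haplotype-level parity coupling
  for (t in tabs) expect_true(all(t$amy1 %% 2 == t$amy2a %% 2))
})

test_that("simulated diploid CNs match the table expectation", {
  # large single-group draw: diploid mean within Monte-Carlo error of 6.92
  cfg <- sim_config(seed = 84, n_samples = 20000, family_children = 0,
                    ancestry_props = c(Arab = 1))
  co <- simulate_cohort(cfg)
  cn <- simulate_cn(cfg, co)
  expect_lt(abs(mean(cn$amy1) - 6.92), 0.05)
  expect_lt(abs(mean(cn$amy2a) - 2.06), 0.02)
  expect_true(all(cn$amy1 %% 2 == cn$amy2a %% 2))
  # children's diploid CN is a sum of inherited parental haplotypes:
  # within a family, each child's CN never exceeds the parental haplotype sums
  cfgf <- sim_config(seed = 85, n_samples = 50)
  cof <- simulate_cohort(cfgf)
  cnf <- simulate_cn(cfgf, cof)
  kids <- !is.na(cof$samples$father)
  expect_true(all(cnf$amy1[kids] <=
                    cnf$amy1[match(cof$samples$father[kids], cnf$sample_id)] +
                    cnf$amy1[match(cof$samples$mother[kids], cnf$sample_id)]))
})

test_that("coverage counts follow the Poisson expectations", {
  loc <- amylase_regions()$AMY1
  expect_equal(simulate_counts(2, loc, depth = 1e-12, seed = 85)$target_count, 0)
  cr <- simulate_counts(rep(6, 10000), loc, depth = 0.15, seed = 85)
  expect_lt(abs(mean(raw_cn(cr)$raw_cn) - 6), 0.01)
  # shared overdispersion cancels in the ratio
  cr_od <- simulate_counts(rep(6, 5000), loc, depth = 0.15,
                           overdispersion = 0.3, seed = 86)
  expect_lt(abs(mean(raw_cn(cr_od)$raw_cn) - 6), 0.05)
})

test_that("null CN effect leaves trait and CN uncorrelated", {
  cfg <- sim_config(seed = 87, n_samples = 3000, beta_cn = 0)
  co <- simulate_cohort(cfg)
  cn <- simulate_cn(cfg, co)
  ph <- simulate_phenotypes(co, cn, cfg)
  expect_lt(abs(cor(ph$trait, cn$amy1)), 0.05)
})

test_that("phenotype variance decomposes to the target heritability", {
  cfg <- sim_config(seed = 88, n_samples = 3000, h2 = 0.3, beta_cn = 0,
                    beta_sex = 0, beta_age = 0)
  co <- simulate_cohort(cfg)
  cn <- simulate_cn(cfg, co)
  ph <- simulate_phenotypes(co, cn, cfg)
  expect_lt(abs(var(ph$trait) - 1), 0.08)
})

test_that("restraint prevalence hits the per-ancestry targets", {
  cfg <- sim_config(seed = 89, n_samples = 10000)
  co <- simulate_cohort(cfg)
  cn <- simulate_cn(cfg, co)
  ph <- simulate_phenotypes(co, cn, cfg)
  ow <- ph$bmi >= 25
  prev <- tapply(ph$restraint[ow], ph$ancestry[ow], mean, na.rm = TRUE)
  expect_lt(abs(prev[["Arab"]] - 0.54), 0.02)
  expect_lt(abs(prev[["Persian"]] - 0.60), 0.02)
  # restraint undefined below the overweight cut
  expect_true(all(is.na(ph$restraint[!ow])))
})

test_that("genotype simulation realises its divergence target", {
  sim <- simulate_genotype_matrix(c(A = 100, B = 100), m = 5000, fst = 0.05,
                                  seed = 90)
  expect_lt(abs(fst_estimate(sim$G, sim$labels) - 0.05), 0.01)
  sim0 <- simulate_genotype_matrix(c(A = 100, B = 100), m = 2000, fst = 0,
                                   seed = 91)
  expect_lt(abs(fst_estimate(sim0$G, sim0$labels)), 0.005)
})

test_that("alignment fixtures round-trip through the counting layer", {
  pre <- tempfile("rt")
  fix <- simulate_bam_fixture(6, pre, depth = 0.005, seed = 92)
  loc <- toy_locus()
  got_t <- sum(vapply(loc$target_intervals, function(iv)
    count_reads(fix$bam, iv), integer(1)))
  expect_equal(got_t, fix$counts$target_count)
  got_r <- sum(vapply(loc$reference_intervals, function(iv)
    count_reads(fix$bam, iv), integer(1)))
  expect_equal(got_r, fix$counts$reference_count)
  # calling the fixture recovers the truth
  cr <- locus_counts(fix$bam, loc, "fx")
  expect_equal(round(raw_cn(cr)$raw_cn / 2) * 2, 6)
  # XA tagging drives the alignability fraction
  fix2 <- simulate_bam_fixture(2, tempfile("rt2"), depth = 0.005,
                               frac_xa = 0.3, seed = 93)
  rep2 <- alignability_report(fix2$bam, loc)
  expect_lt(abs(rep2$frac_properly_paired_unique - 0.7), 0.12)
  # byte-identical replay
  fa <- simulate_bam_fixture(4, tempfile("ra"), seed = 94)
  fb <- simulate_bam_fixture(4, tempfile("rb"), seed = 94)
  sa <- Rsamtools::scanBam(fa$bam)[[1]]
  sb <- Rsamtools::scanBam(fb$bam)[[1]]
  expect_identical(sa$pos, sb$pos)
  expect_identical(sa$mapq, sb$mapq)
})
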