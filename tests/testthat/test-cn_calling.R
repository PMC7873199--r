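test_that("raw CN is the scaled density ratio", {
  cr <- count_record("s1", "AMY1", 600, 1200, 20000, 40000)
  expect_equal(raw_cn(cr)$raw_cn, 2)        # equal densities -> diploid
  cr2 <- count_record("s1", "AMY1", 1800, 1200, 20000, 40000)
  expect_equal(raw_cn(cr2)$raw_cn, 6)       # 3x density ratio -> 6 copies
  expect_equal(raw_cn(cr2, scale = 1)$raw_cn, 3)
})

test_that("raw CN is invariant to doubling all counts", {
  cr <- count_record("s1", "AMY1", 731, 1207, 20000, 20010)
  cr2 <- count_record("s1", "AMY1", 2 * 731, 2 * 1207, 20000, 20010)
  expect_equal(raw_cn(cr)$raw_cn, raw_cn(cr2)$raw_cn)
})

test_that("conditional rounding matches AMY2A parity, with ties upward", {
  expect_equal(conditional_round(7.4, 2.1)[, c("amy1", "amy2a")],
               data.frame(amy1 = 8L, amy2a = 2L))
  expect_equal(conditional_round(7.4, 3.0)[, c("amy1", "amy2a")],
               data.frame(amy1 = 7L, amy2a = 3L))
  # 7.0 equidistant between 6 and 8 under even parity -> ties-up rule
  expect_equal(conditional_round(7.0, 1.9)[, c("amy1", "amy2a")],
               data.frame(amy1 = 8L, amy2a = 2L))
  # AMY2A half-up rounding
  expect_equal(conditional_round(4.0, 2.5)$amy2a, 3L)
})

test_that("parity consistency and rounding-distance bounds hold on random input", {
  set.seed(7)
  raw1 <- runif(20000, 0, 25)
  raw2 <- runif(20000, 0, 6)
  g <- conditional_round(raw1, raw2)
  expect_true(all(g$parity_consistent))
  expect_true(all(g$amy1 %% 2 == g$amy2a %% 2))
  expect_true(all(abs(g$amy1 - raw1) <= 1))
  expect_true(all(abs(g$amy2a - raw2) <= 0.5))
  expect_true(all(g$amy1 >= 0))
})

test_that("genotype calling reshapes counts and preserves raw estimates", {
  counts <- rbind(
    count_record("s1", "AMY1", 740, 400, 20000, 20000),  # raw 3.7
    count_record("s1", "AMY2A", 412, 824, 8240, 16480),  # raw 2.0
    count_record("s2", "AMY1", 1480, 400, 20000, 20000), # raw 7.4
    count_record("s2", "AMY2A", 618, 824, 8240, 16480))  # raw 3.0
  g <- call_genotypes(counts)
  expect_equal(g$amy1, c(4L, 7L))
  expect_equal(g$amy2a, c(2L, 3L))
  expect_equal(g$raw_amy1, c(3.7, 7.4))
  expect_true(all(g$parity_consistent))
})

test_that("AMY2A/AMY2B concordance summary counts discordant patterns", {
  g_all_eq <- data.frame(amy2a = rep(2L, 10), amy2b = rep(2L, 10))
  s <- amy2b_concordance(g_all_eq)
  expect_equal(s$frac_equal, 1)
  expect_false(s$discordant_defined)
  expect_true(is.na(s$frac_discordant_amy2b_two))

  g_mix <- data.frame(amy2a = c(rep(2L, 9), 3L), amy2b = rep(2L, 10))
  s2 <- amy2b_concordance(g_mix)
  expect_equal(s2$frac_equal, 0.9)
  expect_equal(s2$frac_discordant_amy2b_two, 1)
  expect_error(amy2b_concordance(data.frame()), "empty")
})

test_that("association filter removes AMY1 zero and winsorises above the cap", {
  g <- data.frame(sample_id = c("a", "b", "c"), amy1 = c(0L, 7L, 16L))
  f <- filter_for_association(g)
  expect_equal(f$amy1, c(7L, 14L))
  expect_equal(attr(f, "filter_report"), list(removed = 1L, capped = 1L))
  # identity on in-range values
  g2 <- data.frame(amy1 = 2:14)
  expect_equal(filter_for_association(g2)$amy1, 2:14)
  # parameterised cap
  g3 <- data.frame(amy1 = c(11L, 12L))
  expect_equal(filter_for_association(g3, cap = 10)$amy1, c(10L, 10L))
})

test_that("simulated 30x coverage recovers raw CN within sampling error", {
  loc <- amylase_regions()$AMY1
  cr <- simulate_counts(rep(6, 500), loc, depth = 0.15, seed = 21)
  r <- raw_cn(cr)$raw_cn
  # analytic SE of the density ratio at CN 6
  lam_t <- 6 * 0.15 * 20000
  lam_r <- 2 * 0.15 * reference_length(loc)
  se <- 6 * sqrt(1 / lam_t + 1 / lam_r)
  expect_lt(abs(mean(r) - 6), 2 * se / sqrt(500))
  # CN 2: target density tracks reference density
  cr2 <- simulate_counts(rep(2, 500), loc, depth = 0.15, seed = 22)
  expect_lt(abs(mean(cr2$target_density / cr2$reference_density) - 1), 0.01)
})
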