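test_that("Bonferroni threshold divides alpha by the test count", {
  expect_equal(bonferroni_threshold(0.05, 3, 2), 0.05 / 6)
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 2, 5), 0.001)
  expect_error(bonferroni_threshold(0.05, 0, 2), "positive")
})

test_that("BMI dichotomisation keeps obesity cases and lean controls", {
  expect_equal(dichotomize_bmi(c(31, 24, 27)), c(1L, 0L, NA))
  expect_equal(dichotomize_bmi(c(30, 25, NA)), c(1L, NA, NA))
})

test_that("logistic OR converges to 1 under independence", {
  set.seed(20)
  n <- 5000
  cn <- sample(2:14, n, replace = TRUE)
  y <- rbinom(n, 1, 0.4)
  f <- logistic_fit(y, cn)
  expect_lt(abs(log(f$or)), 0.05)
  expect_true(f$ci[1] < 1 && f$ci[2] > 1)
  expect_error(logistic_fit(rep(1, 10), rnorm(10)), "classes")
})

test_that("logistic separation raises an informative error", {
  y <- c(rep(0, 20), rep(1, 20))
  x <- c(rnorm(20, -5), rnorm(20, 5))
  expect_error(logistic_fit(y, x), "separation")
})

test_that("per-copy odds ratio is recovered from the simulator truth", {
  set.seed(21)
  ors <- replicate(100, {
    n <- 950
    cn <- sample(2:14, n, replace = TRUE,
                 prob = dpois(0:12, 5))
    p <- plogis(qlogis(0.41) + log(0.93) * (cn - mean(cn)))
    logistic_fit(rbinom(n, 1, p), cn)$or
  })
  expect_gt(mean(ors), 0.91)
  expect_lt(mean(ors), 0.95)
})

test_that("rank-sum p matches exact enumeration on a tiny example", {
  # all 3-subsets of ranks 1..6: only the observed split is as extreme,
  # on either side -> two-sided p = 2 / choose(6, 3) = 0.1
  g1 <- c(1, 2, 3); g2 <- c(11, 12, 13)
  combs <- combn(6, 3)
  rank_sums <- colSums(matrix(seq_len(6)[combs], nrow = 3))
  obs <- sum(1:3)
  p_exact <- mean(rank_sums <= obs | rank_sums >= sum(4:6) + (obs - sum(1:3)))
  expect_equal(p_exact, 0.1)
  res <- group_tests(c(g1, g2), rep(c("a", "b"), each = 3))
  expect_equal(res$test, "wilcoxon")
  expect_equal(res$p, 0.1)
})

test_that("identical groups give the boundary p of 1", {
  res <- group_tests(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$p, 1)
  expect_error(group_tests(1:5, rep("a", 5)), "two non-empty groups")
})

test_that("rank-sum p-values are uniform under the null", {
  set.seed(22)
  ps <- replicate(500, {
    x <- rnorm(80)
    group_tests(x, rep(c("a", "b"), each = 40))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("categorical variables go through the chi-square path", {
  set.seed(23)
  x <- sample(c("yes", "no"), 200, replace = TRUE)
  g <- rep(c("a", "b"), each = 100)
  res <- group_tests(x, g)
  expect_equal(res$test, "chisq")
  expect_true(res$p > 0 && res$p <= 1)
})

test_that("the association driver produces a full trait-by-predictor table", {
  cfg <- sim_config(seed = 24, n_samples = 400)
  co <- simulate_cohort(cfg)
  cn <- simulate_cn(cfg, co)
  ph <- simulate_phenotypes(co, cn, cfg)
  geno <- filter_for_association(
    data.frame(sample_id = cn$sample_id, amy1 = cn$amy1, amy2a = cn$amy2a))
  res <- associate_cn(geno, ph, as.matrix(co$kinship),
                      traits = c("trait", "bmi"), covars = c("sex", "age"))
  expect_equal(nrow(res), 4L)
  expect_setequal(unique(res$predictor), c("amy1", "amy2a"))
  expect_true(all(res$se > 0))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$n <= 400))
})
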