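test_that("window counts reproduce the cohort-size arithmetic", {
  expect_equal(length(sliding_windows(1518)), 10L)
  expect_equal(length(sliding_windows(948)), 3L)
  expect_equal(length(sliding_windows(750)), 1L)
  expect_error(sliding_windows(700), "at least 750")
  w <- sliding_windows(1518)
  expect_true(all(vapply(w, length, integer(1)) == 750L))
  expect_equal(w[[2]][1], 86L)  # starts advance by the step
  # coverage: every rank below size + step*(k-1) appears in some window
  covered <- sort(unique(unlist(w)))
  expect_true(all(seq_len(750 + 85 * 9) %in% covered))
})

test_that("samples at a centroid are assigned to it; ambiguity is Admixed", {
  centroids <- data.frame(group = c("Arab", "Persian", "EastAfrican"),
                          PC1 = c(-1, 1, 0), PC2 = c(0, 0, 2))
  sc <- data.frame(sample_id = c("a", "b", "c"),
                   PC1 = c(-1, 1, 0), PC2 = c(0, 0, 0))
  asg <- assign_ancestry(sc, centroids)
  expect_equal(asg$group[1:2], c("Arab", "Persian"))
  expect_equal(asg$group[3], "Admixed")  # equidistant between Arab/Persian
  expect_error(assign_ancestry(sc, centroids[1, , drop = FALSE]), ">= 2 groups")
  sc$PC1[1] <- NA
  expect_error(assign_ancestry(sc, centroids), "missing PC")
})

test_that("admixed draws between two drifted groups are mostly recalled", {
  set.seed(71)
  sim <- simulate_genotype_matrix(c(A = 120, B = 120, C = 120), m = 800,
                                  fst = 0.08, seed = 71)
  # admixed individuals: one haplotype-equivalent from each of two groups
  d <- sim$G$dosages
  adm <- sapply(1:40, function(i) {
    a <- d[sample(1:120, 1), ]; b <- d[sample(121:240, 1), ]
    round((a + b) / 2)
  })
  all_d <- rbind(d, t(adm))
  G <- genotype_matrix(all_d, sim$G$variants$chrom, sim$G$variants$pos,
                       sample_ids = c(sim$G$sample_ids, paste0("adm", 1:40)))
  p <- pca_genotypes(G, k = 2)
  lab <- c(sim$labels, rep("adm", 40))
  centroids <- do.call(rbind, lapply(c("A", "B", "C"), function(g) {
    data.frame(group = g,
               PC1 = mean(p$scores$PC1[lab == g]),
               PC2 = mean(p$scores$PC2[lab == g]))
  }))
  asg <- assign_ancestry(p$scores, centroids)
  recall <- mean(asg$group[lab == "adm"] == "Admixed")
  expect_gte(recall, 0.8)
  # pure samples mostly keep their labels
  pure_acc <- mean(asg$group[lab != "adm"] == lab[lab != "adm"])
  expect_gte(pure_acc, 0.9)
})

test_that("PC-space outlier flagging marks distant samples only", {
  set.seed(72)
  sc <- data.frame(sample_id = paste0("s", 1:101), group = "Arab",
                   PC1 = c(rnorm(100, 0, 0.1), 5),
                   PC2 = c(rnorm(100, 0, 0.1), 5))
  flag <- pc_outlier_flag(sc)
  expect_true(flag[101])
  expect_lt(mean(flag[1:100]), 0.05)
})

test_that("a single window reproduces the whole-sample regression", {
  set.seed(73)
  n <- 750
  dat <- data.frame(PC1 = rnorm(n), amy1 = sample(2:14, n, replace = TRUE),
                    sex = rbinom(n, 1, 0.5), age = rnorm(n, 40, 10))
  dat$y <- -0.05 * dat$amy1 + 0.2 * dat$sex + rnorm(n)
  res <- windowed_association(dat, trait = "y", window_size = n, step = 85,
                              transform_within = FALSE)
  expect_equal(nrow(res), 1L)
  direct <- summary(lm(y ~ amy1 + sex + age, dat))$coefficients
  expect_equal(res$beta, direct["amy1", 1], tolerance = 1e-10)
  expect_equal(res$se, direct["amy1", 2], tolerance = 1e-10)
})

test_that("constant-CN windows are flagged and skipped", {
  set.seed(74)
  n <- 800
  dat <- data.frame(PC1 = sort(rnorm(n)), amy1 = rep(6L, n),
                    sex = rbinom(n, 1, 0.5), age = rnorm(n, 40, 10))
  dat$y <- rnorm(n)
  res <- windowed_association(dat, trait = "y", window_size = 750, step = 85)
  expect_true(all(res$skipped))
  expect_true(all(is.na(res$beta)))
})

test_that("an effect ramp along PC1 yields a detectable monotone trend", {
  set.seed(75)
  n <- 1518
  pc1 <- sort(rnorm(n))
  cn <- sample(2:14, n, replace = TRUE)
  slope <- seq(0, -0.3, length.out = n)  # effect strengthens along PC1
  dat <- data.frame(PC1 = pc1, amy1 = cn, sex = rbinom(n, 1, 0.5),
                    age = rnorm(n, 40, 10))
  dat$y <- slope * (cn - mean(cn)) + rnorm(n, 0, 0.5)
  res <- windowed_association(dat, trait = "y")
  expect_equal(nrow(res), 10L)
  tr <- window_trend(res)
  expect_lt(tr$p, 0.05)
  expect_lt(tr$rho, 0)
  # flat truth: trend should not fire
  dat$y <- -0.1 * (cn - mean(cn)) + rnorm(n, 0, 0.5)
  res_flat <- windowed_association(dat, trait = "y")
  expect_gt(window_trend(res_flat)$p, 0.05)
})

test_that("binary outcomes run per window through logistic regression", {
  set.seed(76)
  n <- 800
  dat <- data.frame(PC1 = rnorm(n), amy1 = sample(2:14, n, replace = TRUE),
                    sex = rbinom(n, 1, 0.5), age = rnorm(n, 40, 10),
                    bmi = rnorm(n, 29, 5))
  dat$restraint <- rbinom(n, 1, plogis(0.2 + 0 * dat$amy1))
  res <- windowed_association(dat, binary_outcome = "restraint",
                              covars = c("sex", "age", "bmi"),
                              window_size = 750, step = 85)
  expect_true(all(is.finite(res$or[!res$skipped])))
  expect_true(all(res$or_lo < res$or & res$or < res$or_hi, na.rm = TRUE))
})
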