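#' Default synthetic haplotype copy-number tables
#'
#' Per-ancestry tables of joint (AMY1, AMY2A, AMY2B) haplotype copy
#' numbers and frequencies.  The tables are synthetic: haplotype-level
#' frequencies are not public, so these were constructed to reproduce the
#' reported diploid means (AMY1 6.92 Arab / 7.60 Persian; AMY2A 2.06 /
#' 2.27), the AMY1-AMY2A parity coupling (every haplotype carries AMY1
#' and AMY2A of equal parity, so diploid parity always agrees), the
#' positive AMY1-AMY2A correlation, and a mostly copy-invariable AMY2B.
#'
#' @param path TSV with columns `group`, `amy1`, `amy2a`, `amy2b`,
#'   `frequency`; defaults to the packaged synthetic tables.
#' @return Named list of per-group data.frames.
#' @export
haplotype_tables <- function(path = system.file("extdata",
                                                "haplotype_tables_synthetic.tsv",
                                                package = "amylocnv")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group", "amy1", "amy2a", "amy2b", "frequency")
  stopifnot(all(need %in% names(tab)))
  out <- split(tab[, setdiff(need, "group")], tab$group)
  for (g in names(out)) {
    f <- out[[g]]$frequency
    if (abs(sum(f) - 1) > 1e-6)
      stop("haplotype frequencies for ", g, " do not sum to 1")
    rownames(out[[g]]) <- NULL
  }
  out
}

#' Simulation configuration
#'
#' Bundles every parameter driving the synthetic generators.  Defaults
#' emulate the study conditions: ~30x sequencing depth over 20-kb units,
#' a consanguineous cohort of nuclear families, a small negative AMY1
#' effect on an SD-scaled adiposity trait (-0.02 SD/copy), moderate
#' heritability, ddPCR with 20,000 droplets and three replicates, and
#' Arab/Persian ancestry mixture in the cohort's observed proportions.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_samples Cohort size.
#' @param ancestry_props Named ancestry proportions (families are assigned
#'   whole).
#' @param family_children Children per nuclear family (2 founders +
#'   children); 0 gives an unrelated cohort.
#' @param depth Mean per-haploid-copy read density (reads/bp); 0.15
#'   corresponds to 30x diploid coverage with 100-bp reads.
#' @param overdispersion CV of a shared per-sample gamma depth multiplier
#'   (cancels in the density ratio).
#' @param region_overdispersion CV of an independent per-region gamma
#'   multiplier (does not cancel; stresses calling accuracy).
#' @param beta_cn Trait effect per AMY1 copy (SD units).
#' @param h2 Narrow-sense heritability of the trait's polygenic component.
#' @param beta_sex,beta_age Fixed covariate effects (SD units; age effect
#'   per SD of age).
#' @param age_mean,age_sd Age distribution, truncated to \[18, 80\].
#' @param bmi_mean,bmi_sd Scale used to map the SD-trait to raw BMI.
#' @param or_obesity_per_copy Per-copy odds ratio of the obesity outcome.
#' @param obesity_prevalence Baseline obesity probability at the mean CN.
#' @param restraint_prev Named per-ancestry prevalence of dietary
#'   restraint among overweight/obese individuals.
#' @param or_restraint_per_copy Per-copy odds ratio of restraint.
#' @param droplets,lambda_control,ddpcr_replicates ddPCR generator
#'   settings (droplets per reaction, mean reference molecules per
#'   droplet, replicates).
#' @param hap_tables Haplotype tables, as from [haplotype_tables()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 3000L,
                       ancestry_props = c(Arab = 0.615, Persian = 0.385),
                       family_children = 3L,
                       depth = 0.15,
                       overdispersion = 0.1,
                       region_overdispersion = 0,
                       beta_cn = -0.02,
                       h2 = 0.3,
                       beta_sex = 0.3,
                       beta_age = 0.1,
                       age_mean = 39.11, age_sd = 12.03,
                       bmi_mean = 28.86, bmi_sd = 5.71,
                       or_obesity_per_copy = 0.93,
                       obesity_prevalence = 0.41,
                       restraint_prev = c(Arab = 0.54, Persian = 0.60),
                       or_restraint_per_copy = 1,
                       droplets = 20000L,
                       lambda_control = 0.5,
                       ddpcr_replicates = 3L,
                       hap_tables = haplotype_tables()) {
  stopifnot(n_samples > 0, depth > 0, h2 >= 0, h2 < 1,
            abs(sum(ancestry_props) - 1) < 1e-8,
            all(names(ancestry_props) %in% names(hap_tables)))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a family-structured cohort
#'
#' Builds nuclear families (two unrelated founders plus
#' `family_children` full siblings) until the target size is reached,
#' assigning each family one ancestry group.  Sex is Bernoulli(0.5), age
#' normal truncated to \[18, 80\].  The kinship matrix is the pedigree
#' expectation (self 0.5, parent-offspring and full sibs 0.25, zero
#' across families), hence block-diagonal.
#'
#' @param config A [sim_config()].
#' @return List: `samples` (data.frame `sample_id`, `family_id`, `father`,
#'   `mother`, `ancestry`, `sex` (1 = female), `age`), `kinship`
#'   (n x n matrix with sample_id dimnames).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fam_size <- 2L + config$family_children
  if (fam_size < 1L) stop("inconsistent family specification")
  n_fam <- ceiling(config$n_samples / fam_size)
  rows <- vector("list", n_fam)
  for (f in seq_len(n_fam)) {
    ids <- sprintf("F%04d_I%d", f, seq_len(fam_size))
    fa <- if (config$family_children > 0L) ids[1] else NA_character_
    mo <- if (config$family_children > 0L) ids[2] else NA_character_
    rows[[f]] <- data.frame(
      sample_id = ids, family_id = sprintf("F%04d", f),
      father = c(rep(NA_character_, min(2L, fam_size)),
                 rep(fa, max(0L, fam_size - 2L))),
      mother = c(rep(NA_character_, min(2L, fam_size)),
                 rep(mo, max(0L, fam_size - 2L))),
      stringsAsFactors = FALSE)
  }
  anc_fam <- sample(names(config$ancestry_props), n_fam, replace = TRUE,
                    prob = config$ancestry_props)
  samples <- do.call(rbind, rows)[seq_len(config$n_samples), , drop = FALSE]
  samples$ancestry <- anc_fam[match(samples$family_id,
                                    sprintf("F%04d", seq_len(n_fam)))]
  # drop dangling parent links if the last family was truncated
  samples$father[!(samples$father %in% samples$sample_id)] <- NA
  samples$mother[!(samples$mother %in% samples$sample_id)] <- NA
  n <- nrow(samples)
  samples$sex <- stats::rbinom(n, 1L, 0.5)
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  while (any(bad <- age < 18 | age > 80))
    age[bad] <- stats::rnorm(sum(bad), config$age_mean, config$age_sd)
  samples$age <- age
  fams <- unique(samples$family_id)
  blocks <- lapply(fams, function(f) {
    i <- which(samples$family_id == f)
    pedigree_kinship(data.frame(id = samples$sample_id[i],
                                father = samples$father[i],
                                mother = samples$mother[i],
                                stringsAsFactors = FALSE))
  })
  # family-block sparse kinship; scales to large cohorts
  K <- Matrix::bdiag(blocks)
  dimnames(K) <- list(samples$sample_id, samples$sample_id)
  rownames(samples) <- NULL
  list(samples = samples, kinship = K)
}

#' Simulate true diploid amylase copy numbers on a cohort
#'
#' Founders draw two haplotypes from their ancestry's haplotype table;
#' each child inherits one haplotype from each parent, uniformly at
#' random.  Diploid copy number is the haplotype sum, so AMY1/AMY2A
#' diploid parity agrees whenever every haplotype row couples equal
#' parities (the default tables do).
#'
#' @param config A [sim_config()].
#' @param cohort Result of [simulate_cohort()].
#' @return data.frame `sample_id`, `amy1`, `amy2a`, `amy2b` (true diploid
#'   copies).
#' @export
simulate_cn <- function(config, cohort) {
  set.seed(config$seed + 1L)
  s <- cohort$samples
  n <- nrow(s)
  idx <- stats::setNames(seq_len(n), s$sample_id)
  hap <- matrix(NA_integer_, n, 6)  # h1/h2 x (amy1, amy2a, amy2b)
  # founders: vectorised table draws per ancestry group
  founder <- is.na(s$father) & is.na(s$mother)
  for (g in unique(s$ancestry[founder])) {
    i <- which(founder & s$ancestry == g)
    tab <- config$hap_tables[[g]]
    r1 <- sample.int(nrow(tab), length(i), replace = TRUE, prob = tab$frequency)
    r2 <- sample.int(nrow(tab), length(i), replace = TRUE, prob = tab$frequency)
    hap[i, ] <- cbind(tab$amy1[r1], tab$amy2a[r1], tab$amy2b[r1],
                      tab$amy1[r2], tab$amy2a[r2], tab$amy2b[r2])
  }
  # descendants: fill generation by generation (parents precede children)
  while (any(todo <- is.na(hap[, 1]))) {
    fa <- idx[s$father[todo]]; mo <- idx[s$mother[todo]]
    ready <- !is.na(hap[fa, 1]) & !is.na(hap[mo, 1])
    if (!any(ready)) stop("pedigree has unresolvable parent links")
    i <- which(todo)[ready]; fa <- fa[ready]; mo <- mo[ready]
    off1 <- 3L * (stats::runif(length(i)) < 0.5)  # 0 -> h1, 3 -> h2
    off2 <- 3L * (stats::runif(length(i)) < 0.5)
    for (col in 1:3) {
      hap[i, col] <- hap[cbind(fa, off1 + col)]
      hap[i, col + 3L] <- hap[cbind(mo, off2 + col)]
    }
  }
  data.frame(sample_id = s$sample_id,
             amy1 = hap[, 1] + hap[, 4],
             amy2a = hap[, 2] + hap[, 5],
             amy2b = hap[, 3] + hap[, 6],
             stringsAsFactors = FALSE)
}

#' Simulate read counts for a locus given true copy number
#'
#' Target counts are Poisson with mean `CN * depth * unit_length`
#' (reads from all copies pile onto the locus units but are normalised by
#' one unit length); reference counts are Poisson with mean
#' `2 * depth * reference_length` (the reference is diploid).  A shared
#' per-sample gamma multiplier with CV `overdispersion` mimics
#' library-size variation and cancels in the density ratio; an optional
#' independent per-region gamma (CV `region_overdispersion`) does not
#' cancel.
#'
#' @param true_cn Vector of true diploid copy numbers.
#' @param locus A [locus_region_def()].
#' @param depth Per-haploid-copy read density (reads/bp).
#' @param overdispersion Shared per-sample gamma CV.
#' @param region_overdispersion Independent per-region gamma CV.
#' @param sample_ids Optional ids (default `sim1..simN`).
#' @param seed Optional seed.
#' @return data.frame of count records (one row per sample), as
#'   [count_record()].
#' @export
simulate_counts <- function(true_cn, locus, depth = 0.15,
                            overdispersion = 0, region_overdispersion = 0,
                            sample_ids = NULL, seed = NULL) {
  stopifnot(inherits(locus, "locus_region_def"), depth >= 0, all(true_cn >= 0))
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_cn)
  if (is.null(sample_ids)) sample_ids <- paste0("sim", seq_len(n))
  gshared <- if (overdispersion > 0)
    stats::rgamma(n, shape = 1 / overdispersion^2, scale = overdispersion^2)
  else rep(1, n)
  greg <- function() if (region_overdispersion > 0)
    stats::rgamma(n, shape = 1 / region_overdispersion^2,
                  scale = region_overdispersion^2)
  else rep(1, n)
  lam_t <- true_cn * depth * locus$unit_length * gshared * greg()
  lam_r <- 2 * depth * reference_length(locus) * gshared * greg()
  count_record(sample_ids, locus$locus_name,
               stats::rpois(n, lam_t), stats::rpois(n, lam_r),
               locus$unit_length, reference_length(locus))
}

#' Simulate CN-dependent phenotypes on a cohort
#'
#' Generates `y = beta_cn * CN + beta_sex * sex + beta_age * age_z + g + e`
#' with polygenic `g ~ MVN(0, 2 K sigma2_g)` drawn family-block-wise from
#' the pedigree kinship, `sigma2_g = h2`, `sigma2_e = 1 - h2` (the
#' residual trait scale is 1 SD).  A raw BMI is derived by rescaling a
#' noisy copy of the trait; obesity and dietary-restraint outcomes come
#' from logistic models with configurable per-copy odds ratios, restraint
#' being defined only for overweight/obese individuals (BMI >= 25) with
#' per-ancestry baseline prevalence.
#'
#' @param cohort From [simulate_cohort()].
#' @param cn From [simulate_cn()] (uses `amy1`).
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed + 2`.
#' @return data.frame: `sample_id`, `trait`, `bmi`, `obesity`,
#'   `restraint` (NA when BMI < 25), `sex`, `age`, `ancestry`.
#' @export
simulate_phenotypes <- function(cohort, cn, config, seed = NULL) {
  set.seed(if (is.null(seed)) config$seed + 2L else seed)
  s <- cohort$samples
  stopifnot(identical(s$sample_id, cn$sample_id))
  n <- nrow(s)
  g <- polygenic_draw(cohort$kinship, s$family_id, sqrt(config$h2))
  age_z <- (s$age - mean(s$age)) / stats::sd(s$age)
  e <- stats::rnorm(n, 0, sqrt(1 - config$h2))
  y <- config$beta_cn * cn$amy1 + config$beta_sex * s$sex +
    config$beta_age * age_z + g + e
  # an independent noisy adiposity copy on the raw BMI scale
  y_bmi <- config$beta_cn * cn$amy1 + config$beta_sex * s$sex +
    config$beta_age * age_z +
    polygenic_draw(cohort$kinship, s$family_id, sqrt(config$h2)) +
    stats::rnorm(n, 0, sqrt(1 - config$h2))
  bmi <- config$bmi_mean + config$bmi_sd * (y_bmi - mean(y_bmi)) / stats::sd(y_bmi)
  cnc <- cn$amy1 - mean(cn$amy1)
  obesity <- stats::rbinom(n, 1L, stats::plogis(
    stats::qlogis(config$obesity_prevalence) +
      log(config$or_obesity_per_copy) * cnc))
  restraint <- rep(NA_integer_, n)
  ow <- bmi >= 25
  p_anc <- config$restraint_prev[s$ancestry]
  restraint[ow] <- stats::rbinom(sum(ow), 1L, stats::plogis(
    stats::qlogis(p_anc[ow]) + log(config$or_restraint_per_copy) * cnc[ow]))
  data.frame(sample_id = s$sample_id, trait = y, bmi = bmi,
             obesity = obesity, restraint = restraint,
             sex = s$sex, age = s$age, ancestry = s$ancestry,
             stringsAsFactors = FALSE)
}

# family-block multivariate normal draw with covariance sd^2 * 2K
polygenic_draw <- function(K, family_id, sd_g) {
  n <- nrow(K)
  g <- numeric(n)
  if (sd_g == 0) return(g)
  for (f in unique(family_id)) {
    i <- which(family_id == f)
    L <- chol(as.matrix(2 * K[i, i, drop = FALSE]))
    g[i] <- as.numeric(t(L) %*% stats::rnorm(length(i))) * sd_g
  }
  g
}

#' Simulate ddPCR droplet counts
#'
#' Each droplet receives reference molecules Poisson(`lambda_control`)
#' and target molecules Poisson(`lambda_control * CN / 2`); a droplet is
#' probe-positive when it holds at least one molecule, so positive counts
#' are binomial with occupancy probability `1 - exp(-lambda)`.  Two FAM
#' probes target AMY1 and one targets AMY2A, each in `replicates`
#' independent reactions.
#'
#' @param true_cn data.frame with `sample_id`, `amy1`, `amy2a` (true
#'   diploid copies), or a numeric vector of single-locus CNs.
#' @param droplets Droplets per reaction (default 20000).
#' @param lambda_control Mean reference molecules per droplet.
#' @param replicates Reactions per sample x probe.
#' @param seed Optional seed.
#' @return data.frame: `sample_id`, `probe_id` (`AMY1_p1`, `AMY1_p2`,
#'   `AMY2A_p1`), `replicate`, `fam_positive`, `hex_positive`,
#'   `total_droplets`.
#' @export
simulate_ddpcr <- function(true_cn, droplets = 20000L, lambda_control = 0.5,
                           replicates = 3L, seed = NULL) {
  if (droplets <= 0L) stop("droplets must be positive")
  stopifnot(lambda_control > 0, replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(true_cn))
    true_cn <- data.frame(sample_id = paste0("sim", seq_along(true_cn)),
                          amy1 = true_cn, amy2a = true_cn)
  probes <- data.frame(probe_id = c("AMY1_p1", "AMY1_p2", "AMY2A_p1"),
                       locus = c("amy1", "amy1", "amy2a"),
                       stringsAsFactors = FALSE)
  grid <- expand.grid(si = seq_len(nrow(true_cn)), pi = seq_len(nrow(probes)),
                      replicate = seq_len(replicates))
  cnv <- as.numeric(as.matrix(true_cn[probes$locus])[cbind(grid$si, grid$pi)])
  p_hex <- 1 - exp(-lambda_control)
  p_fam <- 1 - exp(-lambda_control * cnv / 2)
  data.frame(sample_id = true_cn$sample_id[grid$si],
             probe_id = probes$probe_id[grid$pi],
             replicate = grid$replicate,
             fam_positive = stats::rbinom(nrow(grid), droplets, p_fam),
             hex_positive = stats::rbinom(nrow(grid), droplets, p_hex),
             total_droplets = droplets,
             stringsAsFactors = FALSE)
}

#' Simulate a structured genotype matrix
#'
#' Balding-Nichols drift model: each variant has an ancestral frequency
#' drawn uniformly on \[0.05, 0.95\]; population frequencies are Beta
#' distributed around it with divergence `fst`.  Haplotypes are drawn by
#' thresholding an AR(1) latent Gaussian (autocorrelation `ld_rho` between
#' adjacent variants) so adjacent variants can be placed in LD; dosage is
#' the two-haplotype sum.  Optional uniform missingness.
#'
#' @param n_per_pop Named vector of sample counts per population.
#' @param m Number of variants.
#' @param fst Divergence between populations (0 = none).
#' @param ld_rho Latent AR(1) autocorrelation (0 = linkage equilibrium).
#' @param missing_rate Probability a dosage is set missing.
#' @param spacing_bp Distance between adjacent variant positions.
#' @param seed Optional seed.
#' @return List: `G` (a [genotype_matrix()]), `labels` (population per
#'   sample).
#' @export
simulate_genotype_matrix <- function(n_per_pop = c(A = 100, B = 100),
                                     m = 500, fst = 0.05, ld_rho = 0,
                                     missing_rate = 0, spacing_bp = 1000,
                                     seed = NULL) {
  stopifnot(m >= 2, all(n_per_pop > 0), fst >= 0, fst < 1,
            ld_rho >= 0, ld_rho < 1)
  if (!is.null(seed)) set.seed(seed)
  pops <- rep(names(n_per_pop), n_per_pop)
  n <- length(pops)
  p0 <- stats::runif(m, 0.05, 0.95)
  freq <- sapply(names(n_per_pop), function(k) {
    if (fst == 0) p0
    else stats::rbeta(m, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst)
  })
  ar1 <- function(m) {
    z <- numeric(m)
    z[1] <- stats::rnorm(1)
    if (m > 1) for (j in 2:m)
      z[j] <- ld_rho * z[j - 1] + sqrt(1 - ld_rho^2) * stats::rnorm(1)
    z
  }
  hap <- function(pop) {
    z <- if (ld_rho > 0) ar1(m) else stats::rnorm(m)
    as.integer(z < stats::qnorm(freq[, pop]))
  }
  d <- t(vapply(seq_len(n), function(i) hap(pops[i]) + hap(pops[i]),
                integer(m)))
  if (missing_rate > 0)
    d[stats::runif(length(d)) < missing_rate] <- NA
  G <- genotype_matrix(d, chrom = rep("1", m),
                       pos = seq_len(m) * spacing_bp,
                       sample_ids = paste0(pops, "_", seq_len(n)))
  list(G = G, labels = pops)
}

#' Weir-Cockerham fixation index estimate
#'
#' Simple two-level (population/individual) Weir-Cockerham estimator of
#' Fst from dosages, used as an internal check that
#' [simulate_genotype_matrix()] realises its target divergence.
#'
#' @param G A [genotype_matrix()].
#' @param labels Population labels per sample.
#' @return Ratio-of-averages Fst estimate.
#' @export
fst_estimate <- function(G, labels) {
  d <- G$dosages
  labels <- as.factor(labels)
  r <- nlevels(labels)
  stopifnot(r >= 2)
  num <- den <- 0
  for (j in seq_len(ncol(d))) {
    x <- d[, j]; ok <- !is.na(x)
    ni <- tapply(ok, labels, sum)
    if (any(ni < 2)) next
    pi <- tapply(x[ok], labels[ok], mean) / 2
    hi <- tapply(x[ok] == 1, labels[ok], mean)
    nbar <- mean(ni)
    pbar <- sum(ni * pi) / sum(ni)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}
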