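#' Bonferroni-adjusted significance threshold
#'
#' Divides the conventional alpha by the number of tests performed,
#' counting both outcome variables and predictors (or groups): three
#' adiposity traits by two amylase genes gives `0.05 / 6 = 8.33e-3`.
#'
#' @param alpha Family-wise alpha (default 0.05).
#' @param n_outcomes Number of outcome variables tested.
#' @param n_predictors Number of predictors or groups tested.
#' @return `alpha / (n_outcomes * n_predictors)`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_outcomes, n_predictors) {
  n_outcomes <- as.integer(n_outcomes); n_predictors <- as.integer(n_predictors)
  if (is.na(n_outcomes) || is.na(n_predictors) ||
      n_outcomes < 1L || n_predictors < 1L)
    stop("test counts must be positive integers")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  alpha / (n_outcomes * n_predictors)
}

#' Dichotomise BMI into obesity cases and lean controls
#'
#' Cases are `BMI >= case_min` (obesity, default 30 kg/m^2), controls
#' `BMI < control_max` (default 25); the intermediate overweight band is
#' excluded (`NA`).
#'
#' @param bmi Numeric BMI vector (kg/m^2).
#' @param case_min,control_max Band edges.
#' @return Integer vector: 1 case, 0 control, `NA` excluded.
#' @export
dichotomize_bmi <- function(bmi, case_min = 30, control_max = 25) {
  out <- rep(NA_integer_, length(bmi))
  out[!is.na(bmi) & bmi >= case_min] <- 1L
  out[!is.na(bmi) & bmi < control_max] <- 0L
  out
}

#' Logistic regression of a binary outcome on copy number
#'
#' Maximum-likelihood logistic fit; the per-copy odds ratio is
#' `exp(beta)`, with a Wald 95% confidence interval.  Complete or
#' quasi-complete separation is detected (fitted probabilities collapsing
#' to 0/1 or a diverging coefficient) and raised as an error.
#'
#' @param outcome Binary 0/1 vector (both classes required).
#' @param predictor Numeric predictor (e.g. AMY1 copies).
#' @param covariates Optional covariate matrix/data.frame.
#' @return List: `or`, `ci` (length 2), `beta`, `se`, `p`, `n`.
#' @export
logistic_fit <- function(outcome, predictor, covariates = NULL) {
  df <- data.frame(.y = outcome, .x = predictor)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$.y)) < 2L)
    stop("outcome must contain both classes")
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial()))
  mu <- stats::fitted(fit)
  co <- summary(fit)$coefficients
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10) || abs(co[".x", 1]) > 15)
    stop("separation detected: consider penalised (Firth) regression")
  b <- co[".x", 1]; se <- co[".x", 2]
  list(or = exp(b), ci = exp(b + c(-1, 1) * stats::qnorm(0.975) * se),
       beta = b, se = se, p = co[".x", 4], n = nrow(df))
}

#' Two-group tests for descriptive tables
#'
#' Numeric traits are compared with a two-sided Wilcoxon rank-sum test;
#' factor/character variables with a chi-square test on the contingency
#' table.
#'
#' @param x Trait values (numeric) or categories (factor/character).
#' @param groups Two-level grouping vector.
#' @return List: `test` (`"wilcoxon"` or `"chisq"`), `statistic`, `p`.
#' @export
group_tests <- function(x, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L)
    stop("exactly two non-empty groups required")
  if (is.numeric(x)) {
    # ties fall back to the normal approximation; the warning is expected
    ht <- suppressWarnings(stats::wilcox.test(x ~ groups))
    list(test = "wilcoxon", statistic = unname(ht$statistic), p = ht$p.value)
  } else {
    ht <- suppressWarnings(stats::chisq.test(table(x, groups)))
    list(test = "chisq", statistic = unname(ht$statistic), p = ht$p.value)
  }
}

#' Kinship-aware association of amylase CN with quantitative traits
#'
#' High-level driver reproducing the structure of a CN-adiposity
#' association table: for each trait, outliers are removed and the trait
#' inverse-normal transformed, then each predictor is tested with
#' [lmm_fit()] using the thresholded kinship, with the supplied
#' covariates as fixed effects.
#'
#' @param genotypes data.frame with `sample_id` and predictor columns
#'   (e.g. `amy1`, `amy2a`), already passed through
#'   [filter_for_association()].
#' @param pheno data.frame keyed by `sample_id` holding traits and
#'   covariates.
#' @param K Kinship matrix with `sample_id` dimnames (thresholding applied
#'   here via `kinship_threshold`).
#' @param traits Character vector of trait column names in `pheno`.
#' @param covars Character vector of covariate column names in `pheno`.
#' @param predictors Predictor column names in `genotypes`
#'   (default `c("amy1", "amy2a")`).
#' @param kinship_threshold Passed to [threshold_kinship()].
#' @return data.frame with one row per trait x predictor:
#'   `predictor`, `trait`, `n`, `beta`, `se`, `p`, `method`.
#' @export
associate_cn <- function(genotypes, pheno, K, traits, covars,
                         predictors = c("amy1", "amy2a"),
                         kinship_threshold = 0.05) {
  stopifnot("sample_id" %in% names(genotypes), "sample_id" %in% names(pheno))
  dat <- merge(genotypes, pheno, by = "sample_id")
  K <- as.matrix(K)
  if (is.null(rownames(K))) stop("kinship matrix needs sample_id dimnames")
  dat <- dat[dat$sample_id %in% rownames(K), , drop = FALSE]
  Kt <- threshold_kinship(K[dat$sample_id, dat$sample_id], kinship_threshold)
  out <- list()
  for (tr in traits) {
    yall <- preprocess_trait(dat[[tr]])
    for (pr in predictors) {
      keep <- !is.na(yall) & !is.na(dat[[pr]]) &
        stats::complete.cases(dat[, covars, drop = FALSE])
      fit <- lmm_fit(yall[keep],
                     covariates = as.matrix(dat[keep, covars, drop = FALSE]),
                     K = Kt[keep, keep], predictor = dat[[pr]][keep],
                     trait_name = tr, predictor_name = pr)
      out[[paste(tr, pr)]] <- fit$assoc
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
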