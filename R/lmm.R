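#' Kinship-aware variance-component association
#'
#' Fits the linear mixed model `y = X b + g + e` with
#' `Var(g) = sigma2_g * (grm_factor * K)` and `Var(e) = sigma2_e * I` by
#' restricted maximum likelihood, where `K` is the (thresholded) kinship
#' matrix.  The variance ratio `delta = sigma2_e / sigma2_g` is profiled
#' out after rotating the model by the eigenvectors of the kinship
#' covariance, so each likelihood evaluation is closed-form; `delta` is
#' maximised on the log scale by golden-section/parabolic search to a
#' relative log-likelihood tolerance of 1e-8.  The predictor's Wald test
#' uses the normal approximation.
#'
#' With `K = NULL` (or the identity) the model collapses to ordinary
#' least squares, which the estimates reproduce exactly.
#'
#' @param y Numeric trait vector (typically inverse-normal transformed).
#' @param covariates Numeric matrix or data.frame of covariates (no
#'   intercept column; one is added), or `NULL`.
#' @param K Kinship matrix aligned with `y`, or `NULL` for unrelated
#'   samples; alternatively pass a precomputed decomposition via `eig`.
#' @param predictor Numeric predictor vector (e.g. AMY1 copy number), or
#'   `NULL` to fit the null (heritability) model only.
#' @param eig Optional precomputed [kinship_eigen()] result (overrides `K`);
#'   reusing it across many fits on the same cohort is much faster.
#' @param grm_factor Kinship-to-relationship scaling (default 2).
#' @param trait_name,predictor_name Labels for the result rows.
#' @return List with elements
#'   `assoc` (data.frame `predictor`, `trait`, `n`, `beta`, `se`, `p`,
#'   `method`; `NULL` when `predictor` is `NULL`) and
#'   `h2` (data.frame `trait`, `sigma2_g`, `sigma2_e`, `h2` from the fit
#'   without the predictor).
#' @export
lmm_fit <- function(y, covariates = NULL, K = NULL, predictor = NULL,
                    eig = NULL, grm_factor = 2,
                    trait_name = "trait", predictor_name = "predictor") {
  ok <- !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  if (!is.null(predictor)) ok <- ok & !is.na(predictor)
  n_all <- length(y)
  if (!is.null(eig) && any(!ok))
    stop("precomputed eigendecomposition requires complete cases; subset first")
  y <- y[ok]
  n <- length(y)
  X0 <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) X0 <- cbind(X0, covariates[ok, , drop = FALSE])
  if (n < ncol(X0) + 2L) stop("too few samples for the design")
  if (is.null(eig)) {
    if (is.null(K)) {
      eig <- list(u = NULL, d = rep(1, n), n = n)
    } else {
      K <- as.matrix(K)[ok, ok, drop = FALSE]
      eig <- kinship_eigen(K, grm_factor = grm_factor)
    }
  }
  rot <- function(m) if (is.null(eig$u)) m else
    as.matrix(Matrix::crossprod(eig$u, m))
  yt <- rot(cbind(y))
  X0t <- rot(X0)
  null_fit <- reml_profile(yt, X0t, eig$d)
  h2 <- data.frame(trait = trait_name,
                   sigma2_g = null_fit$sigma2_g,
                   sigma2_e = null_fit$sigma2_e,
                   h2 = null_fit$h2)
  assoc <- NULL
  if (!is.null(predictor)) {
    Xt <- cbind(X0t, rot(cbind(predictor[ok])))
    fit <- reml_profile(yt, Xt, eig$d)
    j <- ncol(Xt)
    z <- fit$beta[j] / fit$se[j]
    assoc <- data.frame(predictor = predictor_name, trait = trait_name,
                        n = n, beta = fit$beta[j], se = fit$se[j],
                        p = 2 * stats::pnorm(-abs(z)),
                        method = "lmm_reml", stringsAsFactors = FALSE)
  }
  list(assoc = assoc, h2 = h2, n = n, n_dropped = n_all - n)
}

# Profile REML over delta = sigma2_e/sigma2_g in the rotated model
# Var(y~) = sigma2_g * diag(d + delta).  Returns GLS estimates at the
# optimum; the pure-noise boundary (sigma2_g -> 0) is handled by an
# explicit OLS evaluation and taken when it dominates.
reml_profile <- function(yt, Xt, d, tol = 1e-8, lower = -12, upper = 12) {
  n <- length(yt); p <- ncol(Xt)
  gls <- function(w) {
    XtW <- Xt * w
    XtWX <- crossprod(XtW, Xt)
    XtWy <- crossprod(XtW, yt)
    R <- chol(XtWX)
    beta <- backsolve(R, backsolve(R, XtWy, transpose = TRUE))
    res <- yt - Xt %*% beta
    rss <- sum(w * res^2)
    list(beta = beta, rss = rss, XtWX = XtWX)
  }
  # REML log-likelihood (up to a constant) at log(delta) = ld
  ll <- function(ld) {
    w <- 1 / (d + exp(ld))
    f <- gls(w)
    s2 <- f$rss / (n - p)
    -0.5 * ((n - p) * log(s2) - sum(log(w)) +
              determinant(f$XtWX, logarithm = TRUE)$modulus[1] + (n - p))
  }
  grid <- seq(lower, upper, length.out = 25)
  lls <- vapply(grid, ll, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = tol)
  ld <- if (opt$objective >= lls[i]) opt$maximum else grid[i]
  delta <- exp(ld)
  w <- 1 / (d + delta)
  f <- gls(w)
  sigma2_g <- f$rss / (n - p)
  cov_beta <- sigma2_g * chol2inv(chol(f$XtWX))
  # boundary: at the upper grid edge the genetic component is effectively 0
  at_null <- ld >= upper - 1e-6
  if (at_null) {
    f0 <- gls(rep(1, n))
    s2 <- f0$rss / (n - p)
    return(list(delta = Inf, sigma2_g = 0, sigma2_e = s2, h2 = 0,
                beta = as.numeric(f0$beta),
                se = sqrt(diag(s2 * chol2inv(chol(f0$XtWX)))),
                loglik = ll(upper)))
  }
  list(delta = delta,
       sigma2_g = sigma2_g,
       sigma2_e = sigma2_g * delta,
       h2 = 1 / (1 + delta),
       beta = as.numeric(f$beta),
       se = sqrt(diag(cov_beta)),
       loglik = opt$objective)
}

#' Heritability of a trait under the kinship model
#'
#' Convenience wrapper around [lmm_fit()] without a predictor: returns the
#' REML variance components and `h2 = sigma2_g / (sigma2_g + sigma2_e)`.
#'
#' @inheritParams lmm_fit
#' @return One-row data.frame `trait`, `sigma2_g`, `sigma2_e`, `h2`.
#' @export
heritability <- function(y, covariates = NULL, K = NULL, eig = NULL,
                         grm_factor = 2, trait_name = "trait") {
  lmm_fit(y, covariates, K, predictor = NULL, eig = eig,
          grm_factor = grm_factor, trait_name = trait_name)$h2
}
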