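# Standard bivariate normal CDF P(X <= h, Y <= k) with correlation rho,
# via the one-dimensional reduction
#   Phi2(h, k, rho) = Phi(h) Phi(k) + int_0^rho phi2(h, k, r) dr,
# integrated by fixed-order Gauss-Legendre quadrature (the integrand is
# smooth; 48 nodes give ~1e-12 accuracy over |rho| <= 0.999).
.gl_cache <- new.env(parent = emptyenv())
gl48 <- function() {
  if (is.null(.gl_cache$rule))
    .gl_cache$rule <- pracma::gaussLegendre(48, 0, 1)
  .gl_cache$rule
}

pbvnorm <- function(h, k, rho) {
  if (is.infinite(h) || is.infinite(k)) {
    if (h == -Inf || k == -Inf) return(0)
    if (h == Inf) return(stats::pnorm(k))
    return(stats::pnorm(h))
  }
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(base)
  gl <- gl48()
  r <- rho * gl$x  # rescale the cached [0, 1] rule to [0, rho]
  dens <- exp(-(h^2 - 2 * r * h * k + k^2) / (2 * (1 - r^2))) /
    (2 * pi * sqrt(1 - r^2))
  base + rho * sum(gl$w * dens)
}

polychoric_loglik <- function(tab, rho, a, b) {
  nr <- nrow(tab); nc <- ncol(tab)
  P <- matrix(0, nr + 1L, nc + 1L)
  for (i in seq_len(nr + 1L)) for (j in seq_len(nc + 1L))
    P[i, j] <- pbvnorm(a[i], b[j], rho)
  pr <- P[-1, -1] - P[-(nr + 1L), -1] - P[-1, -(nc + 1L)] +
    P[-(nr + 1L), -(nc + 1L)]
  pr <- pmax(pr, 1e-300)
  sum(tab * log(pr))
}

#' Polychoric correlation of an ordinal contingency table
#'
#' Two-step maximum-likelihood estimator of the correlation of a latent
#' bivariate normal assumed to underlie two ordinal variables (e.g. two
#' copy-number distributions).  Marginal thresholds are fixed at the
#' normal quantiles of the cumulative margin proportions; the correlation
#' is then estimated by maximising the bivariate-normal cell-probability
#' likelihood over (-1, 1).  The p-value is a likelihood-ratio test
#' against independence (`rho = 0`, 1 df).
#'
#' Empty margin categories are collapsed with a warning.
#'
#' @param tab Matrix of cell counts (rows x columns = the two ordinal
#'   variables), at least 2 x 2 after collapsing.
#' @return List: `rho`, `p`, `loglik`, `row_thresholds`, `col_thresholds`,
#'   `n`.
#' @export
polychoric <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative cell counts")
  keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("collapsing empty margin categories")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need >= 2 categories on each margin")
  n <- sum(tab)
  a <- c(-Inf, stats::qnorm(cumsum(rowSums(tab) / n)[-nrow(tab)]), Inf)
  b <- c(-Inf, stats::qnorm(cumsum(colSums(tab) / n)[-ncol(tab)]), Inf)
  obj <- function(rho) polychoric_loglik(tab, rho, a, b)
  opt <- stats::optimize(obj, c(-0.999, 0.999), maximum = TRUE, tol = 1e-7)
  l0 <- obj(0)
  g2 <- max(0, 2 * (opt$objective - l0))
  list(rho = opt$maximum, p = stats::pchisq(g2, df = 1, lower.tail = FALSE),
       loglik = opt$objective,
       row_thresholds = a[-c(1, length(a))],
       col_thresholds = b[-c(1, length(b))], n = n)
}
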