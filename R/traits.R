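#' Remove trait outliers beyond k standard deviations
#'
#' Single pass: mean and SD are computed once from the full input and
#' values with `|x - mean| > k * SD` are dropped.  The rule is applied per
#' trait before any transformation and is not iterated.
#'
#' @param x Numeric trait vector (`NA` allowed and preserved in counting).
#' @param k SD multiplier (default 3).
#' @return Numeric vector of retained values; attribute `"n_removed"`
#'   carries the removal count.  Zero-variance input is returned unchanged
#'   with a warning.
#' @export
remove_outliers <- function(x, k = 3) {
  ok <- !is.na(x)
  if (sum(ok) < 3L) stop("need at least 3 non-missing values")
  m <- mean(x[ok]); s <- stats::sd(x[ok])
  if (s == 0) {
    warning("zero variance: no outlier removal possible")
    attr(x, "n_removed") <- 0L
    return(x)
  }
  drop <- ok & abs(x - m) > k * s
  out <- x[!drop]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Rank-based inverse-normal transform
#'
#' Maps a trait to standard-normal quantiles through its ranks:
#' `y_i = qnorm((r_i - c) / (n + 1 - 2c))` with average ranks for ties.
#' The default offset `c = 0.5` gives `(r - 0.5)/n`; the Blom variant
#' (`c = 3/8`, i.e. `(r - 3/8)/(n + 1/4)`) is available via `offset`.
#'
#' @param x Numeric vector with at least 2 distinct non-missing values.
#' @param offset `"half"` (default) or `"blom"`.
#' @return Transformed vector (same length; `NA` preserved in place).
#' @export
inverse_normal <- function(x, offset = c("half", "blom")) {
  offset <- match.arg(offset)
  ok <- !is.na(x)
  n <- sum(ok)
  if (length(unique(x[ok])) < 2L) stop("all values tied: transform undefined")
  r <- rank(x[ok], ties.method = "average")
  c0 <- if (offset == "half") 0.5 else 3 / 8
  y <- stats::qnorm((r - c0) / (n + 1 - 2 * c0))
  out <- rep(NA_real_, length(x))
  out[ok] <- y
  out
}

#' Outlier-filter and inverse-normalise a trait in one step
#'
#' Convenience wrapper matching the standard preprocessing of adiposity
#' traits: values beyond `k` SD from the mean are set to `NA`, then the
#' remaining values are rank inverse-normal transformed in place (so the
#' output aligns with the input samples).
#'
#' @inheritParams remove_outliers
#' @inheritParams inverse_normal
#' @return Vector aligned with `x`; removed outliers become `NA`.
#' @export
preprocess_trait <- function(x, k = 3, offset = "half") {
  ok <- !is.na(x)
  if (sum(ok) < 3L) stop("need at least 3 non-missing values")
  m <- mean(x[ok]); s <- stats::sd(x[ok])
  if (s > 0) x[ok & abs(x - m) > k * s] <- NA
  inverse_normal(x, offset = offset)
}
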