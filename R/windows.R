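#' Sliding windows of individuals along a ranking
#'
#' Individuals are ranked (by PC1 in the stratified ancestry analysis)
#' and grouped into consecutive-rank windows of `window_size` individuals
#' whose start ranks advance by `step`; only complete windows are
#' returned, giving `floor((n - window_size) / step) + 1` windows.  With
#' the default size 750 and step 85 this yields 10 windows over 1518
#' individuals and 3 over 948.
#'
#' @param n_individuals Number of ranked individuals.
#' @param window_size Individuals per window (default 750).
#' @param step Rank shift between consecutive windows (default 85).
#' @return List of integer rank vectors (1-based, each of length
#'   `window_size`).
#' @export
sliding_windows <- function(n_individuals, window_size = 750, step = 85) {
  stopifnot(step > 0, step <= window_size)
  if (n_individuals < window_size)
    stop("need at least ", window_size, " individuals, got ", n_individuals)
  n_win <- floor((n_individuals - window_size) / step) + 1
  lapply(seq_len(n_win), function(k) {
    s <- (k - 1) * step
    seq.int(s + 1L, s + window_size)
  })
}

#' Per-window association of copy number with traits along PC1
#'
#' Individuals are ranked by `pc1`; within each sliding window the trait
#' is (by default) outlier-filtered and inverse-normal transformed, then
#' regressed on copy number with the supplied covariates by ordinary
#' linear regression.  Optionally a binary outcome (e.g. dietary
#' restraint) is analysed per window by logistic regression instead.
#' Windows with constant copy number are flagged and skipped.
#'
#' @param data data.frame holding all columns referenced below.
#' @param pc1 Name of the PC1 column used for ranking.
#' @param trait Name of the quantitative trait column (linear model), or
#'   `NULL` when only `binary_outcome` is analysed.
#' @param cn Name of the copy-number predictor column.
#' @param covars Character vector of covariate column names.
#' @param binary_outcome Optional name of a 0/1 outcome column analysed
#'   with [logistic_fit()] (odds ratio per copy).
#' @param window_size,step Passed to [sliding_windows()].
#' @param transform_within Apply [preprocess_trait()] within each window
#'   (default `TRUE`); `FALSE` uses the trait as supplied.
#' @return data.frame with one row per window: `window`, `pc1_mean`, `n`,
#'   and either `beta`, `se`, `p` (linear) or `or`, `or_lo`, `or_hi`, `p`
#'   (logistic); skipped windows carry `NA` with `skipped = TRUE`.
#' @export
windowed_association <- function(data, pc1 = "PC1", trait = NULL, cn = "amy1",
                                 covars = c("sex", "age"),
                                 binary_outcome = NULL,
                                 window_size = 750, step = 85,
                                 transform_within = TRUE) {
  stopifnot(pc1 %in% names(data), cn %in% names(data),
            all(covars %in% names(data)))
  if (is.null(trait) && is.null(binary_outcome))
    stop("supply a quantitative trait or a binary outcome")
  ord <- order(data[[pc1]])
  data <- data[ord, , drop = FALSE]
  wins <- sliding_windows(nrow(data), window_size, step)
  rows <- lapply(seq_along(wins), function(k) {
    w <- data[wins[[k]], , drop = FALSE]
    base <- data.frame(window = k, pc1_mean = mean(w[[pc1]]),
                       n = nrow(w), skipped = FALSE)
    if (length(unique(w[[cn]])) < 2L) {
      base$skipped <- TRUE
      base$beta <- NA_real_; base$se <- NA_real_; base$p <- NA_real_
      return(base)
    }
    X <- as.matrix(w[, covars, drop = FALSE])
    if (!is.null(binary_outcome)) {
      fit <- logistic_fit(w[[binary_outcome]], w[[cn]], X)
      base$or <- fit$or; base$or_lo <- fit$ci[1]; base$or_hi <- fit$ci[2]
      base$p <- fit$p
      base$n <- fit$n
    } else {
      y <- if (transform_within) preprocess_trait(w[[trait]]) else w[[trait]]
      df <- data.frame(.y = y, .x = w[[cn]], X)
      lmfit <- stats::lm(.y ~ ., data = df)
      co <- summary(lmfit)$coefficients
      base$beta <- co[".x", 1]; base$se <- co[".x", 2]; base$p <- co[".x", 4]
      base$n <- sum(stats::complete.cases(df))
    }
    base
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    # align columns across skipped/fitted rows
    for (col in c("beta", "se", "p", "or", "or_lo", "or_hi"))
      if (is.null(r[[col]])) r[[col]] <- NA_real_
    r[, c("window", "pc1_mean", "n", "beta", "se", "p",
          "or", "or_lo", "or_hi", "skipped")]
  }))
  rownames(out) <- NULL
  out
}

#' Trend of per-window effect sizes along PC1
#'
#' Spearman rank correlation between window index (PC1 order) and the
#' per-window effect estimate, a simple monotone-trend screen for
#' ancestry-dependent effects.
#'
#' @param window_results data.frame from [windowed_association()].
#' @param column Effect column to test (default `"beta"`).
#' @return List: `rho`, `p` (two-sided), `n_windows`.
#' @export
window_trend <- function(window_results, column = "beta") {
  ok <- !window_results$skipped & !is.na(window_results[[column]])
  if (sum(ok) < 3L) stop("need >= 3 fitted windows for a trend test")
  ht <- suppressWarnings(
    stats::cor.test(window_results$window[ok], window_results[[column]][ok],
                    method = "spearman"))
  list(rho = unname(ht$estimate), p = ht$p.value, n_windows = sum(ok))
}
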