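#' Principal component analysis of a genotype matrix
#'
#' Missing dosages are mean-imputed per variant, columns are centred and
#' scaled to unit variance (zero-variance variants dropped with a
#' warning), and the principal components of the sample-by-sample
#' covariance are extracted by singular value decomposition.  The sign of
#' each component is fixed so that its largest-magnitude variant loading
#' is positive.
#'
#' @param G A [genotype_matrix()] (post-QC).
#' @param k Number of components to return (default 10, capped at the
#'   available rank).
#' @return List: `scores` (data.frame `sample_id`, `PC1..PCk`),
#'   `explained` (eigenvalues of the sample covariance, all of them),
#'   `total_variance` (trace of the sample covariance), `loadings`
#'   (variants x k).
#' @export
pca_genotypes <- function(G, k = 10) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosages
  if (nrow(d) < 2L || ncol(d) < 2L) stop("need >= 2 samples and >= 2 variants")
  for (j in seq_len(ncol(d))) {
    mis <- is.na(d[, j])
    if (any(mis)) d[mis, j] <- mean(d[, j], na.rm = TRUE)
  }
  sds <- apply(d, 2, stats::sd)
  zero <- sds == 0
  if (all(zero)) {
    # degenerate input (e.g. identical samples): zero-variance components
    warning("all variants have zero variance; returning null components")
    k <- min(k, nrow(d))
    scores <- matrix(0, nrow(d), k,
                     dimnames = list(NULL, paste0("PC", seq_len(k))))
    return(list(scores = cbind(data.frame(sample_id = G$sample_ids,
                                          stringsAsFactors = FALSE),
                               as.data.frame(scores)),
                explained = rep(0, nrow(d)), total_variance = 0,
                loadings = NULL))
  }
  if (any(zero)) {
    warning(sum(zero), " zero-variance variant(s) dropped from PCA")
    d <- d[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  Z <- scale(d, center = TRUE, scale = sds)
  m <- ncol(Z)
  sv <- svd(Z)
  # sign convention: largest |loading| positive per component
  for (j in seq_along(sv$d)) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) {
      sv$v[, j] <- -sv$v[, j]; sv$u[, j] <- -sv$u[, j]
    }
  }
  eig <- sv$d^2 / m  # eigenvalues of Z Z' / m
  k <- min(k, length(eig))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = cbind(data.frame(sample_id = G$sample_ids,
                                 stringsAsFactors = FALSE),
                      as.data.frame(scores)),
       explained = eig,
       total_variance = sum(Z^2) / m,
       loadings = sv$v[, seq_len(k), drop = FALSE])
}

#' Nearest-centroid ancestry assignment with an admixture margin
#'
#' Each sample is assigned to the reference group whose centroid is
#' nearest in PC space; samples whose nearest-to-second-nearest distance
#' ratio exceeds `admixed_margin` (i.e. that sit nearly equidistant
#' between two groups) are labelled `"Admixed"`.
#'
#' @param scores data.frame with `sample_id` and `PC*` columns (from
#'   [pca_genotypes()]).
#' @param centroids data.frame with a `group` column and the same `PC*`
#'   columns (>= 2 groups).
#' @param admixed_margin Ratio threshold in (0, 1]; higher is more
#'   permissive.  The default 0.5 flags samples whose nearest centroid is
#'   more than half as far away as the runner-up; in simulated cohorts
#'   with clear structure, pure samples sit well below 0.2 and 50/50
#'   admixed draws well above 0.5.
#' @return data.frame `sample_id`, `group`, `dist_ratio` plus the PC
#'   coordinates.
#' @export
assign_ancestry <- function(scores, centroids, admixed_margin = 0.5) {
  pcs <- grep("^PC[0-9]+$", names(centroids), value = TRUE)
  if (length(pcs) == 0L) stop("centroids need PC columns")
  if (!all(pcs %in% names(scores))) stop("missing PC columns in scores")
  if (nrow(centroids) < 2L) stop("need centroids for >= 2 groups")
  S <- as.matrix(scores[, pcs, drop = FALSE])
  if (any(is.na(S))) stop("missing PC coordinates")
  C <- as.matrix(centroids[, pcs, drop = FALSE])
  D <- outer(rowSums(S^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(S)), rowSums(C^2)) - 2 * S %*% t(C)
  D <- sqrt(pmax(D, 0))
  nearest <- apply(D, 1, which.min)
  d1 <- D[cbind(seq_len(nrow(D)), nearest)]
  d2 <- apply(D, 1, function(r) sort(r)[2])
  ratio <- ifelse(d2 == 0, 1, d1 / d2)
  group <- as.character(centroids$group)[nearest]
  group[ratio > admixed_margin] <- "Admixed"
  cbind(data.frame(sample_id = scores$sample_id, group = group,
                   dist_ratio = ratio, stringsAsFactors = FALSE),
        scores[, pcs, drop = FALSE])
}

#' Flag within-group PC-space outliers
#'
#' Distance-based rule for re-excluding outliers after a region-restricted
#' PCA: a sample is flagged when its distance from its own group centroid
#' exceeds `k` times the group's median absolute deviation of distances.
#'
#' @param scores data.frame with `sample_id`, `group` and `PC*` columns.
#' @param k MAD multiplier (default 6).
#' @return Logical vector aligned with `scores` rows.
#' @export
pc_outlier_flag <- function(scores, k = 6) {
  pcs <- grep("^PC[0-9]+$", names(scores), value = TRUE)
  stopifnot(length(pcs) > 0, "group" %in% names(scores))
  out <- rep(FALSE, nrow(scores))
  for (g in unique(scores$group)) {
    i <- scores$group == g
    S <- as.matrix(scores[i, pcs, drop = FALSE])
    ctr <- colMeans(S)
    dist <- sqrt(rowSums(sweep(S, 2, ctr)^2))
    md <- stats::median(dist); madv <- stats::mad(dist)
    if (madv > 0) out[i] <- dist > md + k * madv
  }
  out
}
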