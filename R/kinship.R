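#' Threshold a kinship matrix
#'
#' Pairs with kinship strictly below `threshold` are treated as unrelated:
#' their off-diagonal coefficients are set to zero.  A pair at exactly the
#' threshold is retained.  The diagonal (self-kinship, 0.5 for a
#' non-inbred individual) is untouched.
#'
#' @param K Symmetric kinship matrix (sample x sample).
#' @param threshold Minimum retained off-diagonal kinship (default 0.05).
#' @return Thresholded matrix, same dimnames.
#' @export
threshold_kinship <- function(K, threshold = 0.05) {
  K <- as.matrix(K)
  if (!isSymmetric(K, tol = 1e-8)) stop("kinship matrix must be symmetric")
  off <- K < threshold
  diag(off) <- FALSE
  K[off] <- 0
  # exact symmetry after numeric tolerance in the check
  (K + t(K)) / 2
}

# connected components of the nonzero pattern (block structure of a
# family-thresholded kinship), without assuming contiguous ordering
nonzero_blocks <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  nc <- 0L
  nz <- abs(A) > 0
  diag(nz) <- TRUE
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    nc <- nc + 1L
    queue <- i
    comp[i] <- nc
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(nz[v, ] & comp == 0L)
      comp[nb] <- nc
      queue <- c(queue, nb)
    }
  }
  split(seq_len(n), comp)
}

#' Eigendecompose a (scaled) kinship matrix block-wise
#'
#' Computes the eigendecomposition of `A = grm_factor * K`, the polygenic
#' covariance pattern used by the mixed model (`grm_factor = 2` converts
#' kinship coefficients to the genomic-relationship scale, giving unit
#' diagonal for non-inbred samples).  A thresholded kinship matrix is
#' block-diagonal over family clusters; the decomposition is performed per
#' block and assembled as a sparse eigenvector matrix, which makes the
#' downstream mixed-model rotation essentially linear in sample size.
#'
#' @param K Symmetric kinship matrix (after [threshold_kinship()]).
#' @param grm_factor Scaling from kinship to relationship (default 2).
#' @return List `u` (sparse n x n eigenvector matrix), `d` (eigenvalues,
#'   aligned with columns of `u`), `n`.
#' @export
kinship_eigen <- function(K, grm_factor = 2) {
  A <- grm_factor * as.matrix(K)
  if (!isSymmetric(A, tol = 1e-8)) stop("kinship matrix must be symmetric")
  n <- nrow(A)
  blocks <- nonzero_blocks(A)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  d <- numeric(n)
  col0 <- 0L
  for (b in blocks) {
    nb <- length(b)
    if (nb == 1L) {
      ii <- c(ii, b); jj <- c(jj, col0 + 1L); xx <- c(xx, 1)
      d[col0 + 1L] <- A[b, b]
    } else {
      e <- eigen(A[b, b, drop = FALSE], symmetric = TRUE)
      ii <- c(ii, rep(b, nb))
      jj <- c(jj, rep(col0 + seq_len(nb), each = nb))
      xx <- c(xx, as.numeric(e$vectors))
      d[col0 + seq_len(nb)] <- e$values
    }
    col0 <- col0 + nb
  }
  if (min(d) < -1e-8 * max(abs(d)))
    stop("kinship covariance is not positive semidefinite; ",
         "consider adding a small diagonal jitter")
  list(u = Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n)),
       d = pmax(d, 0), n = n)
}

#' Expected kinship from a pedigree table
#'
#' Founders are unrelated and non-inbred; kinship is the standard
#' recursive expectation (self 0.5, parent-offspring 0.25, full sibs
#' 0.25).  Suited to the shallow simulated pedigrees used here.
#'
#' @param ped data.frame with `id`, `father`, `mother` (`NA` for founders),
#'   parents listed before children.
#' @return Symmetric kinship matrix with `id` dimnames.
#' @export
pedigree_kinship <- function(ped) {
  stopifnot(all(c("id", "father", "mother") %in% names(ped)))
  ids <- as.character(ped$id)
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  fa <- ifelse(is.na(ped$father), 0L, idx[as.character(ped$father)])
  mo <- ifelse(is.na(ped$mother), 0L, idx[as.character(ped$mother)])
  if (any(fa > seq_len(n), na.rm = TRUE) || any(mo > seq_len(n), na.rm = TRUE))
    stop("parents must precede children in the pedigree table")
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    ki <- if (fa[i] > 0L && mo[i] > 0L) 0.5 * (1 + K[fa[i], mo[i]]) else 0.5
    K[i, i] <- ki
    if (i > 1L) for (j in seq_len(i - 1L)) {
      kij <- 0
      if (fa[i] > 0L) kij <- kij + 0.5 * K[j, fa[i]]
      if (mo[i] > 0L) kij <- kij + 0.5 * K[j, mo[i]]
      K[i, j] <- K[j, i] <- kij
    }
  }
  K
}
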