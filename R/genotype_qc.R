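#' Construct a genotype dosage matrix
#'
#' Container for biallelic genotypes coded as 0/1/2 alternate-allele
#' dosages with `NA` for missing calls, plus variant metadata.
#'
#' @param dosages Numeric matrix, samples x variants, values in
#'   `{0, 1, 2, NA}`.
#' @param chrom,pos Variant chromosome and position vectors (length =
#'   ncol(dosages)); positions must be sorted within chromosome for
#'   windowed operations.
#' @param variant_ids,sample_ids Optional identifiers (defaults generated).
#' @return A `genotype_matrix` object (list with `dosages`, `variants`,
#'   `sample_ids`).
#' @export
genotype_matrix <- function(dosages, chrom, pos, variant_ids = NULL,
                            sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  stopifnot(length(chrom) == m, length(pos) == m)
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(variant_ids))
    variant_ids <- paste0(chrom, ":", pos)
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(rownames(dosages))) rownames(dosages)
                  else paste0("S", seq_len(nrow(dosages)))
  dimnames(dosages) <- list(sample_ids, variant_ids)
  structure(list(dosages = dosages,
                 variants = data.frame(variant_id = variant_ids,
                                       chrom = as.character(chrom),
                                       pos = as.numeric(pos),
                                       stringsAsFactors = FALSE),
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%.1f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

subset_variants <- function(G, keep) {
  genotype_matrix(G$dosages[, keep, drop = FALSE],
                  G$variants$chrom[keep], G$variants$pos[keep],
                  G$variants$variant_id[keep], G$sample_ids)
}

variant_stats <- function(G) {
  d <- G$dosages
  n_called <- colSums(!is.na(d))
  p_alt <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  call_rate <- n_called / nrow(d)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    hwe_exact_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                   sum(x == 2, na.rm = TRUE))
  }, numeric(1))
  data.frame(variant_id = G$variants$variant_id, maf = maf,
             call_rate = call_rate, hwe_p = hwe_p)
}

#' Variant quality control
#'
#' Removes variants failing any of: minor allele frequency
#' `maf > maf_min`, genotyping call rate `> call_rate_min`, HWE exact
#' test `p > hwe_p_min`.  Criteria are evaluated on the input matrix
#' (not sequentially), and per-criterion failure counts are reported.
#'
#' @param G A [genotype_matrix()].
#' @param maf_min Minimum (exclusive) minor allele frequency.
#' @param call_rate_min Minimum (exclusive) call rate.
#' @param hwe_p_min Minimum (exclusive) HWE exact p.
#' @return Filtered [genotype_matrix()]; attribute `"qc_report"` lists
#'   failure counts per criterion and the retained count.
#' @export
variant_qc <- function(G, maf_min = 0.01, call_rate_min = 0.9,
                       hwe_p_min = 1e-6) {
  stopifnot(inherits(G, "genotype_matrix"))
  st <- variant_stats(G)
  fail_maf <- !(st$maf > maf_min) | is.na(st$maf)
  fail_cr <- !(st$call_rate > call_rate_min)
  fail_hwe <- !(st$hwe_p > hwe_p_min)
  keep <- !(fail_maf | fail_cr | fail_hwe)
  if (!any(keep)) stop("all variants removed by QC")
  out <- subset_variants(G, keep)
  attr(out, "qc_report") <- list(n_input = ncol(G$dosages),
                                 n_fail_maf = sum(fail_maf),
                                 n_fail_call_rate = sum(fail_cr),
                                 n_fail_hwe = sum(fail_hwe),
                                 n_retained = sum(keep))
  out
}

pairwise_r2 <- function(d, i, j) {
  ok <- !is.na(d[, i]) & !is.na(d[, j])
  if (sum(ok) < 3L) return(0)
  x <- d[ok, i]; y <- d[ok, j]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Greedy windowed LD pruning
#'
#' Within each base-pair window (anchored at successive variants, sliding
#' by `step_variants`), pairs of retained variants with squared dosage
#' correlation above `r2_max` are broken by removing the lower-MAF member
#' (ties: the later position), repeatedly, until no violating pair
#' remains.  The final retained set contains no pair within `window_bp`
#' of each other with `r^2 > r2_max`.
#'
#' @param G A [genotype_matrix()], positions sorted within chromosome.
#' @param window_bp Window span in bp (default 50000).
#' @param step_variants Window shift in variants (default 5).
#' @param r2_max Maximum tolerated pairwise r-squared (default 0.05).
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(G, window_bp = 50000, step_variants = 5, r2_max = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  v <- G$variants
  for (ch in unique(v$chrom)) {
    p <- v$pos[v$chrom == ch]
    if (is.unsorted(p)) stop("variant positions unsorted on ", ch)
  }
  d <- G$dosages
  maf <- pmin(colMeans(d, na.rm = TRUE) / 2, 1 - colMeans(d, na.rm = TRUE) / 2)
  keep <- rep(TRUE, ncol(d))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    s <- 1L
    while (s <= length(idx)) {
      anchor <- idx[s]
      win <- idx[v$pos[idx] >= v$pos[anchor] &
                 v$pos[idx] <= v$pos[anchor] + window_bp]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2L) break
        # highest-r2 violating pair first, deterministic order
        worst <- NULL; worst_r2 <- r2_max
        for (ii in seq_len(length(act) - 1L)) for (jj in (ii + 1L):length(act)) {
          r2 <- pairwise_r2(d, act[ii], act[jj])
          if (r2 > worst_r2) { worst_r2 <- r2; worst <- c(act[ii], act[jj]) }
        }
        if (is.null(worst)) break
        drop <- if (maf[worst[1]] < maf[worst[2]]) worst[1]
                else if (maf[worst[2]] < maf[worst[1]]) worst[2]
                else max(worst)  # tie: later position
        keep[drop] <- FALSE
      }
      s <- s + step_variants
    }
    # cleanup sweep: the stepped windows can leave a long-range pair jointly
    # covered by no anchored window; enforce the post-condition globally
    repeat {
      changed <- FALSE
      act <- idx[keep[idx]]
      for (a in seq_along(act)) {
        if (!keep[act[a]]) next
        for (b in seq_along(act)) {
          if (b <= a || !keep[act[b]]) next
          if (v$pos[act[b]] - v$pos[act[a]] > window_bp) break
          if (pairwise_r2(d, act[a], act[b]) > r2_max) {
            i <- act[a]; j <- act[b]
            drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j
                    else max(i, j)
            keep[drop] <- FALSE
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  v$variant_id[keep]
}
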