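#' Continuous copy-number estimate from a count record
#'
#' The density ratio of a target locus to its copy-invariant (diploid)
#' reference region estimates copy number on the diploid scale:
#' `raw_cn = scale * target_density / reference_density` with `scale = 2`,
#' so a sample whose target is present at two copies reads 2.0.
#' Normalising the target count by the length of one repeat unit (while
#' summing reads over all paralogous units) makes the expectation equal
#' the true diploid copy number for multi-unit loci such as AMY1.
#'
#' @param count_rec One or more count rows as returned by [locus_counts()].
#' @param scale Copies carried by the reference region (default 2, diploid).
#' @return data.frame `sample_id`, `locus_name`, `raw_cn`.
#' @export
raw_cn <- function(count_rec, scale = 2) {
  stopifnot(all(c("target_density", "reference_density") %in% names(count_rec)))
  if (any(count_rec$reference_density <= 0))
    stop("reference density must be > 0 to normalise copy number")
  data.frame(sample_id = count_rec$sample_id,
             locus_name = count_rec$locus_name,
             raw_cn = scale * count_rec$target_density / count_rec$reference_density,
             stringsAsFactors = FALSE)
}

round_half_up <- function(x) floor(x + 0.5)

# nearest integer to x with given parity (0 even / 1 odd); exact ties to the
# larger candidate
round_to_parity <- function(x, parity) {
  lo <- 2 * floor((x - parity) / 2) + parity
  hi <- lo + 2
  ifelse(x - lo < hi - x, lo, hi)
}

#' Parity-conditional integer rounding of amylase copy numbers
#'
#' AMY1 and AMY2A sit on shared structural haplotypes, so their diploid
#' copy numbers share even/odd parity.  AMY2A (and AMY2B, when present)
#' are rounded half-up to the nearest integer; AMY1 is then rounded to the
#' nearest integer whose parity matches the AMY2A call — nearest even if
#' AMY2A is even, nearest odd if odd.  When the AMY1 estimate is exactly
#' equidistant between the two admissible integers the larger is taken.
#'
#' @param raw_amy1,raw_amy2a Continuous diploid estimates (vectors allowed).
#' @param raw_amy2b Optional continuous AMY2B estimates.
#' @return data.frame `amy1`, `amy2a` (and `amy2b` if supplied),
#'   `parity_consistent` (always `TRUE` by construction).
#' @examples
#' conditional_round(7.4, 2.1)  # AMY1 8 (nearest even), AMY2A 2
#' conditional_round(7.4, 3.0)  # AMY1 7 (nearest odd),  AMY2A 3
#' @export
conditional_round <- function(raw_amy1, raw_amy2a, raw_amy2b = NULL) {
  stopifnot(is.finite(raw_amy1), is.finite(raw_amy2a),
            raw_amy1 >= 0, raw_amy2a >= 0,
            length(raw_amy1) == length(raw_amy2a))
  amy2a <- round_half_up(raw_amy2a)
  amy1 <- round_to_parity(raw_amy1, amy2a %% 2)
  out <- data.frame(amy1 = as.integer(amy1), amy2a = as.integer(amy2a))
  if (!is.null(raw_amy2b)) {
    stopifnot(is.finite(raw_amy2b), raw_amy2b >= 0,
              length(raw_amy2b) == length(raw_amy1))
    out$amy2b <- as.integer(round_half_up(raw_amy2b))
  }
  out$parity_consistent <- out$amy1 %% 2L == out$amy2a %% 2L
  out
}

#' Call integer amylase genotypes from a counts table
#'
#' Reshapes a per-sample/per-locus counts table (as produced by
#' [count_samples()] or read from TSV) into one row per sample, computes
#' continuous estimates with [raw_cn()] and applies [conditional_round()].
#'
#' @param counts data.frame of count records for loci named `AMY1`,
#'   `AMY2A` and optionally `AMY2B`.
#' @param scale Reference copies, passed to [raw_cn()].
#' @return data.frame with `sample_id`, raw and integer CN columns and the
#'   `parity_consistent` flag.
#' @export
call_genotypes <- function(counts, scale = 2) {
  rc <- raw_cn(counts, scale = scale)
  need <- c("AMY1", "AMY2A")
  if (!all(need %in% rc$locus_name))
    stop("counts must contain loci AMY1 and AMY2A")
  wide <- stats::reshape(rc, idvar = "sample_id", timevar = "locus_name",
                         direction = "wide")
  names(wide) <- sub("^raw_cn\\.", "raw_", names(wide))
  has2b <- "raw_AMY2B" %in% names(wide)
  g <- conditional_round(wide$raw_AMY1, wide$raw_AMY2A,
                         if (has2b) wide$raw_AMY2B else NULL)
  out <- cbind(data.frame(sample_id = wide$sample_id,
                          stringsAsFactors = FALSE), g)
  out$raw_amy1 <- wide$raw_AMY1
  out$raw_amy2a <- wide$raw_AMY2A
  if (has2b) out$raw_amy2b <- wide$raw_AMY2B
  rownames(out) <- NULL
  out
}

#' AMY2A/AMY2B copy-number concordance summary
#'
#' Reports the fraction of samples with identical AMY2A and AMY2B integer
#' calls and, among discordant samples, the fraction in which AMY2B is
#' copy-invariable (CN = 2) — the pattern that justifies dropping AMY2B
#' from association analyses.
#'
#' @param genotypes data.frame with integer `amy2a` and `amy2b` columns.
#' @return List with `frac_equal`, `frac_discordant_amy2b_two` (`NA` with
#'   `discordant_defined = FALSE` when no pair is discordant), and counts.
#' @export
amy2b_concordance <- function(genotypes) {
  if (is.null(genotypes) || nrow(genotypes) == 0L)
    stop("empty genotype table")
  stopifnot(all(c("amy2a", "amy2b") %in% names(genotypes)))
  eq <- genotypes$amy2a == genotypes$amy2b
  n_disc <- sum(!eq)
  list(frac_equal = mean(eq),
       frac_discordant_amy2b_two =
         if (n_disc == 0L) NA_real_ else mean(genotypes$amy2b[!eq] == 2L),
       discordant_defined = n_disc > 0L,
       n = nrow(genotypes), n_discordant = n_disc)
}

#' Prepare genotypes for association testing
#'
#' Samples with zero AMY1 copies are removed; rare AMY1 calls above `cap`
#' are winsorised to `cap` (default 14 copies).  AMY2A is left untouched
#' (its zero-copy class is a genuine genotype and is retained).
#'
#' @param genotypes data.frame with an integer `amy1` column.
#' @param cap Winsorisation ceiling for AMY1 (copies).
#' @return Filtered data.frame; a list attribute `"filter_report"` carries
#'   `removed` and `capped` counts.
#' @export
filter_for_association <- function(genotypes, cap = 14L) {
  stopifnot("amy1" %in% names(genotypes), cap > 0)
  drop <- genotypes$amy1 == 0L
  out <- genotypes[!drop, , drop = FALSE]
  capped <- out$amy1 > cap
  out$amy1[capped] <- as.integer(cap)
  rownames(out) <- NULL
  attr(out, "filter_report") <- list(removed = sum(drop), capped = sum(capped))
  out
}
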