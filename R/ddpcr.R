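#' Copy number from droplet counts
#'
#' In droplet digital PCR the sample is partitioned into ~20,000 droplets;
#' the target (FAM) and reference (HEX) probes each classify droplets as
#' positive or negative.  The plain estimator multiplies the positive-count
#' ratio by the reference copy number: `CN = control_copies * FAM+/HEX+`.
#' With `poisson_correct = TRUE` positive fractions are first converted to
#' mean molecules per droplet via the Poisson occupancy relation
#' `lambda = -log(1 - k/total)`, removing the saturation bias of the raw
#' ratio at high occupancy.
#'
#' @param fam_positive,hex_positive Positive droplet counts (vectors allowed).
#' @param total_droplets Droplets generated per reaction (default 20000).
#' @param control_copies Copies of the reference target (default 2, diploid).
#' @param poisson_correct Apply the occupancy correction?
#' @return Continuous copy-number estimate(s).
#' @examples
#' ddpcr_cn(3000, 1000)  # 6 copies
#' @export
ddpcr_cn <- function(fam_positive, hex_positive, total_droplets = 20000L,
                     control_copies = 2, poisson_correct = FALSE) {
  stopifnot(fam_positive >= 0, hex_positive >= 0,
            fam_positive <= total_droplets, hex_positive <= total_droplets)
  if (any(hex_positive == 0))
    stop("no HEX-positive droplets: reference channel empty")
  if (poisson_correct) {
    if (any(fam_positive >= total_droplets) || any(hex_positive >= total_droplets))
      stop("saturated channel: occupancy correction undefined at k = total")
    lam_fam <- -log1p(-fam_positive / total_droplets)
    lam_hex <- -log1p(-hex_positive / total_droplets)
    control_copies * lam_fam / lam_hex
  } else {
    control_copies * fam_positive / hex_positive
  }
}

#' Average replicate ddPCR estimates
#'
#' Computes per-replicate copy numbers with [ddpcr_cn()] and returns their
#' arithmetic mean per sample and probe (each sample is typically run in
#' three independent replicates).
#'
#' @param droplets data.frame with columns `sample_id`, `probe_id`,
#'   `replicate`, `fam_positive`, `hex_positive`, `total_droplets`.
#' @param ... Passed to [ddpcr_cn()].
#' @return data.frame `sample_id`, `probe_id`, `n_replicates`, `cn`.
#' @export
average_replicates <- function(droplets, ...) {
  need <- c("sample_id", "probe_id", "fam_positive", "hex_positive",
            "total_droplets")
  stopifnot(all(need %in% names(droplets)))
  if (nrow(droplets) == 0L) stop("no ddPCR measurements supplied")
  droplets$cn_rep <- ddpcr_cn(droplets$fam_positive, droplets$hex_positive,
                              droplets$total_droplets, ...)
  agg <- stats::aggregate(cn_rep ~ sample_id + probe_id, droplets,
                          function(x) c(n = length(x), m = mean(x)))
  data.frame(sample_id = agg$sample_id, probe_id = agg$probe_id,
             n_replicates = as.integer(agg$cn_rep[, "n"]),
             cn = agg$cn_rep[, "m"], stringsAsFactors = FALSE)
}

#' Reconcile two AMY1 probe calls against the AMY2A parity
#'
#' The AMY1 assay uses two independent FAM probes; the AMY2A call fixes
#' the expected even/odd parity of AMY1.  Each probe call is rounded
#' half-up and tested for parity concordance with AMY2A: if both are
#' concordant they are averaged; if only one is, that call is used; if
#' neither is, the two are averaged.  Averaged values are re-rounded with
#' the parity-conditional rule, so the returned integer always shares the
#' AMY2A parity.
#'
#' @param call_probe1,call_probe2 Continuous AMY1 estimates from the two
#'   probes (replicate-averaged).
#' @param amy2a_call Integer AMY2A copy number.
#' @param concordance One of `"parity"` (default) or `"integer_equality"`
#'   (the two probes agree on the rounded integer).
#' @return Integer AMY1 copy number, parity-consistent with `amy2a_call`.
#' @export
reconcile_amy1 <- function(call_probe1, call_probe2, amy2a_call,
                           concordance = c("parity", "integer_equality")) {
  concordance <- match.arg(concordance)
  stopifnot(call_probe1 >= 0, call_probe2 >= 0, amy2a_call >= 0,
            length(call_probe1) == length(call_probe2),
            length(call_probe1) == length(amy2a_call))
  p <- as.integer(amy2a_call) %% 2L
  r1 <- round_half_up(call_probe1)
  r2 <- round_half_up(call_probe2)
  if (concordance == "parity") {
    ok1 <- r1 %% 2 == p
    ok2 <- r2 %% 2 == p
  } else {
    ok1 <- ok2 <- r1 == r2
  }
  avg <- round_to_parity((r1 + r2) / 2, p)
  out <- ifelse(ok1 & ok2, avg,
         ifelse(ok1, r1,
         ifelse(ok2, r2, avg)))
  # a lone concordant probe call already has the right parity under the
  # parity rule; under integer equality force it
  as.integer(round_to_parity(out, p))
}

#' Build WGS vs ddPCR validation calls
#'
#' @param wgs data.frame with `sample_id`, `amy1`, `amy2a` (integer WGS calls).
#' @param ddpcr data.frame with `sample_id`, `amy1`, `amy2a` (integer ddPCR
#'   calls, e.g. from [average_replicates()] + [reconcile_amy1()]).
#' @return data.frame of validation calls with per-locus concordance flags.
#' @export
validation_calls <- function(wgs, ddpcr) {
  m <- merge(wgs[, c("sample_id", "amy1", "amy2a")],
             ddpcr[, c("sample_id", "amy1", "amy2a")],
             by = "sample_id", suffixes = c("_wgs", "_ddpcr"))
  if (nrow(m) == 0L) stop("no overlapping samples between WGS and ddPCR calls")
  m$concordant_amy1 <- m$amy1_wgs == m$amy1_ddpcr
  m$concordant_amy2a <- m$amy2a_wgs == m$amy2a_ddpcr
  m
}

#' WGS-ddPCR concordance summary
#'
#' Each sample contributes two calls (AMY1 and AMY2A); the concordance
#' percentage is `100 * (n_calls - n_discordant) / n_calls`.
#'
#' @param calls data.frame from [validation_calls()] (columns
#'   `concordant_amy1`, `concordant_amy2a`).
#' @return List: `n_samples`, `n_calls`, `n_discordant`,
#'   `percent_concordant`.
#' @export
concordance <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) stop("empty validation call set")
  stopifnot(all(c("concordant_amy1", "concordant_amy2a") %in% names(calls)))
  n_calls <- 2L * nrow(calls)
  n_disc <- sum(!calls$concordant_amy1) + sum(!calls$concordant_amy2a)
  list(n_samples = nrow(calls), n_calls = n_calls, n_discordant = n_disc,
       percent_concordant = 100 * (n_calls - n_disc) / n_calls)
}
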