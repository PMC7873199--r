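#' Phred score to error probability
#'
#' A mapping quality Q on the Phred scale corresponds to an alignment error
#' probability of `10^(-Q/10)`; MAPQ > 20 therefore bounds the probability
#' of inaccurate mapping at 0.01.
#'
#' @param q Phred-scaled quality score(s), `>= 0`.
#' @return `10^(-q/10)`.
#' @examples
#' phred_to_prob(20)  # 0.01
#' @export
phred_to_prob <- function(q) {
  q <- as.numeric(q)
  if (any(is.na(q)) || any(q < 0)) stop("Phred score must be >= 0")
  10^(-q / 10)
}

bam_flag_policy <- function(flag_policy = c("default", "exclude_duplicates")) {
  flag_policy <- match.arg(flag_policy)
  # default mirrors plain `samtools view -c` on primary records: drop
  # unmapped/secondary/supplementary, keep duplicates
  if (flag_policy == "default") {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                           isSecondaryAlignment = FALSE,
                           isSupplementaryAlignment = FALSE)
  } else {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                           isSecondaryAlignment = FALSE,
                           isSupplementaryAlignment = FALSE,
                           isDuplicate = FALSE)
  }
}

check_bam_interval <- function(bam_file, interval) {
  hdr <- Rsamtools::scanBamHeader(bam_file)[[1]]$targets
  if (!(interval$chrom %in% names(hdr)))
    stop("chromosome '", interval$chrom, "' absent from alignment header")
  if (interval$end > hdr[[interval$chrom]])
    stop("interval end ", interval$end, " exceeds reference length ",
         hdr[[interval$chrom]], " for ", interval$chrom)
  invisible(TRUE)
}

open_bam <- function(bam_file) {
  if (!file.exists(bam_file)) stop("alignment file not found: ", bam_file)
  idx <- paste0(bam_file, ".bai")
  idx2 <- sub("\\.bam$", ".bai", bam_file)
  if (!file.exists(idx) && !file.exists(idx2))
    stop("alignment index (.bai) missing for ", bam_file,
         "; index the file first (samtools index)")
  Rsamtools::BamFile(bam_file)
}

#' Count alignment records overlapping an interval
#'
#' Counts records whose reference-aligned span overlaps the interval by at
#' least one base (samtools `view -c` semantics), with MAPQ at or above
#' `mapq_min` and satisfying the flag policy.  The default policy excludes
#' unmapped, secondary and supplementary records and keeps duplicates.
#'
#' @param bam_file Path to an indexed BAM file.
#' @param interval A [genomic_interval()].
#' @param mapq_min Minimum mapping quality; 0 disables the filter.
#' @param flag_policy `"default"` or `"exclude_duplicates"`.
#' @return Integer record count.
#' @export
count_reads <- function(bam_file, interval, mapq_min = 0L,
                        flag_policy = "default") {
  stopifnot(inherits(interval, "genomic_interval"))
  mapq_min <- as.integer(mapq_min)
  if (is.na(mapq_min) || mapq_min < 0) stop("mapq_min must be >= 0")
  bf <- open_bam(bam_file)
  check_bam_interval(bam_file, interval)
  param <- Rsamtools::ScanBamParam(
    which = intervals_to_granges(interval),
    flag = bam_flag_policy(flag_policy),
    mapqFilter = if (mapq_min > 0L) mapq_min else NA_integer_)
  as.integer(Rsamtools::countBam(bf, param = param)$records)
}

#' Per-locus read counts and densities for one sample
#'
#' Sums [count_reads()] over the target and reference intervals of a locus
#' and converts counts to read densities (reads/bp): the target count is
#' divided by the locus `unit_length`, the reference count by the total
#' reference interval length.
#'
#' @param bam_file Indexed BAM path.
#' @param locus A [locus_region_def()].
#' @param sample_id Sample identifier recorded in the output.
#' @param flag_policy Passed to [count_reads()].
#' @return One-row data.frame: `sample_id`, `locus_name`, `target_count`,
#'   `reference_count`, `target_density`, `reference_density`.
#' @export
locus_counts <- function(bam_file, locus, sample_id, flag_policy = "default") {
  stopifnot(inherits(locus, "locus_region_def"))
  tc <- sum(vapply(locus$target_intervals, function(iv)
    count_reads(bam_file, iv, locus$mapq_min, flag_policy), integer(1)))
  rc <- sum(vapply(locus$reference_intervals, function(iv)
    count_reads(bam_file, iv, locus$mapq_min, flag_policy), integer(1)))
  if (rc == 0L) stop("reference coverage absent for locus ", locus$locus_name)
  count_record(sample_id, locus$locus_name, tc, rc,
               locus$unit_length, reference_length(locus))
}

#' Assemble a count record from raw counts
#'
#' @param sample_id,locus_name Identifiers.
#' @param target_count,reference_count Non-negative read counts.
#' @param unit_length Target normalisation length (bp).
#' @param ref_length Total reference length (bp).
#' @return One-row data.frame with densities filled in.
#' @export
count_record <- function(sample_id, locus_name, target_count, reference_count,
                         unit_length, ref_length) {
  stopifnot(target_count >= 0, reference_count >= 0,
            unit_length > 0, ref_length > 0)
  data.frame(sample_id = sample_id, locus_name = locus_name,
             target_count = target_count, reference_count = reference_count,
             target_density = target_count / unit_length,
             reference_density = reference_count / ref_length,
             stringsAsFactors = FALSE)
}

#' Alignability QC over a locus
#'
#' Among properly paired, mapped records in the target intervals, reports
#' the fraction that map uniquely (no `XA:Z:` alternative-hit tag and no
#' `SA:Z:` split-alignment tag) and the fraction with MAPQ strictly above
#' `mapq_threshold`, together with the Phred error-probability bound for
#' that threshold.  Records seen in more than one target interval are
#' deduplicated.
#'
#' @param bam_file Indexed BAM path.
#' @param locus A [locus_region_def()].
#' @param mapq_threshold MAPQ threshold for the error bound (default 20).
#' @param sample_id Sample identifier.
#' @return One-row data.frame: `sample_id`, `locus_name`,
#'   `frac_properly_paired_unique`, `frac_mapq_gt_threshold`,
#'   `mapping_error_prob_bound`, `n_properly_paired`, `defined`.
#'   With zero properly paired reads the fractions are `NA` and `defined`
#'   is `FALSE` (with a warning), never a silent 0.
#' @export
alignability_report <- function(bam_file, locus, mapq_threshold = 20L,
                                sample_id = basename(bam_file)) {
  stopifnot(inherits(locus, "locus_region_def"))
  bf <- open_bam(bam_file)
  for (iv in locus$target_intervals) check_bam_interval(bam_file, iv)
  param <- Rsamtools::ScanBamParam(
    which = intervals_to_granges(locus$target_intervals),
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE, isUnmappedQuery = FALSE),
    what = c("qname", "flag", "rname", "pos", "mapq"),
    tag = c("XA", "SA"))
  recs <- Rsamtools::scanBam(bf, param = param)
  qname <- unlist(lapply(recs, `[[`, "qname"), use.names = FALSE)
  flag <- unlist(lapply(recs, `[[`, "flag"), use.names = FALSE)
  pos <- unlist(lapply(recs, `[[`, "pos"), use.names = FALSE)
  mapq <- unlist(lapply(recs, `[[`, "mapq"), use.names = FALSE)
  xa <- unlist(lapply(recs, function(r) {
    v <- r$tag$XA
    if (is.null(v)) rep(NA_character_, length(r$qname)) else as.character(v)
  }), use.names = FALSE)
  sa <- unlist(lapply(recs, function(r) {
    v <- r$tag$SA
    if (is.null(v)) rep(NA_character_, length(r$qname)) else as.character(v)
  }), use.names = FALSE)
  keep <- !duplicated(paste(qname, flag, pos, sep = "\r"))
  n <- sum(keep)
  if (n == 0L) {
    warning("no properly paired reads in target intervals of ",
            locus$locus_name, "; alignability fractions undefined")
    frac_unique <- NA_real_; frac_mapq <- NA_real_; defined <- FALSE
  } else {
    frac_unique <- sum(is.na(xa[keep]) & is.na(sa[keep])) / n
    frac_mapq <- sum(mapq[keep] > mapq_threshold, na.rm = TRUE) / n
    defined <- TRUE
  }
  data.frame(sample_id = sample_id, locus_name = locus$locus_name,
             frac_properly_paired_unique = frac_unique,
             frac_mapq_gt_threshold = frac_mapq,
             mapping_error_prob_bound = phred_to_prob(mapq_threshold),
             n_properly_paired = n, defined = defined,
             stringsAsFactors = FALSE)
}

#' Count all loci for a set of samples
#'
#' @param bam_files Named character vector (names = sample ids) of BAM paths.
#' @param regions Named list of [locus_region_def()], e.g. from
#'   [amylase_regions()].
#' @param flag_policy Passed to [count_reads()].
#' @return data.frame of stacked [locus_counts()] rows.
#' @export
count_samples <- function(bam_files, regions, flag_policy = "default") {
  if (is.null(names(bam_files))) names(bam_files) <- basename(bam_files)
  do.call(rbind, lapply(names(bam_files), function(sid) {
    do.call(rbind, lapply(regions, function(loc)
      locus_counts(bam_files[[sid]], loc, sid, flag_policy)))
  }))
}
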