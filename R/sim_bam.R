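#' Write alignment records to a sorted, indexed BAM file
#'
#' Low-level fixture writer: takes a table of alignment records, writes a
#' SAM file on a single toy contig and converts it to a
#' coordinate-sorted, indexed BAM.  Sequences are placeholders (`*`);
#' only the fields relevant to coverage counting and alignability QC are
#' meaningful.
#'
#' @param reads data.frame with columns `pos` (1-based leftmost), `mapq`,
#'   and optionally `flag` (default 99, a properly paired primary
#'   record), `cigar` (default `"100M"`), `qname` (default generated),
#'   `xa`/`sa` (logical: attach an `XA:Z:`/`SA:Z:` tag).
#' @param out_prefix Output path prefix (`.bam` appended by conversion).
#' @param contig,contig_length Toy reference name and length.
#' @return Path to the BAM file (with `.bai` alongside).
#' @export
write_bam_fixture <- function(reads, out_prefix, contig = "amytoy",
                              contig_length = 100000L) {
  stopifnot(is.data.frame(reads), "pos" %in% names(reads))
  n <- nrow(reads)
  pos <- as.integer(reads$pos)
  mapq <- if ("mapq" %in% names(reads)) as.integer(reads$mapq) else rep(60L, n)
  flag <- if ("flag" %in% names(reads)) as.integer(reads$flag) else rep(99L, n)
  cigar <- if ("cigar" %in% names(reads)) reads$cigar else rep("100M", n)
  qname <- if ("qname" %in% names(reads)) reads$qname
           else sprintf("read%06d", seq_len(n))
  xa <- if ("xa" %in% names(reads)) reads$xa else rep(FALSE, n)
  sa <- if ("sa" %in% names(reads)) reads$sa else rep(FALSE, n)
  paired <- bitwAnd(flag, 1L) > 0L
  body <- character(n)
  for (i in seq_len(n)) {
    fields <- c(qname[i], flag[i], contig, pos[i], mapq[i], cigar[i],
                if (paired[i]) "=" else "*",
                if (paired[i]) pos[i] + 200L else 0L,
                if (paired[i]) 300L else 0L, "*", "*")
    tags <- character(0)
    if (isTRUE(xa[i]))
      tags <- c(tags, sprintf("XA:Z:%s,+%d,100M,1;", contig, pos[i] + 5000L))
    if (isTRUE(sa[i]))
      tags <- c(tags, sprintf("SA:Z:%s,%d,+,100M,60,0;", contig, pos[i] + 7000L))
    body[i] <- paste(c(fields, tags), collapse = "\t")
  }
  sam <- paste0(out_prefix, ".sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_length),
               body), sam)
  bam <- Rsamtools::asBam(sam, out_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Locus definition on the toy fixture contig
#'
#' A single-contig miniature of a coverage-genotyping locus: a 20-kb
#' target unit and a 40-kb copy-invariant reference interval on a 100-kb
#' contig, mirroring the field layout of the genomic definitions.
#'
#' @param mapq_min MAPQ policy of the returned locus.
#' @return A [locus_region_def()] on contig `"amytoy"`.
#' @export
toy_locus <- function(mapq_min = 0L) {
  locus_region_def("TOY",
                   target_intervals = list(genomic_interval("amytoy", 10000, 30000)),
                   unit_length = 20000,
                   reference_intervals = list(genomic_interval("amytoy", 50000, 90000)),
                   mapq_min = mapq_min)
}

#' Simulate an alignment fixture realising a coverage model draw
#'
#' Draws per-interval read counts from [simulate_counts()] for a true
#' copy number, places reads uniformly within each target/reference
#' interval of the locus, and writes a sorted indexed BAM plus a
#' companion BED of the locus intervals.  Fractions of reads can carry
#' `XA`/`SA` tags or reduced MAPQ for QC tests.
#'
#' @param true_cn True diploid copy number.
#' @param out_prefix Output prefix for `.bam`/`.bed`.
#' @param locus A [locus_region_def()] on the toy contig (default
#'   [toy_locus()]).
#' @param depth Per-haploid-copy read density (reads/bp); the default
#'   0.015 keeps fixtures small.
#' @param frac_xa,frac_sa Fractions of target reads tagged XA / SA.
#' @param frac_low_mapq Fraction of target reads at MAPQ `low_mapq`.
#' @param low_mapq MAPQ assigned to the low-quality fraction.
#' @param read_len Read length implied by the CIGAR.
#' @param contig_length Toy contig length.
#' @param seed Seed for the count draw and read placement.
#' @return List: `bam`, `bed`, `counts` (the realised count record).
#' @export
simulate_bam_fixture <- function(true_cn, out_prefix, locus = toy_locus(),
                                 depth = 0.015, frac_xa = 0, frac_sa = 0,
                                 frac_low_mapq = 0, low_mapq = 10L,
                                 read_len = 100L, contig_length = 100000L,
                                 seed = 1L) {
  set.seed(seed)
  contig <- locus$target_intervals[[1]]$chrom
  place <- function(iv, n_reads) {
    if (n_reads == 0L) return(integer(0))
    lo <- iv$start + 1L
    hi <- max(lo, iv$end - read_len)
    sort(sample.int(hi - lo + 1L, n_reads, replace = TRUE) + lo - 1L)
  }
  cr <- simulate_counts(true_cn, locus, depth = depth, seed = NULL)
  # split the target total over intervals proportional to length
  tl <- vapply(locus$target_intervals, interval_length, numeric(1))
  tc <- as.integer(stats::rmultinom(1, cr$target_count, tl))
  rl <- vapply(locus$reference_intervals, interval_length, numeric(1))
  rc <- as.integer(stats::rmultinom(1, cr$reference_count, rl))
  pos <- c(unlist(mapply(place, locus$target_intervals, tc, SIMPLIFY = FALSE)),
           unlist(mapply(place, locus$reference_intervals, rc, SIMPLIFY = FALSE)))
  n <- length(pos)
  nt <- sum(tc)
  mapq <- rep(60L, n)
  xa <- sa <- rep(FALSE, n)
  if (nt > 0L) {
    pick <- function(frac) seq_len(nt) %in% sample.int(nt, round(frac * nt))
    if (frac_low_mapq > 0) mapq[seq_len(nt)][pick(frac_low_mapq)] <- low_mapq
    if (frac_xa > 0) xa[seq_len(nt)] <- pick(frac_xa)
    if (frac_sa > 0) sa[seq_len(nt)] <- pick(frac_sa)
  }
  ord <- order(pos)
  reads <- data.frame(pos = pos, mapq = mapq, xa = xa, sa = sa)[ord, ]
  bam <- write_bam_fixture(reads, out_prefix, contig = contig,
                           contig_length = contig_length)
  bed <- paste0(out_prefix, ".bed")
  ivs <- c(locus$target_intervals, locus$reference_intervals)
  names(ivs) <- c(rep("target", length(locus$target_intervals)),
                  rep("reference", length(locus$reference_intervals)))
  write_bed_intervals(ivs, bed)
  list(bam = bam, bed = bed, counts = cr,
       target_counts = tc, reference_counts = rc)
}
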