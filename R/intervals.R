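#' Genomic intervals and locus region definitions
#'
#' All intervals are stored 0-based half-open internally.  Region strings of
#' the form `"chr1:104190000-104210000"` follow the samtools convention
#' (1-based, both ends inclusive) and are converted on ingestion; BED files
#' are read natively as 0-based half-open.  A single internal convention
#' avoids off-by-one drift between the two input styles.
#'
#' @param chrom Chromosome (reference sequence) name.
#' @param start 0-based inclusive start position.
#' @param end 0-based exclusive end position; `end > start`.
#' @return A `genomic_interval` object with fields `chrom`, `start`, `end`.
#' @examples
#' gi <- genomic_interval("chr1", 104189999, 104210000)
#' interval_length(gi)  # 20001 bp
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || end <= start)
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:[%d, %d) (%d bp)\n",
              x$chrom, as.integer(x$start), as.integer(x$end),
              as.integer(interval_length(x))))
  invisible(x)
}

#' Interval length in base pairs
#' @param x A `genomic_interval`.
#' @return `end - start`.
#' @export
interval_length <- function(x) x$end - x$start

#' Parse a samtools-style region string
#'
#' `"chr1:A-B"` is interpreted as 1-based with both ends inclusive and
#' converted to the internal 0-based half-open convention (start `A - 1`,
#' end `B`).  Commas in positions are tolerated.
#'
#' @param x Region string.
#' @return A [genomic_interval()].
#' @examples
#' parse_region("chr1:104190000-104210000")
#' @export
parse_region <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- gsub(",", "", x, fixed = TRUE)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4L) stop("cannot parse region string: ", x)
  a <- as.numeric(m[3]); b <- as.numeric(m[4])
  if (a < 1 || b < a) stop("invalid 1-based region: ", x)
  genomic_interval(m[2], a - 1, b)
}

#' Read intervals from a BED file
#'
#' BED is natively 0-based half-open; coordinates are taken as-is.
#'
#' @param path Path to a BED (tab-separated, >= 3 columns) file.
#' @return List of [genomic_interval()] objects, named from column 4 when
#'   present.
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- lapply(seq_len(nrow(bed)), function(i)
    genomic_interval(as.character(bed[i, 1]), bed[i, 2], bed[i, 3]))
  if (ncol(bed) >= 4L) names(out) <- as.character(bed[, 4])
  out
}

#' Write intervals to a BED file
#' @param intervals List of [genomic_interval()]; names become column 4.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_intervals <- function(intervals, path) {
  df <- data.frame(
    chrom = vapply(intervals, `[[`, "", "chrom"),
    start = vapply(intervals, function(x) format(x$start, scientific = FALSE), ""),
    end = vapply(intervals, function(x) format(x$end, scientific = FALSE), ""))
  if (!is.null(names(intervals))) df$name <- names(intervals)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Define a copy-number locus
#'
#' A locus is a set of (possibly paralogous) target intervals whose read
#' density is compared against copy-invariant reference intervals assumed
#' to be present at exactly two copies in every individual.  `unit_length`
#' is the normalisation length of one repeat unit: for a multi-unit locus
#' such as AMY1 (three near-identical 20-kb units) reads are summed over
#' all units but divided by the length of a single unit, so that a sample
#' with true diploid copy number C has expected density ratio C/2.
#'
#' @param locus_name Locus identifier (e.g. `"AMY1"`).
#' @param target_intervals List of [genomic_interval()] covering the target.
#' @param unit_length Normalisation length (bp) of one repeat unit.
#' @param reference_intervals List of [genomic_interval()] for the
#'   copy-invariant comparator.
#' @param mapq_min Minimum mapping quality for counted reads (0 = no filter).
#' @return A `locus_region_def` object.
#' @export
locus_region_def <- function(locus_name, target_intervals, unit_length,
                             reference_intervals, mapq_min = 0L) {
  stopifnot(is.character(locus_name), length(locus_name) == 1L)
  if (inherits(target_intervals, "genomic_interval"))
    target_intervals <- list(target_intervals)
  if (inherits(reference_intervals, "genomic_interval"))
    reference_intervals <- list(reference_intervals)
  if (length(target_intervals) < 1L || length(reference_intervals) < 1L)
    stop("locus needs >= 1 target and >= 1 reference interval")
  stopifnot(all(vapply(target_intervals, inherits, TRUE, "genomic_interval")),
            all(vapply(reference_intervals, inherits, TRUE, "genomic_interval")))
  unit_length <- as.numeric(unit_length)
  if (is.na(unit_length) || unit_length <= 0) stop("unit_length must be > 0")
  mapq_min <- as.integer(mapq_min)
  if (is.na(mapq_min) || mapq_min < 0) stop("mapq_min must be >= 0")
  structure(list(locus_name = locus_name,
                 target_intervals = target_intervals,
                 unit_length = unit_length,
                 reference_intervals = reference_intervals,
                 mapq_min = mapq_min),
            class = "locus_region_def")
}

#' @export
print.locus_region_def <- function(x, ...) {
  cat(sprintf("<locus_region_def> %s: %d target / %d reference interval(s), unit %g bp, MAPQ >= %d\n",
              x$locus_name, length(x$target_intervals),
              length(x$reference_intervals), x$unit_length, x$mapq_min))
  invisible(x)
}

#' Total reference length of a locus definition
#' @param locus A [locus_region_def()].
#' @return Sum of reference interval lengths (bp).
#' @export
reference_length <- function(locus) {
  sum(vapply(locus$reference_intervals, interval_length, numeric(1)))
}

#' Load locus definitions from a YAML region config
#'
#' The config lists, per locus, samtools-style 1-based inclusive region
#' strings for target and reference intervals, the unit length and the
#' MAPQ policy.  The default config ships the GRCh37 amylase coordinates:
#' AMY1 is counted over its three paralogous ~20-kb units with no MAPQ
#' filter (the repeats depress local mapping quality), AMY2A and AMY2B
#' over single intervals at MAPQ >= 20.
#'
#' @param path YAML file; defaults to the packaged GRCh37 amylase config.
#' @return Named list of [locus_region_def()] objects.
#' @export
load_region_config <- function(path = system.file("extdata", "amylase_grch37.yaml",
                                                  package = "amylocnv")) {
  if (!nzchar(path) || !file.exists(path)) stop("region config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$loci)) stop("region config has no 'loci' section")
  out <- lapply(names(cfg$loci), function(nm) {
    lc <- cfg$loci[[nm]]
    locus_region_def(
      locus_name = nm,
      target_intervals = lapply(lc$target, parse_region),
      unit_length = lc$unit_length,
      reference_intervals = lapply(lc$reference, parse_region),
      mapq_min = if (is.null(lc$mapq_min)) 0L else lc$mapq_min)
  })
  names(out) <- names(cfg$loci)
  out
}

#' Default GRCh37 amylase locus definitions
#' @return Named list of [locus_region_def()] for AMY1, AMY2A, AMY2B.
#' @export
amylase_regions <- function() load_region_config()

# GRanges conversion (1-based closed, as Bioconductor expects)
intervals_to_granges <- function(intervals) {
  if (inherits(intervals, "genomic_interval")) intervals <- list(intervals)
  GenomicRanges::GRanges(
    seqnames = vapply(intervals, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(intervals, function(x) x$start + 1, numeric(1)),
      end = vapply(intervals, `[[`, numeric(1), "end")))
}
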