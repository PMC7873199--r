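# shared fixture builders and independent oracles

# reads fully inside the toy target interval [10000, 30000)
reads_in_target <- function(n, mapq = 60L, flag = 99L, xa = FALSE, sa = FALSE) {
  if (n == 0L)
    return(data.frame(pos = integer(0), mapq = integer(0), flag = integer(0),
                      xa = logical(0), sa = logical(0)))
  data.frame(pos = as.integer(seq(10501, 29000, length.out = n)),
             mapq = mapq, flag = flag, xa = xa, sa = sa)
}

make_fixture_bam <- function(reads, prefix = tempfile("fix")) {
  write_bam_fixture(reads, prefix)
}

# independent full-file scan oracle for interval counting: no ranged query,
# manual overlap/flag/MAPQ filtering over every record
naive_count <- function(bam, interval, mapq_min = 0L) {
  p <- Rsamtools::ScanBamParam(what = c("pos", "cigar", "mapq", "flag"))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !bitwAnd(r$flag, 4L) & !bitwAnd(r$flag, 256L) & !bitwAnd(r$flag, 2048L)
  width <- GenomicAlignments_width(r$cigar)
  lo <- interval$start + 1L; hi <- interval$end  # 1-based closed query
  ok <- keep & r$pos <= hi & (r$pos + width - 1L) >= lo & r$mapq >= mapq_min
  sum(ok, na.rm = TRUE)
}

# reference-span width from CIGAR without GenomicAlignments: sum M/D/N/=/X
GenomicAlignments_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    parts <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    sum(vapply(parts, function(p) {
      op <- substr(p, nchar(p), nchar(p))
      n <- as.integer(substr(p, 1, nchar(p) - 1))
      if (op %in% c("M", "D", "N", "=", "X")) n else 0L
    }, integer(1)))
  }, integer(1), USE.NAMES = FALSE)
}

# exact HWE enumeration oracle via log-factorial cell probabilities
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2; nbb <- (na - h) / 2
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  p_obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

# validation-call table with a chosen number of discordances per locus
make_validation_calls <- function(n_samples, n_disc_amy1, n_disc_amy2a) {
  wgs <- data.frame(sample_id = paste0("V", seq_len(n_samples)),
                    amy1 = rep(6L, n_samples), amy2a = rep(2L, n_samples))
  dd <- wgs
  if (n_disc_amy1 > 0) dd$amy1[seq_len(n_disc_amy1)] <- 8L
  if (n_disc_amy2a > 0) dd$amy2a[seq_len(n_disc_amy2a)] <- 3L
  validation_calls(wgs, dd)
}
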