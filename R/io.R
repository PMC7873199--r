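#' Read and write pipeline tables
#'
#' All pipeline tables are plain TSV with a header row: count records
#' (`sample_id, locus_name, target_count, reference_count,
#' target_density, reference_density`), genotype calls, droplet counts
#' (`sample_id, probe_id, replicate, fam_positive, hex_positive,
#' total_droplets`) and phenotype/covariate tables keyed by `sample_id`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @param x data.frame to write.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kinship matrix from TSV
#'
#' Accepts either a square layout (first column = sample ids, remaining
#' columns one per sample) or a long layout with columns `id1`, `id2`,
#' `kinship` (unlisted pairs default to 0, diagonal to 0.5).
#'
#' @param path TSV path.
#' @return Symmetric matrix with sample_id dimnames.
#' @export
read_kinship <- function(path) {
  tab <- read_tsv_table(path)
  if (all(c("id1", "id2", "kinship") %in% names(tab))) {
    ids <- sort(unique(c(tab$id1, tab$id2)))
    K <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    diag(K) <- 0.5
    for (i in seq_len(nrow(tab))) {
      K[tab$id1[i], tab$id2[i]] <- tab$kinship[i]
      K[tab$id2[i], tab$id1[i]] <- tab$kinship[i]
    }
    K
  } else {
    ids <- as.character(tab[[1]])
    K <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(K) <- "double"
    dimnames(K) <- list(ids, ids)
    if (!isSymmetric(K, tol = 1e-8)) stop("kinship matrix is not symmetric")
    K
  }
}
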