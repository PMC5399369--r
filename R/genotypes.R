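## The genotype container: subjects x SNPs additive-coded calls plus
## per-SNP metadata.  Calls count copies of the declared minor allele
## (0, 1, 2) with NA for missing genotypes.

#' Construct a genotype matrix
#'
#' @param subjects character vector of unique subject ids.
#' @param snps data.frame of per-SNP metadata with at least columns
#'   `snp_id`, `minor_allele`; typically also `gene_label`, `chr`, `bp`,
#'   `major_allele`.
#' @param calls integer matrix, subjects in rows and SNPs in columns, values
#'   in \{0, 1, 2, NA\} counting minor-allele copies.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(subjects, snps, calls) {
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) stop("subject ids must be unique")
  if (!is.data.frame(snps) || !"snp_id" %in% names(snps)) {
    stop("'snps' must be a data.frame with an 'snp_id' column")
  }
  if (anyDuplicated(snps$snp_id)) stop("snp ids must be unique")
  calls <- as.matrix(calls)
  if (nrow(calls) != length(subjects) || ncol(calls) != nrow(snps)) {
    stop("'calls' must be length(subjects) x nrow(snps)")
  }
  bad <- !is.na(calls) & !(calls %in% c(0, 1, 2))
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(subjects, snps$snp_id)
  structure(list(subjects = subjects, snps = snps, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$subjects), "subjects x",
      nrow(x$snps), "SNPs\n")
  n_miss <- sum(is.na(x$calls))
  cat("  missing calls:", n_miss,
      sprintf("(%.2f%%)", 100 * n_miss / length(x$calls)), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Per-SNP genotype counts
#'
#' Tabulates homozygous-major (0 copies), heterozygous (1 copy),
#' homozygous-minor (2 copies) and missing calls for every SNP.
#'
#' @param g a [genotype_matrix()].
#' @return data.frame with columns snp_id, n_AA, n_Aa, n_aa, n_missing.
#' @export
genotype_counts <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  counts <- t(apply(g$calls, 2, function(col) {
    c(sum(col == 0, na.rm = TRUE), sum(col == 1, na.rm = TRUE),
      sum(col == 2, na.rm = TRUE), sum(is.na(col)))
  }))
  data.frame(snp_id = g$snps$snp_id, n_AA = counts[, 1], n_Aa = counts[, 2],
             n_aa = counts[, 3], n_missing = counts[, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Subset a genotype matrix by SNP id
#'
#' @param g a [genotype_matrix()].
#' @param keep character vector of snp ids to retain (original order kept).
#' @return a [genotype_matrix()] restricted to `keep`.
#' @export
subset_snps <- function(g, keep) {
  stopifnot(inherits(g, "genotype_matrix"))
  miss <- setdiff(keep, g$snps$snp_id)
  if (length(miss)) stop("unknown snp ids: ", paste(miss, collapse = ", "))
  idx <- which(g$snps$snp_id %in% keep)
  genotype_matrix(g$subjects, g$snps[idx, , drop = FALSE],
                  g$calls[, idx, drop = FALSE])
}
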