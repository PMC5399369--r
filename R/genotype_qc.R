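## Genotype quality control: minor-allele frequency, the exact
## Hardy-Weinberg test, missingness filters, identity-by-state distances and
## classical multidimensional scaling for population-structure assessment.

#' Per-SNP minor-allele frequency
#'
#' MAF is the minor-allele copy count over twice the number of non-missing
#' calls, folded to min(f, 1 - f) so it always lies in [0, 0.5].  When the
#' allele declared minor turns out to be the major allele in the data
#' (folded), the SNP is flagged.
#'
#' @param g a [genotype_matrix()].
#' @return data.frame: snp_id, maf (NA when every call is missing),
#'   `flipped` (declared minor allele is empirically major), n_missing.
#' @export
compute_maf <- function(g) {
  cnt <- genotype_counts(g)
  n_obs <- cnt$n_AA + cnt$n_Aa + cnt$n_aa
  raw <- (cnt$n_Aa + 2 * cnt$n_aa) / (2 * n_obs)
  maf <- pmin(raw, 1 - raw)
  maf[n_obs == 0] <- NA_real_
  data.frame(snp_id = cnt$snp_id, maf = maf,
             flipped = !is.na(maf) & raw > 0.5,
             n_missing = cnt$n_missing,
             stringsAsFactors = FALSE)
}

#' Per-SNP and per-subject genotype missingness
#'
#' @param g a [genotype_matrix()].
#' @return list of two data.frames: `snp` (snp_id, missing_rate) and
#'   `subject` (subject_id, missing_rate).
#' @export
compute_missing_rates <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  miss <- is.na(g$calls)
  list(
    snp = data.frame(snp_id = g$snps$snp_id,
                     missing_rate = colMeans(miss),
                     row.names = NULL, stringsAsFactors = FALSE),
    subject = data.frame(subject_id = g$subjects,
                         missing_rate = rowMeans(miss),
                         row.names = NULL, stringsAsFactors = FALSE)
  )
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test for a biallelic genotype table: conditioning on
#' the observed allele counts, the probability of each possible heterozygote
#' count h (same parity as the minor-allele count) is computed, and the
#' p-value is the total probability of all tables no more probable than the
#' observed one.  Probabilities are evaluated through a numerically stable
#' log-ratio recurrence, so the test is reliable at the low minor-allele
#' frequencies where the chi-square approximation breaks down.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return p-value in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  if (!.is_count(n_AA) || !.is_count(n_Aa) || !.is_count(n_aa)) {
    stop("genotype counts must be non-negative integers")
  }
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("genotype counts must sum to at least 1")
  rare <- min(n_Aa + 2 * n_aa, n_Aa + 2 * n_AA)  # fold to minor allele
  if (rare == 0) return(1)
  h_min <- rare %% 2
  h_max <- min(rare, 2 * n - rare)
  hs <- seq(h_min, h_max, by = 2)
  ## log P(h+2)/P(h) = log[4 * homRare(h) * homCommon(h) / ((h+2)(h+1))]
  hom_rare <- (rare - hs) / 2
  hom_common <- n - hs - hom_rare
  if (length(hs) > 1) {
    ratios <- log(4) + log(hom_rare[-length(hs)]) +
      log(hom_common[-length(hs)]) -
      log(hs[-length(hs)] + 2) - log(hs[-length(hs)] + 1)
    lp <- c(0, cumsum(ratios))
  } else {
    lp <- 0
  }
  w <- exp(lp - max(lp))
  prob <- w / sum(w)
  p_obs <- prob[match(n_Aa, hs)]
  if (is.na(p_obs)) {
    stop("heterozygote count ", n_Aa,
         " is impossible for the implied allele counts")
  }
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

#' Hardy-Weinberg exact test for every SNP in a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @return data.frame: snp_id, p_hwe (NA when all calls are missing).
#' @export
hwe_test <- function(g) {
  cnt <- genotype_counts(g)
  p <- vapply(seq_len(nrow(cnt)), function(i) {
    if (cnt$n_AA[i] + cnt$n_Aa[i] + cnt$n_aa[i] == 0) return(NA_real_)
    hwe_exact_pvalue(cnt$n_AA[i], cnt$n_Aa[i], cnt$n_aa[i])
  }, numeric(1))
  data.frame(snp_id = cnt$snp_id, p_hwe = p, stringsAsFactors = FALSE)
}

#' Apply SNP-level quality control
#'
#' A SNP is removed when its folded minor-allele frequency falls below
#' `maf_min`, its exact Hardy-Weinberg p-value falls below `hwe_min_p`, or
#' its missing rate exceeds `miss_max` (defaults: MAF < 1%, HWE < 1e-6,
#' missingness > 5%).  Per-criterion exclusion counts are reported
#' non-exclusively (a SNP failing several filters is counted under each)
#' while the union is removed once.  SNPs with every call missing are
#' removed under the missingness criterion.  Subject-level call rates are
#' reported but not filtered on.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min,hwe_min_p,miss_max thresholds in [0, 1].
#' @return list: `genotypes` (filtered [genotype_matrix()]) and `report`
#'   (class `qc_report`).
#' @export
apply_snp_qc <- function(g, maf_min = 0.01, hwe_min_p = 1e-6,
                         miss_max = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"), nrow(g$snps) > 0)
  .check_probability(maf_min, "maf_min")
  .check_probability(hwe_min_p, "hwe_min_p")
  .check_probability(miss_max, "miss_max")
  maf <- compute_maf(g)
  miss <- compute_missing_rates(g)
  hwe <- hwe_test(g)
  fail_maf <- !is.na(maf$maf) & maf$maf < maf_min
  fail_hwe <- !is.na(hwe$p_hwe) & hwe$p_hwe < hwe_min_p
  fail_miss <- miss$snp$missing_rate > miss_max
  removed <- fail_maf | fail_hwe | fail_miss
  kept <- g$snps$snp_id[!removed]
  report <- structure(list(
    thresholds = c(maf_min = maf_min, hwe_min_p = hwe_min_p,
                   miss_max = miss_max),
    convention = paste("per-criterion counts are non-exclusive;",
                       "the union of failing SNPs is removed once"),
    excluded = list(maf = g$snps$snp_id[fail_maf],
                    hwe = g$snps$snp_id[fail_hwe],
                    missingness = g$snps$snp_id[fail_miss]),
    n_excluded = c(maf = sum(fail_maf), hwe = sum(fail_hwe),
                   missingness = sum(fail_miss),
                   total = sum(removed)),
    n_retained = length(kept),
    snp_table = data.frame(snp_id = g$snps$snp_id, maf = maf$maf,
                           p_hwe = hwe$p_hwe,
                           missing_rate = miss$snp$missing_rate,
                           removed = removed, stringsAsFactors = FALSE),
    subject_call_rate = transform(miss$subject,
                                  call_rate = 1 - missing_rate)
  ), class = "qc_report")
  filtered <- if (length(kept)) subset_snps(g, kept) else
    genotype_matrix(g$subjects, g$snps[0, , drop = FALSE],
                    g$calls[, 0, drop = FALSE])
  list(genotypes = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality-control report\n")
  cat("  thresholds: MAF <", x$thresholds["maf_min"],
      "| HWE p <", x$thresholds["hwe_min_p"],
      "| missing >", x$thresholds["miss_max"], "\n")
  cat(" ", x$convention, "\n")
  cat("  excluded: MAF", x$n_excluded["maf"], "| HWE", x$n_excluded["hwe"],
      "| missingness", x$n_excluded["missingness"],
      "| union", x$n_excluded["total"], "\n")
  cat("  retained:", x$n_retained, "SNPs\n")
  invisible(x)
}

#' Identity-by-state distance matrix
#'
#' For two subjects the IBS similarity at one SNP with additive codes a, b
#' is 1 - |a - b| / 2 (the shared-allele fraction); the distance is one
#' minus the mean similarity over SNPs non-missing in both subjects.  The
#' result is symmetric with a zero diagonal and values in [0, 1].
#'
#' @param g a [genotype_matrix()].
#' @return subjects x subjects distance matrix; pairs with no jointly
#'   observed SNP are NA and listed in attribute `undefined_pairs`.
#' @export
ibs_distance <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  G <- g$calls
  n <- nrow(G)
  if (n < 2) stop("need at least 2 subjects")
  D <- matrix(0, n, n, dimnames = list(g$subjects, g$subjects))
  for (i in seq_len(n - 1)) {
    gi <- G[i, ]
    block <- G[(i + 1):n, , drop = FALSE]
    diffs <- abs(sweep(block, 2, gi, "-")) / 2
    d <- rowMeans(diffs, na.rm = TRUE)
    d[rowSums(!is.na(diffs)) == 0] <- NA_real_
    D[i, (i + 1):n] <- d
    D[(i + 1):n, i] <- d
  }
  und <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
  if (nrow(und)) {
    warning(nrow(und), " subject pair(s) share no non-missing SNP; ",
            "distance undefined")
    attr(D, "undefined_pairs") <-
      data.frame(subject_1 = rownames(D)[und[, 1]],
                 subject_2 = colnames(D)[und[, 2]],
                 stringsAsFactors = FALSE)
  }
  D
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centers the squared-distance matrix and eigendecomposes it;
#' coordinates are the leading eigenvectors scaled by the square roots of
#' their (non-negative) eigenvalues.  Negative eigenvalues, which arise for
#' non-Euclidean inputs, carry no coordinates and are reported alongside.
#'
#' @param distances symmetric distance matrix with zero diagonal (no NAs).
#' @param k number of requested output dimensions.
#' @return list of class `mds_embedding`: `points` (subjects x k', column-
#'   centered), `eig` (all eigenvalues, non-increasing), `k` (dimensions
#'   actually returned; less than requested when fewer positive eigenvalues
#'   exist, with a warning).
#' @export
classical_mds <- function(distances, k = 2) {
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (n != ncol(distances) || anyNA(distances) ||
      !isTRUE(all.equal(distances, t(distances), tolerance = 1e-8)) ||
      any(abs(diag(distances)) > 1e-12)) {
    stop("'distances' must be a complete symmetric matrix with zero diagonal")
  }
  if (!.is_count(k) || k < 1) stop("'k' must be a positive integer")
  if (k > n - 1) stop("'k' cannot exceed n - 1")
  ## full-rank solve; negative/zero eigenvalues are handled below, so the
  ## advisory warning cmdscale prints about them is redundant here
  fit <- suppressWarnings(cmdscale(distances, k = n - 1, eig = TRUE))
  eig <- fit$eig
  n_pos <- sum(eig > max(eig[1], 0) * 1e-12)
  k_out <- min(k, n_pos)
  if (k_out < k) {
    warning("only ", n_pos, " positive eigenvalue(s); returning ", k_out,
            " dimension(s)")
  }
  pts <- fit$points[, seq_len(k_out), drop = FALSE]
  colnames(pts) <- paste0("C", seq_len(k_out))
  structure(list(points = pts, eig = eig, k = k_out),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("classical MDS embedding:", nrow(x$points), "subjects x", x$k,
      "dimensions\n")
  pos <- x$eig[x$eig > 0]
  cat("  leading eigenvalues:",
      paste(signif(utils::head(pos, 4), 4), collapse = ", "), "\n")
  invisible(x)
}
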