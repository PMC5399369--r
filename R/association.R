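## Per-SNP additive-model association of intermediate phenotypes (node
## degree centralities, MDS-UPDRS) with age and sex covariates, and
## permutation-based empirical p-values.

## Internal OLS of y on [1, snp, age, sex]; inputs already complete-case.
.snp_ols <- function(y, snp, age, sex) {
  X <- cbind(intercept = 1, snp = snp, age = age, sex = sex)
  n <- length(y)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  cf <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  beta <- cf[["snp"]]
  t_stat <- beta / se
  list(beta = beta, se = se, t = t_stat,
       p = 2 * pt(abs(t_stat), df, lower.tail = FALSE), n = n, df = df)
}

#' Additive-model SNP regression with age and sex covariates
#'
#' Ordinary least squares of one intermediate phenotype on minor-allele
#' count, age and sex (coded F = 0, M = 1).  Subjects with a missing
#' genotype call or phenotype are dropped (per-SNP complete-case).  A SNP
#' that is constant after dropping missing calls is flagged untestable
#' rather than raising an error, so panel scans can proceed.
#'
#' @param y numeric phenotype vector.
#' @param snp_calls additive genotype codes (0/1/2, NA allowed).
#' @param age,sex covariates aligned with `y` (sex numeric 0/1 or "F"/"M").
#' @return list: beta, se, t, p, n, df, untestable.
#' @export
fit_snp_model <- function(y, snp_calls, age, sex) {
  if (is.character(sex) || is.factor(sex)) {
    sex <- .as_numeric_column(data.frame(sex = sex, stringsAsFactors = FALSE),
                              "sex")
  }
  keep <- complete.cases(y, snp_calls, age, sex)
  y <- y[keep]; snp <- as.numeric(snp_calls[keep])
  age <- age[keep]; sex <- sex[keep]
  if (length(y) < 5) stop("need at least 5 complete cases")
  if (length(unique(snp)) < 2) {
    return(list(beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
                n = length(y), df = NA_integer_, untestable = TRUE))
  }
  c(.snp_ols(y, snp, age, sex), untestable = FALSE)
}

#' Permutation empirical p-value for a SNP effect
#'
#' The observed |t| of the SNP coefficient is compared against `n_perm`
#' refits in which the phenotype vector is randomly permuted across
#' subjects while genotypes and covariates stay fixed (the standard
#' quantitative-trait permutation null; set `permute = "genotype"` to
#' permute the genotype column instead).  The empirical p-value uses the
#' add-one rule, p = (1 + #\{perm |t| >= obs |t|\}) / (1 + n_perm), so it is
#' never zero and is deterministic given the seed.
#'
#' Subject order is part of the input contract: the permutation stream is
#' applied to the rows as given, so callers wanting order invariance must
#' canonicalise row order first (as [assoc_scan()] does by subject id).
#'
#' @inheritParams fit_snp_model
#' @param n_perm number of permutations (default 10,000).
#' @param seed integer seed for the permutation stream.
#' @param permute which column to permute, "phenotype" (default) or
#'   "genotype".
#' @return list: p_empirical, observed (the [fit_snp_model()] result),
#'   n_perm, seed.
#' @export
permutation_empirical_p <- function(y, snp_calls, age, sex,
                                    n_perm = 10000, seed = 1,
                                    permute = c("phenotype", "genotype")) {
  permute <- match.arg(permute)
  if (!.is_count(n_perm) || n_perm < 1) stop("'n_perm' must be a positive count")
  if (n_perm < 100) warning("n_perm < 100: empirical p-values are coarse")
  obs <- fit_snp_model(y, snp_calls, age, sex)
  if (isTRUE(obs$untestable)) {
    stop("SNP is constant after dropping missing calls; no permutation test")
  }
  if (is.character(sex) || is.factor(sex)) {
    sex <- .as_numeric_column(data.frame(sex = sex, stringsAsFactors = FALSE),
                              "sex")
  }
  keep <- complete.cases(y, snp_calls, age, sex)
  y <- y[keep]; snp <- as.numeric(snp_calls[keep])
  age <- age[keep]; sex <- sex[keep]
  n <- length(y)
  X <- cbind(1, snp, age, sex)
  Qf <- qr.Q(qr(X))
  ## Frisch-Waugh: residualise the permuted column on the fixed remainder,
  ## then compute every permuted t in one set of matrix products.
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  if (permute == "phenotype") {
    Z <- X[, -2, drop = FALSE]
    Qz <- qr.Q(qr(Z))
    sres <- snp - Qz %*% crossprod(Qz, snp)
    sxx <- sum(sres^2)
    Y <- matrix(y[P], n, n_perm)
    betas <- drop(crossprod(sres, Y)) / sxx
    rss <- colSums(Y^2) - colSums(crossprod(Qf, Y)^2)
    t_perm <- betas / sqrt((rss / (n - 4)) / sxx)
  } else {
    Z <- X[, -2, drop = FALSE]
    Qz <- qr.Q(qr(Z))
    yres <- y - Qz %*% crossprod(Qz, y)
    S <- matrix(snp[P], n, n_perm)
    Sres <- S - Qz %*% crossprod(Qz, S)
    sxx <- colSums(Sres^2)
    betas <- drop(crossprod(yres, Sres)) / sxx
    rss <- sum(yres^2) - betas^2 * sxx
    t_perm <- betas / sqrt((rss / (n - 4)) / sxx)
  }
  exceed <- sum(abs(t_perm) >= abs(obs$t))
  list(p_empirical = (1 + exceed) / (1 + n_perm), observed = obs,
       n_perm = n_perm, seed = seed)
}

#' Association scan over phenotypes and candidate SNPs
#'
#' Runs the covariate-adjusted additive model with permutation empirical
#' p-values for every (phenotype, SNP) combination.  Rows are aligned and
#' canonicalised by subject id before any random draw, and every
#' combination gets an independent permutation stream derived from the
#' master seed, so the scan is invariant to input row order and
#' reproducible.
#'
#' @param phenotypes data.frame with a `subject_id` column plus one column
#'   per phenotype to scan (e.g. significant node degree centralities and
#'   `mds_updrs`).
#' @param genotypes a [genotype_matrix()].
#' @param covariates data.frame with subject_id, age, sex.
#' @param candidate_snps SNP ids to test (duplicates dropped with warning).
#' @param n_perm permutations per combination.
#' @param seed master seed.
#' @return data.frame, one row per (phenotype, SNP), sorted by phenotype
#'   then empirical p-value: phenotype, gene_label, snp_id, bp,
#'   minor_allele, beta, se, t, p_nominal, p_empirical, n, n_perm, seed.
#' @export
assoc_scan <- function(phenotypes, genotypes, covariates, candidate_snps,
                       n_perm = 10000, seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (length(candidate_snps) == 0L) stop("'candidate_snps' must be non-empty")
  if (anyDuplicated(candidate_snps)) {
    warning("duplicate candidate SNP ids dropped")
    candidate_snps <- unique(candidate_snps)
  }
  missing_snps <- setdiff(candidate_snps, genotypes$snps$snp_id)
  if (length(missing_snps)) {
    stop("candidate SNPs absent from panel: ",
         paste(missing_snps, collapse = ", "))
  }
  ids <- sort(genotypes$subjects)
  ids <- ids[ids %in% phenotypes$subject_id & ids %in% covariates$subject_id]
  pin <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
  cov <- covariates[match(ids, covariates$subject_id), , drop = FALSE]
  calls <- genotypes$calls[ids, , drop = FALSE]
  pheno_names <- setdiff(names(phenotypes), "subject_id")
  combos <- expand.grid(snp = candidate_snps, phenotype = pheno_names,
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    ph <- combos$phenotype[r]; sid <- combos$snp[r]
    sub_seed <- derive_seed(seed, paste("assoc", ph, sid))
    meta <- genotypes$snps[genotypes$snps$snp_id == sid, ]
    snp <- calls[, sid]
    fit <- fit_snp_model(pin[[ph]], snp, cov$age, cov$sex)
    if (isTRUE(fit$untestable)) {
      p_emp <- NA_real_
    } else {
      p_emp <- permutation_empirical_p(pin[[ph]], snp, cov$age, cov$sex,
                                       n_perm = n_perm,
                                       seed = sub_seed)$p_empirical
    }
    data.frame(phenotype = ph,
               gene_label = meta$gene_label %||% NA_character_,
               snp_id = sid, bp = meta$bp %||% NA_integer_,
               minor_allele = meta$minor_allele,
               beta = fit$beta, se = fit$se, t = fit$t,
               p_nominal = fit$p, p_empirical = p_emp, n = fit$n,
               n_perm = n_perm, seed = sub_seed,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(match(res$phenotype, pheno_names), res$p_empirical), ]
  rownames(res) <- NULL
  res
}
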