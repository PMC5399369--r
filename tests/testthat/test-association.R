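test_that("additive SNP model recovers noiseless effects and matches lm", {
  set.seed(5)
  n <- 60
  snp <- sample(0:2, n, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  age <- rnorm(n, 62, 9)
  sex <- rbinom(n, 1, 0.5)
  y <- 1 + 2 * snp + 0.1 * age - 0.5 * sex
  fit <- fit_snp_model(y, snp, age, sex)
  expect_equal(fit$beta, 2, tolerance = 1e-10)

  # algebraic oracle: normal-equations solve on a noisy instance
  y2 <- y + rnorm(n)
  fit2 <- fit_snp_model(y2, snp, age, sex)
  X <- cbind(1, snp, age, sex)
  beta_ne <- solve(crossprod(X), crossprod(X, y2))
  sigma2 <- sum((y2 - X %*% beta_ne)^2) / (n - 4)
  se_ne <- sqrt(diag(solve(crossprod(X))) * sigma2)[2]
  expect_equal(fit2$beta, beta_ne[2], tolerance = 1e-8)
  expect_equal(fit2$se, unname(se_ne), tolerance = 1e-8)
  sm <- summary(lm(y2 ~ snp + age + sex))$coefficients
  expect_equal(fit2$t, sm["snp", "t value"], tolerance = 1e-8)
  expect_equal(fit2$p, sm["snp", "Pr(>|t|)"], tolerance = 1e-8)

  # missing calls are dropped per SNP; constant SNPs are flagged untestable
  snp_na <- snp; snp_na[1:5] <- NA
  expect_equal(fit_snp_model(y2, snp_na, age, sex)$n, n - 5)
  const <- fit_snp_model(y2, rep(1, n), age, sex)
  expect_true(const$untestable)
  expect_true(is.na(const$p))
  expect_error(fit_snp_model(y2[1:4], snp[1:4], age[1:4], sex[1:4]),
               "complete cases")
})

test_that("nominal p-values are calibrated under the null", {
  set.seed(6)
  reps <- 2000
  hits <- vapply(seq_len(reps), function(r) {
    n <- 50
    snp <- sample(0:2, n, replace = TRUE, prob = c(0.49, 0.42, 0.09))
    fit_snp_model(rnorm(n), snp, rnorm(n, 60, 8), rbinom(n, 1, 0.5))$p < 0.05
  }, logical(1))
  mc <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(hits) - 0.05), 3 * mc)
})

test_that("permutation empirical p obeys the add-one rule and its bounds", {
  set.seed(7)
  n <- 80
  snp <- sample(0:2, n, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  age <- rnorm(n, 62, 9); sex <- rbinom(n, 1, 0.5)
  # a planted standardized effect of 1 is essentially never exceeded
  y <- snp / sd(snp) + rnorm(n)
  pe <- permutation_empirical_p(y, snp, age, sex, n_perm = 1000, seed = 8)
  expect_equal(pe$p_empirical, 1 / 1001)
  # determinism given the seed
  pe2 <- permutation_empirical_p(y, snp, age, sex, n_perm = 1000, seed = 8)
  expect_identical(pe$p_empirical, pe2$p_empirical)
  # the empirical p can never be zero and never exceeds 1
  ynull <- rnorm(n)
  pn <- permutation_empirical_p(ynull, snp, age, sex, n_perm = 200, seed = 9)
  expect_gte(pn$p_empirical, 1 / 201)
  expect_lte(pn$p_empirical, 1)
  expect_warning(
    permutation_empirical_p(ynull, snp, age, sex, n_perm = 50, seed = 1),
    "coarse")
  # genotype-label permutation is available as the alternative null
  pg <- permutation_empirical_p(y, snp, age, sex, n_perm = 500, seed = 10,
                                permute = "genotype")
  expect_lte(pg$p_empirical, 0.05)
})

test_that("stronger planted effects never raise the median empirical p", {
  med_p <- vapply(c(0, 0.4, 0.8), function(eff) {
    ps <- vapply(1:15, function(s) {
      set.seed(1000 + s)
      n <- 60
      snp <- sample(0:2, n, replace = TRUE, prob = c(0.49, 0.42, 0.09))
      y <- eff * snp + rnorm(n)
      permutation_empirical_p(y, snp, rnorm(n, 60, 8), rbinom(n, 1, 0.5),
                              n_perm = 300, seed = s)$p_empirical
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_true(all(diff(med_p) <= 0))
})

test_that("assoc_scan is row-order invariant, deduplicated and well-formed", {
  co <- make_feature_cohort(seed = 51)
  truth <- default_true_model()
  ph <- generate_phenotype(list(subjects = co$subjects,
                                features = co$features), truth, seed = 52)
  phen <- data.frame(subject_id = co$subjects$subject_id,
                     thalamus = co$features$thalamus,
                     mds_updrs = ph$mds_updrs)
  cov <- co$subjects[, c("subject_id", "age", "sex")]
  res <- assoc_scan(phen, co$genotypes, cov,
                    c("rs9346876", "rs363611"), n_perm = 300, seed = 3)
  expect_equal(nrow(res), 4)
  expect_true(all(res$p_empirical >= 1 / 301 & res$p_empirical <= 1))
  # sorted by phenotype then empirical p
  expect_equal(unique(res$phenotype), c("thalamus", "mds_updrs"))
  for (phn in unique(res$phenotype)) {
    expect_false(is.unsorted(res$p_empirical[res$phenotype == phn]))
  }

  # shuffling input subject order changes nothing
  ord <- sample(nrow(phen))
  res_shuf <- assoc_scan(phen[ord, ], co$genotypes, cov[rev(ord), ],
                         c("rs9346876", "rs363611"), n_perm = 300, seed = 3)
  expect_equal(res, res_shuf)

  expect_warning(
    res_dup <- assoc_scan(phen, co$genotypes, cov,
                          c("rs363611", "rs363611"), n_perm = 200, seed = 1),
    "duplicate")
  expect_equal(nrow(res_dup), 2)

  expect_error(assoc_scan(phen, co$genotypes, cov, character(0)), "non-empty")
  expect_error(assoc_scan(phen, co$genotypes, cov, "rs000"), "absent")

  # one phenotype x one SNP -> exactly one row
  one <- assoc_scan(phen[, c("subject_id", "mds_updrs")], co$genotypes, cov,
                    "rs363611", n_perm = 200, seed = 2)
  expect_equal(nrow(one), 1)
})

test_that("a planted genotype-connectivity effect tops the scan", {
  hits <- vapply(1:20, function(s) {
    b <- simulate_cohort(n_hc = 40, n_pd = 40, fibers_per_pair = 4,
                         snp_dc_effects = list(thalamus = c(rs1473533 = 0.002)),
                         seed = 7000 + s)
    phen <- data.frame(subject_id = b$subjects$subject_id,
                       thalamus = b$dc$thalamus)
    res <- assoc_scan(phen, b$genotypes,
                      b$subjects[, c("subject_id", "age", "sex")],
                      b$genotypes$snps$snp_id, n_perm = 200,
                      seed = derive_seed(7000 + s, "scan"))
    res$snp_id[which.min(res$p_empirical)] == "rs1473533"
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})
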