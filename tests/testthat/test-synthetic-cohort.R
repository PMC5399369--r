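test_that("generate_subjects produces balanced, matched, reproducible cohorts", {
  s <- generate_subjects(40, 40, seed = 1)
  expect_equal(nrow(s), 80)
  expect_equal(as.integer(table(s$group)[c("HC", "PD")]), c(40L, 40L))
  expect_false(anyDuplicated(s$subject_id) > 0)
  expect_true(all(is.na(s$mds_updrs)))
  expect_true(all(s$gds >= 0 & s$gds <= 15))
  expect_true(all(s$moca >= 20 & s$moca <= 30))

  expect_identical(generate_subjects(2, 2, seed = 7),
                   generate_subjects(2, 2, seed = 7))
  expect_error(generate_subjects(0, 40), "counts")
  expect_error(generate_subjects(40, 1), "counts")

  # age is drawn from the same distribution in both groups: the two-sample
  # t-test should be non-significant in the vast majority of draws
  matched <- vapply(1:100, function(s) {
    tab <- generate_subjects(40, 40, seed = s)
    t.test(age ~ group, tab)$p.value > 0.05
  }, logical(1))
  expect_gte(mean(matched), 0.90)
})

test_that("generate_genotypes respects target MAF, HWE distortion and missingness", {
  subj <- generate_subjects(20, 20, seed = 1)
  mono <- data.frame(snp_id = "m1", minor_allele = "A", major_allele = "G",
                     target_maf = 0, hwe_f = 0, missing_rate = 0)
  g <- generate_genotypes(subj, mono, seed = 1)
  expect_true(all(g$calls == 0))

  bad <- transform(mono, target_maf = 0.6)
  expect_error(generate_genotypes(subj, bad, seed = 1), "target_maf")

  big <- generate_subjects(5000, 5000, seed = 2)
  panel <- data.frame(snp_id = "s1", minor_allele = "A", major_allele = "G",
                      target_maf = 0.3, hwe_f = 0, missing_rate = 0.10)
  gg <- generate_genotypes(big, panel, seed = 3)
  maf <- compute_maf(gg)
  expect_lt(abs(maf$maf - 0.3), 0.01)
  mr <- compute_missing_rates(gg)$snp$missing_rate
  expect_lt(abs(mr - 0.10), 0.01)

  # strong inbreeding-style distortion must be caught by the exact HWE test
  # at the quality-control threshold
  viol <- data.frame(snp_id = "v1", minor_allele = "A", major_allele = "G",
                     target_maf = 0.3, hwe_f = 0.8, missing_rate = 0)
  n1000 <- generate_subjects(500, 500, seed = 4)
  ps <- vapply(1:25, function(s) {
    hwe_test(generate_genotypes(n1000, viol, seed = s))$p_hwe
  }, numeric(1))
  expect_true(all(ps < 1e-6))
})

test_that("generate_streamlines hits degree-centrality targets and directions", {
  subj <- generate_subjects(40, 40, seed = 5)
  sl <- generate_streamlines(subj, seed = 5)
  dc <- cohort_degree_centrality(sl, subject_ids = subj$subject_id)
  is_hc <- subj$group == "HC"
  # published direction: pallidum lower in PD, associative/motor/thalamus higher
  expect_lt(mean(dc$pallidum[!is_hc]), mean(dc$pallidum[is_hc]))
  expect_gt(mean(dc$associative[!is_hc]), mean(dc$associative[is_hc]))
  expect_gt(mean(dc$motor[!is_hc]), mean(dc$motor[is_hc]))
  expect_gt(mean(dc$thalamus[!is_hc]), mean(dc$thalamus[is_hc]))

  # group means land near the configured targets
  targets <- default_dc_targets()
  for (nd in c("associative", "pallidum")) {
    for (grp in c("HC", "PD")) {
      tg <- targets[targets$node == nd & targets$group == grp, ]
      got <- mean(dc[[nd]][subj$group == grp])
      expect_lt(abs(got - tg$mean), 3 * tg$sd / sqrt(40))
    }
  }

  expect_error(
    generate_streamlines(subj, transform(default_dc_targets(),
                                         mean = mean - 1), seed = 1),
    "must be >= 0")

  # smoke case: one subject, one fiber per pair round-trips to finite
  # positive edge weights
  one <- generate_subjects(2, 2, seed = 9)[1, , drop = FALSE]
  sl1 <- generate_streamlines(one, seed = 9, fibers_per_pair = 1)
  cm <- build_connectivity(sl1)
  expect_true(all(is.finite(cm)))
  expect_true(all(cm[upper.tri(cm)] > 0))

  expect_identical(generate_streamlines(subj[1:4, ], seed = 3),
                   generate_streamlines(subj[1:4, ], seed = 3))
})

test_that("generate_phenotype realises the declared linear model", {
  b <- list(
    subjects = generate_subjects(10, 10, seed = 2),
    features = data.frame(x = 1:20, z = rep(c(0, 1), 10))
  )
  # noiseless limit: score equals intercept + the single term exactly
  noiseless <- list(intercept = 5, coefficients = c(x = 1), noise_sd = 1e-12)
  out <- generate_phenotype(b, noiseless, seed = 1)
  expect_equal(out$mds_updrs, 5 + b$features$x, tolerance = 1e-9)

  truth <- list(intercept = 1, coefficients = c("x:z" = 2), noise_sd = 0.5)
  out2 <- generate_phenotype(b, truth, seed = 3)
  expect_identical(out2, generate_phenotype(b, truth, seed = 3))
  expect_equal(unname(attr(out2, "design")[, "x:z"]),
               b$features$x * b$features$z)

  bad <- list(intercept = 0, coefficients = c(nope = 1), noise_sd = 1)
  expect_error(generate_phenotype(b, bad, seed = 1), "nope")

  # negative scores are clipped at zero and the clip count reported
  low <- list(intercept = -100, coefficients = c(x = 0.1), noise_sd = 1)
  out3 <- generate_phenotype(b, low, seed = 4)
  expect_true(all(out3$mds_updrs >= 0))
  expect_equal(attr(out3, "n_clipped"), 20)
})

test_that("refitting the generating model recovers planted coefficients", {
  co <- make_feature_cohort(seed = 31)
  truth <- default_true_model()
  bundle <- list(subjects = co$subjects, features = co$features)
  ph <- generate_phenotype(bundle, truth, seed = 32)
  fit <- fit_ols(ph$mds_updrs, co$features, names(truth$coefficients))
  est <- fit$coefficients[names(truth$coefficients)]
  se <- fit$se[names(truth$coefficients)]
  # every planted coefficient (including the SNPxSNP interaction) within 3 SE
  expect_true(all(abs(est - truth$coefficients) < 3 * se))
})

test_that("simulate_cohort components share one subject universe", {
  b <- simulate_cohort(n_hc = 10, n_pd = 10, fibers_per_pair = 4, seed = 6)
  ids <- b$subjects$subject_id
  expect_identical(b$genotypes$subjects, ids)
  expect_identical(b$dc$subject_id, ids)
  expect_true(all(b$streamlines$subject_id %in% ids))
  expect_true(all(b$subjects$mds_updrs >= 0))
  # every operand of every true-model term resolves to a feature column
  ops <- unique(unlist(strsplit(names(b$truth$coefficients), ":", fixed = TRUE)))
  expect_true(all(ops %in% names(b$features)))
})
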