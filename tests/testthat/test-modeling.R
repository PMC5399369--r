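test_that("build_design assembles intercept, interactions and site dummies", {
  dat <- data.frame(a = 1:5, b = c(2, 4, 6, 8, 10), ones = 1,
                    site = c(1, 1, 2, 3, 3), sex = c("M", "F", "M", "F", "M"))
  d0 <- build_design(dat, character(0))
  expect_equal(dim(d0$X), c(5, 1))
  expect_equal(unname(d0$X[, 1]), rep(1, 5))

  d1 <- build_design(dat, c("a", "ones:b"))
  expect_equal(unname(d1$X[, "ones:b"]), dat$b)

  # oracle loop: every interaction column equals the recomputed product
  set.seed(11)
  rnd <- as.data.frame(matrix(rnorm(40), 10))
  names(rnd) <- paste0("v", 1:4)
  terms <- c("v1", "v2", "v1:v2", "v2:v3", "v3:v4")
  dd <- build_design(rnd, terms)
  for (tm in grep(":", terms, value = TRUE)) {
    ops <- strsplit(tm, ":")[[1]]
    expect_equal(unname(dd$X[, tm]), rnd[[ops[1]]] * rnd[[ops[2]]])
  }

  ds <- build_design(dat, c("a", "site"))
  expect_equal(sum(ds$assign == 2), 2)  # 3 site levels -> 2 dummies
  expect_equal(unname(ds$X[, "site2"]), c(0, 0, 1, 0, 0))

  # declared character coding
  dsex <- build_design(dat, "sex")
  expect_equal(unname(dsex$X[, "sex"]), c(1, 0, 1, 0, 1))

  expect_error(build_design(dat, "missing_col"), "missing_col")
  expect_error(build_design(dat, "a:site"), "site")
})

test_that("fit_ols matches the algebra and refuses rank deficiency", {
  set.seed(12)
  n <- 50
  dat <- make_design_data(n, 3, 0, seed = 12)
  beta <- c(2, -1, 0.5)
  y_exact <- as.matrix(dat) %*% beta + 3
  m <- fit_ols(drop(y_exact), dat, names(dat))
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_lt(max(abs(m$residuals)), 1e-10)

  y <- drop(y_exact) + rnorm(n)
  m2 <- fit_ols(y, dat, names(dat))
  X <- cbind(1, as.matrix(dat))
  beta_pinv <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(m2$coefficients), unname(drop(beta_pinv)),
               tolerance = 1e-8)
  lmf <- summary(lm(y ~ sig1 + sig2 + sig3, dat))
  expect_equal(m2$adj_r_squared, lmf$adj.r.squared, tolerance = 1e-10)
  expect_equal(unname(m2$se), unname(lmf$coefficients[, "Std. Error"]),
               tolerance = 1e-8)
  expect_equal(m2$adj_r_squared,
               1 - (1 - m2$r_squared) * (n - 1) / (n - 3 - 1))
  expect_lte(m2$adj_r_squared, m2$r_squared)

  dat$dup <- dat$sig1
  expect_error(fit_ols(y, dat, c("sig1", "sig2", "dup")), "dup")
})

test_that("overall model p-value is calibrated on pure noise", {
  set.seed(13)
  hits <- vapply(1:1000, function(r) {
    dat <- as.data.frame(matrix(rnorm(40 * 3), 40))
    fit_ols(rnorm(40), dat, names(dat))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("sequential ANOVA decomposes variance exactly", {
  set.seed(14)
  n <- 60
  dat <- make_design_data(n, 4, 0, seed = 14)
  y <- 2 * dat$sig1 - dat$sig3 + rnorm(n)
  m <- fit_ols(y, dat, names(dat))
  an <- sequential_anova(m)
  # the decomposition identities
  expect_equal(sum(an$pct_explained), 100 * m$r_squared, tolerance = 1e-8)
  expect_equal(sum(an$sum_sq) + m$rss, m$ss_total, tolerance = 1e-8)
  # agreement with the reference sequential ANOVA
  ref <- anova(lm(y ~ sig1 + sig2 + sig3 + sig4, dat))
  expect_equal(an$sum_sq, ref[["Sum Sq"]][1:4], tolerance = 1e-8)
  expect_equal(an$f_statistic, ref[["F value"]][1:4], tolerance = 1e-8)
  expect_equal(an$p_value, ref[["Pr(>F)"]][1:4], tolerance = 1e-8)

  # orthogonal predictors: sequential SS do not depend on term order
  # columns mutually orthogonal and orthogonal to the intercept
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  orth_c <- as.data.frame(Q); names(orth_c) <- c("o1", "o2", "o3")
  y2 <- orth_c$o1 + 0.5 * orth_c$o3 + rnorm(n, 0, 0.3)
  a1 <- sequential_anova(fit_ols(y2, orth_c, c("o1", "o2", "o3")))
  a2 <- sequential_anova(fit_ols(y2, orth_c, c("o3", "o2", "o1")))
  expect_equal(sort(a1$sum_sq), sort(a2$sum_sq), tolerance = 1e-8)

  # single-term model: its share is the whole R-squared
  ms <- fit_ols(y, dat, "sig1")
  expect_equal(sequential_anova(ms)$pct_explained, 100 * ms$r_squared,
               tolerance = 1e-10)
})

test_that("backward stepwise removes noise, keeps signal, and is reproducible", {
  set.seed(15)
  dat <- make_design_data(80, 2, 3, seed = 15)
  y <- 1.5 * dat$sig1 + 1.2 * dat$sig2 + rnorm(80)
  m <- backward_stepwise(y, dat, names(dat))
  expect_true(all(c("sig1", "sig2") %in% m$terms))
  tr <- attr(m, "trace")
  expect_true(all(tr$p_after <= tr$p_before))

  m_again <- backward_stepwise(y, dat, names(dat))
  expect_identical(m$terms, m_again$terms)
  expect_identical(attr(m, "trace"), attr(m_again, "trace"))

  # all-noise start: the final model shrinks in a majority of draws
  shrank <- vapply(1:20, function(s) {
    datn <- make_design_data(80, 0, 6, seed = 200 + s)
    set.seed(300 + s)
    mn <- backward_stepwise(rnorm(80), datn, names(datn))
    length(mn$terms) < 6
  }, logical(1))
  expect_gt(mean(shrank), 0.5)

  # rank-deficient starts are pre-pruned with a warning
  dat$clone <- dat$sig1
  expect_warning(mp <- backward_stepwise(y, dat, names(dat)),
                 "rank-deficient")
  # exactly one of the two aliased columns survives pre-pruning
  expect_length(attr(mp, "initial_terms"), ncol(dat) - 1)
})

test_that("three-model construction prefers the combined feature set", {
  co <- make_feature_cohort(seed = 61)
  truth <- default_true_model()
  ph <- generate_phenotype(list(subjects = co$subjects,
                                features = co$features), truth, seed = 62)
  mods <- build_three_models(ph$mds_updrs, co$features,
                             imaging_features = c("motor", "thalamus",
                                                  "pallidum"),
                             snp_features = c("rs9346876", "rs363611"))
  expect_s3_class(mods, "pk_models")
  expect_equal(mods$comparison$model, c("A", "B", "C"))
  expect_gte(mods$C$adj_r_squared,
             max(mods$A$adj_r_squared, mods$B$adj_r_squared) - 0.02)

  expect_error(build_three_models(ph$mds_updrs, co$features,
                                  character(0), "rs363611"), "non-empty")

  # all-noise truth: apparent fit stays modest (backward selection on the
  # overall p inflates adj-R2 somewhat by construction) and cross-validated
  # error honestly recovers the noise scale
  noise_stats <- t(vapply(1:10, function(s) {
    con <- make_feature_cohort(seed = 600 + s)
    set.seed(700 + s)
    yn <- rnorm(80, 30, 8)
    mn <- suppressWarnings(build_three_models(
      yn, con$features, imaging_features = c("motor", "thalamus"),
      snp_features = c("rs9346876", "rs363611"), interaction_cap = 8))
    cv <- suppressWarnings(loocv_predict(yn, con$features, mn$C$terms))
    c(max(mn$comparison$adj_r_squared), cv$rmse)
  }, numeric(2)))
  expect_lt(median(noise_stats[, 1]), 0.25)
  expect_gt(median(noise_stats[, 2]), 0.85 * 8)
  expect_lt(median(noise_stats[, 2]), 1.3 * 8)
})

test_that("term-set assembly caps interactions and guards fittability", {
  ts <- make_term_set(c("f1", "f2", "f3"), covariates = c("age", "gds"),
                      n = 80, interaction_cap = 4)
  expect_equal(sum(grepl(":", ts)), 4)
  expect_equal(ts[1:5], c("f1", "f2", "f3", "age", "gds"))
  # feature x feature interactions enumerate first
  expect_equal(grep(":", ts, value = TRUE)[1:3],
               c("f1:f2", "f1:f3", "f2:f3"))
  # small n forces interactions out
  ts_small <- make_term_set(c("f1", "f2"), covariates = c("age", "gds"),
                            n = 16, interaction_cap = 10)
  expect_equal(sum(grepl(":", ts_small)), 1)
})

test_that("LOOCV matches the leverage closed form and is accurate when true", {
  set.seed(16)
  n <- 60
  dat <- make_design_data(n, 3, 0, seed = 16)
  y_exact <- drop(as.matrix(dat) %*% c(1, 2, -1)) + 4
  cv0 <- loocv_predict(y_exact, dat, names(dat))
  expect_lt(cv0$rmse, 1e-6)
  expect_gt(cv0$pearson_r, 0.999999)

  y <- y_exact + rnorm(n)
  cv <- loocv_predict(y, dat, names(dat))
  X <- cbind(1, as.matrix(dat))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  res <- y - X %*% solve(crossprod(X), crossprod(X, y))
  pred_loo <- y - res / (1 - diag(H))
  expect_equal(cv$predictions, drop(pred_loo), tolerance = 1e-8)
  expect_equal(cv$n_folds, n)
  expect_equal(length(cv$skipped_folds), 0)

  # a column that is non-degenerate only thanks to one subject makes that
  # fold rank deficient; it is skipped and reported
  dat2 <- dat; dat2$spike <- c(1, rep(0, n - 1))
  expect_warning(cv2 <- loocv_predict(y, dat2, names(dat2)), "skipped")
  expect_equal(cv2$skipped_folds, 1L)
})
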