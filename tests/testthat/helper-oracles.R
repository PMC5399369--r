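# Independent oracles used across tests.  Each deliberately takes a
# different computational route from the implementation it checks.

# Exact Hardy-Weinberg p-value by direct enumeration: every heterozygote
# count with the right parity, probabilities from the closed-form
# log-factorial expression (the implementation uses a ratio recurrence).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  logp <- vapply(hs, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) -
      lgamma(hom_common + 1) + h * log(2) +
      lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp)
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_Aa, hs)]
  sum(prob[prob <= p_obs * (1 + 1e-12)])
}

# A minimal data.frame of numeric predictors for modeling tests.
make_design_data <- function(n, p_signal, p_noise, seed) {
  set.seed(seed)
  dat <- as.data.frame(matrix(rnorm(n * (p_signal + p_noise)), n))
  names(dat) <- c(if (p_signal > 0) paste0("sig", seq_len(p_signal)),
                  if (p_noise > 0) paste0("noise", seq_len(p_noise)))
  dat
}

# Directly drawn degree-centrality features plus genotypes and covariates:
# the cheap stand-in for a full streamline-backed cohort in simulations
# where only the feature table matters.
make_feature_cohort <- function(seed, n_hc = 40, n_pd = 40) {
  subjects <- generate_subjects(n_hc, n_pd, seed = seed)
  genotypes <- generate_genotypes(subjects, default_snp_panel(),
                                  seed = seed + 1)
  targets <- default_dc_targets()
  set.seed(seed + 2)
  nodes <- unique(targets$node)
  dc <- sapply(nodes, function(nd) {
    tg <- targets[targets$node == nd, ]
    mu <- ifelse(subjects$group == "HC",
                 tg$mean[tg$group == "HC"], tg$mean[tg$group == "PD"])
    sg <- ifelse(subjects$group == "HC",
                 tg$sd[tg$group == "HC"], tg$sd[tg$group == "PD"])
    pmax(rnorm(nrow(subjects), mu, sg), 1e-4)
  })
  features <- cbind(as.data.frame(dc),
                    as.data.frame(genotypes$calls),
                    subjects[, c("group", "age", "sex", "handedness",
                                 "family_history", "gds", "moca", "site")])
  rownames(features) <- NULL
  list(subjects = subjects, genotypes = genotypes, features = features)
}

expect_no_na <- function(x) expect_false(anyNA(x))
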