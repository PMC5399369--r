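## Synthetic-cohort generator.
##
## The restricted clinical database behind this analysis cannot be shipped,
## so every downstream stage is exercised against a generated cohort with
## known ground truth: 40 HC + 40 PD subjects by default, a candidate SNP
## panel for PD-linked genes, streamline tables constructed backward from
## target degree-centrality distributions, and an MDS-UPDRS score generated
## from a declared linear model with SNPxSNP and imaging x SNP interactions.

#' Default candidate SNP panel
#'
#' Seven single-nucleotide polymorphisms in genes previously linked with
#' Parkinson's disease (PARK2, PARK7, SNCA, HtrA2, GIGYF2), with simulation
#' parameters: target minor-allele frequency, an inbreeding-style
#' Hardy-Weinberg distortion coefficient (`hwe_f`, 0 = equilibrium), and a
#' per-call missingness rate.  With `include_qc_failures = TRUE` the panel
#' is extended by simulated junk SNPs that violate each quality-control
#' criterion (low MAF, strong HWE distortion, high missingness), so that the
#' QC stage has planted positives to find.
#'
#' @param include_qc_failures add 3 low-MAF, 2 HWE-violating and 4
#'   high-missingness simulated SNPs.
#' @return data.frame, one row per SNP.
#' @export
default_snp_panel <- function(include_qc_failures = FALSE) {
  panel <- data.frame(
    snp_id       = c("rs6901583", "rs225103", "rs1473533", "rs9346876",
                     "rs9364608", "rs363611", "rs7421653"),
    gene_label   = c("PARK2", "PARK7", "SNCA", "PARK2", "PARK2", "HtrA2",
                     "GIGYF2"),
    chr          = c(6L, 1L, 4L, 6L, 6L, 2L, 2L),
    bp           = c(162543210L, 8042301L, 90735702L, 162032871L,
                     162034799L, 74759708L, 233711471L),
    minor_allele = c("C", "T", "T", "C", "G", "T", "G"),
    major_allele = c("A", "G", "A", "A", "T", "C", "A"),
    target_maf   = c(0.25, 0.30, 0.35, 0.30, 0.28, 0.32, 0.22),
    hwe_f        = 0,
    missing_rate = c(0, 0.01, 0, 0, 0.01, 0, 0),
    causal_role  = c("dc:associative", "dc:motor", "dc:thalamus",
                     "updrs", "none", "updrs+interaction",
                     "interaction"),
    stringsAsFactors = FALSE
  )
  if (include_qc_failures) {
    junk <- data.frame(
      snp_id       = sprintf("rs%07d", 9000001:9000009),
      gene_label   = "simulated",
      chr          = 22L,
      bp           = as.integer(seq(1e6, by = 5e4, length.out = 9)),
      minor_allele = "A",
      major_allele = "G",
      target_maf   = c(0.002, 0.003, 0.004, 0.30, 0.25, 0.30, 0.28, 0.32, 0.26),
      hwe_f        = c(0, 0, 0, 0.8, 0.8, 0, 0, 0, 0),
      missing_rate = c(0, 0, 0, 0, 0, 0.15, 0.20, 0.15, 0.25),
      causal_role  = "qc_failure",
      stringsAsFactors = FALSE
    )
    panel <- rbind(panel, junk)
  }
  panel
}

#' Generate a subject table
#'
#' Draws a demographically matched cohort of healthy controls (HC) and PD
#' patients.  Age and sex are drawn from the same distributions for both
#' groups (the study design matches groups on demographics), alongside
#' handedness, family history, Geriatric Depression Scale (GDS, 0-15),
#' Montreal Cognitive Assessment (MoCA, 20-30) and acquisition site (1-9).
#' The MDS-UPDRS column is initialised to NA and filled later by
#' [generate_phenotype()].
#'
#' @param n_hc,n_pd group sizes (default 40 + 40).
#' @param seed integer seed; output is a pure function of the arguments.
#' @param age_mean,age_sd age distribution (years).
#' @param n_sites number of acquisition sites.
#' @return data.frame with one row per subject.
#' @export
generate_subjects <- function(n_hc = 40, n_pd = 40, seed = 1,
                              age_mean = 62, age_sd = 9, n_sites = 9) {
  if (!.is_count(n_hc) || !.is_count(n_pd) || n_hc < 2 || n_pd < 2) {
    stop("'n_hc' and 'n_pd' must be integer counts >= 2")
  }
  set.seed(seed)
  n <- n_hc + n_pd
  group <- c(rep("HC", n_hc), rep("PD", n_pd))
  balanced_sex <- function(k) sample(rep(c("M", "F"), length.out = k))
  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = group,
    age = round(pmin(pmax(rnorm(n, age_mean, age_sd), 35), 85), 1),
    sex = c(balanced_sex(n_hc), balanced_sex(n_pd)),
    handedness = sample(c("R", "L"), n, replace = TRUE, prob = c(0.9, 0.1)),
    family_history = rbinom(n, 1, 0.2),
    gds = pmin(pmax(round(rnorm(n, 4, 2.5)), 0), 15),
    moca = pmin(pmax(round(rnorm(n, 26.5, 2)), 20), 30),
    site = sample(seq_len(n_sites), n, replace = TRUE),
    mds_updrs = NA_real_,
    stringsAsFactors = FALSE
  )
  subjects
}

#' Generate additive-coded genotypes for a cohort
#'
#' Each SNP is drawn independently.  Under equilibrium the three genotype
#' classes follow Hardy-Weinberg proportions at the SNP's target minor-allele
#' frequency q: (1-q)^2, 2q(1-q), q^2.  A nonzero inbreeding-style
#' coefficient f distorts these to (1-q)^2 + fq(1-q), 2q(1-q)(1-f),
#' q^2 + fq(1-q), shifting mass between heterozygotes and homozygotes while
#' preserving the allele frequency; missing calls are injected at the SNP's
#' `missing_rate`.
#'
#' @param subjects a subject table from [generate_subjects()].
#' @param panel a SNP panel (see [default_snp_panel()]); columns `target_maf`,
#'   `hwe_f`, `missing_rate` control the draw.
#' @param seed integer seed.
#' @return a [genotype_matrix()].
#' @export
generate_genotypes <- function(subjects, panel, seed = 1) {
  if (!is.data.frame(panel) || nrow(panel) == 0L) {
    stop("'panel' must be a non-empty data.frame")
  }
  if (any(panel$target_maf < 0 | panel$target_maf > 0.5)) {
    stop("'target_maf' must lie in [0, 0.5]")
  }
  set.seed(seed)
  n <- nrow(subjects)
  m <- nrow(panel)
  calls <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    q <- panel$target_maf[j]
    f <- if ("hwe_f" %in% names(panel)) panel$hwe_f[j] else 0
    p_het <- 2 * q * (1 - q) * (1 - f)
    p_aa <- q^2 + f * q * (1 - q)
    p_AA <- 1 - p_het - p_aa
    probs <- c(p_AA, p_het, p_aa)
    if (any(probs < -1e-12)) {
      stop("hwe_f = ", f, " at target_maf = ", q,
           " yields negative genotype frequencies")
    }
    probs <- pmax(probs, 0)
    calls[, j] <- sample(0:2, n, replace = TRUE, prob = probs)
    mr <- if ("missing_rate" %in% names(panel)) panel$missing_rate[j] else 0
    if (mr > 0) calls[rbinom(n, 1, mr) == 1, j] <- NA_integer_
  }
  genotype_matrix(subjects$subject_id, panel, calls)
}

#' Default degree-centrality targets per node and group
#'
#' Group-level means and standard deviations of weighted degree centrality
#' for the eight circuit nodes.  The four nodes with published group
#' differences carry those values (associative, motor and thalamus higher in
#' PD; pallidum lower in PD); the remaining four nodes are given plausible
#' magnitudes with no group difference.
#'
#' @return data.frame with columns node, group, mean, sd.
#' @export
default_dc_targets <- function() {
  tab <- rbind(
    c("associative",      0.017, 0.004, 0.019, 0.004),
    c("motor",            0.012, 0.003, 0.015, 0.003),
    c("thalamus",         0.007, 0.002, 0.008, 0.002),
    c("pallidum",         0.006, 0.001, 0.005, 0.001),
    c("caudate",          0.010, 0.002, 0.010, 0.002),
    c("putamen",          0.011, 0.003, 0.011, 0.003),
    c("limbic",           0.014, 0.003, 0.014, 0.003),
    c("substantia_nigra", 0.004, 0.001, 0.004, 0.001)
  )
  data.frame(
    node = rep(tab[, 1], each = 2),
    group = rep(c("HC", "PD"), times = nrow(tab)),
    mean = as.numeric(t(tab[, c(2, 4)])),
    sd = as.numeric(t(tab[, c(3, 5)])),
    stringsAsFactors = FALSE
  )
}

#' Default per-allele SNP effects on node degree centrality
#'
#' Modest additive shifts of a node's degree centrality per copy of the
#' minor allele, used by [simulate_cohort()] to plant genotype-connectivity
#' associations for the association stage to recover.
#'
#' @return named list: node -> named numeric vector of per-allele effects.
#' @export
default_snp_dc_effects <- function() {
  list(
    associative = c(rs6901583 = 0.0015),
    motor       = c(rs225103 = 0.0010),
    thalamus    = c(rs1473533 = 0.0008)
  )
}

## Symmetric Sinkhorn balancing: given positive target row sums d, find a
## symmetric nonnegative matrix with zero diagonal whose row sums equal d.
.balance_edges <- function(d, tol = 1e-13, max_iter = 1000L) {
  k <- length(d)
  W <- outer(d, d)
  diag(W) <- 0
  for (it in seq_len(max_iter)) {
    rs <- rowSums(W)
    if (max(abs(rs - d)) < tol) break
    s <- sqrt(d / rs)
    W <- W * outer(s, s)
    diag(W) <- 0
  }
  ## one asymmetric-free polish: scale rows then resymmetrise
  rs <- rowSums(W)
  if (max(abs(rs - d)) >= tol) {
    W <- W * (d / rs)
    W <- (W + t(W)) / 2
  }
  W
}

#' Generate per-subject streamline tables from degree-centrality targets
#'
#' Works backward from the quantity that matters downstream: for each
#' subject, node degree centralities are drawn from the group's target
#' normal distribution (truncated at a small positive floor), split into a
#' symmetric zero-diagonal edge-weight matrix with exactly those row sums,
#' and each edge weight is then realised as a set of fiber records (lengths
#' in mm, per-fiber FA in (0,1)) whose fiber-density edge weight — mean FA
#' times 2/(S_i+S_j) times the sum of reciprocal lengths — reproduces the
#' target edge exactly.
#'
#' @param subjects subject table.
#' @param dc_targets data.frame as [default_dc_targets()]; must cover all
#'   atlas nodes for both groups, with non-negative means.
#' @param seed integer seed.
#' @param atlas region atlas from [roi_atlas()].
#' @param fibers_per_pair fiber records drawn per connected region pair.
#' @param dc_shift optional numeric matrix (subjects x nodes, columns named
#'   by node) of additive per-subject shifts applied to the drawn degree
#'   centralities before edge construction; used to plant SNP effects.
#' @return data.frame with columns subject_id, region_i, region_j, fiber_id,
#'   length_mm, mean_fa.
#' @export
generate_streamlines <- function(subjects, dc_targets = default_dc_targets(),
                                 seed = 1, atlas = roi_atlas(),
                                 fibers_per_pair = 8, dc_shift = NULL) {
  nodes <- atlas$region
  need <- expand.grid(node = nodes, group = c("HC", "PD"),
                      stringsAsFactors = FALSE)
  key <- paste(dc_targets$node, dc_targets$group)
  if (!all(paste(need$node, need$group) %in% key)) {
    stop("'dc_targets' must cover all ", length(nodes),
         " atlas nodes for both groups")
  }
  if (any(dc_targets$mean < 0)) stop("degree-centrality target means must be >= 0")
  set.seed(seed)
  k <- length(nodes)
  mu <- matrix(0, 2, k, dimnames = list(c("HC", "PD"), nodes))
  sg <- mu
  for (r in seq_len(nrow(dc_targets))) {
    mu[dc_targets$group[r], dc_targets$node[r]] <- dc_targets$mean[r]
    sg[dc_targets$group[r], dc_targets$node[r]] <- dc_targets$sd[r]
  }
  areas <- setNames(atlas$surface_area_mm2, atlas$region)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  out <- vector("list", nrow(subjects))
  for (s in seq_len(nrow(subjects))) {
    grp <- subjects$group[s]
    d <- rnorm(k, mu[grp, ], sg[grp, ])
    if (!is.null(dc_shift)) {
      d <- d + dc_shift[s, nodes]
    }
    d <- pmax(d, 1e-4)
    W <- .balance_edges(d)
    np <- nrow(pairs)
    nf <- fibers_per_pair
    fa <- matrix(pmin(pmax(rnorm(np * nf, rep(runif(np, 0.40, 0.60), each = nf),
                                 0.05), 0.05), 0.95), nf, np)
    raw_len <- matrix(rlnorm(np * nf, log(40), 0.25), nf, np)
    recs <- vector("list", np)
    for (pidx in seq_len(np)) {
      i <- pairs[pidx, 1]; j <- pairs[pidx, 2]
      w <- W[i, j]
      if (w <= 0) next
      mfa <- mean(fa[, pidx])
      need_invlen <- w * (areas[i] + areas[j]) / (2 * mfa)
      lens <- raw_len[, pidx] * (sum(1 / raw_len[, pidx]) / need_invlen)
      recs[[pidx]] <- data.frame(
        subject_id = subjects$subject_id[s],
        region_i = nodes[i], region_j = nodes[j],
        fiber_id = seq_len(nf), length_mm = lens, mean_fa = fa[, pidx],
        stringsAsFactors = FALSE
      )
    }
    out[[s]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default true generating model for the clinical score
#'
#' The MDS-UPDRS is generated as a linear combination of degree centralities
#' of three nodes, additive codes of two PD-linked SNPs, demographic and
#' cognitive covariates, and two two-way interactions (a SNP x SNP pair and
#' an imaging x SNP pair), plus Gaussian noise.  Coefficient magnitudes are
#' scaled to the units of each column (degree centralities are of order
#' 0.01, so their coefficients are large) and the noise standard deviation
#' is chosen so the true model explains roughly 70% of score variance at
#' n = 80.
#'
#' @return list with `intercept`, named `coefficients` (interaction terms use
#'   "a:b" keys), and `noise_sd`.
#' @export
default_true_model <- function() {
  list(
    intercept = 30,
    coefficients = c(
      motor = 600, thalamus = 900, pallidum = -2000,
      rs9346876 = 3, rs363611 = 3,
      "rs9346876:rs363611" = 3,
      "thalamus:rs363611" = 500,
      gds = 0.8, sex = 2, age = 0.15
    ),
    noise_sd = 6
  )
}

#' Generate MDS-UPDRS scores from a declared true model
#'
#' Builds the realized design matrix from the cohort bundle's feature table
#' (degree centralities, genotypes, covariates), computes
#' intercept + X beta + Normal(0, noise_sd), and clips negative scores at 0.
#' The realized design, the truth specification and the clip count are
#' attached so parameter-recovery tests can refit the exact generating form.
#'
#' @param bundle a cohort bundle from [simulate_cohort()] or any list with
#'   `subjects` and a `features` data.frame containing every term column.
#' @param truth a true-model specification, see [default_true_model()].
#' @param seed integer seed for the noise draw.
#' @return the subject table with `mds_updrs` filled; attributes
#'   `design` (realized design matrix), `truth`, and `n_clipped`.
#' @export
generate_phenotype <- function(bundle, truth = default_true_model(), seed = 1) {
  feats <- bundle$features
  stopifnot(is.data.frame(feats))
  cf <- truth$coefficients
  if (is.null(truth$noise_sd) || truth$noise_sd < 0) {
    stop("'noise_sd' must be non-negative")
  }
  n <- nrow(feats)
  X <- matrix(0, n, length(cf), dimnames = list(NULL, names(cf)))
  for (term in names(cf)) {
    ops <- strsplit(term, ":", fixed = TRUE)[[1]]
    col <- rep(1, n)
    for (op in ops) {
      if (!op %in% names(feats)) {
        stop("true-model term '", term, "' refers to unknown column '",
             op, "'")
      }
      col <- col * .as_numeric_column(feats, op)
    }
    if (anyNA(col)) {
      stop("true-model term '", term, "' has missing values in its column(s)")
    }
    X[, term] <- col
  }
  set.seed(seed)
  eps <- rnorm(n, 0, truth$noise_sd)
  y <- truth$intercept + drop(X %*% cf) + eps
  n_clipped <- sum(y < 0)
  y <- pmax(y, 0)
  subjects <- bundle$subjects
  subjects$mds_updrs <- y
  attr(subjects, "design") <- X
  attr(subjects, "truth") <- truth
  attr(subjects, "n_clipped") <- n_clipped
  subjects
}

#' Simulate a complete synthetic cohort
#'
#' End-to-end generator: subjects, genotypes, streamline tables (with
#' planted SNP effects on node degree centrality), per-subject connectivity
#' and degree centrality, and the clinical score from the declared true
#' model.  Each component uses an independent sub-seed derived from the
#' master seed, so the whole bundle is a pure function of its arguments.
#'
#' @param n_hc,n_pd group sizes.
#' @param panel SNP panel (see [default_snp_panel()]).
#' @param dc_targets degree-centrality targets (see [default_dc_targets()]).
#' @param truth true clinical-score model (see [default_true_model()]).
#' @param snp_dc_effects planted SNP effects on node degree centrality
#'   (see [default_snp_dc_effects()]); NULL for none.
#' @param atlas region atlas.
#' @param fibers_per_pair fibers per connected region pair.
#' @param seed master integer seed.
#' @return a cohort bundle: list with `subjects`, `genotypes`, `streamlines`,
#'   `dc` (subjects x nodes degree-centrality data.frame), `features`
#'   (dc + genotype codes + covariates), `truth`, and `atlas`.
#' @export
simulate_cohort <- function(n_hc = 40, n_pd = 40,
                            panel = default_snp_panel(),
                            dc_targets = default_dc_targets(),
                            truth = default_true_model(),
                            snp_dc_effects = default_snp_dc_effects(),
                            atlas = roi_atlas(), fibers_per_pair = 8,
                            seed = 1) {
  subjects <- generate_subjects(n_hc, n_pd, seed = derive_seed(seed, "subjects"))
  genotypes <- generate_genotypes(subjects, panel,
                                  seed = derive_seed(seed, "genotypes"))
  dc_shift <- NULL
  if (!is.null(snp_dc_effects) && length(snp_dc_effects)) {
    dc_shift <- matrix(0, nrow(subjects), nrow(atlas),
                       dimnames = list(subjects$subject_id, atlas$region))
    for (node in names(snp_dc_effects)) {
      for (snp in names(snp_dc_effects[[node]])) {
        calls <- genotypes$calls[, snp]
        calls[is.na(calls)] <- 0L
        dc_shift[, node] <- dc_shift[, node] +
          snp_dc_effects[[node]][[snp]] * calls
      }
    }
  }
  streamlines <- generate_streamlines(
    subjects, dc_targets, seed = derive_seed(seed, "streamlines"),
    atlas = atlas, fibers_per_pair = fibers_per_pair, dc_shift = dc_shift
  )
  dc <- cohort_degree_centrality(streamlines, atlas, subjects$subject_id)
  features <- cbind(
    dc[, atlas$region, drop = FALSE],
    as.data.frame(genotypes$calls, stringsAsFactors = FALSE),
    subjects[, c("group", "age", "sex", "handedness", "family_history",
                 "gds", "moca", "site")]
  )
  bundle <- list(subjects = subjects, genotypes = genotypes,
                 streamlines = streamlines, dc = dc, features = features,
                 truth = truth, atlas = atlas)
  bundle$subjects <- generate_phenotype(bundle, truth,
                                        seed = derive_seed(seed, "phenotype"))
  bundle$features$mds_updrs <- bundle$subjects$mds_updrs
  bundle
}
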