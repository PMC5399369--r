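## End-to-end orchestration: simulate -> genotype QC -> connectome ->
## group tests -> association -> three-model construction -> LOOCV, driven
## by a single configuration and a single master seed.

#' Default pipeline configuration
#'
#' Collects every tunable of the pipeline in one list: sample sizes, QC
#' thresholds, the group-test alpha, permutation count, interaction cap and
#' master seed.  The SNP panel used by the default configuration includes
#' planted quality-control failures so the QC stage is exercised.
#'
#' @param seed master integer seed.
#' @param n_hc,n_pd group sizes.
#' @param maf_min,hwe_min_p,miss_max SNP QC thresholds.
#' @param alpha corrected significance level for group tests and the
#'   association-feature cut.
#' @param n_perm permutations per association test.
#' @param interaction_cap maximum interaction terms per model.
#' @param mds_k dimensions of the population-structure embedding.
#' @param min_features minimum number of imaging / SNP features carried
#'   into the models; when fewer reach significance the top-ranked ones are
#'   used so the models stay constructible.
#' @param fibers_per_pair streamlines per connected region pair.
#' @param include_qc_failures plant QC-violating SNPs in the panel.
#' @return a named configuration list.
#' @export
pipeline_config <- function(seed = 1, n_hc = 40, n_pd = 40,
                            maf_min = 0.01, hwe_min_p = 1e-6,
                            miss_max = 0.05, alpha = 0.05, n_perm = 10000,
                            interaction_cap = 16, mds_k = 4,
                            min_features = 2, fibers_per_pair = 8,
                            include_qc_failures = TRUE) {
  list(seed = seed, n_hc = n_hc, n_pd = n_pd, maf_min = maf_min,
       hwe_min_p = hwe_min_p, miss_max = miss_max, alpha = alpha,
       n_perm = n_perm, interaction_cap = interaction_cap, mds_k = mds_k,
       min_features = min_features, fibers_per_pair = fibers_per_pair,
       include_qc_failures = include_qc_failures)
}

.config_fingerprint <- function(config) {
  canon <- config[order(names(config))]
  txt <- jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full imaging-genetics pipeline
#'
#' Executes every stage in dependency order on a synthetic cohort: cohort
#' simulation, SNP quality control with IBS/MDS population-structure
#' assessment, per-subject connectome construction with degree
#' centralities, Bonferroni-corrected group comparisons, the
#' permutation-based association scan of significant node centralities and
#' MDS-UPDRS, construction of the three stepwise regression models, and
#' leave-one-out cross-validation of each.  All outputs are written as
#' plain-text tables under `out_dir` together with a run manifest (config
#' snapshot, package version, per-stage seeds, output checksums, stage
#' timings and the fiber-density formula variant in use).
#'
#' With `cache = TRUE`, a previous run in `out_dir` whose manifest matches
#' the configuration fingerprint and whose output checksums still verify is
#' reused instead of recomputed.
#'
#' @param config configuration list from [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param cache reuse a verified previous run.
#' @return invisibly, a list with the manifest and the in-memory stage
#'   results (bundle, qc, dc_tests, association, models, cv).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, cache = FALSE) {
  stopifnot(is.list(config), !missing(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- .config_fingerprint(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (cache && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (identical(old$config_fingerprint, fp)) {
      files <- names(old$checksums)
      paths <- file.path(out_dir, files)
      if (all(file.exists(paths)) &&
          identical(unname(tools::md5sum(paths)),
                    unname(unlist(old$checksums)))) {
        message("cached run verified; outputs reused")
        return(invisible(list(manifest = old, cached = TRUE)))
      }
    }
  }
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  seed <- config$seed

  ## -- stage 1: simulate -------------------------------------------------
  bundle <- tick("simulate", simulate_cohort(
    n_hc = config$n_hc, n_pd = config$n_pd,
    panel = default_snp_panel(config$include_qc_failures),
    fibers_per_pair = config$fibers_per_pair, seed = seed
  ))
  write_tsv(bundle$subjects, file.path(out_dir, "subjects.tsv"))
  write_plink(bundle$genotypes, file.path(out_dir, "genotypes"),
              sex = bundle$subjects$sex)
  write_tsv(bundle$streamlines, file.path(out_dir, "streamlines.tsv"))
  jsonlite::write_json(bundle$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)

  ## -- stage 2: genotype QC ---------------------------------------------
  qc <- tick("qc", apply_snp_qc(bundle$genotypes, config$maf_min,
                                config$hwe_min_p, config$miss_max))
  write_tsv(qc$report$snp_table, file.path(out_dir, "qc_snp_table.tsv"))
  jsonlite::write_json(
    list(thresholds = as.list(qc$report$thresholds),
         convention = qc$report$convention,
         n_excluded = as.list(qc$report$n_excluded),
         n_retained = qc$report$n_retained),
    file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  mds <- tick("mds", {
    d <- ibs_distance(qc$genotypes)
    classical_mds(d, k = min(config$mds_k, nrow(d) - 1))
  })
  write_tsv(data.frame(subject_id = rownames(mds$points), mds$points,
                       stringsAsFactors = FALSE),
            file.path(out_dir, "mds_coordinates.tsv"))

  ## -- stage 3: connectome + group tests --------------------------------
  dc <- tick("connectome", {
    conn_dir <- file.path(out_dir, "connectivity")
    dir.create(conn_dir, showWarnings = FALSE)
    rows <- split(seq_len(nrow(bundle$streamlines)),
                  bundle$streamlines$subject_id)
    for (id in bundle$subjects$subject_id) {
      cm <- build_connectivity(bundle$streamlines[rows[[id]], ],
                               bundle$atlas)
      write_connectivity_csv(cm, file.path(conn_dir, paste0(id, ".csv")))
    }
    cohort_degree_centrality(bundle$streamlines, bundle$atlas,
                             bundle$subjects$subject_id)
  })
  write_tsv(dc, file.path(out_dir, "degree_centrality.tsv"))
  nodes <- bundle$atlas$region
  is_hc <- bundle$subjects$group == "HC"
  dc_tests <- tick("dc_tests", group_dc_tests(
    dc[is_hc, nodes], dc[!is_hc, nodes], alpha = config$alpha
  ))
  write_tsv(dc_tests, file.path(out_dir, "dc_group_tests.tsv"))
  sig_nodes <- dc_tests$node[dc_tests$significant]
  if (length(sig_nodes) < config$min_features) {
    sig_nodes <- dc_tests$node[order(dc_tests$p_bonferroni)][
      seq_len(config$min_features)]
  }

  ## -- stage 4: association --------------------------------------------
  assoc <- tick("association", {
    phen <- cbind(dc[, c("subject_id", sig_nodes)],
                  mds_updrs = bundle$subjects$mds_updrs)
    candidates <- qc$genotypes$snps$snp_id
    assoc_scan(phen, qc$genotypes,
               bundle$subjects[, c("subject_id", "age", "sex")],
               candidates, n_perm = config$n_perm,
               seed = derive_seed(seed, "association"))
  })
  write_tsv(assoc, file.path(out_dir, "association.tsv"))
  sig_snps <- unique(assoc$snp_id[!is.na(assoc$p_empirical) &
                                    assoc$p_empirical < config$alpha])
  if (length(sig_snps) < config$min_features) {
    ranked <- assoc[order(assoc$p_empirical), ]
    sig_snps <- unique(ranked$snp_id)[seq_len(config$min_features)]
  }

  ## -- stage 5: models + LOOCV ------------------------------------------
  ## regression terms must be complete: the few missing genotype calls of a
  ## selected SNP are imputed with the per-SNP mean dosage so every subject
  ## keeps a leave-one-out fold (imputed counts recorded in the manifest)
  n_imputed <- 0L
  for (sid in sig_snps) {
    col <- bundle$features[[sid]]
    if (anyNA(col)) {
      n_imputed <- n_imputed + sum(is.na(col))
      col[is.na(col)] <- mean(col, na.rm = TRUE)
      bundle$features[[sid]] <- col
    }
  }
  models <- tick("models", build_three_models(
    bundle$features$mds_updrs, bundle$features,
    imaging_features = sig_nodes, snp_features = sig_snps,
    interaction_cap = config$interaction_cap
  ))
  for (mn in c("A", "B", "C")) {
    an <- sequential_anova(models[[mn]])
    an_out <- rbind(an, data.frame(term = "Total", df = NA, sum_sq = NA,
                                   f_statistic = NA, p_value = NA,
                                   pct_explained = attr(an, "total_pct")))
    write_tsv(an_out, file.path(out_dir, paste0("model_", mn, "_anova.tsv")))
    write_tsv(data.frame(term = names(models[[mn]]$coefficients),
                         estimate = unname(models[[mn]]$coefficients)),
              file.path(out_dir, paste0("model_", mn, "_coefficients.tsv")))
    write_tsv(attr(models[[mn]], "trace"),
              file.path(out_dir, paste0("model_", mn, "_stepwise_trace.tsv")))
  }
  write_tsv(models$comparison, file.path(out_dir, "model_comparison.tsv"))
  cv <- tick("loocv", lapply(models[c("A", "B", "C")], function(m) {
    loocv_predict(bundle$features$mds_updrs, bundle$features, m$terms)
  }))
  cv_summary <- data.frame(
    model = names(cv),
    rmse = vapply(cv, function(x) x$rmse, numeric(1)),
    pearson_r = vapply(cv, function(x) x$pearson_r, numeric(1)),
    pearson_p = vapply(cv, function(x) x$pearson_p, numeric(1)),
    n_folds = vapply(cv, function(x) x$n_folds, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  write_tsv(cv_summary, file.path(out_dir, "loocv_summary.tsv"))
  for (mn in names(cv)) {
    write_tsv(data.frame(subject_id = bundle$subjects$subject_id,
                         actual = cv[[mn]]$actual,
                         predicted = cv[[mn]]$predictions),
              file.path(out_dir, paste0("loocv_", mn, "_predictions.tsv")))
  }

  ## -- manifest ----------------------------------------------------------
  out_files <- sort(setdiff(
    list.files(out_dir, recursive = TRUE), "manifest.json"))
  checksums <- tools::md5sum(file.path(out_dir, out_files))
  names(checksums) <- out_files
  manifest <- list(
    package_version = as.character(utils::packageVersion("parkig")),
    config = config,
    config_fingerprint = fp,
    fiber_density_variant = FIBER_DENSITY_VARIANT,
    stage_seeds = list(
      master = seed,
      subjects = derive_seed(seed, "subjects"),
      genotypes = derive_seed(seed, "genotypes"),
      streamlines = derive_seed(seed, "streamlines"),
      phenotype = derive_seed(seed, "phenotype"),
      association = derive_seed(seed, "association")
    ),
    significant_nodes = as.list(sig_nodes),
    model_snps = as.list(sig_snps),
    n_imputed_genotype_calls = n_imputed,
    timings_sec = as.list(timings),
    checksums = as.list(checksums)
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, bundle = bundle, qc = qc, mds = mds,
                 dc = dc, dc_tests = dc_tests, association = assoc,
                 models = models, cv = cv, cached = FALSE))
}
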