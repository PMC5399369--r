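## MDS-UPDRS regression models: design construction with two-way
## interactions, OLS with sequential (Type-I) variance decomposition,
## backward stepwise elimination on the overall model p-value, and
## leave-one-out cross-validated prediction.

#' Build a design matrix from a term set
#'
#' Terms are column names of `data` (main effects) or "a:b" strings
#' (two-way interactions, computed as elementwise products of the
#' uncentered operand columns; operands need not themselves be terms).
#' The categorical `site` column expands to reference-coded indicator
#' columns and may not appear inside an interaction.  Character covariates
#' with a declared coding (sex F=0/M=1, handedness R=0/L=1, group HC=0/PD=1)
#' are converted automatically.
#'
#' @param data data.frame holding every source column.
#' @param terms character vector of terms, in model order.
#' @return list: `X` (n x (1+p) matrix, intercept first), `assign` (term
#'   index per column, 0 = intercept), `terms`.
#' @export
build_design <- function(data, terms) {
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  assign <- 0L
  for (k in seq_along(terms)) {
    term <- terms[k]
    ops <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (length(ops) > 1 && "site" %in% ops) {
      stop("'site' may not appear in an interaction term")
    }
    if (identical(ops, "site")) {
      f <- factor(data$site)
      mm <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0("site", levels(f)[-1])
      for (cn in colnames(mm)) cols[[cn]] <- mm[, cn]
      assign <- c(assign, rep(k, ncol(mm)))
    } else {
      col <- rep(1, n)
      for (op in ops) col <- col * .as_numeric_column(data, op)
      if (anyNA(col)) stop("term '", term, "' has missing values")
      cols[[term]] <- col
      assign <- c(assign, k)
    }
  }
  X <- do.call(cbind, cols)
  list(X = X, assign = assign, terms = terms)
}

#' Fit an ordinary least-squares model over a term set
#'
#' QR-based least squares of the score on the design built from `terms`,
#' with R-squared, adjusted R-squared (1 - (1-R2)(n-1)/(n-p-1), p = number
#' of slope columns) and the overall F-test against the intercept-only
#' model.  A rank-deficient design is refused with the offending columns
#' named.
#'
#' @param y numeric response.
#' @param data data.frame of source columns.
#' @param terms character term set (see [build_design()]).
#' @return object of class `pk_lm`.
#' @export
fit_ols <- function(y, data, terms) {
  des <- build_design(data, terms)
  X <- des$X
  n <- length(y)
  p <- ncol(X) - 1L
  if (n <= p + 1) stop("need n > p + 1 (n = ", n, ", p = ", p, ")")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design is rank deficient; dependent column(s): ",
         paste(dropped, collapse = ", "))
  }
  cf <- qr.coef(qx, y)
  fitted <- drop(X %*% cf)
  res <- y - fitted
  ss_total <- sum((y - mean(y))^2)
  rss <- sum(res^2)
  sigma2 <- rss / (n - p - 1)
  se <- numeric(ncol(X))
  se[qx$pivot] <- sqrt(diag(chol2inv(qr.R(qx))) * sigma2)
  names(se) <- colnames(X)
  r2 <- 1 - rss / ss_total
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  fstat <- if (p > 0) (r2 / p) / ((1 - r2) / (n - p - 1)) else NA_real_
  p_val <- if (p > 0) pf(fstat, p, n - p - 1, lower.tail = FALSE) else NA_real_
  structure(list(
    coefficients = cf, se = se, fitted = fitted, residuals = res,
    r_squared = r2, adj_r_squared = adj_r2,
    f_statistic = fstat, p_value = p_val,
    qr = qx, assign = des$assign, terms = terms,
    n = n, p = p, y = y, X = X, ss_total = ss_total, rss = rss
  ), class = "pk_lm")
}

#' @export
print.pk_lm <- function(x, ...) {
  cat("linear model:", length(x$terms), "term(s), n =", x$n, "\n")
  cat(sprintf("  R2 = %.4f  adj-R2 = %.4f  F = %.3f  p = %.3g\n",
              x$r_squared, x$adj_r_squared, x$f_statistic, x$p_value))
  invisible(x)
}

#' Sequential (Type-I) analysis of variance
#'
#' Decomposes the model sum of squares term by term in model order, from
#' the squared orthogonal effects of the QR factorisation (the intercept
#' absorbs the mean first).  Each term's F statistic is taken against the
#' final model's residual mean square, and its percentage of explained
#' variance is 100 * SS_term / SS_total(y).  By construction the per-term
#' percentages sum to 100 * R-squared, and the term sums of squares plus the
#' residual sum of squares recover the total sum of squares exactly.
#'
#' @param model a fitted `pk_lm` from [fit_ols()].
#' @return data.frame per term: term, df, sum_sq, f_statistic, p_value,
#'   pct_explained; attribute `total_pct` = 100 * R-squared.
#' @export
sequential_anova <- function(model) {
  stopifnot(inherits(model, "pk_lm"))
  eff <- qr.qty(model$qr, model$y)[seq_len(ncol(model$X))]
  mse <- model$rss / (model$n - model$p - 1)
  out <- lapply(seq_along(model$terms), function(k) {
    idx <- which(model$assign == k)
    ss <- sum(eff[idx]^2)
    df <- length(idx)
    f <- (ss / df) / mse
    data.frame(term = model$terms[k], df = df, sum_sq = ss,
               f_statistic = f,
               p_value = pf(f, df, model$n - model$p - 1, lower.tail = FALSE),
               pct_explained = 100 * ss / model$ss_total,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "total_pct") <- 100 * model$r_squared
  attr(res, "ss_residual") <- model$rss
  attr(res, "ss_total") <- model$ss_total
  res
}

## Drop terms until the design is full rank; returns the pruned term set.
.prune_rank_deficient <- function(y, data, terms) {
  repeat {
    des <- build_design(data, terms)
    qx <- qr(des$X)
    if (qx$rank == ncol(des$X)) return(terms)
    bad_col <- qx$pivot[qx$rank + 1]
    bad_term <- des$assign[bad_col]
    if (bad_term == 0) stop("intercept column dependent; degenerate input")
    warning("dropping rank-deficient term '", terms[bad_term],
            "' before stepwise selection")
    terms <- terms[-bad_term]
  }
}

#' Backward stepwise elimination on the overall model p-value
#'
#' Starting from the full term set, every current term is evaluated for
#' removal; the removal that most lowers the overall regression p-value is
#' committed if it lowers it strictly, and the process repeats until no
#' removal improves the p-value.  Ties are broken toward the earliest term
#' in model order, so the elimination path is deterministic.  The final
#' model always keeps at least one term.
#'
#' @param y numeric response.
#' @param data data.frame of source columns.
#' @param terms initial term set (pre-pruned, with a warning, if rank
#'   deficient).
#' @return the final fitted `pk_lm`, with attribute `trace`: a data.frame
#'   logging each elimination step (step, removed term, model p before and
#'   after).
#' @export
backward_stepwise <- function(y, data, terms) {
  terms <- .prune_rank_deficient(y, data, terms)
  current <- terms
  fit <- fit_ols(y, data, current)
  trace <- list()
  step <- 0L
  repeat {
    if (length(current) <= 1L) break
    cand_p <- vapply(seq_along(current), function(k) {
      fit_ols(y, data, current[-k])$p_value
    }, numeric(1))
    best <- which.min(cand_p)
    if (cand_p[best] < fit$p_value) {
      step <- step + 1L
      trace[[step]] <- data.frame(step = step, removed = current[best],
                                  p_before = fit$p_value,
                                  p_after = cand_p[best],
                                  stringsAsFactors = FALSE)
      current <- current[-best]
      fit <- fit_ols(y, data, current)
    } else break
  }
  attr(fit, "trace") <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), removed = character(),
               p_before = numeric(), p_after = numeric())
  attr(fit, "initial_terms") <- terms
  fit
}

#' Assemble a candidate term set with capped two-way interactions
#'
#' Main effects are the features plus covariates; candidate interactions
#' are enumerated deterministically (feature x feature pairs first, then
#' feature x numeric-covariate, then covariate x covariate) and truncated
#' at `interaction_cap`.  `site` enters as a main effect only.  A final
#' guard drops trailing interactions so the design stays comfortably
#' overdetermined (at least 10 residual degrees of freedom).
#'
#' @param features character vector of feature columns (imaging and/or SNP).
#' @param covariates covariate columns (default the clinical set).
#' @param n sample size, for the fittability guard.
#' @param n_site_levels number of site indicator columns implied by `site`.
#' @param interaction_cap maximum number of interaction terms.
#' @return character term vector.
#' @export
make_term_set <- function(features,
                          covariates = c("family_history", "moca", "gds",
                                         "sex", "age", "site"),
                          n = 80, n_site_levels = 9,
                          interaction_cap = 16) {
  if (length(features) == 0L) stop("'features' must be non-empty")
  num_cov <- setdiff(covariates, "site")
  pair_terms <- function(v) {
    if (length(v) < 2) return(character())
    apply(combn(v, 2), 2, paste, collapse = ":")
  }
  cross_terms <- function(a, b) {
    if (!length(a) || !length(b)) return(character())
    as.vector(t(outer(a, b, paste, sep = ":")))
  }
  inter <- c(pair_terms(features), cross_terms(features, num_cov),
             pair_terms(num_cov))
  if (length(inter) > interaction_cap) inter <- inter[seq_len(interaction_cap)]
  mains <- c(features, covariates)
  n_cols <- length(mains) - ("site" %in% covariates) +
    ("site" %in% covariates) * (n_site_levels - 1)
  while (length(inter) && n_cols + length(inter) > n - 11) {
    inter <- inter[-length(inter)]
  }
  c(mains, inter)
}

#' Build the three clinical-score models
#'
#' Constructs and backward-selects the three MDS-UPDRS regressions:
#' model A from imaging features (node degree centralities) plus
#' covariates, model B from genetic features (SNP additive codes) plus
#' covariates, and model C from both, each starting from main effects plus
#' capped two-way interactions.
#'
#' @param y numeric MDS-UPDRS scores.
#' @param data data.frame holding every feature and covariate column.
#' @param imaging_features,snp_features character column names.
#' @param covariates covariate columns.
#' @param interaction_cap maximum interaction terms per model.
#' @return list of class `pk_models`: `A`, `B`, `C` (fitted `pk_lm`s) and
#'   `comparison` (data.frame of adj-R2, overall p, term counts).
#' @export
build_three_models <- function(y, data, imaging_features, snp_features,
                               covariates = c("family_history", "moca",
                                              "gds", "sex", "age", "site"),
                               interaction_cap = 16) {
  if (!length(imaging_features)) stop("'imaging_features' must be non-empty")
  if (!length(snp_features)) stop("'snp_features' must be non-empty")
  n <- nrow(data)
  n_site <- if ("site" %in% covariates) length(unique(data$site)) else 1
  sets <- list(
    A = make_term_set(imaging_features, covariates, n, n_site,
                      interaction_cap),
    B = make_term_set(snp_features, covariates, n, n_site, interaction_cap),
    C = make_term_set(c(imaging_features, snp_features), covariates, n,
                      n_site, interaction_cap)
  )
  fits <- lapply(sets, function(ts) backward_stepwise(y, data, ts))
  comparison <- data.frame(
    model = names(fits),
    n_terms = vapply(fits, function(f) length(f$terms), integer(1)),
    adj_r_squared = vapply(fits, function(f) f$adj_r_squared, numeric(1)),
    p_value = vapply(fits, function(f) f$p_value, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(c(fits, list(comparison = comparison)), class = "pk_models")
}

#' @export
print.pk_models <- function(x, ...) {
  cat("MDS-UPDRS model comparison (A imaging, B genetics, C combined)\n")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}

#' Leave-one-out cross-validated prediction
#'
#' Holds the term set fixed (as selected on the full data) and, for each
#' subject in turn, refits the coefficients on the remaining n - 1 subjects
#' and predicts the held-out score.  Performance is summarised by the root
#' mean squared error and the Pearson correlation between predicted and
#' actual scores.  Folds whose reduced design is rank deficient are skipped
#' and reported.
#'
#' @param y numeric response.
#' @param data data.frame of source columns.
#' @param terms fixed term set.
#' @return object of class `pk_cv`: predictions, rmse, pearson_r,
#'   pearson_p, n_folds, skipped_folds.
#' @export
loocv_predict <- function(y, data, terms) {
  des <- build_design(data, terms)
  X <- des$X
  n <- length(y)
  if (n < ncol(X) + 2) stop("need n >= p + 3 for leave-one-out folds")
  pred <- rep(NA_real_, n)
  skipped <- integer()
  for (i in seq_len(n)) {
    qx <- qr(X[-i, , drop = FALSE])
    if (qx$rank < ncol(X)) {
      skipped <- c(skipped, i)
      next
    }
    cf <- qr.coef(qx, y[-i])
    pred[i] <- sum(X[i, ] * cf)
  }
  if (length(skipped)) {
    warning(length(skipped), " fold(s) skipped for rank deficiency")
  }
  ok <- !is.na(pred)
  ct <- cor.test(pred[ok], y[ok])
  structure(list(predictions = pred, actual = y,
                 rmse = sqrt(mean((pred[ok] - y[ok])^2)),
                 pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
                 n_folds = n, skipped_folds = skipped),
            class = "pk_cv")
}

#' @export
print.pk_cv <- function(x, ...) {
  cat("leave-one-out cross-validation:", x$n_folds, "folds\n")
  cat(sprintf("  RMSE = %.3f  Pearson r = %.3f (p = %.3g)\n",
              x$rmse, x$pearson_r, x$pearson_p))
  invisible(x)
}

#' Scatter plot of actual versus predicted scores
#'
#' @param cv a `pk_cv` object from [loocv_predict()].
#' @param main plot title.
#' @return invisibly, the cv object.
#' @export
plot_loocv <- function(cv, main = "Actual vs predicted MDS-UPDRS") {
  stopifnot(inherits(cv, "pk_cv"))
  graphics::plot(cv$actual, cv$predictions, xlab = "Actual MDS-UPDRS",
                 ylab = "Predicted MDS-UPDRS", main = main, pch = 19)
  graphics::abline(0, 1, lty = 2)
  invisible(cv)
}
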