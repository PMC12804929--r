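# Quantify and decompose the performance gap between the non-linear and
# linear predictors: paired bootstrap, FDR, gap-source classification,
# iterative complexity, staged boosting decomposition, transfer evaluation,
# and the exact binomial replication CI.

#' Paired bootstrap model comparison
#'
#' One resample index vector per bootstrap is applied to both prediction
#' vectors (paired resampling), R-squared and RMSE are computed per resample,
#' and 95% percentile confidence intervals are taken at the 2.5%/97.5%
#' quantiles. The empirical p-value is the proportion of resamples where
#' model A's R-squared is less than or equal to model B's. Significance is
#' non-overlapping R-squared CIs with model A ahead on the mean. Resamples
#' with zero-variance y are skipped and logged.
#'
#' @param y_true observed test values (length >= 10)
#' @param pred_a,pred_b test predictions of the two models (A is the
#'   non-linear/flexible model by convention)
#' @param n_boot number of bootstrap resamples
#' @param seed RNG seed
#' @return a `bootstrap_summary` list: per-model mean R2/RMSE and CIs, `gap`
#'   (mean R2 A - mean R2 B) with `gap_ci`, `significant_nonoverlap`,
#'   `empirical_p`, `n`, `n_boot_effective`
#' @export
bootstrap_compare <- function(y_true, pred_a, pred_b, n_boot = 1000L,
                              seed = 1L) {
  n <- length(y_true)
  assert_that(n >= 10 && length(pred_a) == n && length(pred_b) == n,
              "need equal-length inputs with n >= 10")
  set.seed(seed)
  r2a <- r2b <- ra <- rb <- rep(NA_real_, n_boot)
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    yt <- y_true[i]
    if (var(yt) == 0) { skipped <- skipped + 1L; next }
    r2a[b] <- r2_score(yt, pred_a[i])
    r2b[b] <- r2_score(yt, pred_b[i])
    ra[b] <- rmse_score(yt, pred_a[i])
    rb[b] <- rmse_score(yt, pred_b[i])
  }
  ok <- !is.na(r2a)
  assert_that(any(ok), "all bootstrap resamples degenerate")
  ci <- function(x) unname(quantile(x[ok], c(0.025, 0.975)))
  ci_a <- ci(r2a); ci_b <- ci(r2b)
  mean_a <- mean(r2a[ok]); mean_b <- mean(r2b[ok])
  structure(list(
    r2_a = mean_a, r2_b = mean_b, r2_ci_a = ci_a, r2_ci_b = ci_b,
    rmse_a = mean(ra[ok]), rmse_b = mean(rb[ok]),
    rmse_ci_a = ci(ra), rmse_ci_b = ci(rb),
    gap = mean_a - mean_b, gap_ci = ci(r2a - r2b),
    significant_nonoverlap = (ci_a[1] > ci_b[2]) && (mean_a > mean_b),
    empirical_p = mean(r2a[ok] <= r2b[ok]),
    boot_r2_a = r2a[ok], boot_r2_b = r2b[ok],
    n = n, n_boot_effective = sum(ok), n_boot_skipped = skipped,
    seed = seed), class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf(paste0("bootstrap_summary (n=%d, B=%d): R2 A=%.4f [%.4f, %.4f]",
                     " vs B=%.4f [%.4f, %.4f]\n  gap=%.4f, empirical p=%.4g,",
                     " significant=%s\n"),
              x$n, x$n_boot_effective, x$r2_a, x$r2_ci_a[1], x$r2_ci_a[2],
              x$r2_b, x$r2_ci_b[1], x$r2_ci_b[2], x$gap, x$empirical_p,
              x$significant_nonoverlap))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure with monotonicity enforcement. Zero p-values are clipped
#' to `1/n_boot_floor` before adjustment when `n_boot_floor` is given (BH on
#' exact zeros is degenerate for empirical p-values).
#'
#' @param p_values numeric vector in [0, 1]
#' @param n_boot_floor optional bootstrap count used to clip exact zeros
#' @return q-values in input order
#' @export
fdr_adjust <- function(p_values, n_boot_floor = NULL) {
  p <- p_values
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must be in [0,1]")
  if (!is.null(n_boot_floor)) p <- pmax(p, 1 / n_boot_floor)
  n <- length(p)
  ord <- order(p)
  q <- p[ord] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[ord] <- q
  out
}

#' Classify the source of a performance gap
#'
#' `none` when the full-model gap is not significant; otherwise
#' `covariate_nonlinearity` when the covariate-only non-linear-vs-linear gap
#' reaches the full gap minus delta (delta = half-width of the full gap's
#' bootstrap CI), else `genetic_or_other_nonlinearity`.
#'
#' @param summary_full [bootstrap_compare()] of the genotype+covariate models
#' @param summary_cov_only [bootstrap_compare()] of the covariate-only models,
#'   computed on the same test rows
#' @return one of `"none"`, `"covariate_nonlinearity"`,
#'   `"genetic_or_other_nonlinearity"`
#' @export
classify_gap_source <- function(summary_full, summary_cov_only) {
  assert_that(inherits(summary_full, "bootstrap_summary") &&
                inherits(summary_cov_only, "bootstrap_summary"),
              "both arguments must be bootstrap summaries")
  assert_that(summary_full$n == summary_cov_only$n,
              "summaries computed on different sample sets")
  if (!summary_full$significant_nonoverlap) return("none")
  delta <- diff(summary_full$gap_ci) / 2
  if (summary_cov_only$gap >= summary_full$gap - delta) {
    "covariate_nonlinearity"
  } else {
    "genetic_or_other_nonlinearity"
  }
}

# term builders for the iterative complexity schedule
complexity_terms <- function(term, Xg, C) {
  switch(term,
    covariates = C,
    genotypes_additive = Xg,
    covariate_nonlinear = {
      num <- C[, apply(C, 2, function(v) length(unique(v)) > 2), drop = FALSE]
      if (ncol(num) == 0) return(NULL)
      sq <- num^2; colnames(sq) <- paste0(colnames(num), "_sq")
      lg <- apply(num, 2, function(v) log(v - min(v) + 1))
      colnames(lg) <- paste0(colnames(num), "_log")
      cbind(sq, lg)
    },
    genotype_onehot = {
      het <- (Xg > 0.5) & (Xg < 1.5)
      hom <- Xg >= 1.5
      out <- cbind(het, hom) * 1
      colnames(out) <- c(paste0(colnames(Xg), "_het"),
                         paste0(colnames(Xg), "_hom"))
      out
    },
    exe = {
      if (ncol(C) < 2) return(NULL)
      pr <- combn(ncol(C), 2)
      out <- C[, pr[1, ], drop = FALSE] * C[, pr[2, ], drop = FALSE]
      colnames(out) <- paste0(colnames(C)[pr[1, ]], "_x_",
                              colnames(C)[pr[2, ]])
      out
    },
    gxe = {
      out <- do.call(cbind, lapply(seq_len(ncol(Xg)), function(j) {
        o <- Xg[, j] * C
        colnames(o) <- paste0(colnames(Xg)[j], "_x_", colnames(C))
        o
      }))
      out
    },
    gxg = {
      if (ncol(Xg) < 2) return(NULL)
      pr <- combn(ncol(Xg), 2)
      out <- Xg[, pr[1, ], drop = FALSE] * Xg[, pr[2, ], drop = FALSE]
      colnames(out) <- paste0(colnames(Xg)[pr[1, ]], "_x_",
                              colnames(Xg)[pr[2, ]])
      out
    },
    stopf("unknown complexity term '%s'", term))
}

# Ridge-stabilized OLS on standardized columns: expanded complexity designs
# are exactly collinear by construction (e.g. additive = het + 2*hom), so a
# tiny per-unit-variance penalty (1e-8, scaled by n) keeps the solve
# well-posed without materially biasing the fit.
ridge_fit <- function(X, y, lambda = 1e-8) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  keep <- scl > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  XtX <- crossprod(Xs)
  diag(XtX) <- diag(XtX) + lambda * nrow(X)
  beta <- solve(XtX, crossprod(Xs, y - mean(y)))
  mu <- mean(y)
  list(beta = beta, predict = function(Xn) {
    Xn <- sweep(sweep(Xn[, keep, drop = FALSE], 2, ctr[keep]), 2,
                scl[keep], "/")
    as.vector(Xn %*% beta) + mu
  })
}

#' Iterative complexity analysis
#'
#' Starting from covariates plus additively encoded genotypes, refits a
#' (ridge-stabilized, lambda = 1e-8) linear model as successively more complex
#' terms are added, recording the validation R-squared and its change at each
#' step. Default schedule: covariates, additive genotypes, non-linear
#' covariate terms (squares and shifted logs), one-hot genotypes, ExE, GxE,
#' GxG products.
#'
#' @param y trait vector
#' @param G_sel [genotype_matrix()] restricted to the selected (top) variants
#' @param covariates covariate data.frame or design matrix
#' @param splits list with integer indices `train` and `val`
#' @param schedule ordered character vector of term names
#' @return `complexity_ledger` data.frame: term, r2 (validation), delta_r2
#' @export
iterative_complexity <- function(y, G_sel, covariates, splits,
                                 schedule = c("covariates",
                                              "genotypes_additive",
                                              "covariate_nonlinear",
                                              "genotype_onehot",
                                              "exe", "gxe", "gxg")) {
  C <- if (is.data.frame(covariates)) covariate_design(covariates) else
    as.matrix(covariates)
  Xg <- encode(G_sel, "additive")$X
  tr <- splits$train; va <- splits$val
  X <- NULL
  out <- data.frame(term = character(0), r2 = numeric(0),
                    delta_r2 = numeric(0), stringsAsFactors = FALSE)
  prev <- NA_real_
  for (term in schedule) {
    block <- complexity_terms(term, Xg, C)
    if (!is.null(block)) X <- cbind(X, block)
    fit <- ridge_fit(X[tr, , drop = FALSE], y[tr])
    r2 <- r2_score(y[va], fit$predict(X[va, , drop = FALSE]))
    out[nrow(out) + 1L, ] <- list(term, r2,
                                  if (is.na(prev)) 0 else r2 - prev)
    prev <- r2
  }
  class(out) <- c("complexity_ledger", class(out))
  out
}

#' Staged boosting decomposition
#'
#' Fits the interaction-constrained booster at the three stages (per-variant
#' isolation, +GxG, +GxE) with identical seeds and early-stopping protocol,
#' and reports validation/test R-squared per stage with successive gains.
#'
#' @param design additive genotype matrix (samples x variants)
#' @param covariates numeric covariate matrix
#' @param y trait vector
#' @param splits list with integer indices `train`, `val`, `test`
#' @param params booster overrides (see [fit_constrained_boost()])
#' @param seed seed shared by all stages
#' @return data.frame: stage, r2_val, r2_test, gain_val, gain_test
#' @export
decompose_stages <- function(design, covariates, y, splits, params = list(),
                             seed = 1L) {
  Xg <- if (inherits(design, "encoded_design")) design$X else as.matrix(design)
  Xc <- if (!is.null(covariates)) as.matrix(covariates) else
    matrix(numeric(0), nrow(Xg), 0)
  trval <- c(splits$train, splits$val)
  params$val_idx <- length(splits$train) + seq_along(splits$val)
  stages <- c("base", "plus_gxg", "plus_gxe")
  rows <- lapply(stages, function(st) {
    fit <- fit_constrained_boost(Xg[trval, , drop = FALSE],
                                 if (ncol(Xc)) Xc[trval, , drop = FALSE],
                                 y[trval], stage = st, params = params,
                                 seed = seed)
    pv <- boost_predict(fit, cbind(Xg, Xc)[splits$val, , drop = FALSE])
    ptst <- boost_predict(fit, cbind(Xg, Xc)[splits$test, , drop = FALSE])
    data.frame(stage = st, r2_val = r2_score(y[splits$val], pv),
               r2_test = r2_score(y[splits$test], ptst),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$gain_val <- c(0, diff(out$r2_val))
  out$gain_test <- c(0, diff(out$r2_test))
  out
}

#' Group-wise transfer evaluation of the performance gap
#'
#' For every trait and group, runs [bootstrap_compare()]; a group's gap is set
#' to 0 when both models' mean bootstrapped R-squared is negative. Groups with
#' fewer than 10 samples are excluded with a warning. When more than one trait
#' is supplied, the Pearson correlation of gaps across traits is reported for
#' every group pair (NA when undefined, e.g. zero variance).
#'
#' @param data nested list: `data[[trait]][[group]]` is a list with `y_true`,
#'   `pred_a`, `pred_b`
#' @param n_boot,seed passed to [bootstrap_compare()]
#' @return list: `gaps` (data.frame trait/group/gap/r2_a/r2_b/zeroed),
#'   `gap_correlation` (group x group matrix or NULL for a single trait)
#' @export
transfer_gap <- function(data, n_boot = 1000L, seed = 1L) {
  assert_that(length(data) >= 1, "no traits supplied")
  rows <- list()
  for (trait in names(data)) {
    groups <- data[[trait]]
    assert_that(length(groups) >= 2, "need >= 2 groups per trait")
    for (grp in names(groups)) {
      d <- groups[[grp]]
      if (length(d$y_true) < 10) {
        warning(sprintf("group '%s' (trait '%s') has < 10 samples; excluded",
                        grp, trait))
        next
      }
      s <- bootstrap_compare(d$y_true, d$pred_a, d$pred_b, n_boot = n_boot,
                             seed = seed)
      zeroed <- s$r2_a < 0 && s$r2_b < 0
      rows[[length(rows) + 1L]] <- data.frame(
        trait = trait, group = grp, gap = if (zeroed) 0 else s$gap,
        r2_a = s$r2_a, r2_b = s$r2_b, zeroed = zeroed,
        stringsAsFactors = FALSE)
    }
  }
  gaps <- do.call(rbind, rows)
  gap_cor <- NULL
  if (length(unique(gaps$trait)) > 1) {
    wide <- tapply(gaps$gap, list(gaps$trait, gaps$group), mean)
    grps <- colnames(wide)
    gap_cor <- matrix(NA_real_, length(grps), length(grps),
                      dimnames = list(grps, grps))
    for (a in seq_along(grps)) for (b in seq_along(grps)) {
      ga <- wide[, a]; gb <- wide[, b]
      ok <- !is.na(ga) & !is.na(gb)
      if (sum(ok) >= 3 && sd(ga[ok]) > 0 && sd(gb[ok]) > 0) {
        gap_cor[a, b] <- cor(ga[ok], gb[ok])
      }
    }
  }
  list(gaps = gaps, gap_correlation = gap_cor)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval via beta quantiles; the lower bound is 0 when there are no
#' successes and the upper bound is 1 when all trials succeed.
#'
#' @param successes number of successes (0 <= successes <= n)
#' @param n number of trials (>= 1)
#' @param level confidence level
#' @return named numeric vector `c(lower, upper)` on the proportion scale
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  assert_that(n >= 1 && successes >= 0 && successes <= n,
              "need 0 <= successes <= n, n >= 1")
  a <- (1 - level) / 2
  lower <- if (successes == 0) 0 else qbeta(a, successes, n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - a, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}
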