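# R-side wrapper for the compiled histogram booster, exposing the staged
# interaction constraints used by the decomposition analyses.

# Quantile binning shared by training and prediction. Returns 0-based bin
# indices and the cut points needed to bin new data identically.
make_bins <- function(X, n_bins = 32L) {
  X <- as.matrix(X)
  cuts <- lapply(seq_len(ncol(X)), function(j) {
    qs <- unique(quantile(X[, j], probs = seq_len(n_bins - 1L) / n_bins,
                          type = 1, names = FALSE))
    qs[is.finite(qs)]
  })
  list(cuts = cuts, n_bins = n_bins, binned = apply_bins(cuts, X))
}

apply_bins <- function(cuts, X) {
  X <- as.matrix(X)
  B <- matrix(0L, nrow(X), ncol(X))
  for (j in seq_len(ncol(X))) {
    B[, j] <- findInterval(X[, j], cuts[[j]])
  }
  B
}

stage_groups <- function(stage, n_variants, n_cov) {
  switch(stage,
    base = c(seq_len(n_variants), rep(n_variants + 1L, n_cov)),
    plus_gxg = c(rep(1L, n_variants), rep(2L, n_cov)),
    plus_gxe = rep(1L, n_variants + n_cov),
    stopf("unknown stage '%s' (use base / plus_gxg / plus_gxe)", stage))
}

#' Interaction-constrained gradient boosting
#'
#' Gradient-boosted regression trees (squared loss, histogram splits) whose
#' allowed feature interactions depend on the decomposition stage:
#' `base` isolates every variant in its own interaction group with all
#' covariates sharing one group (covariates may interact among themselves; no
#' variant-variant or variant-covariate splits on one tree path), `plus_gxg`
#' lets variants interact with each other but not with covariates, and
#' `plus_gxe` removes all constraints. Early stopping on a validation subset.
#'
#' @param design additive-coded genotype matrix (samples x variants) or an
#'   [encode()] result
#' @param covariates numeric covariate matrix or NULL
#' @param y trait vector
#' @param stage `"base"`, `"plus_gxg"` or `"plus_gxe"`
#' @param params overrides: `eta` (0.1), `max_depth` (3), `n_rounds` (300),
#'   `lambda` (1), `min_child` (20), `patience` (20), `n_bins` (32),
#'   `val_frac` (0.15) or explicit `val_idx`
#' @param seed RNG seed (validation split)
#' @return `model_bundle` of kind `"boosted_tree"`
#' @export
fit_constrained_boost <- function(design, covariates = NULL, y,
                                  stage = c("base", "plus_gxg", "plus_gxe"),
                                  params = list(), seed = 1L) {
  stage <- match.arg(stage)
  Xg <- if (inherits(design, "encoded_design")) design$X else as.matrix(design)
  n_variants <- ncol(Xg)
  Xc <- if (!is.null(covariates)) as.matrix(covariates) else
    matrix(numeric(0), nrow(Xg), 0)
  X <- cbind(Xg, Xc)
  assert_that(nrow(X) == length(y), "design and y disagree on n")
  p <- list(eta = 0.1, max_depth = 3L, n_rounds = 300L, lambda = 1,
            min_child = 20L, patience = 20L, n_bins = 32L, val_frac = 0.15)
  p[names(params)] <- params
  if (is.null(p$val_idx)) {
    set.seed(seed)
    p$val_idx <- sample.int(nrow(X), max(2L, round(p$val_frac * nrow(X))))
  }
  tr <- setdiff(seq_len(nrow(X)), p$val_idx)
  bins <- make_bins(X[tr, , drop = FALSE], p$n_bins)
  Btr <- bins$binned
  Bva <- apply_bins(bins$cuts, X[p$val_idx, , drop = FALSE])
  groups <- stage_groups(stage, n_variants, ncol(Xc))
  fit <- boost_fit_cpp(Btr, y[tr], Bva, y[p$val_idx],
                       as.integer(groups), as.integer(p$n_bins),
                       p$eta, as.integer(p$max_depth),
                       as.integer(p$n_rounds), p$lambda,
                       as.integer(p$min_child), as.integer(p$patience))
  fit$eta <- p$eta
  structure(list(kind = "boosted_tree", fit = fit, cuts = bins$cuts,
                 stage = stage, p = ncol(X), n_variants = n_variants,
                 seed = seed,
                 meta = list(n_trees = length(fit$trees),
                             best_iter = fit$best_iter,
                             val_loss = fit$val_loss)),
            class = "model_bundle")
}

#' Predict from a boosted-tree bundle
#' @param bundle `model_bundle` of kind `"boosted_tree"`
#' @param newdata matrix with the training column layout (genotypes then
#'   covariates)
#' @return numeric predictions
#' @export
boost_predict <- function(bundle, newdata) {
  X <- as.matrix(newdata)
  assert_that(ncol(X) == bundle$p,
              "newdata has %d columns, model expects %d", ncol(X), bundle$p)
  B <- apply_bins(bundle$cuts, X)
  as.vector(boost_predict_cpp(bundle$fit, B, bundle$fit$best_iter))
}
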