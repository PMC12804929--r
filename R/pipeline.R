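#' Make train/validation/test splits
#'
#' @param sample_ids character vector of ids
#' @param fractions length-3 numeric (train, validation, test), summing to
#'   <= 1, or integer counts
#' @param seed RNG seed
#' @param group_labels optional vector (aligned with `sample_ids`) of group
#'   labels for transfer evaluation
#' @param holdout_groups labels whose members are reserved as extra named test
#'   groups and never enter train/validation/test
#' @return a `split_spec`: `train`, `val`, `test` id vectors plus `groups`
#'   (named list of held-out group ids) and the seed
#' @export
make_splits <- function(sample_ids, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                        group_labels = NULL, holdout_groups = NULL) {
  assert_that(length(fractions) == 3, "fractions must have length 3")
  ids <- as.character(sample_ids)
  groups <- list()
  if (!is.null(holdout_groups)) {
    assert_that(!is.null(group_labels) && length(group_labels) == length(ids),
                "group_labels must align with sample_ids")
    for (gl in holdout_groups) {
      groups[[gl]] <- ids[group_labels == gl]
    }
    ids <- ids[!(group_labels %in% holdout_groups)]
  }
  n <- length(ids)
  counts <- if (all(fractions <= 1) && sum(fractions) <= 1 + 1e-9) {
    c(round(fractions[1] * n), round(fractions[2] * n))
  } else {
    as.integer(fractions[1:2])
  }
  n_test <- if (all(fractions <= 1) && sum(fractions) <= 1 + 1e-9) {
    min(n - sum(counts), round(fractions[3] * n))
  } else as.integer(fractions[3])
  assert_that(counts[1] >= 1 && counts[2] >= 1 && n_test >= 1,
              "every split must be non-empty")
  assert_that(sum(counts) + n_test <= n, "splits exceed available samples")
  set.seed(seed)
  perm <- sample(ids)
  structure(list(train = sort(perm[seq_len(counts[1])]),
                 val = sort(perm[counts[1] + seq_len(counts[2])]),
                 test = sort(perm[counts[1] + counts[2] + seq_len(n_test)]),
                 groups = groups, seed = seed),
            class = "split_spec")
}

#' Pipeline configuration
#'
#' Defaults mirror the reference protocol: GWAS pre-filter at p < 1e-3,
#' 10 CV runs with the first 3 sharing the pre-filtered variant set,
#' attribution-guided Bayesian optimization of the top-variant fraction for
#' runs 4+, elastic-net benchmark on the full variant set.
#'
#' @param prefilter_p GWAS pre-filter threshold (strict)
#' @param n_runs number of CV runs
#' @param n_shared_runs leading runs trained on the full pre-filtered set and
#'   used for attribution averaging
#' @param bo_n_iter BO evaluations after the seed fractions
#' @param bo_seeds fractions evaluated before BO proposals
#' @param rank_by `"attribution"` or `"gwas_p"` (small-cohort variant)
#' @param en_alphas,n_lambda,en_kfolds elastic-net grid
#' @param arch network architecture overrides (see
#'   [fit_nonlinear_predictor()])
#' @param linear_full if TRUE the linear baseline sees all variants, not the
#'   pre-filtered subset
#' @param seed base seed; per-run seeds are `seed + run_index`
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(prefilter_p = 1e-3, n_runs = 10L,
                            n_shared_runs = 3L, bo_n_iter = 10L,
                            bo_seeds = c(0.1, 0.25, 0.5, 1),
                            rank_by = c("attribution", "gwas_p"),
                            en_alphas = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
                            n_lambda = 200L, en_kfolds = 10L,
                            arch = list(), linear_full = TRUE, seed = 1L) {
  rank_by <- match.arg(rank_by)
  assert_that(n_runs >= n_shared_runs && n_shared_runs >= 1,
              "need n_runs >= n_shared_runs >= 1")
  structure(list(prefilter_p = prefilter_p, n_runs = as.integer(n_runs),
                 n_shared_runs = as.integer(n_shared_runs),
                 bo_n_iter = as.integer(bo_n_iter), bo_seeds = bo_seeds,
                 rank_by = rank_by, en_alphas = en_alphas,
                 n_lambda = as.integer(n_lambda),
                 en_kfolds = as.integer(en_kfolds), arch = arch,
                 linear_full = linear_full, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the per-trait end-to-end pipeline
#'
#' (1) GWAS scan on the training rows only, pre-filter at `prefilter_p`;
#' (2) the first `n_shared_runs` runs train the non-linear predictor on all
#' pre-filtered variants with distinct seeds; (3) integrated-gradients
#' attributions on the validation set are averaged over those runs to rank
#' variants; (4) one BO pass over the top-fraction, scored on the validation
#' set; (5) the remaining runs train on the BO-selected subset; (6) the
#' ensemble prediction is the mean test prediction over all runs; (7) the
#' elastic-net benchmark is trained on train+validation rows, by default on
#' the full variant set. Test rows are touched only for final predictions.
#'
#' @param G [genotype_matrix()]
#' @param S covariate table (row order matching `G$samples`)
#' @param trait numeric trait vector aligned with `G$samples`
#' @param config [pipeline_config()]
#' @param splits [make_splits()] result; defaults to an 80/10/10 split under
#'   `config$seed`
#' @return a `pipeline_result`: `predictions` (test data.frame with
#'   `y_true`, `y_pred_nonlinear`, `y_pred_linear`), `runs` (per-run metadata),
#'   `bo` trace, `selected_variants`, `prefiltered_variants`, `degraded` flag,
#'   `rows_touched`, `config`, `splits`
#' @export
run_trait_pipeline <- function(G, S, trait, config = pipeline_config(),
                               splits = NULL) {
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  n <- length(G$samples)
  assert_that(length(trait) == n && nrow(S) == n,
              "trait/covariates must align with genotype samples")
  if (is.null(splits)) splits <- make_splits(G$samples, seed = config$seed)
  idx <- lapply(splits[c("train", "val", "test")],
                function(ids) match(ids, G$samples))
  assert_that(!anyNA(unlist(idx)), "split ids missing from genotypes")
  assert_that(var(trait[idx$train]) > 0, "trait constant on training rows")
  C <- covariate_design(S)

  scan <- gwas_scan(G[idx$train, ], trait[idx$train],
                    C[idx$train, , drop = FALSE])
  pre_ids <- prefilter(scan, config$prefilter_p)
  rows_touched <- list(gwas = idx$train)

  if (length(pre_ids) == 0) {
    # degrade to covariate-only models, flagged
    boost <- fit_constrained_boost(
      matrix(numeric(0), length(idx$train) + length(idx$val), 0),
      C[c(idx$train, idx$val), , drop = FALSE],
      trait[c(idx$train, idx$val)], stage = "plus_gxe",
      params = list(val_idx = length(idx$train) + seq_along(idx$val)),
      seed = config$seed)
    en <- fit_elastic_net_cv(C[c(idx$train, idx$val), , drop = FALSE],
                             trait[c(idx$train, idx$val)],
                             alphas = config$en_alphas,
                             n_lambda = config$n_lambda,
                             k_folds = config$en_kfolds, seed = config$seed)
    preds <- data.frame(
      sample_id = splits$test, y_true = trait[idx$test],
      y_pred_nonlinear = boost_predict(
        boost, cbind(matrix(numeric(0), length(idx$test), 0),
                     C[idx$test, , drop = FALSE])),
      y_pred_linear = predict(en, C[idx$test, , drop = FALSE]),
      stringsAsFactors = FALSE)
    return(structure(list(predictions = preds, runs = list(), bo = NULL,
                          selected_variants = character(0),
                          prefiltered_variants = character(0),
                          degraded = TRUE, rows_touched = rows_touched,
                          config = config, splits = splits),
                     class = "pipeline_result"))
  }

  G_pre <- G[, pre_ids]
  onehot <- encode(G_pre, "onehot")
  Xg <- onehot$X
  arch <- config$arch
  train_run <- function(variant_ids, run_seed) {
    cols <- onehot$colmap$variant %in% variant_ids
    fit_nonlinear_predictor(
      design = list(train = Xg[idx$train, cols, drop = FALSE],
                    val = Xg[idx$val, cols, drop = FALSE]),
      covariates = list(train = C[idx$train, , drop = FALSE],
                        val = C[idx$val, , drop = FALSE]),
      y_train = trait[idx$train], y_val = trait[idx$val],
      arch = arch, seed = run_seed)
  }
  predict_run <- function(model, variant_ids, rows) {
    cols <- onehot$colmap$variant %in% variant_ids
    predict(model, list(X_geno = Xg[rows, cols, drop = FALSE],
                        X_cov = C[rows, , drop = FALSE]))
  }

  runs <- vector("list", config$n_runs)
  attr_scores <- list()
  for (r in seq_len(config$n_shared_runs)) {
    model <- train_run(pre_ids, config$seed + r)
    ig <- attribute_integrated_gradients(
      model, list(X_geno = Xg[idx$val, , drop = FALSE],
                  X_cov = C[idx$val, , drop = FALSE]))
    attr_scores[[r]] <- variant_attribution(ig, pre_ids)
    runs[[r]] <- list(run = r, variants = pre_ids, val_r2 = model$meta$val_r2,
                      model = model)
  }
  rows_touched$train_runs <- idx$train
  rows_touched$attribution <- idx$val

  ranking <- if (config$rank_by == "attribution") {
    select_top_snvs(attr_scores, k = length(pre_ids))
  } else {
    pre_scan <- scan[scan$variant %in% pre_ids, ]
    pre_scan$variant[order(pre_scan$p)]
  }
  objective <- function(fraction) {
    k <- max(1L, ceiling(fraction * length(ranking)))
    m <- train_run(ranking[seq_len(k)], config$seed + 100L)
    m$meta$val_r2
  }
  bo <- NULL
  selected <- pre_ids
  if (config$n_runs > config$n_shared_runs && length(pre_ids) > 1) {
    bo <- bo_fraction_search(objective, seeds = config$bo_seeds,
                             n_iter = config$bo_n_iter,
                             seed = config$seed)
    k_sel <- max(1L, ceiling(bo$best_fraction * length(ranking)))
    selected <- ranking[seq_len(k_sel)]
  }
  if (config$n_runs > config$n_shared_runs) {
    for (r in (config$n_shared_runs + 1L):config$n_runs) {
      model <- train_run(selected, config$seed + r)
      runs[[r]] <- list(run = r, variants = selected,
                        val_r2 = model$meta$val_r2, model = model)
    }
  }
  rows_touched$bo <- c(idx$train, idx$val)

  test_preds <- vapply(runs, function(rr) {
    predict_run(rr$model, rr$variants, idx$test)
  }, numeric(length(idx$test)))
  if (is.null(dim(test_preds))) test_preds <- matrix(test_preds, nrow = 1)
  ensemble <- rowMeans(test_preds)

  lin_G <- if (config$linear_full) G else G_pre
  Xlin <- cbind(encode(lin_G, "additive")$X, C)
  trval <- c(idx$train, idx$val)
  en <- fit_elastic_net_cv(Xlin[trval, , drop = FALSE], trait[trval],
                           alphas = config$en_alphas,
                           n_lambda = config$n_lambda,
                           k_folds = config$en_kfolds, seed = config$seed)
  lin_pred <- predict(en, Xlin[idx$test, , drop = FALSE])

  preds <- data.frame(sample_id = splits$test, y_true = trait[idx$test],
                      y_pred_nonlinear = ensemble, y_pred_linear = lin_pred,
                      stringsAsFactors = FALSE)
  structure(list(predictions = preds,
                 runs = lapply(runs, function(rr) rr[c("run", "variants",
                                                       "val_r2")]),
                 per_run_test_pred = test_preds,
                 bo = bo, selected_variants = selected,
                 prefiltered_variants = pre_ids, degraded = FALSE,
                 rows_touched = rows_touched, config = config,
                 splits = splits),
            class = "pipeline_result")
}

#' Small-cohort pipeline variant
#'
#' Same orchestration as [run_trait_pipeline()] but with 20 CV runs, variant
#' ranking by training GWAS p-value, and BO seeded with the fractions of
#' pre-filtered variants passing p-value thresholds 1e-8 ... 1e-4 before free
#' search.
#'
#' @inheritParams run_trait_pipeline
#' @param seed_thresholds GWAS p-value thresholds converted to seed fractions
#' @return a `pipeline_result`
#' @export
run_small_cohort_variant <- function(G, S, trait, config = pipeline_config(),
                                     splits = NULL,
                                     seed_thresholds = 10^seq(-8, -4)) {
  if (is.null(splits)) splits <- make_splits(G$samples, seed = config$seed)
  tr_idx <- match(splits$train, G$samples)
  C <- covariate_design(S)
  scan <- gwas_scan(G[tr_idx, ], trait[tr_idx], C[tr_idx, , drop = FALSE])
  pre <- scan[scan$estimable & scan$p < config$prefilter_p, ]
  fracs <- if (nrow(pre) > 0) {
    vapply(seed_thresholds, function(t) mean(pre$p < t), numeric(1))
  } else numeric(0)
  fracs <- sort(unique(pmax(fracs, 1 / max(nrow(pre), 1))))
  fracs <- fracs[fracs > 0 & fracs <= 1]
  if (length(fracs) == 0) fracs <- c(0.5, 1)
  cfg <- config
  cfg$n_runs <- 20L
  cfg$rank_by <- "gwas_p"
  cfg$bo_seeds <- fracs
  run_trait_pipeline(G, S, trait, cfg, splits = splits)
}
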