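# Penalized linear baseline. Backed by glmnet; the module contract (CV over a
# mixing-parameter grid with a per-fold lambda path, then an ensemble of the
# per-fold winners) is implemented here.

#' Elastic-net baseline with CV grid search and fold ensembling
#'
#' For each of `k_folds` folds and each mixing value in `alphas`, a full
#' lambda path (length `n_lambda`) is fit on the in-fold data; the (alpha,
#' lambda) pair with the best held-out-fold R-squared is selected for that
#' fold. The final predictor averages the k per-fold winners' predictions.
#'
#' @param X numeric predictor matrix (standardized internally by glmnet)
#' @param y numeric response, non-constant
#' @param alphas mixing-parameter grid
#' @param n_lambda lambda path length per alpha
#' @param k_folds number of CV folds (n must be >= k_folds)
#' @param seed RNG seed controlling fold assignment
#' @param lambda_min_ratio smallest path lambda as a fraction of the largest
#' @param lambda optional explicit decreasing lambda sequence overriding the
#'   automatic path; include a value near 0 to recover plain OLS in the
#'   well-conditioned limit
#' @return a `model_bundle` with kind `"elastic_net"`; `$cv` records the
#'   per-fold selected alpha/lambda and held-out R-squared, `$fold` the fold
#'   assignment
#' @export
fit_elastic_net_cv <- function(X, y, alphas = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
                               n_lambda = 200L, k_folds = 10L, seed = 1L,
                               lambda_min_ratio = 1e-4, lambda = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  assert_that(n == length(y), "X and y disagree on n")
  assert_that(var(y) > 0, "constant response: nothing to fit")
  assert_that(n >= k_folds, "need n >= k_folds")
  set.seed(seed)
  fold <- sample(rep(seq_len(k_folds), length.out = n))
  models <- vector("list", k_folds)
  cv <- data.frame(fold = seq_len(k_folds), alpha = NA_real_,
                   lambda = NA_real_, r2 = NA_real_)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    best <- list(r2 = -Inf)
    for (a in alphas) {
      fit <- if (is.null(lambda)) {
        glmnet::glmnet(X[tr, , drop = FALSE], y[tr], alpha = a,
                       nlambda = n_lambda,
                       lambda.min.ratio = lambda_min_ratio,
                       standardize = TRUE)
      } else {
        glmnet::glmnet(X[tr, , drop = FALSE], y[tr], alpha = a,
                       lambda = lambda, standardize = TRUE)
      }
      pred <- predict(fit, X[!tr, , drop = FALSE])
      r2s <- apply(pred, 2, function(p) r2_score(y[!tr], p))
      j <- which.max(r2s)
      if (r2s[j] > best$r2) {
        best <- list(r2 = r2s[j], alpha = a, lambda = fit$lambda[j], fit = fit)
      }
    }
    models[[f]] <- best[c("alpha", "lambda", "fit")]
    cv$alpha[f] <- best$alpha; cv$lambda[f] <- best$lambda; cv$r2[f] <- best$r2
  }
  structure(list(kind = "elastic_net", models = models, cv = cv,
                 fold = fold, seed = seed, p = ncol(X)),
            class = "model_bundle")
}

#' Predict from a fitted model bundle
#'
#' @param object a `model_bundle`
#' @param newdata matrix of predictors (or for network bundles, a list with
#'   `X_geno` and `X_cov`)
#' @param ... unused
#' @return numeric vector of predictions
#' @export
predict.model_bundle <- function(object, newdata, ...) {
  switch(object$kind,
    elastic_net = {
      newdata <- as.matrix(newdata)
      preds <- vapply(object$models, function(mm) {
        as.vector(predict(mm$fit, newdata, s = mm$lambda))
      }, numeric(nrow(newdata)))
      if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
      rowMeans(preds)
    },
    nonlinear_net = lc_net_forward(object$net, newdata$X_geno %||% newdata,
                                   newdata$X_cov)$yhat,
    boosted_tree = boost_predict(object, newdata),
    linear_ols = as.vector(cbind(1, as.matrix(newdata)) %*% object$beta),
    stopf("unknown model kind '%s'", object$kind))
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("model_bundle kind=%s (p=%s)\n", x$kind, x$p %||% "?"))
  invisible(x)
}
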