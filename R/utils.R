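#' @useDynLib pqtlgap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef complete.cases cor dnorm lm.fit model.matrix pnorm
#'   predict pt qbeta qnorm quantile rbinom rnorm runif sd setNames var
#' @importFrom utils head read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

#' Coefficient of determination
#'
#' R-squared against the mean of the observed values, the convention used by
#' scikit-learn's `r2_score`: can be negative on held-out data when the model
#' predicts worse than the mean.
#'
#' @param y_true observed values
#' @param y_pred predicted values
#' @return scalar R-squared
#' @export
r2_score <- function(y_true, y_pred) {
  assert_that(length(y_true) == length(y_pred), "length mismatch in r2_score")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Root mean squared error
#' @param y_true observed values
#' @param y_pred predicted values
#' @return scalar RMSE
#' @export
rmse_score <- function(y_true, y_pred) {
  sqrt(mean((y_true - y_pred)^2))
}

# Per-column mean imputation of an {0,1,2,NA} dosage matrix; all-NA columns
# become 0. Returns a plain numeric matrix.
impute_dosage <- function(dosage) {
  X <- dosage
  storage.mode(X) <- "double"
  if (!anyNA(X)) return(X)
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- cm[idx[, 2L]]
  X
}

# Derive a stream-specific 32-bit seed from a base seed without collisions
# across small offsets.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}
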