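# Per-variant and pairwise association scans. All tests are OLS with exact
# residual degrees of freedom; covariates are adjusted for by the
# Frisch-Waugh-Lovell residualization, which leaves coefficients, SEs and
# t-tests identical to the full regression when the df are counted correctly.

#' Build a numeric covariate design matrix
#'
#' Numeric columns pass through; factors/characters are expanded to
#' treatment-coded dummies. No intercept column (fitters add their own).
#'
#' @param S covariate data.frame
#' @param exclude column names to drop (default `sample_id`)
#' @return numeric matrix with one row per sample (0 columns when S is NULL)
#' @export
covariate_design <- function(S, exclude = "sample_id") {
  if (is.null(S)) return(NULL)
  S <- S[, setdiff(names(S), exclude), drop = FALSE]
  if (ncol(S) == 0) return(NULL)
  model.matrix(~ ., data = as.data.frame(lapply(S, function(v) {
    if (is.character(v)) factor(v) else v
  })))[, -1, drop = FALSE]
}

# Orthonormal basis of [1 | C]; residualize(v) = v - Q (Q'v).
covariate_projector <- function(n, C = NULL) {
  X <- cbind(rep(1, n), C)
  qrX <- qr(X)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  list(Q = Q, rank = qrX$rank)
}

residualize <- function(proj, v) {
  v - proj$Q %*% crossprod(proj$Q, v)
}

#' Additive-coded genome-wide association scan
#'
#' For each variant, OLS of the trait on additive dosage (missing mean-imputed
#' per variant) plus covariates; two-sided t-test on the dosage coefficient.
#' Variants with no dosage variance after covariate adjustment are flagged
#' inestimable with p = 1 by convention.
#'
#' @param G [genotype_matrix()]
#' @param y numeric trait vector
#' @param covariates covariate data.frame or design matrix (optional)
#' @return data.frame: variant, chrom, pos, coding, beta, se, t, p, estimable
#' @export
gwas_scan <- function(G, y, covariates = NULL) {
  n <- length(y)
  assert_that(n == nrow(G$dosage), "trait and genotypes disagree on n")
  C <- if (is.data.frame(covariates)) covariate_design(covariates) else covariates
  proj <- covariate_projector(n, C)
  X <- impute_dosage(G$dosage)
  Gres <- X - proj$Q %*% crossprod(proj$Q, X)
  yres <- as.vector(residualize(proj, y))
  ss_g <- colSums(Gres^2)
  df <- n - proj$rank - 1L
  assert_that(df >= 1, "not enough residual degrees of freedom")
  gy <- as.vector(crossprod(Gres, yres))
  beta <- ifelse(ss_g > 1e-12, gy / ss_g, NA_real_)
  rss <- sum(yres^2) - ifelse(is.na(beta), 0, beta * gy)
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / ss_g)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  estimable <- ss_g > 1e-12 & is.finite(p)
  p[!estimable] <- 1
  data.frame(variant = G$variants$id, chrom = G$variants$chrom,
             pos = G$variants$pos, coding = "additive",
             beta = beta, se = ifelse(estimable, se, NA_real_),
             t = ifelse(estimable, tstat, NA_real_), p = p,
             estimable = estimable, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Pre-filter variants on scan p-values
#'
#' Keeps variants with p strictly below the threshold (inestimable records
#' never pass), preserving scan order.
#'
#' @param records data.frame from [gwas_scan()]
#' @param p_threshold strict upper bound on p (default 1e-3)
#' @return character vector of variant ids
#' @export
prefilter <- function(records, p_threshold = 1e-3) {
  records$variant[records$estimable & records$p < p_threshold]
}

#' Per-genotype (one-hot) non-additivity test
#'
#' OLS with heterozygote and homozygote-alternate indicators (homozygous
#' reference is the dropped reference level) plus covariates. Also returns a
#' 1-df dominance contrast testing the heterozygote effect against half the
#' homozygote-alternate effect (deviation from additivity).
#'
#' @param g dosage vector in \{0,1,2,NA\} (missing dropped)
#' @param y trait vector
#' @param covariates covariate data.frame or design matrix (optional)
#' @return list with `coefficients` (data.frame term/beta/se/t/p),
#'   `dominance` (contrast estimate/se/t/p or NAs when inestimable),
#'   `classes_present`, `n`
#' @export
nonadditivity_ols <- function(g, y, covariates = NULL) {
  C <- if (is.data.frame(covariates)) covariate_design(covariates) else covariates
  obs <- !is.na(g)
  g <- g[obs]; y <- y[obs]
  if (!is.null(C)) C <- C[obs, , drop = FALSE]
  classes <- sort(unique(g))
  assert_that(length(classes) >= 2, "need >= 2 observed genotype classes")
  Z <- cbind(het = as.numeric(g == 1), hom_alt = as.numeric(g == 2))
  present <- c(1 %in% classes, 2 %in% classes)
  Z <- Z[, present, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, Z, C)
  fit <- lm.fit(X, y)
  df <- length(y) - fit$rank
  assert_that(df >= 1, "not enough residual degrees of freedom")
  sigma2 <- sum(fit$residuals^2) / df
  R <- qr.R(fit$qr)[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  XtXinv <- chol2inv(R)
  piv <- fit$qr$pivot[seq_len(fit$rank)]
  vc <- matrix(NA_real_, ncol(X), ncol(X),
               dimnames = list(colnames(X), colnames(X)))
  vc[piv, piv] <- XtXinv * sigma2
  b <- fit$coefficients
  se <- sqrt(diag(vc))
  tstat <- b / se
  p <- 2 * pt(-abs(tstat), df)
  terms <- c("(Intercept)", colnames(Z))
  coefs <- data.frame(term = terms, beta = b[terms], se = se[terms],
                      t = tstat[terms], p = p[terms],
                      stringsAsFactors = FALSE, row.names = NULL)
  dominance <- list(estimate = NA_real_, se = NA_real_, t = NA_real_,
                    p = NA_real_)
  if (all(present) && !anyNA(b[c("het", "hom_alt")])) {
    ct <- setNames(numeric(ncol(X)), colnames(X))
    ct["het"] <- 1; ct["hom_alt"] <- -0.5
    est <- sum(ct * ifelse(is.na(b), 0, b))
    vce <- as.numeric(t(ct) %*% ifelse(is.na(vc), 0, vc) %*% ct)
    dominance <- list(estimate = est, se = sqrt(vce),
                      t = est / sqrt(vce),
                      p = 2 * pt(-abs(est / sqrt(vce)), df))
  }
  list(coefficients = coefs, dominance = dominance,
       classes_present = classes, n = length(y))
}

#' Number of pairwise interaction tests
#'
#' @param n_variants variants entering the scan per trait
#' @param n_traits number of traits pooled in the family
#' @return `choose(n_variants, 2) * n_traits`
#' @export
interaction_pair_count <- function(n_variants, n_traits = 1) {
  choose(n_variants, 2) * n_traits
}

#' Bonferroni threshold for the interaction scan
#' @param n_pairs total pairs tested in the family
#' @param alpha family-wise error rate
#' @return alpha / n_pairs
#' @export
bonferroni_threshold <- function(n_pairs, alpha = 0.05) {
  assert_that(n_pairs >= 1, "n_pairs must be >= 1")
  alpha / n_pairs
}

#' Pairwise epistasis scan
#'
#' For every variant pair, OLS with one-hot main effects for both variants, a
#' single product term of the additive codings, and covariates; the reported
#' test is the two-sided t-test on the product coefficient. Pairs whose
#' product term is collinear with the main effects are skipped and logged.
#'
#' @param G_top [genotype_matrix()] restricted to the variants to scan
#' @param y trait vector
#' @param covariates covariate data.frame or design matrix (optional)
#' @param alpha family-wise level for the Bonferroni threshold
#' @param cross_chromosome_only test only pairs on different chromosomes
#' @param n_comparisons Bonferroni denominator; defaults to the number of
#'   pairs tested in this run, pass a pooled count (e.g.
#'   [interaction_pair_count()] across traits) to reproduce a pooled family
#' @return list with `results` (all tested pairs, sorted by p), `hits`
#'   (p < threshold), `n_pairs_tested`, `bonferroni_threshold`, `skipped`
#' @export
interaction_scan <- function(G_top, y, covariates = NULL, alpha = 0.05,
                             cross_chromosome_only = FALSE,
                             n_comparisons = NULL) {
  n <- length(y)
  m <- nrow(G_top$variants)
  assert_that(m >= 2, "need at least two variants")
  C <- if (is.data.frame(covariates)) covariate_design(covariates) else covariates
  proj <- covariate_projector(n, C)
  X <- impute_dosage(G_top$dosage)
  yres <- as.vector(residualize(proj, y))
  # residualized one-hot and additive codings, precomputed per variant
  H1 <- X == 1; H2 <- X == 2
  H1r <- H1 - proj$Q %*% crossprod(proj$Q, H1)
  H2r <- H2 - proj$Q %*% crossprod(proj$Q, H2)
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  if (cross_chromosome_only) {
    chr <- G_top$variants$chrom
    pairs <- pairs[chr[pairs[, 1]] != chr[pairs[, 2]], , drop = FALSE]
  }
  res <- vector("list", nrow(pairs))
  skipped <- character(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    prod_ij <- X[, i] * X[, j]
    Z <- cbind(H1r[, i], H2r[, i], H1r[, j], H2r[, j],
               as.vector(residualize(proj, prod_ij)))
    fit <- lm.fit(Z, yres)
    df <- n - proj$rank - fit$rank
    cf <- fit$coefficients
    # the product term is column 5; identified only if not pivoted out
    if (is.na(cf[5]) || df < 1) {
      skipped <- c(skipped, paste0(G_top$variants$id[i], ":",
                                   G_top$variants$id[j]))
      next
    }
    R <- qr.R(fit$qr)[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
    XtXinv <- chol2inv(R)
    piv <- fit$qr$pivot[seq_len(fit$rank)]
    sigma2 <- sum(fit$residuals^2) / df
    vdiag <- rep(NA_real_, 5)
    vdiag[piv] <- diag(XtXinv) * sigma2
    se <- sqrt(vdiag[5])
    tstat <- cf[5] / se
    res[[k]] <- data.frame(variant_i = G_top$variants$id[i],
                           variant_j = G_top$variants$id[j],
                           chrom_i = G_top$variants$chrom[i],
                           chrom_j = G_top$variants$chrom[j],
                           beta3 = cf[5], se = se, t = tstat,
                           p = 2 * pt(-abs(tstat), df),
                           stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  n_tested <- if (is.null(results)) 0L else nrow(results)
  denom <- n_comparisons %||% n_tested
  thr <- if (denom >= 1) bonferroni_threshold(denom, alpha) else NA_real_
  if (!is.null(results)) {
    results <- results[order(results$p), , drop = FALSE]
    rownames(results) <- NULL
  }
  list(results = results,
       hits = if (is.null(results)) NULL else
         results[results$p < thr, , drop = FALSE],
       n_pairs_tested = n_tested, bonferroni_threshold = thr,
       skipped = skipped)
}
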