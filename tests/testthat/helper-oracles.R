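# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense normal equations instead of FWL
# residualization, log-factorial enumeration instead of the recurrence, a
# plain re-implementation of the paired bootstrap.

# OLS via dense normal equations; returns beta, se, t, p for every column.
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- unname(sqrt(diag(solve(XtX)) * sigma2))
  tstat <- as.vector(beta) / se
  list(beta = as.vector(beta), se = se, t = tstat,
       p = 2 * pt(-abs(tstat), df), df = df, rss = sum(res^2))
}

# HWE exact test by direct log-factorial enumeration over heterozygote counts.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (rare == 0) return(1)
  common <- 2 * n - rare
  hets <- seq(rare %% 2, min(rare, common), by = 2)
  logp <- vapply(hets, function(h) {
    homr <- (rare - h) / 2
    homc <- n - h - homr
    lfactorial(n) - lfactorial(h) - lfactorial(homr) - lfactorial(homc) +
      h * log(2) + lfactorial(rare) + lfactorial(common) - lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[hets == n_het]
  # same tie-inclusion slack as the implementation under test
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# the same distribution, as a vector over heterozygote counts
hwe_oracle_distribution <- function(rare, n) {
  common <- 2 * n - rare
  hets <- seq(rare %% 2, min(rare, common), by = 2)
  logp <- vapply(hets, function(h) {
    homr <- (rare - h) / 2
    homc <- n - h - homr
    lfactorial(n) - lfactorial(h) - lfactorial(homr) - lfactorial(homc) +
      h * log(2)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  list(hets = hets, probs = probs / sum(probs))
}

# Naive paired-bootstrap re-implementation (same RNG protocol as
# bootstrap_compare, independent computation of the statistics).
naive_bootstrap <- function(y, a, b, n_boot, seed) {
  set.seed(seed)
  n <- length(y)
  r2 <- function(yt, yp) 1 - sum((yt - yp)^2) / sum((yt - mean(yt))^2)
  r2a <- r2b <- rma <- rmb <- rep(NA_real_, n_boot)
  for (k in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    if (var(y[i]) == 0) next
    r2a[k] <- r2(y[i], a[i]); r2b[k] <- r2(y[i], b[i])
    rma[k] <- sqrt(mean((y[i] - a[i])^2)); rmb[k] <- sqrt(mean((y[i] - b[i])^2))
  }
  ok <- !is.na(r2a)
  list(r2_a = mean(r2a[ok]), r2_b = mean(r2b[ok]),
       r2_ci_a = unname(quantile(r2a[ok], c(0.025, 0.975))),
       r2_ci_b = unname(quantile(r2b[ok], c(0.025, 0.975))),
       rmse_a = mean(rma[ok]), rmse_b = mean(rmb[ok]),
       gap = mean(r2a[ok]) - mean(r2b[ok]),
       empirical_p = mean(r2a[ok] <= r2b[ok]))
}

# small simulated study shared by several files
make_study <- function(n = 400, m = 25, seed = 42, missing_rate = 0,
                       n_pcs = 2) {
  G <- simulate_genotypes(geno_sim_config(n, m, missing_rate = missing_rate,
                                          seed = seed))
  S <- simulate_covariates(n, n_pcs = n_pcs, seed = seed)
  list(G = G, S = S)
}
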