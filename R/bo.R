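# Bayesian optimization of a single fraction in (0, 1]: Gaussian-process
# surrogate (RBF kernel) with expected-improvement acquisition maximized on a
# dense grid. Seed fractions are always evaluated before any proposal.

gp_posterior <- function(x, y, x_new, lengthscale = 0.15, noise = 1e-6) {
  ymu <- mean(y); ysd <- max(sd(y), 1e-12)
  ys <- (y - ymu) / ysd
  k <- function(a, b) exp(-0.5 * outer(a, b, "-")^2 / lengthscale^2)
  K <- k(x, x) + diag(noise + 1e-10, length(x))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  Ks <- k(x_new, x)
  mu <- as.vector(Ks %*% alpha)
  v <- forwardsolve(t(L), t(Ks))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  list(mu = mu * ysd + ymu, sd = sqrt(s2) * ysd)
}

expected_improvement <- function(mu, sd, best) {
  z <- (mu - best) / sd
  (mu - best) * pnorm(z) + sd * dnorm(z)
}

#' Search the top-variant fraction by Bayesian optimization
#'
#' Evaluates the seed fractions first, then runs `n_iter` rounds of
#' GP-surrogate expected-improvement search over (0, 1]. Non-finite objective
#' values are recorded as failures and excluded from the surrogate; the search
#' continues.
#'
#' @param objective function(fraction) -> validation score (higher is better)
#' @param seeds fractions evaluated before any proposal
#' @param n_iter number of BO evaluations after the seeds
#' @param seed RNG seed (proposal jitter)
#' @param bounds search interval within (0, 1]
#' @return list: `best_fraction`, `best_score`, `trace` (data.frame fraction /
#'   score / phase in evaluation order)
#' @export
bo_fraction_search <- function(objective, seeds = c(0.1, 0.25, 0.5, 1),
                               n_iter = 15L, seed = 1L,
                               bounds = c(0.005, 1)) {
  assert_that(length(seeds) >= 1 || n_iter >= 1, "nothing to evaluate")
  assert_that(all(seeds > 0 & seeds <= 1), "seed fractions must be in (0,1]")
  set.seed(seed)
  trace <- data.frame(fraction = numeric(0), score = numeric(0),
                      phase = character(0), stringsAsFactors = FALSE)
  eval_point <- function(f, phase) {
    s <- tryCatch(objective(f), error = function(e) NA_real_)
    if (!is.finite(s)) s <- NA_real_
    trace[nrow(trace) + 1L, ] <<- list(f, s, phase)
  }
  for (f in seeds) eval_point(f, "seed")
  grid <- seq(bounds[1], bounds[2], length.out = 512L)
  if (n_iter > 0) for (it in seq_len(n_iter)) {
    ok <- !is.na(trace$score)
    if (sum(ok) < 2 || sd(trace$fraction[ok]) == 0) {
      cand <- runif(1, bounds[1], bounds[2])
    } else {
      post <- gp_posterior(trace$fraction[ok], trace$score[ok], grid)
      ei <- expected_improvement(post$mu, post$sd, max(trace$score[ok]))
      # avoid re-evaluating (numerically) visited points
      seen <- vapply(grid, function(g) min(abs(g - trace$fraction)),
                     numeric(1))
      ei[seen < 1e-4] <- -Inf
      cand <- grid[which.max(ei)] + runif(1, -1, 1) * 1e-4
      cand <- min(max(cand, bounds[1]), bounds[2])
    }
    eval_point(cand, "bo")
  }
  ok <- which(!is.na(trace$score))
  assert_that(length(ok) > 0, "all objective evaluations failed")
  best <- ok[which.max(trace$score[ok])]
  list(best_fraction = trace$fraction[best], best_score = trace$score[best],
       trace = trace)
}
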