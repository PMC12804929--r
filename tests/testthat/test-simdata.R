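test_that("simulated genotypes hit their drawn MAF and obey the seed", {
  cfg <- geno_sim_config(50000, 1, maf_range = c(0.3, 0.3), seed = 7)
  G <- simulate_genotypes(cfg)
  expect_equal(unname(colMeans(G$dosage) / 2), 0.3, tolerance = 0.01 / 0.3)

  cfg2 <- geno_sim_config(500, 30, missing_rate = 0.05, seed = 9)
  expect_identical(simulate_genotypes(cfg2)$dosage,
                   simulate_genotypes(cfg2)$dosage)
  expect_error(geno_sim_config(0, 5), "positive")
  expect_error(geno_sim_config(10, 5, maf_range = c(0, 0.5)), "maf_range")
})

test_that("LD structure is present within blocks and absent without", {
  G0 <- simulate_genotypes(geno_sim_config(10000, 10, ld_block_size = 1,
                                           seed = 3))
  r_adj <- vapply(1:9, function(j) {
    cor(G0$dosage[, j], G0$dosage[, j + 1])
  }, numeric(1))
  expect_true(all(abs(r_adj) < 0.05))

  Gld <- simulate_genotypes(geno_sim_config(4000, 12, ld_block_size = 4,
                                            ld_decay = 0.8, seed = 3))
  within <- c(cor(Gld$dosage[, 1], Gld$dosage[, 2]),
              cor(Gld$dosage[, 5], Gld$dosage[, 6]))
  across <- cor(Gld$dosage[, 4], Gld$dosage[, 5])
  expect_true(all(within > 0.4))
  expect_lt(abs(across), 0.08)
})

test_that("simulated genotypes are in Hardy-Weinberg proportions", {
  G <- simulate_genotypes(geno_sim_config(10000, 200, seed = 5))
  d <- G$dosage
  p <- vapply(seq_len(ncol(d)), function(j) {
    hwe_exact_test(sum(d[, j] == 0), sum(d[, j] == 1), sum(d[, j] == 2))
  }, numeric(1))
  expect_gte(mean(p > 1e-6), 0.99)
})

test_that("trait simulation: null, noiseless additive, dominance cases", {
  st <- make_study(n = 10000, m = 10, seed = 21)
  null_spec <- effect_spec(noise_sd = 1)
  tr <- simulate_trait(st$G, st$S, null_spec, seed = 4)
  expect_gte(var(tr$y), 0.9)
  expect_lte(var(tr$y), 1.1)

  add_spec <- effect_spec(additive = data.frame(variant = c(2, 5),
                                                beta = c(1, -0.5)),
                          noise_sd = 0)
  tra <- simulate_trait(st$G, st$S, add_spec, seed = 4)
  X <- cbind(1, st$G$dosage[, c(2, 5)])
  fit <- lm.fit(X, tra$y)
  expect_lt(sum(fit$residuals^2) / sum((tra$y - mean(tra$y))^2), 1e-9)

  dom_spec <- effect_spec(dominance = data.frame(variant = 3, m0 = 0,
                                                 m1 = 1, m2 = 1),
                          noise_sd = 0)
  trd <- simulate_trait(st$G, st$S, dom_spec, seed = 4)
  g <- st$G$dosage[, 3]
  expect_equal(mean(trd$y[g == 1]), mean(trd$y[g == 2]), tolerance = 1e-9)
  r2_add <- summary(lm(trd$y ~ g))$r.squared
  r2_onehot <- summary(lm(trd$y ~ factor(g)))$r.squared
  expect_lt(r2_add, r2_onehot)
})

test_that("ground-truth ledger accounts for the trait variance", {
  st <- make_study(n = 8000, m = 20, seed = 31)
  spec <- effect_spec(
    additive = data.frame(variant = 1:3, beta = c(0.5, -0.4, 0.3)),
    dominance = data.frame(variant = 5, m0 = 0, m1 = 0.8, m2 = 0.8),
    epistasis = list(list(variant_i = 7, variant_j = 8,
                          table = matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 2), 3))),
    gxe = data.frame(variant = 9, covariate = "sex", beta = 0.6),
    noise_sd = 1)
  tr <- simulate_trait(st$G, st$S, spec, seed = 12)
  # components are not mutually orthogonal, so compare against the full
  # covariance-based total rather than the naive sum of variances
  expect_equal(var(tr$y), var(rowSums(tr$components)), tolerance = 1e-12)
  total <- sum(tr$ledger$variance) +
    2 * sum(cov(tr$components)[upper.tri(cov(tr$components))])
  expect_equal(var(tr$y), total, tolerance = 1e-8)
  # each ledger entry matches the empirical variance of its component, and
  # off-diagonal covariance is Monte-Carlo small (independent draws)
  expect_equal(tr$ledger$variance, unname(apply(tr$components, 2, var)))
  offdiag <- cov(tr$components)[upper.tri(cov(tr$components))]
  expect_lt(max(abs(offdiag)), 3 * max(tr$ledger$variance) / sqrt(nrow(st$S)))
})

test_that("log2like warp is monotone and sign-preserving; errors are typed", {
  st <- make_study(n = 200, m = 5, seed = 8)
  spec_raw <- effect_spec(additive = data.frame(variant = 1, beta = 1),
                          noise_sd = 0.5)
  spec_log <- effect_spec(additive = data.frame(variant = 1, beta = 1),
                          noise_sd = 0.5, scale = "log2like")
  y_raw <- simulate_trait(st$G, st$S, spec_raw, seed = 2)$y
  y_log <- simulate_trait(st$G, st$S, spec_log, seed = 2)$y
  expect_identical(order(y_raw), order(y_log))
  expect_identical(sign(y_raw), sign(y_log))

  bad <- effect_spec(gxe = data.frame(variant = 1, covariate = "nope",
                                      beta = 1))
  expect_error(simulate_trait(st$G, st$S, bad, seed = 1), "unknown covariate")
})

test_that("covariate simulation honours its shape contract", {
  S <- simulate_covariates(1000, n_pcs = 20, seed = 6)
  expect_length(grep("^PC", names(S)), 20)
  expect_true(all(c("age", "sex", "center") %in% names(S)))
  expect_identical(S, simulate_covariates(1000, n_pcs = 20, seed = 6))
  S0 <- simulate_covariates(50, n_pcs = 0, seed = 6)
  expect_length(grep("^PC", names(S0)), 0)
})

test_that("write_study round-trips and the .bed payload is bit-exact", {
  st <- make_study(n = 60, m = 12, seed = 13, missing_rate = 0.05)
  tr <- simulate_trait(st$G, st$S, effect_spec(noise_sd = 1), seed = 1)
  td <- withr::local_tempdir()
  write_study(st$G, st$S, list(y = tr$y), td)
  G2 <- read_plink(file.path(td, "study"))
  expect_identical(st$G$dosage, G2$dosage)
  expect_identical(st$G$variants$id, G2$variants$id)

  # 4 samples x 5 variants: ceil(4/4) = 1 byte per variant + 3 magic bytes
  G4 <- st$G[1:4, 1:5]
  write_plink(G4, file.path(td, "tiny"))
  expect_identical(file.size(file.path(td, "tiny.bed")), 3 + 5 * 1)

  G_empty <- st$G[, integer(0)]
  expect_error(write_plink(G_empty, file.path(td, "none")), "no variants")
})
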