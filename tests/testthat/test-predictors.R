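test_that("encode obeys the stated column contracts", {
  d <- matrix(c(0L, 1L, 2L, NA), 4, 3)
  G <- genotype_matrix(d, data.frame(chrom = 1, id = c("a", "b", "c"),
                                     pos = 1:3, allele1 = "A", allele2 = "G"),
                       paste0("S", 1:4))
  oh <- encode(G, "onehot")
  expect_identical(ncol(oh$X), 12L)  # 4m columns
  expect_equal(unname(oh$X[2, 1:4]), c(0, 1, 0, 0))  # dosage 1
  expect_equal(unname(oh$X[4, 1:4]), c(0, 0, 0, 1))  # missing indicator

  ad <- encode(G, "additive")
  expect_equal(unname(ad$X[4, 1]), 1)  # mean of observed {0,1,2}
  # column map is invertible
  expect_identical(oh$colmap$variant[match("b.het", oh$colmap$column)], "b")
})

test_that("elastic net reduces to OLS at vanishing penalty", {
  set.seed(21)
  n <- 400; p <- 5
  X <- matrix(rnorm(n * p), n)
  beta <- c(1, -2, 0.5, 0, 3)
  y <- as.vector(X %*% beta) + rnorm(n, 0, 0.1)
  lam <- c(0.5, 0.05, 1e-10)  # explicit path ending at a vanishing penalty
  en <- fit_elastic_net_cv(X, y, k_folds = 4, seed = 2, lambda = lam)
  # the near-zero end of every fold path equals the OLS fit on that fold's
  # in-fold data to high precision, for any alpha
  for (f in 1:4) {
    m <- en$models[[f]]
    tr <- en$fold != f
    o <- ols_oracle(cbind(1, X[tr, ]), y[tr])
    b_path <- as.numeric(coef(m$fit, s = 1e-10))
    expect_equal(b_path, o$beta, tolerance = 1e-6)
  }
  pred_en <- predict(en, X)
  o_all <- ols_oracle(cbind(1, X), y)
  expect_lt(max(abs(pred_en - as.vector(cbind(1, X) %*% o_all$beta))), 0.05)

  # noiseless realizable target: out-of-fold R2 > 0.999
  y0 <- as.vector(X %*% beta)
  en0 <- fit_elastic_net_cv(X, y0, k_folds = 4, seed = 2, lambda = lam)
  expect_true(all(en0$cv$r2 > 0.999))
  expect_error(fit_elastic_net_cv(X, rep(1, n)), "constant")
})

test_that("lasso coefficient equals the soft-thresholded slope", {
  set.seed(22)
  n <- 200
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- 0.4 * x + rnorm(n)
  fit <- glmnet::glmnet(cbind(x, 0), y, alpha = 1, standardize = FALSE)
  for (k in c(5L, 20L, length(fit$lambda))) {
    lam <- fit$lambda[k]
    b_ols <- mean(x * (y - mean(y)))
    b_expect <- sign(b_ols) * max(abs(b_ols) - lam, 0)
    expect_equal(unname(coef(fit, s = lam, exact = FALSE)[2]), b_expect,
                 tolerance = 1e-6)
  }
})

# shared benchmark harness: train/val/test at 70/15/15, elastic net on
# additive encoding + covariates vs the network on one-hot + covariates
net_vs_enet <- function(n, m, seed_g, spec, maf = c(0.05, 0.5)) {
  G <- simulate_genotypes(geno_sim_config(n, m, maf_range = maf,
                                          seed = seed_g))
  S <- simulate_covariates(n, n_pcs = 0, seed = seed_g)
  tr <- simulate_trait(G, S, spec, seed = 10)
  oh <- encode(G, "onehot"); ad <- encode(G, "additive")
  C <- covariate_design(S)
  itr <- 1:round(0.7 * n)
  iva <- (round(0.7 * n) + 1):round(0.85 * n)
  ite <- (round(0.85 * n) + 1):n
  en <- fit_elastic_net_cv(cbind(ad$X, C)[c(itr, iva), ], tr$y[c(itr, iva)],
                           alphas = c(0.01, 1), n_lambda = 60, k_folds = 4,
                           seed = 1)
  net <- fit_nonlinear_predictor(
    list(train = oh$X[itr, ], val = oh$X[iva, ]),
    list(train = C[itr, ], val = C[iva, ]),
    tr$y[itr], tr$y[iva],
    arch = list(max_epochs = 200, lr = 3e-3, patience = 25, dropout = 0.3,
                weight_decay = 1e-2),
    seed = 1)
  c(enet = r2_score(tr$y[ite], predict(en, cbind(ad$X, C)[ite, ])),
    net = r2_score(tr$y[ite], predict(net, list(X_geno = oh$X[ite, ],
                                                X_cov = C[ite, ]))))
}

test_that("the nonlinear predictor learns planted non-additive structure", {
  # dominance plus XOR-type epistasis (no additive component) at common
  # MAFs: most trait variance is invisible to the additive linear model
  xor_tab <- outer(0:2, 0:2, function(a, b) 1.5 * ((a >= 1) != (b >= 1)))
  spec <- effect_spec(
    dominance = data.frame(variant = c(5, 12), m0 = 0, m1 = 1.2, m2 = 0.1),
    epistasis = list(list(variant_i = 20, variant_j = 40, table = xor_tab)),
    noise_sd = 0.6)
  r2 <- net_vs_enet(3000, 60, 33, spec, maf = c(0.3, 0.5))
  expect_gt(r2["net"], r2["enet"] + 0.05)
})

test_that("on a purely additive trait the net matches the elastic net", {
  spec <- effect_spec(additive = data.frame(variant = c(3, 9, 15, 22, 30),
                                            beta = c(0.6, -0.5, 0.5, 0.4,
                                                     -0.4)),
                      noise_sd = 0.8)
  r2 <- net_vs_enet(5000, 60, 34, spec)
  expect_lt(abs(r2["net"] - r2["enet"]), 0.05)
})

test_that("zero-epoch training returns the untrained initialization", {
  st <- make_study(n = 300, m = 10, seed = 35, n_pcs = 0)
  y <- rnorm(300)
  oh <- encode(st$G, "onehot")
  net <- fit_nonlinear_predictor(
    list(train = oh$X[1:200, ], val = oh$X[201:300, ]),
    NULL, y[1:200], y[201:300],
    arch = list(max_epochs = 0), seed = 3)
  expect_identical(net$meta$epochs, 0L)
  expect_lt(abs(net$meta$val_r2), 0.3)  # untrained: no learned signal
})

test_that("integrated gradients is exact for an affine network", {
  # biases large enough that every ReLU stays active over the whole path:
  # the network is then affine and IG must equal w * (x - x') exactly
  arch <- list(window = 1L, units_per_window = 2L, hidden = c(3L),
               dropout = 0, cols_per_variant = 4L, n_variants = 2L)
  net <- pqtlgap:::lc_net_init(8L, 0L, arch, seed = 5)
  for (nm in names(net$params)) {
    if (grepl("^W", nm)) net$params[[nm]] <- net$params[[nm]] * 0.2
    if (grepl("^b", nm) && nm != paste0("bd", net$n_dense)) {
      net$params[[nm]] <- rep(10, length(net$params[[nm]]))
    }
  }
  model <- structure(list(kind = "nonlinear_net", net = net, p = 8L),
                     class = "model_bundle")
  X <- matrix(runif(5 * 8), 5)
  ig <- attribute_integrated_gradients(model, list(X_geno = X), n_steps = 8)
  # effective affine weights from the (everywhere-active) linear composition
  W1 <- net$params$W1
  w_eff <- W1 %*% net$params$Wd1 %*% net$params$Wd2
  expect_equal(ig$attr_geno, X * matrix(w_eff, 5, 8, byrow = TRUE),
               tolerance = 1e-10)
  expect_lt(ig$completeness_err, 1e-10)

  # zero output head: all attributions vanish
  net0 <- net; net0$params$Wd2 <- net0$params$Wd2 * 0
  m0 <- structure(list(kind = "nonlinear_net", net = net0, p = 8L),
                  class = "model_bundle")
  ig0 <- attribute_integrated_gradients(m0, list(X_geno = X), n_steps = 8)
  expect_true(all(ig0$attr_geno == 0))
  expect_error(attribute_integrated_gradients(model, list(X_geno = X),
                                              n_steps = 1), "n_steps")
})

test_that("IG completeness holds on a trained network", {
  st <- make_study(n = 600, m = 12, seed = 36, n_pcs = 0)
  spec <- effect_spec(dominance = data.frame(variant = 4, m0 = 0, m1 = 1,
                                             m2 = 1), noise_sd = 0.5)
  tr <- simulate_trait(st$G, st$S, spec, seed = 2)
  oh <- encode(st$G, "onehot")
  C <- covariate_design(st$S)
  net <- fit_nonlinear_predictor(
    list(train = oh$X[1:400, ], val = oh$X[401:600, ]),
    list(train = C[1:400, ], val = C[401:600, ]),
    tr$y[1:400], tr$y[401:600], arch = list(max_epochs = 25), seed = 4)
  ig <- attribute_integrated_gradients(
    net, list(X_geno = oh$X[401:450, ], X_cov = C[401:450, ]),
    n_steps = 2048)
  expect_lt(ig$completeness_err, 1e-3)
})

test_that("select_top_snvs ranks, averages absolutes, breaks ties by index", {
  s1 <- c(a = 3, b = 1, c = 2)
  expect_identical(select_top_snvs(list(s1), k = 2), c("a", "c"))
  s2 <- c(a = -3, b = -1, c = -2)
  expect_identical(select_top_snvs(list(s1, s2), k = 2),
                   select_top_snvs(list(s1), k = 2))
  ties <- c(a = 1, b = 2, c = 1)
  expect_identical(select_top_snvs(list(ties), k = 2), c("b", "a"))
  expect_message(out <- select_top_snvs(list(s1), k = 10), "returning all")
  expect_length(out, 3)
})

test_that("bo_fraction_search honours seeds, monotone and unimodal shapes", {
  mono <- bo_fraction_search(function(f) f, seeds = c(0.2, 0.5, 0.9),
                             n_iter = 0, seed = 1)
  expect_identical(mono$best_fraction, 0.9)
  expect_identical(mono$trace$phase, rep("seed", 3))

  uni <- bo_fraction_search(function(f) -(f - 0.3)^2,
                            seeds = c(0.1, 0.9), n_iter = 15, seed = 2)
  expect_lt(abs(uni$best_fraction - 0.3), 0.1)

  flaky <- bo_fraction_search(function(f) if (f < 0.5) NaN else f,
                              seeds = c(0.2, 0.8), n_iter = 5, seed = 3)
  expect_true(is.na(flaky$trace$score[1]))
  expect_gte(flaky$best_fraction, 0.5)
})

test_that("constrained boosting isolates GxG and GxE signal by stage", {
  st <- make_study(n = 3000, m = 20, seed = 37, n_pcs = 0)
  X <- pqtlgap:::impute_dosage(st$G$dosage)
  C <- covariate_design(st$S)
  splits <- list(train = 1:1800, val = 1801:2400, test = 2401:3000)

  # epistasis-only trait
  set.seed(6)
  y_gxg <- 1.2 * (X[, 3] >= 1) * (X[, 11] >= 1) + rnorm(3000, 0, 0.6)
  ds <- decompose_stages(X, C, y_gxg, splits, seed = 2)
  expect_gt(ds$gain_val[ds$stage == "plus_gxg"], 0.02)
  expect_lt(abs(ds$gain_val[ds$stage == "plus_gxe"]), 0.04)

  # GxE-only trait
  sex <- st$S$sex
  y_gxe <- 1.2 * X[, 5] * sex + rnorm(3000, 0, 0.6)
  ds2 <- decompose_stages(X, C, y_gxe, splits, seed = 2)
  expect_gt(ds2$gain_val[ds2$stage == "plus_gxe"], 0.02)
  expect_gt(ds2$gain_val[ds2$stage == "plus_gxe"],
            ds2$gain_val[ds2$stage == "plus_gxg"])

  # null trait: nothing to gain anywhere
  y0 <- rnorm(3000)
  ds0 <- decompose_stages(X, C, y0, splits, seed = 2)
  expect_true(all(abs(ds0$r2_val) < 0.02))
  expect_error(fit_constrained_boost(X, C, y0, stage = "nope"),
               "should be one of")
})
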