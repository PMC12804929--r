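test_that("bootstrap_compare: degenerate and decisive cases", {
  set.seed(51)
  y <- rnorm(100)
  p1 <- y + rnorm(100, 0, 0.5)
  same <- bootstrap_compare(y, p1, p1, n_boot = 200, seed = 1)
  expect_identical(same$gap, 0)
  expect_identical(same$empirical_p, 1)
  expect_false(same$significant_nonoverlap)

  perfect <- bootstrap_compare(y, y, rep(mean(y), 100), n_boot = 200,
                               seed = 1)
  expect_equal(perfect$r2_a, 1)
  expect_lt(abs(perfect$r2_b), 0.1)
  expect_true(perfect$significant_nonoverlap)
  expect_identical(perfect$empirical_p, 0)
  expect_error(bootstrap_compare(y[1:5], p1[1:5], p1[1:5]), "n >= 10")
})

test_that("bootstrap_compare agrees exactly with a naive re-implementation", {
  set.seed(52)
  y <- rnorm(20)
  a <- y + rnorm(20, 0, 0.3)
  b <- y + rnorm(20, 0, 0.6)
  s <- bootstrap_compare(y, a, b, n_boot = 400, seed = 7)
  o <- naive_bootstrap(y, a, b, n_boot = 400, seed = 7)
  for (f in c("r2_a", "r2_b", "rmse_a", "rmse_b", "gap", "empirical_p")) {
    expect_equal(s[[f]], o[[f]], tolerance = 1e-12)
  }
  expect_equal(s$r2_ci_a, o$r2_ci_a, tolerance = 1e-12)
  expect_equal(s$r2_ci_b, o$r2_ci_b, tolerance = 1e-12)
})

test_that("fdr_adjust implements BH step-up", {
  expect_identical(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(53)
  p <- runif(50)^2
  q <- fdr_adjust(p)
  expect_equal(q, stats::p.adjust(p, "BH"))
  perm <- sample(50)
  expect_equal(fdr_adjust(p[perm]), q[perm])
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  # zero clipping only with an explicit bootstrap floor
  expect_equal(fdr_adjust(c(0, 0.5), n_boot_floor = 1000)[1],
               stats::p.adjust(c(1e-3, 0.5), "BH")[1])
})

test_that("classify_gap_source follows the delta rule", {
  set.seed(54)
  n <- 200
  y <- rnorm(n)
  # not significant -> none
  a <- y + rnorm(n, 0, 0.5); b <- y + rnorm(n, 0, 0.55)
  s_full <- bootstrap_compare(y, a, b, n_boot = 300, seed = 2)
  s_cov <- bootstrap_compare(y, b, b, n_boot = 300, seed = 2)
  expect_identical(classify_gap_source(s_full, s_cov), "none")

  # clear full gap fully present in the covariate-only comparison
  a2 <- y + rnorm(n, 0, 0.2); b2 <- rep(mean(y), n)
  s_full2 <- bootstrap_compare(y, a2, b2, n_boot = 300, seed = 2)
  s_cov2 <- bootstrap_compare(y, a2, b2, n_boot = 300, seed = 3)
  expect_identical(classify_gap_source(s_full2, s_cov2),
                   "covariate_nonlinearity")

  # clear full gap absent from the covariate-only comparison
  s_cov3 <- bootstrap_compare(y, b2 + rnorm(n, 0, 0.01), b2, n_boot = 300,
                              seed = 2)
  expect_identical(classify_gap_source(s_full2, s_cov3),
                   "genetic_or_other_nonlinearity")
  s_bad <- bootstrap_compare(y[1:50], a2[1:50], b2[1:50], n_boot = 50,
                             seed = 1)
  expect_error(classify_gap_source(s_full2, s_bad), "different sample sets")
})

test_that("iterative complexity telescopes and localizes planted GxE", {
  st <- make_study(n = 8000, m = 10, seed = 55, n_pcs = 1)
  X <- pqtlgap:::impute_dosage(st$G$dosage)
  pc1 <- st$S$PC1  # zero-mean modifier: the interaction has no additive
  covs <- st$S[, c("sample_id", "age", "sex", "PC1")]  # marginal component
  splits <- list(train = 1:6000, val = 6001:8000)

  set.seed(9)
  y <- 0.3 * X[, 2] + 1.0 * X[, 4] * pc1 + rnorm(8000, 0, 0.8)
  led <- iterative_complexity(y, st$G, covs, splits)
  expect_equal(sum(led$delta_r2), led$r2[nrow(led)] - led$r2[1],
               tolerance = 1e-12)
  expect_identical(led$term[which.max(led$delta_r2)], "gxe")

  y0 <- rnorm(8000)
  led0 <- iterative_complexity(y0, st$G, covs, splits)
  expect_true(all(abs(led0$delta_r2) < 0.01))
})

test_that("transfer_gap zeroes double-negative groups and correlates gaps", {
  set.seed(56)
  mk <- function(sd_a, sd_b, n = 80, flip = FALSE) {
    y <- rnorm(n)
    pa <- if (flip) -y else y + rnorm(n, 0, sd_a)
    pb <- if (flip) -y else y + rnorm(n, 0, sd_b)
    list(y_true = y, pred_a = pa, pred_b = pb)
  }
  data <- list(
    t1 = list(g1 = mk(0.3, 0.8), g2 = mk(0, 0, flip = TRUE)),
    t2 = list(g1 = mk(0.4, 0.9), g2 = mk(0, 0, flip = TRUE)),
    t3 = list(g1 = mk(0.5, 1.0), g2 = mk(0, 0, flip = TRUE)))
  tg <- transfer_gap(data, n_boot = 200, seed = 3)
  g2rows <- tg$gaps[tg$gaps$group == "g2", ]
  expect_true(all(g2rows$zeroed))
  expect_true(all(g2rows$gap == 0))
  expect_true(all(tg$gaps$gap[tg$gaps$group == "g1"] > 0))
  # zero-variance gaps in g2 make the correlation undefined -> NA
  expect_true(is.na(tg$gap_correlation["g1", "g2"]))
  expect_warning(
    transfer_gap(list(t1 = list(g1 = mk(0.5, 0.2),
                                g2 = mk(0.5, 0.2, n = 5))),
                 n_boot = 50),
    "excluded")
})

test_that("a frequency-shifted target group shrinks the gap", {
  # recessive causal effect whose alt allele is much rarer in the target
  # group: hom-alt carriers (where the one-hot advantage lives) all but
  # vanish, so both models lose accuracy and the gap decays
  set.seed(57)
  n <- 1500
  g_src <- rbinom(n, 2, 0.45)
  g_tgt <- rbinom(n, 2, 0.08)
  mk_trait <- function(g) c(0, 0, 1.5)[g + 1] + rnorm(length(g), 0, 0.8)
  y_src <- mk_trait(g_src); y_tgt <- mk_trait(g_tgt)
  itr <- 1:1000; ite <- 1001:1500
  df <- function(g) data.frame(h1 = as.numeric(g == 1),
                               h2 = as.numeric(g == 2), g = g)
  fit_oh <- lm(y_src[itr] ~ h1 + h2, df(g_src[itr]))
  fit_ad <- lm(y_src[itr] ~ g, df(g_src[itr]))
  data <- list(trait = list(
    source = list(y_true = y_src[ite],
                  pred_a = predict(fit_oh, df(g_src[ite])),
                  pred_b = predict(fit_ad, df(g_src[ite]))),
    target = list(y_true = y_tgt[ite],
                  pred_a = predict(fit_oh, df(g_tgt[ite])),
                  pred_b = predict(fit_ad, df(g_tgt[ite])))))
  tg <- transfer_gap(data, n_boot = 300, seed = 4)
  gap_src <- tg$gaps$gap[tg$gaps$group == "source"]
  gap_tgt <- tg$gaps$gap[tg$gaps$group == "target"]
  expect_lt(gap_tgt, gap_src)
})

test_that("clopper_pearson matches the quoted interval and the inversion", {
  ci <- clopper_pearson(124, 137)
  expect_equal(round(100 * 124 / 137, 1), 90.5)
  expect_equal(round(unname(ci), 3), c(0.843, 0.949))
  expect_identical(unname(clopper_pearson(0, 10)[1]), 0)
  expect_identical(unname(clopper_pearson(10, 10)[2]), 1)
  bt <- stats::binom.test(5, 10)$conf.int
  expect_equal(unname(clopper_pearson(5, 10)), as.numeric(bt),
               tolerance = 1e-6)
  expect_error(clopper_pearson(11, 10), "successes")
})
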