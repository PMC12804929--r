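#' Genotype simulation configuration
#'
#' @param n_samples number of individuals
#' @param n_variants number of variants
#' @param maf_range MAF bounds, drawn uniformly per variant (per LD block when
#'   `ld_block_size > 1`); both within (0, 0.5]
#' @param ld_block_size number of consecutive variants per LD block; 1 means
#'   fully independent variants
#' @param ld_decay copy probability of the first-order copy-with-mutation
#'   process within a block (per haplotype, each variant copies the previous
#'   variant's allele with this probability), in [0, 1)
#' @param missing_rate completely-at-random missingness fraction in [0, 1)
#' @param seed RNG seed
#' @return a `geno_sim_config` list
#' @export
geno_sim_config <- function(n_samples, n_variants, maf_range = c(0.05, 0.5),
                            ld_block_size = 1L, ld_decay = 0.8,
                            missing_rate = 0, seed = 1L) {
  assert_that(n_samples >= 1 && n_variants >= 1,
              "n_samples and n_variants must be positive")
  assert_that(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
                maf_range[1] <= maf_range[2],
              "maf_range must lie within (0, 0.5]")
  assert_that(missing_rate >= 0 && missing_rate < 1, "missing_rate must be in [0,1)")
  assert_that(ld_block_size >= 1, "ld_block_size must be >= 1")
  assert_that(ld_decay >= 0 && ld_decay < 1, "ld_decay must be in [0,1)")
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 maf_range = as.numeric(maf_range),
                 ld_block_size = as.integer(ld_block_size),
                 ld_decay = as.numeric(ld_decay),
                 missing_rate = as.numeric(missing_rate),
                 seed = as.integer(seed)),
            class = "geno_sim_config")
}

#' Simulate a genotype matrix
#'
#' Draws diploid genotypes in Hardy-Weinberg proportions at per-variant MAFs
#' sampled uniformly from `maf_range`. With `ld_block_size > 1`, variants are
#' grouped into blocks sharing one MAF, and within a block each haplotype
#' copies the previous variant's allele with probability `ld_decay`
#' (refreshing from the block MAF otherwise), producing positive adjacent
#' correlation that decays geometrically with distance. Missingness is
#' completely at random.
#'
#' @param config a [geno_sim_config()]
#' @return a [genotype_matrix()]; the drawn MAF of each variant is recorded in
#'   `$variants$sim_maf`
#' @export
simulate_genotypes <- function(config) {
  assert_that(inherits(config, "geno_sim_config"), "config must be a geno_sim_config")
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_variants
  bs <- config$ld_block_size
  block <- rep(seq_len(ceiling(m / bs)), each = bs)[seq_len(m)]
  n_blocks <- max(block)
  block_maf <- runif(n_blocks, config$maf_range[1], config$maf_range[2])
  if (bs == 1L) {
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
  } else {
    maf <- block_maf[block]
  }
  # two haplotypes per sample; copy-with-mutation chain restarts at block edges
  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    fresh1 <- rbinom(n, 1L, maf[j])
    fresh2 <- rbinom(n, 1L, maf[j])
    if (bs > 1L && j > 1L && block[j] == block[j - 1L]) {
      cp1 <- runif(n) < config$ld_decay
      cp2 <- runif(n) < config$ld_decay
      h1[, j] <- ifelse(cp1, h1[, j - 1L], fresh1)
      h2[, j] <- ifelse(cp2, h2[, j - 1L], fresh2)
    } else {
      h1[, j] <- fresh1
      h2[, j] <- fresh2
    }
  }
  dosage <- h1 + h2
  if (config$missing_rate > 0) {
    dosage[runif(n * m) < config$missing_rate] <- NA_integer_
  }
  alleles <- c("A", "C", "G", "T")
  a1 <- sample(alleles, m, replace = TRUE)
  a2 <- vapply(a1, function(a) sample(setdiff(alleles, a), 1L), character(1))
  variants <- data.frame(chrom = block %% 22L + 1L,
                         id = sprintf("rs%06d", seq_len(m)),
                         pos = seq_len(m) * 1000L,
                         allele1 = a1, allele2 = a2,
                         sim_maf = maf,
                         stringsAsFactors = FALSE)
  genotype_matrix(dosage, variants, sprintf("S%05d", seq_len(n)))
}

#' Simulate covariates
#'
#' Emulates the covariate block used alongside genotypes: continuous age,
#' binary sex, categorical assessment center and genotyping array, and
#' standard-normal genetic principal components.
#'
#' @param n_samples number of individuals
#' @param n_pcs number of principal-component columns (0 allowed)
#' @param age_range uniform range for age in years
#' @param n_centers number of center levels
#' @param seed RNG seed
#' @return data.frame with `sample_id`, `age`, `sex` (0/1), `center`,
#'   `array` (factors) and `PC1..PCk`
#' @export
simulate_covariates <- function(n_samples, n_pcs = 20L, age_range = c(40, 70),
                                n_centers = 5L, seed = 1L) {
  assert_that(n_samples >= 1, "n_samples must be >= 1")
  assert_that(n_pcs >= 0, "n_pcs must be >= 0")
  set.seed(seed)
  S <- data.frame(sample_id = sprintf("S%05d", seq_len(n_samples)),
                  age = runif(n_samples, age_range[1], age_range[2]),
                  sex = rbinom(n_samples, 1L, 0.5),
                  center = factor(sample(paste0("C", seq_len(n_centers)),
                                         n_samples, replace = TRUE)),
                  array = factor(sample(c("axiom", "bileve"), n_samples,
                                        replace = TRUE, prob = c(0.9, 0.1))),
                  stringsAsFactors = FALSE)
  if (n_pcs > 0) {
    pcs <- matrix(rnorm(n_samples * n_pcs), n_samples, n_pcs,
                  dimnames = list(NULL, paste0("PC", seq_len(n_pcs))))
    S <- cbind(S, as.data.frame(pcs))
  }
  S
}

#' Trait effect specification
#'
#' Ground truth for [simulate_trait()]. Effects are expressed on the additive
#' dosage coding except dominance and epistasis, which are genotype-class
#' means/offsets (matching how dominance displays as class means rather than
#' an additive + deviation decomposition).
#'
#' @param additive data.frame (`variant`, `beta`): trait units per effect
#'   allele copy
#' @param dominance data.frame (`variant`, `m0`, `m1`, `m2`): mean trait
#'   offset for genotype classes 0/1/2
#' @param epistasis list of `list(variant_i =, variant_j =, table = 3x3
#'   matrix)` of trait offsets per genotype combination (rows = genotype of
#'   variant_i 0/1/2, columns = variant_j)
#' @param gxe data.frame (`variant`, `covariate`, `beta`): coefficient on
#'   dosage x covariate product
#' @param exe data.frame (`covariate_a`, `covariate_b`, `beta`)
#' @param covariate_fns named list of functions taking the covariate table
#'   and returning one numeric contribution per sample (e.g. a sex-gated
#'   logistic step in age)
#' @param noise_sd Gaussian noise standard deviation (trait units), >= 0
#' @param scale `"raw"` or `"log2like"` (monotone sign-preserving
#'   `sign(y) * log2(1 + |y|)` warp applied after summation)
#' @return an `effect_spec` list
#' @export
effect_spec <- function(additive = NULL, dominance = NULL, epistasis = list(),
                        gxe = NULL, exe = NULL, covariate_fns = list(),
                        noise_sd = 1, scale = c("raw", "log2like")) {
  scale <- match.arg(scale)
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  for (e in epistasis) {
    assert_that(all(dim(as.matrix(e$table)) == c(3, 3)) &&
                  all(is.finite(as.matrix(e$table))),
                "epistasis tables must be finite 3x3")
  }
  structure(list(additive = additive, dominance = dominance,
                 epistasis = epistasis, gxe = gxe, exe = exe,
                 covariate_fns = covariate_fns,
                 noise_sd = noise_sd, scale = scale),
            class = "effect_spec")
}

log2like_warp <- function(y) sign(y) * log2(1 + abs(y))

covariate_column <- function(S, name) {
  assert_that(name %in% names(S), "unknown covariate '%s' in effect spec", name)
  v <- S[[name]]
  if (is.factor(v) || is.character(v)) stopf("covariate '%s' is not numeric", name)
  as.numeric(v)
}

#' Simulate a trait from planted effects
#'
#' The trait is the sum of all specified components plus Gaussian noise;
#' missing genotypes are mean-imputed before effect computation. The returned
#' ledger reports the empirical variance contributed by each component on this
#' sample set (computed on the raw scale, before any warp).
#'
#' @param G [genotype_matrix()]
#' @param S covariate table from [simulate_covariates()]
#' @param spec [effect_spec()]
#' @param seed RNG seed for the noise draw
#' @return list with `y` (trait vector), `components` (matrix of per-sample
#'   contributions) and `ledger` (data.frame component/variance)
#' @export
simulate_trait <- function(G, S, spec, seed = 1L) {
  assert_that(inherits(spec, "effect_spec"), "spec must be an effect_spec")
  n <- nrow(G$dosage)
  assert_that(nrow(S) == n, "covariate table and genotypes disagree on n")
  X <- impute_dosage(G$dosage)
  m <- ncol(X)
  check_var <- function(v) assert_that(all(v >= 1 & v <= m),
                                       "effect spec references variant outside matrix")
  comp <- list()
  if (!is.null(spec$additive) && nrow(spec$additive)) {
    check_var(spec$additive$variant)
    comp$additive <- as.vector(X[, spec$additive$variant, drop = FALSE] %*%
                                 spec$additive$beta)
  }
  if (!is.null(spec$dominance) && nrow(spec$dominance)) {
    check_var(spec$dominance$variant)
    v <- numeric(n)
    for (k in seq_len(nrow(spec$dominance))) {
      gk <- round(X[, spec$dominance$variant[k]])
      means <- c(spec$dominance$m0[k], spec$dominance$m1[k], spec$dominance$m2[k])
      v <- v + means[pmin(pmax(gk, 0), 2) + 1]
    }
    comp$dominance <- v
  }
  if (length(spec$epistasis)) {
    v <- numeric(n)
    for (e in spec$epistasis) {
      check_var(c(e$variant_i, e$variant_j))
      gi <- pmin(pmax(round(X[, e$variant_i]), 0), 2)
      gj <- pmin(pmax(round(X[, e$variant_j]), 0), 2)
      tab <- as.matrix(e$table)
      v <- v + tab[cbind(gi + 1, gj + 1)]
    }
    comp$epistasis <- v
  }
  if (!is.null(spec$gxe) && nrow(spec$gxe)) {
    check_var(spec$gxe$variant)
    v <- numeric(n)
    for (k in seq_len(nrow(spec$gxe))) {
      v <- v + spec$gxe$beta[k] * X[, spec$gxe$variant[k]] *
        covariate_column(S, spec$gxe$covariate[k])
    }
    comp$gxe <- v
  }
  if (!is.null(spec$exe) && nrow(spec$exe)) {
    v <- numeric(n)
    for (k in seq_len(nrow(spec$exe))) {
      v <- v + spec$exe$beta[k] *
        covariate_column(S, spec$exe$covariate_a[k]) *
        covariate_column(S, spec$exe$covariate_b[k])
    }
    comp$exe <- v
  }
  if (length(spec$covariate_fns)) {
    v <- numeric(n)
    for (f in spec$covariate_fns) {
      contrib <- f(S)
      assert_that(length(contrib) == n && all(is.finite(contrib)),
                  "covariate_fn must return one finite value per sample")
      v <- v + contrib
    }
    comp$covariate_fn <- v
  }
  set.seed(seed)
  noise <- rnorm(n, 0, spec$noise_sd)
  comp$noise <- noise
  components <- do.call(cbind, comp)
  y <- rowSums(components)
  ledger <- data.frame(component = colnames(components),
                       variance = apply(components, 2, var),
                       stringsAsFactors = FALSE)
  if (spec$scale == "log2like") y <- log2like_warp(y)
  list(y = y, components = components, ledger = ledger)
}

#' Write a simulated study to disk
#'
#' Emits PLINK1 `.bed/.bim/.fam` plus tab-separated covariate and trait tables
#' that [read_plink()] and `read.table` read back losslessly.
#'
#' @param G [genotype_matrix()]
#' @param S covariate table (must carry `sample_id` in `G`'s sample order)
#' @param traits named list or data.frame of trait vectors
#' @param out_dir output directory (created if absent)
#' @param prefix basename for the PLINK files
#' @return invisibly, the paths written
#' @export
write_study <- function(G, S, traits, out_dir, prefix = "study") {
  assert_that(identical(as.character(S$sample_id), G$samples),
              "covariate table sample order differs from genotypes")
  traits <- as.data.frame(traits)
  assert_that(nrow(traits) == length(G$samples),
              "trait length differs from sample count")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plink_prefix <- file.path(out_dir, prefix)
  write_plink(G, plink_prefix)
  cov_path <- file.path(out_dir, paste0(prefix, ".covariates.tsv"))
  write.table(S, cov_path, sep = "\t", quote = FALSE, row.names = FALSE)
  trait_path <- file.path(out_dir, paste0(prefix, ".traits.tsv"))
  write.table(cbind(sample_id = G$samples, traits), trait_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = paste0(plink_prefix, ".bed"),
              bim = paste0(plink_prefix, ".bim"),
              fam = paste0(plink_prefix, ".fam"),
              covariates = cov_path, traits = trait_path))
}
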