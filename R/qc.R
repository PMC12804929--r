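#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the allele counts, the p-value is the sum of
#' the probabilities of all heterozygote counts whose probability does not
#' exceed that of the observed count (plain formulation, no mid-p). Computed
#' with the standard stable recurrence over heterozygote counts.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype class counts (>= 0, total > 0)
#' @return exact p-value in (0, 1]
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  assert_that(n_hom_ref >= 0 && n_het >= 0 && n_hom_alt >= 0,
              "genotype counts must be non-negative")
  n <- n_hom_ref + n_het + n_hom_alt
  assert_that(n > 0, "total genotype count must be positive")
  rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (rare == 0) return(1)
  d <- hwe_het_distribution(rare, n)
  p_obs <- d$probs[which(d$hets == n_het)]
  # relative slack so exact probability ties (symmetric configurations) are
  # included regardless of floating-point rounding
  min(1, sum(d$probs[d$probs <= p_obs * (1 + 1e-9)]))
}

# Conditional distribution of the heterozygote count given the rare allele
# count, via the numerically stable mode-outward recurrence.
hwe_het_distribution <- function(rare, n) {
  common <- 2 * n - rare
  het_max <- min(rare, common)
  hets <- seq(rare %% 2, het_max, by = 2)
  probs <- numeric(length(hets))
  mid <- floor(rare * common / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1
  i_mid <- which(hets == mid)
  probs[i_mid] <- 1
  if (i_mid > 1) {
    for (i in seq(i_mid, 2)) {
      het <- hets[i]
      homr <- (rare - het) / 2
      homc <- n - het - homr
      probs[i - 1] <- probs[i] * het * (het - 1) / (4 * (homr + 1) * (homc + 1))
    }
  }
  if (i_mid < length(hets)) {
    for (i in seq(i_mid, length(hets) - 1)) {
      het <- hets[i]
      homr <- (rare - het) / 2
      homc <- n - het - homr
      probs[i + 1] <- probs[i] * 4 * homr * homc / ((het + 2) * (het + 1))
    }
  }
  list(hets = hets, probs = probs / sum(probs))
}

#' QC threshold set
#'
#' Boundary conventions follow PLINK: `mind`/`geno` remove strictly greater
#' missingness, `maf` keeps frequencies >= the threshold, `hwe` removes
#' p-values strictly below the threshold, `kinship` removes members of pairs
#' with kinship >= the threshold.
#'
#' @param mind max per-sample missing fraction
#' @param geno max per-variant missing fraction
#' @param hwe_p min HWE exact test p-value
#' @param maf min minor allele frequency
#' @param kinship max pairwise kinship
#' @return a `qc_thresholds` list
#' @export
qc_thresholds <- function(mind = 0.10, geno = 0.01, hwe_p = 1e-6,
                          maf = 0.005, kinship = 0.0884) {
  vals <- c(mind = mind, geno = geno, hwe_p = hwe_p, maf = maf, kinship = kinship)
  assert_that(all(vals >= 0 & vals <= 1), "all thresholds must lie in [0,1]")
  structure(as.list(vals), class = "qc_thresholds")
}

# Greedy kinship pruning: repeatedly drop the sample involved in the most
# remaining above-threshold pairs (ties -> smaller index) until none remain.
kinship_prune <- function(K, threshold) {
  n <- nrow(K)
  A <- (K >= threshold)
  diag(A) <- FALSE
  removed <- logical(n)
  repeat {
    deg <- rowSums(A)
    if (all(deg == 0)) break
    drop <- which.max(deg)  # which.max takes the first (smallest index) on ties
    removed[drop] <- TRUE
    A[drop, ] <- FALSE
    A[, drop] <- FALSE
  }
  which(removed)
}

#' Apply the QC filter cascade
#'
#' Filters are applied in order: kinship (if a matrix is supplied), sample
#' missingness (`mind`), variant missingness (`geno`), Hardy-Weinberg
#' (`hwe_p`), minor allele frequency (`maf`). The report reconciles exactly at
#' every step.
#'
#' @param G [genotype_matrix()]
#' @param thresholds [qc_thresholds()]
#' @param kinship optional square kinship matrix over `G$samples` (dimnames
#'   used when present, otherwise positional)
#' @return list with `genotypes` (filtered matrix) and `report` (data.frame
#'   step/type/removed/samples_left/variants_left)
#' @export
qc_filter <- function(G, thresholds = qc_thresholds(), kinship = NULL) {
  assert_that(inherits(thresholds, "qc_thresholds"), "thresholds must be qc_thresholds")
  steps <- list()
  note <- function(step, type, removed) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = step, type = type, removed = removed,
      samples_left = length(G$samples), variants_left = nrow(G$variants),
      stringsAsFactors = FALSE)
  }
  if (!is.null(kinship)) {
    K <- as.matrix(kinship)
    assert_that(nrow(K) == ncol(K), "kinship matrix must be square")
    if (!is.null(rownames(K))) {
      assert_that(all(G$samples %in% rownames(K)),
                  "kinship matrix lacks some samples")
      K <- K[G$samples, G$samples]
    } else {
      assert_that(nrow(K) == length(G$samples),
                  "kinship matrix size differs from sample count")
    }
    drop <- kinship_prune(K, thresholds$kinship)
    if (length(drop)) G <- G[-drop, ]
    note("kinship", "sample", length(drop))
  }
  miss_s <- rowMeans(is.na(G$dosage))
  drop <- which(miss_s > thresholds$mind)
  if (length(drop)) G <- G[-drop, ]
  note("mind", "sample", length(drop))
  assert_that(length(G$samples) > 0, "QC removed all samples")
  miss_v <- colMeans(is.na(G$dosage))
  drop <- which(miss_v > thresholds$geno)
  if (length(drop)) G <- G[, -drop]
  note("geno", "variant", length(drop))
  assert_that(nrow(G$variants) > 0, "QC removed all variants")
  counts <- genotype_counts(G)
  hwe_p <- vapply(seq_len(nrow(counts)), function(j) {
    if (counts$total[j] == 0) return(1)
    hwe_exact_test(counts$hom_ref[j], counts$het[j], counts$hom_alt[j])
  }, numeric(1))
  drop <- which(hwe_p < thresholds$hwe_p)
  if (length(drop)) G <- G[, -drop]
  note("hwe", "variant", length(drop))
  assert_that(nrow(G$variants) > 0, "QC removed all variants")
  maf <- variant_maf(G)
  drop <- which(!(maf >= thresholds$maf))  # keeps MAF >= threshold; NaN dropped
  if (length(drop)) G <- G[, -drop]
  note("maf", "variant", length(drop))
  assert_that(nrow(G$variants) > 0, "QC removed all variants")
  list(genotypes = G, report = do.call(rbind, steps))
}

#' QC removal ledger arithmetic
#'
#' Reconciles an ordered sequence of removal counts against an initial total:
#' at every step, initial - removed-so-far = remaining. Used to check filter
#' bookkeeping reported alongside [qc_filter()].
#'
#' @param initial starting count (samples or variants)
#' @param removed named numeric vector of per-step removal counts, in
#'   application order
#' @return data.frame: step, removed, remaining (final row holds the final
#'   count)
#' @export
qc_ledger <- function(initial, removed) {
  assert_that(initial >= 0 && all(removed >= 0), "counts must be non-negative")
  remaining <- initial - cumsum(removed)
  assert_that(all(remaining >= 0), "removals exceed the available count")
  data.frame(step = names(removed) %||% seq_along(removed),
             removed = as.numeric(removed), remaining = remaining,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Observed genotype class counts per variant (hom_ref = dosage 0).
genotype_counts <- function(G) {
  d <- G$dosage
  data.frame(hom_ref = colSums(d == 0L, na.rm = TRUE),
             het = colSums(d == 1L, na.rm = TRUE),
             hom_alt = colSums(d == 2L, na.rm = TRUE),
             total = colSums(!is.na(d)))
}

#' Windowed LD pruning
#'
#' Slides a window of `window` variants by `step`; within each window, when a
#' retained pair has squared Pearson correlation of (mean-imputed) dosages
#' greater than `r2_max`, the later-indexed variant is dropped.
#'
#' @param G [genotype_matrix()]
#' @param window window size in variants
#' @param step slide in variants
#' @param r2_max maximum allowed squared correlation
#' @return integer indices of retained variants
#' @export
ld_prune <- function(G, window = 50L, step = 5L, r2_max = 0.8) {
  assert_that(window >= step && step >= 1, "need window >= step >= 1")
  m <- nrow(G$variants)
  X <- impute_dosage(G$dosage)
  keep <- rep(TRUE, m)
  start <- 1L
  repeat {
    end <- min(start + window - 1L, m)
    idx <- which(keep[start:end]) + start - 1L
    if (length(idx) > 1) {
      sds <- apply(X[, idx, drop = FALSE], 2, sd)
      r2 <- suppressWarnings(cor(X[, idx, drop = FALSE]))^2
      for (a in seq_along(idx)) {
        if (!keep[idx[a]]) next
        for (b in seq_along(idx)) {
          if (b <= a || !keep[idx[b]]) next
          r2ab <- if (sds[a] == 0 || sds[b] == 0) 0 else r2[a, b]
          if (r2ab > r2_max) keep[idx[b]] <- FALSE
        }
      }
    }
    if (end == m) break
    start <- start + step
  }
  which(keep)
}

#' Rank-based inverse normal transformation
#'
#' Blom variant: z = qnorm((rank - 3/8) / (n + 1/4)) with average ranks for
#' ties; missing values stay missing.
#'
#' @param x numeric trait vector (>= 2 distinct non-missing values)
#' @return transformed vector, same length and NA pattern as `x`
#' @export
int_transform <- function(x) {
  obs <- !is.na(x)
  n <- sum(obs)
  assert_that(n >= 2, "need at least 2 non-missing values")
  assert_that(length(unique(x[obs])) > 1,
              "all non-missing values identical: INT undefined")
  r <- rank(x[obs], ties.method = "average")
  z <- rep(NA_real_, length(x))
  z[obs] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  z
}
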