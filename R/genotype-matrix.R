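#' Genotype matrix container
#'
#' Holds a samples x variants dosage matrix with values in \{0, 1, 2, NA\}
#' (NA encodes a missing genotype; dosage counts copies of `allele1`,
#' matching `plink --recode A`) together with per-variant metadata and sample
#' identifiers. This is the substrate every downstream stage operates on.
#'
#' @param dosage integer matrix, samples in rows, variants in columns;
#'   values 0/1/2/NA
#' @param variants data.frame with columns `chrom`, `id`, `pos`, `allele1`,
#'   `allele2` (one row per variant; `cm` optional, defaults to 0)
#' @param samples character vector of unique sample ids
#' @return an object of class `genotype_matrix`
#' @export
genotype_matrix <- function(dosage, variants, samples) {
  dosage <- as.matrix(dosage)
  assert_that(is.data.frame(variants), "variants must be a data.frame")
  need <- c("chrom", "id", "pos", "allele1", "allele2")
  assert_that(all(need %in% names(variants)),
              "variants must have columns %s", paste(need, collapse = ", "))
  if (is.null(variants$cm)) variants$cm <- 0
  samples <- as.character(samples)
  assert_that(nrow(dosage) == length(samples),
              "dosage has %d rows but %d sample ids", nrow(dosage), length(samples))
  assert_that(ncol(dosage) == nrow(variants),
              "dosage has %d columns but %d variant rows", ncol(dosage), nrow(variants))
  assert_that(!anyDuplicated(samples), "sample ids must be unique")
  assert_that(!anyDuplicated(variants$id), "variant ids must be unique")
  assert_that(all(variants$pos >= 0), "variant positions must be non-negative")
  vals <- dosage[!is.na(dosage)]
  assert_that(all(vals %in% c(0, 1, 2)), "dosage values must be in {0,1,2,NA}")
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(samples, variants$id)
  rownames(variants) <- NULL
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x genotype_matrix
#' @param i sample index (logical, integer or character)
#' @param j variant index (logical, integer or character)
#' @param ... unused
#' @return genotype_matrix restricted to the selected samples/variants
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$variants))
  if (is.character(i)) i <- match(i, x$samples)
  if (is.character(j)) j <- match(j, x$variants$id)
  genotype_matrix(x$dosage[i, j, drop = FALSE],
                  x$variants[j, , drop = FALSE],
                  x$samples[i])
}

# Per-variant frequency of allele1 among observed genotypes.
allele1_freq <- function(G) {
  colMeans(G$dosage, na.rm = TRUE) / 2
}

# Per-variant minor allele frequency among observed genotypes.
variant_maf <- function(G) {
  f <- allele1_freq(G)
  pmin(f, 1 - f, na.rm = FALSE)
}
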