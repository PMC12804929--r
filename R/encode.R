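#' Encode genotypes for modeling
#'
#' `additive`: one column per variant, missing dosages imputed with the
#' per-variant mean of observed dosages. `onehot`: four indicator columns per
#' variant (hom-ref, het, hom-alt, missing).
#'
#' @param G [genotype_matrix()]
#' @param scheme `"additive"` or `"onehot"`
#' @return list of class `encoded_design`: `X` (numeric matrix), `scheme`,
#'   `colmap` (data.frame column/variant/class mapping each column back to a
#'   variant and genotype class)
#' @export
encode <- function(G, scheme = c("additive", "onehot")) {
  scheme <- match.arg(scheme)
  ids <- G$variants$id
  if (scheme == "additive") {
    X <- impute_dosage(G$dosage)
    colnames(X) <- ids
    colmap <- data.frame(column = ids, variant = ids, class = "additive",
                         stringsAsFactors = FALSE)
  } else {
    d <- G$dosage
    m <- ncol(d)
    X <- matrix(0, nrow(d), 4L * m)
    cls <- c("hom_ref", "het", "hom_alt", "missing")
    for (k in 1:3) {
      X[, seq(k, by = 4L, length.out = m)] <- (!is.na(d)) & d == (k - 1L)
    }
    X[, seq(4, by = 4L, length.out = m)] <- is.na(d)
    cols <- paste(rep(ids, each = 4L), rep(cls, m), sep = ".")
    colnames(X) <- cols
    colmap <- data.frame(column = cols, variant = rep(ids, each = 4L),
                         class = rep(cls, m), stringsAsFactors = FALSE)
  }
  structure(list(X = X, scheme = scheme, colmap = colmap),
            class = "encoded_design")
}
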