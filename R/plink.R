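# PLINK1 binary genotype I/O.
#
# .bed layout: magic bytes 0x6c 0x1b, mode byte 0x01 (SNP-major), then
# ceil(n_samples/4) bytes per variant. Each byte packs four samples, the
# first sample in the two low-order bits. 2-bit codes: 00 = hom A1,
# 01 = missing, 10 = het, 11 = hom A2. Dosage counts A1 copies
# (00 -> 2, 10 -> 1, 11 -> 0), matching `plink --recode A`.

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

# code value (0..3) -> dosage; 1 = missing
.code_to_dosage <- c(2L, NA_integer_, 1L, 0L)
# dosage (0,1,2) -> code value
.dosage_to_code <- c(3L, 2L, 0L)

# 256 x 4 lookup: byte value -> four dosages (low-order sample first)
.bed_decode_table <- local({
  b <- 0:255
  cbind(.code_to_dosage[bitwAnd(b, 3L) + 1L],
        .code_to_dosage[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
        .code_to_dosage[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
        .code_to_dosage[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L])
})

#' Read a PLINK1 fileset
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist and be
#'   mutually consistent
#' @return a [genotype_matrix()]
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) assert_that(file.exists(p), "missing PLINK file: %s", p)
  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "pos", "allele1", "allele2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "character", "character", "character"))
  n <- nrow(fam)
  m <- nrow(bim)
  assert_that(m >= 1, "%s has no variants", paths[2])
  assert_that(n >= 1, "%s has no samples", paths[3])
  bpv <- ceiling(n / 4)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  assert_that(length(raw) >= 3 && identical(raw[1:3], BED_MAGIC),
              "%s: bad magic bytes (not a SNP-major PLINK1 .bed)", paths[1])
  payload <- raw[-(1:3)]
  assert_that(length(payload) == bpv * m,
              "%s: payload is %d bytes but %d samples x %d variants needs %d",
              paths[1], length(payload), n, m, bpv * m)
  codes <- .bed_decode_table[as.integer(payload) + 1L, , drop = FALSE]
  # bytes for variant j are rows (j-1)*bpv + 1 .. j*bpv; samples read row-wise
  dosage <- matrix(t(codes), nrow = 4L * bpv)[seq_len(n), , drop = FALSE]
  variants <- data.frame(chrom = bim$chrom, id = bim$id, cm = bim$cm,
                         pos = bim$pos, allele1 = bim$allele1,
                         allele2 = bim$allele2, stringsAsFactors = FALSE)
  genotype_matrix(dosage, variants, fam[[2]])
}

#' Write a PLINK1 fileset
#'
#' @param G [genotype_matrix()]
#' @param prefix output path prefix
#' @return invisibly, the three paths written
#' @export
write_plink <- function(G, prefix) {
  n <- length(G$samples)
  m <- nrow(G$variants)
  assert_that(m >= 1, "cannot write a PLINK fileset with no variants")
  bpv <- ceiling(n / 4)
  d <- G$dosage
  code <- matrix(1L, nrow = 4L * bpv, ncol = m)  # pad/missing = 01
  obs <- !is.na(d)
  codes_obs <- matrix(NA_integer_, n, m)
  codes_obs[obs] <- .dosage_to_code[d[obs] + 1L]
  codes_obs[!obs] <- 1L
  code[seq_len(n), ] <- codes_obs
  code[seq_len(4L * bpv) > n, ] <- 0L  # pad bits zero, as plink writes
  i1 <- seq(1L, 4L * bpv, by = 4L)
  bytes <- code[i1, , drop = FALSE] + 4L * code[i1 + 1L, , drop = FALSE] +
    16L * code[i1 + 2L, , drop = FALSE] + 64L * code[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(BED_MAGIC, con)
  writeBin(as.raw(bytes), con)
  v <- G$variants
  bim <- data.frame(v$chrom, v$id, v$cm %||% 0, v$pos, v$allele1, v$allele2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(G$samples, G$samples, 0L, 0L, 0L, -9L)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}
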