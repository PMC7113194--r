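# PLINK 1 binary genotype files.
#
# bed: 3 magic bytes 0x6c 0x1b 0x01 (SNP-major), then ceil(n/4) bytes per
# SNP, 2 bits per subject, low bits first:
#   00 homozygous A1/A1 (dosage 2)   01 missing
#   10 heterozygous     (dosage 1)   11 homozygous A2/A2 (dosage 0)
# Dosage counts copies of A1, the first allele column of the bim file.

.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))
# index by code + 1
.BED_DECODE <- c(2L, NA_integer_, 1L, 0L)

#' Read PLINK bed/bim/fam genotypes
#'
#' Decodes the standard PLINK 1 binary triple (`prefix.bed`, `prefix.bim`,
#' `prefix.fam`) in SNP-major mode into a [GenotypeData-class] object.
#' Dosages count copies of allele A1 (bim column 5); the 2-bit code 01 is a
#' missing call.
#'
#' @param prefix path without extension.
#' @return A [GenotypeData-class].
#' @examples
#' cfg <- simConfig(nSubjects = 5, nSnps = 4, nChromosomes = 2, seed = 7)
#' g <- simulateGenotypes(cfg)
#' pre <- file.path(tempdir(), "toy")
#' writePlink(g, pre)
#' g2 <- readPlink(pre)
#' stopifnot(identical(dosages(g), dosages(g2)))
#' @export
readPlink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("missing file: ", f)
  }
  snps <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("chrom", "id", "cm", "pos",
                                          "a1", "a2"),
                            colClasses = c("integer", "character", "numeric",
                                           "integer", "character",
                                           "character"))
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("fid", "iid", "pat", "mat",
                                            "sex", "pheno"),
                              colClasses = c("character", "character",
                                             "character", "character",
                                             "integer", "numeric"))
  n <- nrow(fam_df)
  m <- nrow(snps)
  bpv <- ceiling(n / 4)  # bytes per SNP

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || !identical(raw[1:3], .BED_MAGIC)) {
    stop("not a SNP-major PLINK bed file (bad magic bytes): ", bed)
  }
  body <- raw[-(1:3)]
  if (length(body) != bpv * m) {
    stop("bed size inconsistent with bim/fam: expected ", bpv * m,
         " data bytes, found ", length(body))
  }
  # unpack all 2-bit codes at once: 4 genotypes per byte, low bits first
  ints <- as.integer(body)
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, ints %/% 64L)
  dos <- matrix(.BED_DECODE[codes + 1L], nrow = 4L * bpv, ncol = m)
  dos <- dos[seq_len(n), , drop = FALSE]
  rownames(dos) <- fam_df$iid
  colnames(dos) <- snps$id
  methods::new("GenotypeData",
               dosages = dos,
               snps = snps[, c("id", "chrom", "pos", "a1", "a2")],
               samples = fam_df[, c("fid", "iid", "sex")])
}

#' @rdname readPlink
#' @param geno a [GenotypeData-class] to write.
#' @export
writePlink <- function(geno, prefix) {
  stopifnot(methods::is(geno, "GenotypeData"))
  snps <- snpInfo(geno)
  samples <- sampleInfo(geno)
  dos <- dosages(geno)
  n <- nrow(dos)
  m <- ncol(dos)
  bpv <- ceiling(n / 4)

  utils::write.table(
    data.frame(snps$chrom, snps$id, 0, snps$pos, snps$a1, snps$a2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(samples$fid, samples$iid, 0, 0, samples$sex, -9),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  # dosage -> 2-bit code; pad each SNP's column to a multiple of 4 subjects
  code <- matrix(0L, nrow = 4L * bpv, ncol = m)  # zero-bit padding, as plink writes
  enc <- c(3L, 2L, 0L)  # dosage 0,1,2 -> code
  cod <- ifelse(is.na(dos), 1L, enc[dos + 1L])
  code[seq_len(n), ] <- cod
  # pack groups of 4 codes, low bits first
  i4 <- seq(1L, 4L * bpv, by = 4L)
  bytes <- code[i4, , drop = FALSE] + 4L * code[i4 + 1L, , drop = FALSE] +
    16L * code[i4 + 2L, , drop = FALSE] + 64L * code[i4 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.BED_MAGIC, con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}
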