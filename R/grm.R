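#' Compute a genetic relationship matrix
#'
#' Realized-relationship estimator on standardized dosages with the GCTA
#' diagonal. With in-sample allele-1 frequency `p_i` of SNP `i` and dosage
#' `x_ij` of subject `j`:
#' off-diagonal `A_jk = (1/m) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) /
#' (2 p_i (1 - p_i))`, diagonal `A_jj = 1 + (1/m) sum_i (x_ij^2 -
#' (1 + 2 p_i) x_ij + 2 p_i^2) / (2 p_i (1 - p_i))`. Missing genotypes are
#' skipped pairwise: each entry is averaged over the SNPs observed in both
#' subjects, and the per-pair SNP count is kept alongside the matrix.
#' Monomorphic SNPs are excluded with a warning.
#'
#' @param geno a [GenotypeData-class].
#' @param component `"all"` or a chromosome number; restricts the SNP set
#'   and labels the result.
#' @return A [GRM-class].
#' @examples
#' g <- simulateGenotypes(simConfig(nSubjects = 20, nSnps = 50, seed = 2))
#' A <- computeGRM(g)
#' mean(diag(grmMatrix(A)))
#' @export
computeGRM <- function(geno, component = "all") {
  dos <- dosages(geno)
  if (!identical(component, "all")) {
    sel <- snpInfo(geno)$chrom == as.integer(component)
    if (!any(sel)) stop("no SNPs on chromosome ", component)
    dos <- dos[, sel, drop = FALSE]
  }
  p <- colMeans(dos, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic SNP(s) excluded from GRM")
  }
  if (!any(poly)) stop("no polymorphic SNPs usable for GRM")
  dos <- dos[, poly, drop = FALSE]
  p <- p[poly]
  n <- nrow(dos)

  denom <- 2 * p * (1 - p)
  obs <- !is.na(dos)
  Z <- sweep(dos, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(denom), "/")
  Z[!obs] <- 0
  num <- tcrossprod(Z)                      # pair sums of standardized products
  np <- tcrossprod(obs * 1)                 # SNPs observed in both subjects
  A <- num / pmax(np, 1)

  # GCTA diagonal: 1 + mean over observed SNPs of
  # (x^2 - (1+2p) x + 2 p^2) / (2 p (1-p))
  X0 <- dos
  X0[!obs] <- 0
  diagterm <- (X0^2 - sweep(X0, 2, 1 + 2 * p, "*") +
                 outer(rep(1, n), 2 * p^2) * obs) %*% (1 / denom)
  # the sweep multiplies zeros at missing entries, and the 2p^2 term is
  # masked by obs, so only observed SNPs contribute
  mdiag <- rowSums(obs)
  diag(A) <- 1 + drop(diagterm) / pmax(mdiag, 1)
  diag(np) <- mdiag

  ids <- subjectIds(geno)
  dimnames(A) <- list(ids, ids)
  storage.mode(np) <- "integer"
  methods::new("GRM", mat = A, nPairs = np, ids = ids,
               component = as.character(component))
}

#' Per-chromosome GRMs
#'
#' One [GRM-class] per chromosome present in the panel, using only that
#' chromosome's SNPs; chromosomes with no SNPs are skipped with a warning.
#' The SNP-count-weighted average of the per-chromosome matrices equals the
#' genome-wide GRM.
#'
#' @param geno a [GenotypeData-class].
#' @return Named list of [GRM-class] objects, keyed by chromosome.
#' @export
partitionByChromosome <- function(geno) {
  chroms <- sort(unique(snpInfo(geno)$chrom))
  out <- lapply(chroms, function(ch) computeGRM(geno, component = ch))
  names(out) <- as.character(chroms)
  out
}

#' Principal components of a GRM
#'
#' Top-k eigenvectors scaled by the square root of their eigenvalues, the
#' standard population-structure covariates. Deterministic up to sign; each
#' column's sign is fixed so its largest-magnitude loading is positive.
#'
#' @param grm a [GRM-class].
#' @param k number of components (default 10; must be < number of subjects).
#' @return A [PCScores-class].
#' @export
computePCs <- function(grm, k = 10) {
  A <- grmMatrix(grm)
  n <- nrow(A)
  if (k > n - 1) stop("k must be at most n - 1 = ", n - 1)
  eg <- eigen(A, symmetric = TRUE)
  vals <- eg$values[seq_len(k)]
  vecs <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- sweep(vecs, 2, sqrt(pmax(vals, 0)), "*")
  rownames(scores) <- subjectIds(grm)
  colnames(scores) <- paste0("PC", seq_len(k))
  methods::new("PCScores", scores = scores, values = vals,
               ids = subjectIds(grm))
}

#' Write PC scores as a covariate file
#'
#' Tab-separated FID, IID, PC1..PCk — the layout GCTA and PLINK accept as a
#' quantitative covariate file.
#'
#' @param pcs a [PCScores-class].
#' @param fids family ids (defaults to the subject ids).
#' @param path output file.
#' @export
writePCCovariates <- function(pcs, path, fids = NULL) {
  ids <- subjectIds(pcs)
  if (is.null(fids)) fids <- ids
  df <- data.frame(FID = fids, IID = ids, pcScores(pcs),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a GRM in the GCTA binary dialect
#'
#' `prefix.grm.bin` holds the lower triangle (diagonal included) row by row
#' as 4-byte little-endian floats; `prefix.grm.N.bin` the per-pair SNP
#' counts in the same layout; `prefix.grm.id` is a two-column text file
#' (FID, IID). The round trip is exact to float32 precision.
#'
#' @param grm a [GRM-class].
#' @param prefix path without the `.grm.*` extensions.
#' @param fids family ids for the id file (defaults to subject ids).
#' @export
writeGRMBinary <- function(grm, prefix, fids = NULL) {
  A <- grmMatrix(grm)
  np <- grmPairCounts(grm)
  ids <- subjectIds(grm)
  if (is.null(fids)) fids <- ids
  n <- length(ids)
  lower <- which(row(A) >= col(A))
  ord <- order(row(A)[lower], col(A)[lower])
  tri <- lower[ord]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(A[tri]), con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(np[tri]), con, size = 4, endian = "little")
  close(con)
  utils::write.table(data.frame(fids, ids), paste0(prefix, ".grm.id"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(prefix)
}

#' @rdname writeGRMBinary
#' @param component label to attach to the object read back.
#' @export
readGRMBinary <- function(prefix, component = "all") {
  idf <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  n <- nrow(idf)
  ntri <- n * (n + 1) / 2
  binpath <- paste0(prefix, ".grm.bin")
  nfloats <- file.size(binpath) / 4
  if (nfloats != ntri) {
    stop("GRM size mismatch: id file lists ", n, " subjects (needs ", ntri,
         " floats) but ", binpath, " holds ", nfloats)
  }
  vals <- readBin(binpath, what = "numeric", n = ntri, size = 4,
                  endian = "little")
  npath <- paste0(prefix, ".grm.N.bin")
  nvals <- readBin(npath, what = "numeric", n = ntri, size = 4,
                   endian = "little")
  A <- matrix(0, n, n)
  # fill lower triangle row by row
  k <- 1L
  for (i in seq_len(n)) {
    A[i, 1:i] <- vals[k:(k + i - 1)]
    k <- k + i
  }
  A[upper.tri(A)] <- t(A)[upper.tri(A)]
  np <- matrix(0, n, n)
  k <- 1L
  for (i in seq_len(n)) {
    np[i, 1:i] <- nvals[k:(k + i - 1)]
    k <- k + i
  }
  np[upper.tri(np)] <- t(np)[upper.tri(np)]
  ids <- idf[[2]]
  dimnames(A) <- list(ids, ids)
  dimnames(np) <- list(ids, ids)
  storage.mode(np) <- "integer"
  methods::new("GRM", mat = A, nPairs = np, ids = ids,
               component = component)
}
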