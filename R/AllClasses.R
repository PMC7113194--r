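#' @import methods
NULL

#' Genotype dosage matrix with SNP and sample metadata
#'
#' Container for a subjects-by-SNPs dosage matrix. Dosages count copies of
#' allele 1 (the A1 column of a PLINK bim file), so each entry is 0, 1, 2 or
#' `NA` for a missing call. Per-SNP metadata (chromosome, base-pair position,
#' allele labels) lives in `snps`; per-sample metadata (family/individual id,
#' sex code) in `samples`.
#'
#' @slot dosages integer matrix, subjects x SNPs, values in {0,1,2,NA}.
#' @slot snps data.frame with columns `id`, `chrom`, `pos`, `a1`, `a2`;
#'   one row per SNP, rownames free.
#' @slot samples data.frame with columns `fid`, `iid`, `sex`
#'   (1 = male, 2 = female, 0 = unknown); one row per subject.
#'
#' @seealso [readPlink()], [writePlink()], [snpSummary()], [computeGRM()]
#' @export
setClass("GenotypeData",
  representation(
    dosages = "matrix",
    snps = "data.frame",
    samples = "data.frame"
  )
)

setValidity("GenotypeData", function(object) {
  msg <- character()
  d <- object@dosages
  if (nrow(object@snps) != ncol(d)) {
    msg <- c(msg, "nrow(snps) must equal ncol(dosages)")
  }
  if (nrow(object@samples) != nrow(d)) {
    msg <- c(msg, "nrow(samples) must equal nrow(dosages)")
  }
  need_snp <- c("id", "chrom", "pos", "a1", "a2")
  if (!all(need_snp %in% names(object@snps))) {
    msg <- c(msg, paste("snps needs columns:", paste(need_snp, collapse = ", ")))
  }
  need_sam <- c("fid", "iid", "sex")
  if (!all(need_sam %in% names(object@samples))) {
    msg <- c(msg, paste("samples needs columns:", paste(need_sam, collapse = ", ")))
  }
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L))) {
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  if (length(msg)) msg else TRUE
})

#' Genetic relationship matrix
#'
#' Realized genomic relationship between all subject pairs, computed from
#' standardized SNP dosages (the GCTA estimator; see [computeGRM()]). The
#' `nPairs` matrix records how many SNPs contributed to each entry, which
#' differs between pairs when genotypes are missing.
#'
#' @slot mat symmetric numeric matrix, subjects x subjects.
#' @slot nPairs integer matrix, SNPs used per pair (same shape as `mat`).
#' @slot ids character vector of subject ids (matches matrix order).
#' @slot component `"all"` for a genome-wide GRM or a chromosome label.
#'
#' @export
setClass("GRM",
  representation(
    mat = "matrix",
    nPairs = "matrix",
    ids = "character",
    component = "character"
  )
)

setValidity("GRM", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (!all(dim(object@mat) == c(n, n))) {
    msg <- c(msg, "mat must be n x n with n = length(ids)")
  }
  if (!all(dim(object@nPairs) == c(n, n))) {
    msg <- c(msg, "nPairs must match mat dimensions")
  }
  if (n && max(abs(object@mat - t(object@mat))) > 1e-8) {
    msg <- c(msg, "mat must be symmetric")
  }
  if (length(object@component) != 1L) {
    msg <- c(msg, "component must be a single label")
  }
  if (length(msg)) msg else TRUE
})

#' Principal-component scores from a GRM
#'
#' Top-k eigenvectors of a genetic relationship matrix, each scaled by the
#' square root of its eigenvalue; the usual population-structure covariates.
#' Column signs are fixed so the largest-magnitude loading of each component
#' is positive, making covariate files reproducible.
#'
#' @slot scores numeric matrix, subjects x k.
#' @slot values eigenvalues, decreasing.
#' @slot ids subject ids matching the rows of `scores`.
#'
#' @export
setClass("PCScores",
  representation(
    scores = "matrix",
    values = "numeric",
    ids = "character"
  )
)

setValidity("PCScores", function(object) {
  msg <- character()
  if (nrow(object@scores) != length(object@ids)) {
    msg <- c(msg, "scores rows must match ids")
  }
  if (ncol(object@scores) != length(object@values)) {
    msg <- c(msg, "one eigenvalue per score column")
  }
  if (length(object@values) > 1 && any(diff(object@values) > 1e-8)) {
    msg <- c(msg, "eigenvalues must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Variance-component (GREML) fit
#'
#' Result of restricted maximum-likelihood estimation of the model
#' y = Xb + sum_c g_c + e with Var(g_c) = A_c * sigma2_g[c] and
#' Var(e) = I * sigma2_e. Heritability is h2 = sum(sigma2_g) / (sum(sigma2_g)
#' + sigma2_e); per-component fractions are in `h2Components`. Standard
#' errors come from the inverse average-information matrix and the delta
#' method. `logLikNull` is the restricted log-likelihood with all genetic
#' components removed, `lrt` the (clamped, non-negative) likelihood-ratio
#' statistic and `pvalue` its tail probability under the 50:50 chi-square
#' 0/1 mixture null.
#'
#' @slot sigma2g named numeric, one genetic variance per component.
#' @slot sigma2e residual variance.
#' @slot h2 total SNP heritability.
#' @slot h2Components per-component variance fractions.
#' @slot se named list: `components` (SEs for c(sigma2g, sigma2e)) and `h2`.
#' @slot logLik restricted log-likelihood of the full model.
#' @slot logLikNull restricted log-likelihood with genetic variance omitted.
#' @slot lrt likelihood-ratio statistic, clamped at zero.
#' @slot pvalue mixture-null p-value.
#' @slot converged logical.
#' @slot status "converged", "failed" or "non-identifiable".
#' @slot iterations iteration count.
#' @slot n number of subjects used.
#'
#' @export
setClass("GREMLFit",
  representation(
    sigma2g = "numeric",
    sigma2e = "numeric",
    h2 = "numeric",
    h2Components = "numeric",
    se = "list",
    logLik = "numeric",
    logLikNull = "numeric",
    lrt = "numeric",
    pvalue = "numeric",
    converged = "logical",
    status = "character",
    iterations = "integer",
    n = "integer"
  )
)

setValidity("GREMLFit", function(object) {
  msg <- character()
  if (any(object@sigma2g < 0) || object@sigma2e < 0) {
    msg <- c(msg, "variance components must be non-negative")
  }
  if (length(object@h2) == 1 && !is.na(object@h2) &&
      (object@h2 < 0 || object@h2 > 1)) {
    msg <- c(msg, "h2 must lie in [0, 1]")
  }
  if (length(object@lrt) == 1 && !is.na(object@lrt) && object@lrt < 0) {
    msg <- c(msg, "lrt must be >= 0")
  }
  if (length(msg)) msg else TRUE
})
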