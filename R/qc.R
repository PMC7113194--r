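#' Per-SNP summary statistics
#'
#' Allele-1 frequency, minor allele frequency, call rate and the
#' Hardy-Weinberg p-value for every SNP, all computed on non-missing calls
#' only.
#'
#' @param geno a [GenotypeData-class].
#' @param hweExact use the exact conditional test instead of the 1-df
#'   chi-square goodness-of-fit test.
#' @return data.frame: id, chrom, pos, a1, a2, freq (allele 1), maf,
#'   call_rate, hwe_p.
#' @export
snpSummary <- function(geno, hweExact = FALSE) {
  dos <- dosages(geno)
  nonmiss <- colSums(!is.na(dos))
  freq <- colMeans(dos, na.rm = TRUE) / 2
  freq[nonmiss == 0] <- NA_real_
  n2 <- colSums(dos == 2L, na.rm = TRUE)
  n1 <- colSums(dos == 1L, na.rm = TRUE)
  n0 <- colSums(dos == 0L, na.rm = TRUE)
  hwe <- vapply(seq_len(ncol(dos)), function(i) {
    if (nonmiss[i] == 0) return(NA_real_)
    hweTest(n2[i], n1[i], n0[i], exact = hweExact)
  }, numeric(1))
  cbind(snpInfo(geno),
        data.frame(freq = freq, maf = pmin(freq, 1 - freq),
                   call_rate = nonmiss / nrow(dos), hwe_p = hwe))
}

#' Hardy-Weinberg equilibrium test
#'
#' Tests observed genotype counts against the Hardy-Weinberg expectation at
#' the sample allele frequency. The default is the 1-df chi-square
#' goodness-of-fit test; `exact = TRUE` uses the exact conditional test
#' (probability of heterozygote counts given the minor-allele count, summing
#' all tables no more probable than the observed one). A monomorphic SNP
#' returns p = 1 by convention.
#'
#' @param nHomRef,nHet,nHomAlt genotype counts (non-negative, sum >= 1).
#' @param exact use the exact test.
#' @return p-value.
#' @examples
#' hweTest(25, 50, 25)   # exact HWE proportions: p = 1
#' hweTest(50, 0, 50)    # chi-square 100, p << 1e-5
#' @export
hweTest <- function(nHomRef, nHet, nHomAlt, exact = FALSE) {
  counts <- c(nHomRef, nHet, nHomAlt)
  if (any(counts < 0) || sum(counts) < 1) {
    stop("genotype counts must be non-negative and sum to at least 1")
  }
  n <- sum(counts)
  nA <- 2 * nHomRef + nHet
  na <- 2 * nHomAlt + nHet
  if (nA == 0 || na == 0) return(1)  # monomorphic
  if (exact) return(.hweExact(nHet, min(nA, na), n))
  p <- nA / (2 * n)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((counts - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# exact HWE: distribution of heterozygote count given n and the rarer
# allele count, via the standard recurrence on log probabilities
.hweExact <- function(nHet, nRare, n) {
  hets <- seq(nRare %% 2, nRare, by = 2)
  logp <- vapply(hets, function(h) {
    homr <- (nRare - h) / 2
    homc <- n - h - homr
    lchoose(n, h) + lchoose(n - h, homr) + h * log(2) -
      (lgamma(2 * n + 1) - lgamma(nRare + 1) - lgamma(2 * n - nRare + 1))
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(nHet, hets)]
  min(1, sum(prob[prob <= obs + 1e-12]))
}

#' Apply SNP-level quality-control filters
#'
#' Removes SNPs with Hardy-Weinberg p-value below `hweThr`, minor allele
#' frequency below `mafThr`, or call rate below `callThr` — all strict
#' inequalities. A SNP failing several rules is attributed to the first
#' failed rule in the order HWE, MAF, call rate. MAF and HWE use
#' non-missing calls only.
#'
#' @param geno a [GenotypeData-class].
#' @param hweThr,mafThr,callThr thresholds in `[0, 1]`.
#' @param hweExact passed to [snpSummary()].
#' @return list with `genotypes` (filtered [GenotypeData-class]) and
#'   `report` (named list of per-rule removal counts and survivors).
#' @export
applySnpFilters <- function(geno, hweThr = 1e-5, mafThr = 0.05,
                            callThr = 0.95, hweExact = FALSE) {
  for (thr in c(hweThr, mafThr, callThr)) {
    if (thr < 0 || thr > 1) stop("QC thresholds must lie in [0, 1]")
  }
  ss <- snpSummary(geno, hweExact = hweExact)
  fail_hwe <- !is.na(ss$hwe_p) & ss$hwe_p < hweThr
  fail_maf <- !is.na(ss$maf) & ss$maf < mafThr
  fail_call <- ss$call_rate < callThr
  # attribute each removed SNP to the first failed rule
  rule <- rep(NA_character_, nrow(ss))
  rule[fail_call] <- "call_rate"
  rule[fail_maf] <- "maf"
  rule[fail_hwe] <- "hwe"
  keep <- is.na(rule)
  if (!any(keep)) stop("SNP QC removed every SNP; nothing left to analyse")
  report <- list(
    input_snps = nrow(ss),
    removed_hwe = sum(rule == "hwe", na.rm = TRUE),
    removed_maf = sum(rule == "maf", na.rm = TRUE),
    removed_call_rate = sum(rule == "call_rate", na.rm = TRUE),
    surviving_snps = sum(keep)
  )
  list(genotypes = .subsetGeno(geno, snps = which(keep)), report = report)
}

#' Apply sample-level quality-control filters
#'
#' Removes subjects whose fraction of missing genotype calls is strictly
#' greater than `missThr`.
#'
#' @param geno a [GenotypeData-class].
#' @param missThr maximum tolerated per-sample missing call rate.
#' @return list with `genotypes` and `report` (counts).
#' @export
applySampleFilters <- function(geno, missThr = 0.05) {
  if (missThr < 0 || missThr > 1) stop("missThr must lie in [0, 1]")
  dos <- dosages(geno)
  missrate <- rowMeans(is.na(dos))
  keep <- missrate <= missThr
  if (!any(keep)) stop("sample QC removed every subject")
  report <- list(
    input_samples = nrow(dos),
    removed_missing = sum(!keep),
    surviving_samples = sum(keep)
  )
  list(genotypes = .subsetGeno(geno, samples = which(keep)), report = report)
}

.subsetGeno <- function(geno, samples = NULL, snps = NULL) {
  dos <- dosages(geno)
  sm <- sampleInfo(geno)
  sn <- snpInfo(geno)
  if (!is.null(samples)) {
    dos <- dos[samples, , drop = FALSE]
    sm <- sm[samples, , drop = FALSE]
  }
  if (!is.null(snps)) {
    dos <- dos[, snps, drop = FALSE]
    sn <- sn[snps, , drop = FALSE]
  }
  rownames(sm) <- NULL
  rownames(sn) <- NULL
  methods::new("GenotypeData", dosages = dos, snps = sn, samples = sm)
}

#' Write a QC report as TSV and JSON
#'
#' @param report named list as returned by the filter functions (or a
#'   concatenation of several).
#' @param prefix output path without extension; writes `prefix.tsv` and
#'   `prefix.json`.
#' @export
writeQcReport <- function(report, prefix) {
  df <- data.frame(metric = names(report),
                   count = unlist(report, use.names = FALSE))
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report, paste0(prefix, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(prefix)
}
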