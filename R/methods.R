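#' @describeIn GenotypeData-class dosage matrix (subjects x SNPs).
#' @export
setMethod("dosages", "GenotypeData", function(x) x@dosages)

#' @describeIn GenotypeData-class per-SNP metadata data.frame.
#' @export
setMethod("snpInfo", "GenotypeData", function(x) x@snps)

#' @describeIn GenotypeData-class per-sample metadata data.frame.
#' @export
setMethod("sampleInfo", "GenotypeData", function(x) x@samples)

#' @describeIn GenotypeData-class number of subjects.
#' @export
setMethod("nSamples", "GenotypeData", function(x) nrow(x@dosages))

#' @describeIn GenotypeData-class number of SNPs.
#' @export
setMethod("nSnps", "GenotypeData", function(x) ncol(x@dosages))

#' @describeIn GenotypeData-class subject ids (iid column).
#' @export
setMethod("subjectIds", "GenotypeData", function(x) as.character(x@samples$iid))

setMethod("show", "GenotypeData", function(object) {
  d <- object@dosages
  miss <- if (length(d)) mean(is.na(d)) else 0
  cat("GenotypeData:", nrow(d), "subjects x", ncol(d), "SNPs\n")
  cat(sprintf("  chromosomes: %s\n",
              paste(sort(unique(object@snps$chrom)), collapse = " ")))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
})

#' @describeIn GRM-class relationship matrix.
#' @export
setMethod("grmMatrix", "GRM", function(x) x@mat)

#' @describeIn GRM-class SNPs used per subject pair.
#' @export
setMethod("grmPairCounts", "GRM", function(x) x@nPairs)

#' @describeIn GRM-class subject ids.
#' @export
setMethod("subjectIds", "GRM", function(x) x@ids)

#' @describeIn GRM-class component label ("all" or a chromosome).
#' @export
setMethod("grmComponent", "GRM", function(x) x@component)

setMethod("show", "GRM", function(object) {
  n <- length(object@ids)
  cat("GRM (component ", object@component, "): ", n, " subjects, ",
      max(object@nPairs), " SNPs\n", sep = "")
  if (n > 1) {
    off <- object@mat[upper.tri(object@mat)]
    cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f\n",
                mean(diag(object@mat)), mean(off)))
  }
})

#' @describeIn PCScores-class score matrix (subjects x k).
#' @export
setMethod("pcScores", "PCScores", function(x) x@scores)

#' @describeIn PCScores-class eigenvalues.
#' @export
setMethod("pcValues", "PCScores", function(x) x@values)

#' @describeIn PCScores-class subject ids.
#' @export
setMethod("subjectIds", "PCScores", function(x) x@ids)

setMethod("show", "PCScores", function(object) {
  cat("PCScores:", nrow(object@scores), "subjects x",
      ncol(object@scores), "components\n")
  ve <- object@values / sum(abs(object@values))
  cat(sprintf("  leading eigenvalue fraction: %.3f\n", ve[1]))
})

#' @describeIn GREMLFit-class total SNP heritability.
#' @export
setMethod("heritability", "GREMLFit", function(x) x@h2)

#' @describeIn GREMLFit-class named vector c(sigma2g components, sigma2e).
#' @export
setMethod("varComponents", "GREMLFit", function(x) {
  c(x@sigma2g, e = x@sigma2e)
})

setMethod("show", "GREMLFit", function(object) {
  cat("GREMLFit (", length(object@sigma2g), " genetic component",
      if (length(object@sigma2g) > 1) "s", ", n = ", object@n, ")\n", sep = "")
  cat(sprintf("  h2 = %.4f (SE %.4f)\n", object@h2, object@se$h2))
  cat(sprintf("  logLik = %.4f, null = %.4f, LRT = %.4f, p = %.4g\n",
              object@logLik, object@logLikNull, object@lrt, object@pvalue))
  cat("  status:", object@status, "after", object@iterations, "iterations\n")
})
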