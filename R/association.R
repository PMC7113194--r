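#' Per-SNP linear-regression GWAS
#'
#' Ordinary least squares of the response on intercept + SNP dosage +
#' covariates, one SNP at a time, with a two-sided t-test on the dosage
#' coefficient. Subjects with a missing dosage are dropped for that SNP
#' only (no imputation). SNPs monomorphic after subsetting get an NA row
#' with a reason. SNPs with complete dosages share one residualization of
#' the covariates (Frisch-Waugh), which is algebraically identical to the
#' full regression.
#'
#' @param response numeric vector (e.g. B0 or B1 of one trait), aligned to
#'   the genotype subjects.
#' @param geno a [GenotypeData-class].
#' @param covariates optional numeric matrix/data.frame of covariates
#'   (without intercept), aligned to `response`.
#' @param model tag recorded in the output (e.g. `"B0"`, `"B1"`).
#' @param trait trait name recorded in the output.
#' @return data.frame, one row per SNP: SNP, CHR, BP, A1, A2, MAF, HWE_P,
#'   BETA, SE, T, P, N, model, trait, note.
#' @export
runGWAS <- function(response, geno, covariates = NULL, model = "B0",
                    trait = "trait") {
  dos <- dosages(geno)
  n <- nrow(dos)
  if (length(response) != n) {
    stop("response (", length(response),
         ") must align with genotype subjects (", n, ")")
  }
  X0 <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    X0 <- cbind(X0, as.matrix(covariates))
  }
  if (qr(X0)$rank < ncol(X0)) stop("covariate matrix is rank deficient")
  usable <- !is.na(response) & stats::complete.cases(X0)

  ss <- snpSummary(geno)
  m <- ncol(dos)
  beta <- se <- tval <- pval <- rep(NA_real_, m)
  nuse <- rep(NA_integer_, m)
  note <- rep("", m)

  yv <- response[usable]
  Xu <- X0[usable, , drop = FALSE]
  qrX <- qr(Xu)
  p0 <- qrX$rank
  dfres <- sum(usable) - p0 - 1L
  ry <- qr.resid(qrX, yv)
  syy <- sum(ry^2)

  complete <- colSums(is.na(dos[usable, , drop = FALSE])) == 0L

  if (any(complete)) {
    D <- dos[usable, complete, drop = FALSE]
    RD <- qr.resid(qrX, D)
    sxx <- colSums(RD^2)
    mono <- sxx <= 1e-12 * nrow(D)
    sxy <- colSums(RD * ry)
    b <- ifelse(mono, NA_real_, sxy / sxx)
    rss <- syy - b^2 * sxx
    s2 <- rss / dfres
    sE <- sqrt(s2 / sxx)
    tv <- b / sE
    pv <- 2 * stats::pt(abs(tv), df = dfres, lower.tail = FALSE)
    idx <- which(complete)
    beta[idx] <- b
    se[idx] <- ifelse(mono, NA_real_, sE)
    tval[idx] <- ifelse(mono, NA_real_, tv)
    pval[idx] <- ifelse(mono, NA_real_, pv)
    nuse[idx] <- nrow(D)
    note[idx[mono]] <- "monomorphic"
  }

  for (j in which(!complete)) {
    ok <- usable & !is.na(dos[, j])
    x <- dos[ok, j]
    if (length(unique(x)) < 2) {
      note[j] <- "monomorphic"
      next
    }
    Xj <- cbind(X0[ok, , drop = FALSE], x)
    fit <- stats::lm.fit(Xj, response[ok])
    dfj <- length(x) - fit$rank
    if (dfj < 1 || is.na(fit$coefficients[ncol(Xj)])) {
      note[j] <- "underdetermined"
      next
    }
    s2j <- sum(fit$residuals^2) / dfj
    R <- qr.R(fit$qr)
    XtXinv <- chol2inv(R)
    sEj <- sqrt(s2j * XtXinv[ncol(Xj), ncol(Xj)])
    bj <- fit$coefficients[ncol(Xj)]
    beta[j] <- bj
    se[j] <- sEj
    tval[j] <- bj / sEj
    pval[j] <- 2 * stats::pt(abs(bj / sEj), df = dfj, lower.tail = FALSE)
    nuse[j] <- length(x)
  }

  data.frame(
    SNP = ss$id, CHR = ss$chrom, BP = ss$pos, A1 = ss$a1, A2 = ss$a2,
    MAF = ss$maf, HWE_P = ss$hwe_p,
    BETA = beta, SE = se, T = tval, P = pval, N = nuse,
    model = model, trait = trait, note = note,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1); NA values propagate.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return Adjusted values, same length and order.
#' @export
bhFDR <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Significance thresholds for association results
#'
#' @param genomeWide genome-wide significance level (default 1e-7).
#' @param suggestive suggestive level (default 1e-5).
#' @param fdrAlpha FDR level for adjusted heritability/association
#'   p-values (default 0.05).
#' @return list of class `SignificanceConfig`.
#' @export
significanceConfig <- function(genomeWide = 1e-7, suggestive = 1e-5,
                               fdrAlpha = 0.05) {
  if (genomeWide > suggestive) {
    stop("genomeWide threshold must not exceed the suggestive threshold")
  }
  structure(list(genomeWide = genomeWide, suggestive = suggestive,
                 fdrAlpha = fdrAlpha),
            class = "SignificanceConfig")
}

#' Classify association results against significance thresholds
#'
#' Tags each SNP `"genome-wide"` when `P < genomeWide` (strictly),
#' `"suggestive"` when `genomeWide <= P < suggestive`, else `"null"`, and
#' returns the table sorted by p-value within trait/model.
#'
#' @param results data.frame from [runGWAS()].
#' @param config a [significanceConfig()].
#' @return The annotated, sorted results with a `hit` column.
#' @export
classifyHits <- function(results, config = significanceConfig()) {
  hit <- rep("null", nrow(results))
  hit[!is.na(results$P) & results$P < config$suggestive] <- "suggestive"
  hit[!is.na(results$P) & results$P < config$genomeWide] <- "genome-wide"
  results$hit <- hit
  results[order(results$trait, results$model, results$P), , drop = FALSE]
}

#' Genomic inflation factor
#'
#' Lambda_GC: the median association chi-square (from two-sided p-values,
#' 1 df) divided by the theoretical null median 0.4549. Values near 1
#' indicate a calibrated test; inflation suggests stratification or
#' polygenicity.
#'
#' @param pvalues p-values (NA dropped).
#' @return list with `lambda` and a `qq` data.frame of observed vs
#'   expected -log10 p for QQ plotting.
#' @export
genomicInflation <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) stop("no non-missing p-values")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1,
                                                 lower.tail = FALSE)
  obs <- sort(p)
  expd <- (seq_along(obs) - 0.5) / length(obs)
  list(lambda = lambda,
       qq = data.frame(expected = -log10(expd), observed = -log10(obs)))
}
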