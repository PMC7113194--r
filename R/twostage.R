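#' Trait configuration table
#'
#' Declares, per trait, whether it is analysed on the natural-log scale
#' (the usual treatment for right-skewed traits such as triglycerides or
#' fasting glucose) and which trait group it belongs to.
#'
#' @param name trait names.
#' @param transform `"identity"` or `"log"` per trait (recycled).
#' @param group free-text group label per trait (recycled), e.g.
#'   anthropometric, biochemistry, cardiopulmonary, red blood cell.
#' @return data.frame with columns name, transform, group.
#' @export
traitConfig <- function(name, transform = "identity", group = "other") {
  transform <- rep_len(transform, length(name))
  if (!all(transform %in% c("identity", "log"))) {
    stop("transform must be 'identity' or 'log'")
  }
  data.frame(name = name, transform = transform,
             group = rep_len(group, length(name)),
             stringsAsFactors = FALSE)
}

#' Apply per-trait transforms to a long phenotype table
#'
#' Natural log for traits flagged `"log"`; non-positive values under a log
#' flag are set missing with a warning. Identity-flagged traits pass
#' through untouched.
#'
#' @param pheno long-format phenotype data.frame (subject_id, period, age,
#'   sex, trait, value).
#' @param traitConfigs a [traitConfig()] table.
#' @return The transformed table.
#' @export
applyTraitTransforms <- function(pheno, traitConfigs) {
  logTraits <- traitConfigs$name[traitConfigs$transform == "log"]
  for (tr in logTraits) {
    sel <- pheno$trait == tr
    bad <- sel & !is.na(pheno$value) & pheno$value <= 0
    if (any(bad)) {
      warning(sum(bad), " non-positive value(s) of ", tr,
              " set missing before log transform")
      pheno$value[bad] <- NA_real_
    }
    ok <- sel & !is.na(pheno$value)
    pheno$value[ok] <- log(pheno$value[ok])
  }
  pheno
}

#' Drop trait-periods with excessive missingness
#'
#' A (trait, period) cell whose missing fraction exceeds `maxMissing`
#' (strictly) is removed for that trait only. The missing fraction counts
#' both absent rows and NA values, against the number of subjects observed
#' at least once for the trait.
#'
#' @param pheno long-format phenotype data.frame.
#' @param maxMissing maximum tolerated missing fraction (default 0.5).
#' @return list with `phenotypes` and `report` (data.frame of excluded
#'   trait/period cells with their missing rates).
#' @export
excludeSparseTraitPeriods <- function(pheno, maxMissing = 0.5) {
  excluded <- list()
  keep <- rep(TRUE, nrow(pheno))
  for (tr in unique(pheno$trait)) {
    sel <- pheno$trait == tr
    subjects <- unique(pheno$subject_id[sel])
    for (per in sort(unique(pheno$period[sel]))) {
      cell <- sel & pheno$period == per
      nobs <- sum(cell & !is.na(pheno$value))
      missrate <- 1 - nobs / length(subjects)
      if (missrate > maxMissing) {
        keep[cell] <- FALSE
        excluded[[length(excluded) + 1L]] <-
          data.frame(trait = tr, period = per, missing_rate = missrate)
      }
    }
  }
  report <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(trait = character(), period = integer(),
               missing_rate = numeric())
  list(phenotypes = pheno[keep, , drop = FALSE], report = report)
}

#' Keep subjects with enough repeated measurements
#'
#' Per trait, drops subjects with fewer than `minObs` non-missing visits
#' for that trait (other traits are unaffected).
#'
#' @param pheno long-format phenotype data.frame.
#' @param minObs minimum visits required (default 3).
#' @return Filtered table.
#' @export
filterMinMeasurements <- function(pheno, minObs = 3) {
  keep <- rep(TRUE, nrow(pheno))
  for (tr in unique(pheno$trait)) {
    sel <- pheno$trait == tr & !is.na(pheno$value)
    cnt <- table(pheno$subject_id[sel])
    ok <- names(cnt)[cnt >= minObs]
    keep[pheno$trait == tr & !(pheno$subject_id %in% ok)] <- FALSE
  }
  pheno[keep, , drop = FALSE]
}

#' Stage 1: period-specific residual variances
#'
#' For each visit period, regresses the trait across subjects on intercept,
#' sex, age and the top principal components, and records the residual
#' variance (residual sum of squares over residual degrees of freedom).
#' These `w` values quantify the period-to-period heteroscedasticity and
#' weight the per-subject regressions in stage 2.
#'
#' @param pheno long-format phenotype table (one trait's rows are used).
#' @param pcs a [PCScores-class] or a matrix of covariate scores with
#'   rownames matching subject ids; `NULL` for no PC adjustment.
#' @param trait trait name to process.
#' @return data.frame: trait, period, w (residual variance), n.
#' @export
estimatePeriodWeights <- function(pheno, pcs, trait) {
  dat <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
  if (!nrow(dat)) stop("no observations for trait ", trait)
  S <- NULL
  if (!is.null(pcs)) {
    S <- if (methods::is(pcs, "PCScores")) pcScores(pcs) else as.matrix(pcs)
  }
  out <- list()
  for (per in sort(unique(dat$period))) {
    d <- dat[dat$period == per, , drop = FALSE]
    X <- cbind(1, sex = as.numeric(d$sex == 2), age = d$age)
    if (!is.null(S)) {
      idx <- match(d$subject_id, rownames(S))
      if (anyNA(idx)) {
        stop("subjects missing from the PC score matrix for trait ", trait)
      }
      X <- cbind(X, S[idx, , drop = FALSE])
    }
    if (nrow(d) <= ncol(X) + 2) {
      warning("period ", per, " of ", trait,
              " underdetermined (n = ", nrow(d), "); excluded")
      next
    }
    fit <- stats::lm.fit(X, d$value)
    dfres <- nrow(d) - fit$rank
    w <- sum(fit$residuals^2) / dfres
    if (w <= .Machine$double.eps * stats::var(d$value + 1)) {
      stop("degenerate cell: residual variance is zero for trait ", trait,
           " at period ", per)
    }
    out[[length(out) + 1L]] <- data.frame(trait = trait, period = per,
                                          w = w, n = nrow(d))
  }
  if (!length(out)) stop("no usable periods for trait ", trait)
  do.call(rbind, out)
}

#' Stage 2: per-subject weighted trajectory fits
#'
#' Fits, for every subject with at least `minObs` visits and two distinct
#' ages, the weighted least-squares line `y_j = B0 + B1 (age_j -
#' mean(age)) + e_j`, where `mean(age)` is the unweighted mean of the
#' subject's observed ages. `B0` is the subject's expected trait value at
#' their own mean age; `B1` the average change per year. Observation
#' weights come from the stage-1 period variances: `"inverse"` (default)
#' uses `1/w_j`, the standard heteroscedasticity correction that
#' down-weights noisy periods; `"literal"` uses `w_j` itself. Observations
#' from periods without a stage-1 weight are excluded.
#'
#' @param pheno long-format phenotype table.
#' @param weights stage-1 table from [estimatePeriodWeights()], or `NULL`
#'   for equal weights.
#' @param trait trait to process.
#' @param weightScheme `"inverse"` or `"literal"` (see above).
#' @param minObs minimum non-missing visits per subject (default 3).
#' @return data.frame: subject_id, trait, B0, B1, mean_age, n_obs, sigma2
#'   (weighted residual variance; 0 when a subject has exactly 2 visits).
#' @examples
#' ph <- data.frame(subject_id = "s1", period = 1:3, age = c(40, 42, 44),
#'                  sex = 1, trait = "t", value = c(10, 12, 14))
#' fitSubjectTrajectories(ph, NULL, "t")  # B0 = 12, B1 = 1
#' @export
fitSubjectTrajectories <- function(pheno, weights, trait,
                                   weightScheme = c("inverse", "literal"),
                                   minObs = 3) {
  weightScheme <- match.arg(weightScheme)
  dat <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
  wtab <- NULL
  if (!is.null(weights)) {
    wtab <- weights[weights$trait == trait, , drop = FALSE]
    dat <- dat[dat$period %in% wtab$period, , drop = FALSE]
  }
  out <- list()
  dropped <- 0L
  for (id in unique(dat$subject_id)) {
    d <- dat[dat$subject_id == id, , drop = FALSE]
    if (nrow(d) < max(2L, minObs)) next
    if (length(unique(d$age)) < 2) {
      dropped <- dropped + 1L
      next
    }
    wv <- if (is.null(wtab)) rep(1, nrow(d)) else {
      wj <- wtab$w[match(d$period, wtab$period)]
      if (weightScheme == "inverse") 1 / wj else wj
    }
    agec <- d$age - mean(d$age)
    # weighted normal equations for (B0, B1) on (1, centred age)
    sw <- sum(wv)
    swx <- sum(wv * agec)
    swxx <- sum(wv * agec^2)
    swy <- sum(wv * d$value)
    swxy <- sum(wv * agec * d$value)
    det <- sw * swxx - swx^2
    if (det <= 0) {
      dropped <- dropped + 1L
      next
    }
    b0 <- (swxx * swy - swx * swxy) / det
    b1 <- (sw * swxy - swx * swy) / det
    r <- d$value - b0 - b1 * agec
    sigma2 <- if (nrow(d) > 2) sum(wv * r^2) / (nrow(d) - 2) else 0
    out[[length(out) + 1L]] <- data.frame(
      subject_id = id, trait = trait, B0 = b0, B1 = b1,
      mean_age = mean(d$age), n_obs = nrow(d), sigma2 = sigma2,
      stringsAsFactors = FALSE
    )
  }
  if (dropped) {
    warning(dropped, " subject(s) dropped for trait ", trait,
            ": fewer than two distinct ages")
  }
  if (!length(out)) {
    return(data.frame(subject_id = character(), trait = character(),
                      B0 = numeric(), B1 = numeric(), mean_age = numeric(),
                      n_obs = integer(), sigma2 = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
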