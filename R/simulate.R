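#' Simulation settings for a synthetic longitudinal cohort
#'
#' Builds the parameter set for [simulateGenotypes()] and
#' [simulateLongitudinalPhenotypes()]. The defaults emulate a biennial
#' community-cohort design: six visit periods two years apart, baseline age
#' uniform on 40-69 years, mildly heteroscedastic visit noise and 10% of
#' visits missing at random. Subject-level intercepts (phenotypic average,
#' b0) and slopes (annual change, b1) each split into a polygenic part with
#' variance `h2 * var` and an environmental part with variance
#' `(1 - h2) * var`.
#'
#' @param nSubjects,nSnps cohort and panel size.
#' @param nPeriods number of visit periods (>= 2).
#' @param mafRange allele-frequency range, within (0, 0.5].
#' @param h2B0,h2B1 target SNP heritability of intercept and slope, in [0, 1).
#' @param varB0,varB1 total variances of the true intercept and slope. The
#'   slope default (0.25) keeps the slope signal well above the per-visit
#'   noise contribution to the fitted slope, as in a design with a 10-year
#'   follow-up window.
#' @param periodNoiseVariances per-period residual variances of a single
#'   visit (length `nPeriods`, strictly positive).
#' @param baselineAgeRange range of the uniform baseline age, years.
#' @param visitSpacing years between consecutive periods.
#' @param missingVisitProb probability a visit is missing, independently.
#' @param sexEffect,ageEffect fixed effects added to every observation
#'   (`sexEffect * I(female)` and `ageEffect * age`).
#' @param envCor correlation of the environmental parts of b0 and b1.
#' @param dropoutPeriods optional vector of period indices subjected to
#'   extra whole-period missingness (emulating a trait not measured at a
#'   visit wave).
#' @param dropoutProb missingness probability applied in `dropoutPeriods`
#'   (replaces `missingVisitProb` there).
#' @param nChromosomes SNPs are split into this many equal blocks labelled
#'   as autosomes 1..nChromosomes.
#' @param chromProportions optional positive weights (length `nChromosomes`)
#'   giving unequal SNP shares per chromosome.
#' @param seed integer seed; all randomness in the generators flows from it.
#'
#' @return A validated list of class `SimulationConfig`.
#' @examples
#' cfg <- simConfig(nSubjects = 50, nSnps = 100, seed = 1)
#' geno <- simulateGenotypes(cfg)
#' @export
simConfig <- function(nSubjects = 300, nSnps = 1000, nPeriods = 6,
                      mafRange = c(0.05, 0.5),
                      h2B0 = 0.3, h2B1 = 0.2,
                      varB0 = 1, varB1 = 0.25,
                      periodNoiseVariances = NULL,
                      baselineAgeRange = c(40, 69), visitSpacing = 2,
                      missingVisitProb = 0.1,
                      sexEffect = 0.3, ageEffect = 0.02,
                      envCor = 0,
                      dropoutPeriods = integer(), dropoutProb = 0.6,
                      nChromosomes = 22, chromProportions = NULL,
                      seed = 1L) {
  if (is.null(periodNoiseVariances)) {
    base <- c(1.0, 1.3, 0.9, 1.2, 0.8, 1.1)
    periodNoiseVariances <- rep_len(base, nPeriods)
  }
  cfg <- list(
    nSubjects = as.integer(nSubjects), nSnps = as.integer(nSnps),
    nPeriods = as.integer(nPeriods), mafRange = as.numeric(mafRange),
    h2B0 = h2B0, h2B1 = h2B1, varB0 = varB0, varB1 = varB1,
    periodNoiseVariances = as.numeric(periodNoiseVariances),
    baselineAgeRange = as.numeric(baselineAgeRange),
    visitSpacing = visitSpacing,
    missingVisitProb = missingVisitProb,
    sexEffect = sexEffect, ageEffect = ageEffect, envCor = envCor,
    dropoutPeriods = as.integer(dropoutPeriods), dropoutProb = dropoutProb,
    nChromosomes = as.integer(nChromosomes),
    chromProportions = chromProportions,
    seed = as.integer(seed)
  )
  if (cfg$nSubjects < 1 || cfg$nSnps < 1) {
    stop("nSubjects and nSnps must be at least 1")
  }
  if (cfg$nPeriods < 2) stop("nPeriods must be at least 2")
  if (length(cfg$mafRange) != 2 || cfg$mafRange[1] <= 0 ||
      cfg$mafRange[2] > 0.5 || cfg$mafRange[1] > cfg$mafRange[2]) {
    stop("mafRange must lie within (0, 0.5] with min <= max")
  }
  for (h in c(cfg$h2B0, cfg$h2B1)) {
    if (h < 0 || h >= 1) stop("heritabilities must lie in [0, 1)")
  }
  if (length(cfg$periodNoiseVariances) != cfg$nPeriods ||
      any(cfg$periodNoiseVariances <= 0)) {
    stop("periodNoiseVariances must be ", cfg$nPeriods,
         " strictly positive values")
  }
  if (cfg$missingVisitProb < 0 || cfg$missingVisitProb >= 1) {
    stop("missingVisitProb must lie in [0, 1)")
  }
  if (abs(cfg$envCor) > 1) stop("envCor must lie in [-1, 1]")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a post-QC genotype panel
#'
#' Draws each SNP's allele frequency uniformly from `cfg$mafRange` and each
#' dosage as Binomial(2, p) per subject, i.e. Hardy-Weinberg proportions
#' with no linkage disequilibrium. SNPs are assigned to chromosomes in
#' contiguous blocks (equal by default, or proportional to
#' `chromProportions`).
#'
#' @param cfg a [simConfig()] object.
#' @return A [GenotypeData-class] object (no missing calls).
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  n <- cfg$nSubjects
  m <- cfg$nSnps
  p <- stats::runif(m, cfg$mafRange[1], cfg$mafRange[2])
  dos <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  storage.mode(dos) <- "integer"

  props <- cfg$chromProportions
  if (is.null(props)) props <- rep(1, cfg$nChromosomes)
  if (length(props) != cfg$nChromosomes || any(props <= 0)) {
    stop("chromProportions must be ", cfg$nChromosomes, " positive weights")
  }
  # contiguous blocks whose sizes follow the weights and sum to m exactly
  bounds <- round(cumsum(props) / sum(props) * m)
  sizes <- diff(c(0L, bounds))
  chrom <- rep(seq_len(cfg$nChromosomes), times = sizes)

  snps <- data.frame(
    id = sprintf("snp%d", seq_len(m)),
    chrom = as.integer(chrom),
    pos = as.integer(seq_len(m) * 1000L),
    a1 = rep("A", m), a2 = rep("G", m),
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    fid = sprintf("F%d", seq_len(n)),
    iid = sprintf("S%d", seq_len(n)),
    sex = sample(c(1L, 2L), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  rownames(dos) <- samples$iid
  colnames(dos) <- snps$id
  methods::new("GenotypeData", dosages = dos, snps = snps, samples = samples)
}

# draw a polygenic score from i.i.d. standardized SNP effects and rescale it
# so its sample variance equals the target exactly
.polygenicScore <- function(W, targetVar) {
  m <- ncol(W)
  u <- stats::rnorm(m)
  g <- drop(W %*% u)
  v <- stats::var(g)
  if (targetVar == 0 || v == 0) {
    return(list(g = rep(0, nrow(W)), effects = rep(0, m)))
  }
  s <- sqrt(targetVar / v)
  list(g = g * s, effects = u * s)
}

#' Simulate longitudinal phenotypes on a genotype panel
#'
#' Generates per-subject true intercepts `b0` and slopes `b1` as polygenic
#' score plus environmental residual, then observations
#' `y_ij = b0_i + b1_i (age_ij - mean(age_i)) + sexEffect * female_i +
#' ageEffect * age_ij + e_ij` with `Var(e_ij)` equal to the configured
#' period noise variance. Polygenic scores use i.i.d. Gaussian effects on
#' standardized dosages, rescaled so the realized (in-sample) genetic
#' variance hits `h2 * var` exactly; environmental residuals are drawn with
#' the complementary variance. `mean(age_i)` is the mean over the subject's
#' *observed* visits, so the intercept is the expected trait value at the
#' subject's own mean age. Visits are removed independently with
#' `missingVisitProb` (and `dropoutProb` within `dropoutPeriods`).
#'
#' @param geno a [GenotypeData-class] from [simulateGenotypes()].
#' @param cfg the same [simConfig()] used for the genotypes.
#' @param trait trait name written into the long table.
#' @return A list with `phenotypes` (long-format data.frame: subject_id,
#'   period, age, sex, trait, value) and `truth` (per-subject b0, b1 and
#'   their genetic parts, plus per-SNP effects on the standardized scale).
#' @export
simulateLongitudinalPhenotypes <- function(geno, cfg, trait = "trait1") {
  stopifnot(inherits(cfg, "SimulationConfig"), methods::is(geno, "GenotypeData"))
  if (cfg$nPeriods < 2) stop("nPeriods must be at least 2")
  set.seed(cfg$seed + 1L)

  X <- dosages(geno)
  n <- nrow(X)
  p <- colMeans(X, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  W <- scale(X[, keep, drop = FALSE],
             center = 2 * p[keep],
             scale = sqrt(2 * p[keep] * (1 - p[keep])))

  g0 <- .polygenicScore(W, cfg$h2B0 * cfg$varB0)
  g1 <- .polygenicScore(W, cfg$h2B1 * cfg$varB1)

  # environmental parts, optionally correlated between intercept and slope
  z0 <- stats::rnorm(n)
  z1 <- cfg$envCor * z0 + sqrt(1 - cfg$envCor^2) * stats::rnorm(n)
  e0 <- z0 * sqrt((1 - cfg$h2B0) * cfg$varB0)
  e1 <- z1 * sqrt((1 - cfg$h2B1) * cfg$varB1)
  b0 <- g0$g + e0
  b1 <- g1$g + e1

  sex <- sampleInfo(geno)$sex
  female <- as.numeric(sex == 2L)
  baseAge <- stats::runif(n, cfg$baselineAgeRange[1], cfg$baselineAgeRange[2])

  pmiss <- rep(cfg$missingVisitProb, cfg$nPeriods)
  pmiss[cfg$dropoutPeriods] <- cfg$dropoutProb
  obs <- matrix(stats::runif(n * cfg$nPeriods) >= rep(pmiss, each = n),
                nrow = n)

  rows <- vector("list", n)
  ids <- subjectIds(geno)
  for (i in seq_len(n)) {
    per <- which(obs[i, ])
    if (!length(per)) next
    age <- baseAge[i] + (per - 1) * cfg$visitSpacing
    mu <- b0[i] + b1[i] * (age - mean(age)) +
      cfg$sexEffect * female[i] + cfg$ageEffect * age
    y <- mu + stats::rnorm(length(per),
                           sd = sqrt(cfg$periodNoiseVariances[per]))
    rows[[i]] <- data.frame(
      subject_id = ids[i], period = per, age = age, sex = sex[i],
      trait = trait, value = y, stringsAsFactors = FALSE
    )
  }
  pheno <- do.call(rbind, rows)
  rownames(pheno) <- NULL

  truth <- list(
    b0 = stats::setNames(b0, ids), b1 = stats::setNames(b1, ids),
    b0_genetic = stats::setNames(g0$g, ids),
    b1_genetic = stats::setNames(g1$g, ids),
    snp_effects_b0 = stats::setNames(g0$effects, colnames(W)),
    snp_effects_b1 = stats::setNames(g1$effects, colnames(W))
  )
  list(phenotypes = pheno, truth = truth)
}

#' Read/write the long-format phenotype table
#'
#' Tab-separated with header columns subject_id, period, age, sex, trait,
#' value; one row per observed visit.
#'
#' @param pheno long-format data.frame.
#' @param path file path.
#' @export
writeLongPhenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeLongPhenotypes
#' @export
readLongPhenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(subject_id = "character"))
}

#' @rdname writeLongPhenotypes
#' @param truth the `truth` element returned by
#'   [simulateLongitudinalPhenotypes()].
#' @export
writeTrueEffects <- function(truth, path) {
  df <- data.frame(subject_id = names(truth$b0),
                   b0 = truth$b0, b1 = truth$b1,
                   b0_genetic = truth$b0_genetic,
                   b1_genetic = truth$b1_genetic,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
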