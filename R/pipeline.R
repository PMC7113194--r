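#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis: input paths, trait
#' declarations, QC thresholds, the repeated-measures inclusion rule,
#' number of principal components, REML and significance settings, and the
#' seed. Can also be loaded from a YAML file with the same field names via
#' [readPipelineConfig()].
#'
#' @param genotypePrefix PLINK bed/bim/fam prefix.
#' @param phenotypeFile long-format phenotype TSV (subject_id, period,
#'   age, sex, trait, value).
#' @param outputDir directory for all stage outputs (created if needed).
#' @param traits a [traitConfig()] table; `NULL` derives identity
#'   transforms for every trait found in the phenotype file.
#' @param hweThr,mafThr,callThr,sampleMissThr QC thresholds.
#' @param maxMissingRate trait-period exclusion threshold (default 0.5).
#' @param minMeasurements repeated-measures inclusion rule (default 3).
#' @param nPCs principal components used as covariates (default 10).
#' @param gwas run the per-SNP association stage (default TRUE).
#' @param chromosomal run the joint per-chromosome fit for the trait with
#'   the highest significant B1 heritability (default TRUE); set a trait
#'   name to override the choice.
#' @param weightScheme stage-2 weighting, see [fitSubjectTrajectories()].
#' @param significance a [significanceConfig()].
#' @param maxIter REML iteration cap.
#' @param seed integer seed recorded in the manifest.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(genotypePrefix, phenotypeFile, outputDir,
                           traits = NULL,
                           hweThr = 1e-5, mafThr = 0.05, callThr = 0.95,
                           sampleMissThr = 0.05,
                           maxMissingRate = 0.5, minMeasurements = 3,
                           nPCs = 10, gwas = TRUE, chromosomal = TRUE,
                           weightScheme = "inverse",
                           significance = significanceConfig(),
                           maxIter = 100, seed = 1L) {
  for (thr in c(hweThr, mafThr, callThr, sampleMissThr, maxMissingRate)) {
    if (thr < 0 || thr > 1) stop("thresholds must lie in [0, 1]")
  }
  if (minMeasurements < 2) stop("minMeasurements must be at least 2")
  structure(list(
    genotypePrefix = genotypePrefix, phenotypeFile = phenotypeFile,
    outputDir = outputDir, traits = traits,
    hweThr = hweThr, mafThr = mafThr, callThr = callThr,
    sampleMissThr = sampleMissThr, maxMissingRate = maxMissingRate,
    minMeasurements = minMeasurements, nPCs = nPCs,
    gwas = gwas, chromosomal = chromosomal, weightScheme = weightScheme,
    significance = significance, maxIter = maxIter, seed = as.integer(seed)
  ), class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file whose keys mirror the `pipelineConfig()`
#'   arguments (traits given as a list of name/transform/group records).
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  traits <- NULL
  if (!is.null(raw$traits)) {
    traits <- do.call(rbind, lapply(raw$traits, function(tr) {
      traitConfig(tr$name, tr$transform %||% "identity",
                  tr$group %||% "other")
    }))
  }
  args <- raw[setdiff(names(raw), "traits")]
  args$traits <- traits
  do.call(pipelineConfig, args)
}

.tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full heritability and GWAS pipeline
#'
#' Executes, in order: sample and SNP quality control; genome-wide GRM and
#' principal components; trait transforms, trait-period exclusion and the
#' minimum-measurement rule; stage-1 period weights; stage-2 subject
#' trajectories (B0, B1); GREML heritability of B0 and B1 per trait with
#' FDR across traits; a joint per-chromosome fit for the top-B1 trait; and
#' per-SNP GWAS of B0 and B1 with hit classification. Every intermediate
#' table is written to the output directory as TSV and a JSON run manifest
#' records configuration, input checksums and per-stage counts.
#'
#' @param config a [pipelineConfig()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
runFull <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  logmsg <- function(...) message("[longherit] ", ...)

  manifest <- list(
    package_version = as.character(utils::packageVersion("longherit")),
    seed = config$seed,
    config = config[setdiff(names(config), "traits")],
    input_checksums = list(
      bed = unname(tools::md5sum(paste0(config$genotypePrefix, ".bed"))),
      phenotypes = unname(tools::md5sum(config$phenotypeFile))
    ),
    stages = list(), warnings = character()
  )
  addWarn <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  withCallingHandlers({
    logmsg("reading genotypes")
    geno <- readPlink(config$genotypePrefix)
    manifest$stages$input <- list(samples = nSamples(geno),
                                  snps = nSnps(geno))

    logmsg("sample QC")
    sf <- applySampleFilters(geno, config$sampleMissThr)
    logmsg("SNP QC")
    qf <- applySnpFilters(sf$genotypes, config$hweThr, config$mafThr,
                          config$callThr)
    geno <- qf$genotypes
    manifest$stages$qc <- c(sf$report, qf$report)
    writeQcReport(c(sf$report, qf$report),
                  file.path(config$outputDir, "qc_report"))

    logmsg("GRM and principal components")
    grm <- computeGRM(geno)
    writeGRMBinary(grm, file.path(config$outputDir, "grm_all"),
                   fids = sampleInfo(geno)$fid)
    pcs <- computePCs(grm, k = config$nPCs)
    writePCCovariates(pcs, file.path(config$outputDir, "pcs.tsv"),
                      fids = sampleInfo(geno)$fid)

    logmsg("phenotypes")
    pheno <- readLongPhenotypes(config$phenotypeFile)
    traits <- config$traits
    if (is.null(traits)) traits <- traitConfig(unique(pheno$trait))
    pheno <- applyTraitTransforms(pheno, traits)
    sp <- excludeSparseTraitPeriods(pheno, config$maxMissingRate)
    pheno <- sp$phenotypes
    .tsv(sp$report, file.path(config$outputDir,
                              "excluded_trait_periods.tsv"))
    pheno <- filterMinMeasurements(pheno, config$minMeasurements)
    # keep only subjects that survived genotype QC
    pheno <- pheno[pheno$subject_id %in% subjectIds(geno), , drop = FALSE]
    manifest$stages$phenotypes <- list(
      rows = nrow(pheno), traits = length(unique(pheno$trait)),
      subjects = length(unique(pheno$subject_id)),
      excluded_trait_periods = nrow(sp$report))

    logmsg("two-stage trajectories")
    allw <- list()
    alltraj <- list()
    for (tr in traits$name) {
      if (!tr %in% pheno$trait) next
      w <- estimatePeriodWeights(pheno, pcs, tr)
      traj <- fitSubjectTrajectories(pheno, w, tr,
                                     weightScheme = config$weightScheme,
                                     minObs = config$minMeasurements)
      allw[[tr]] <- w
      alltraj[[tr]] <- traj
    }
    weights <- do.call(rbind, allw)
    trajectories <- do.call(rbind, alltraj)
    rownames(weights) <- rownames(trajectories) <- NULL
    .tsv(weights, file.path(config$outputDir, "period_weights.tsv"))
    .tsv(trajectories, file.path(config$outputDir, "trajectories.tsv"))
    manifest$stages$trajectories <- list(
      rows = nrow(trajectories),
      subjects = length(unique(trajectories$subject_id)))

    logmsg("GREML heritability (B0 and B1 separately)")
    ids <- subjectIds(geno)
    sex <- as.numeric(sampleInfo(geno)$sex == 2)
    herit <- list()
    for (tr in names(alltraj)) {
      traj <- alltraj[[tr]]
      idx <- match(traj$subject_id, ids)
      for (resp in c("B0", "B1")) {
        y <- traj[[resp]]
        X <- cbind(1, age = traj$mean_age, sex = sex[idx])
        sub <- .subsetGRM(grm, idx)
        fit <- fitGREML(y, X, sub, maxIter = config$maxIter)
        herit[[paste(tr, resp)]] <- data.frame(
          trait = tr, response = resp, n = fit@n,
          h2 = fit@h2, se = fit@se$h2,
          sigma2g = sum(fit@sigma2g), sigma2e = fit@sigma2e,
          logL0 = fit@logLikNull, logL1 = fit@logLik,
          LRT = fit@lrt, p = fit@pvalue, status = fit@status,
          stringsAsFactors = FALSE)
      }
    }
    heritTab <- do.call(rbind, herit)
    rownames(heritTab) <- NULL
    # FDR across traits, within each response
    heritTab$FDR <- NA_real_
    for (resp in unique(heritTab$response)) {
      i <- heritTab$response == resp
      heritTab$FDR[i] <- bhFDR(heritTab$p[i])
    }
    .tsv(heritTab, file.path(config$outputDir, "heritability.tsv"))
    manifest$stages$heritability <- list(fits = nrow(heritTab))

    chromTab <- NULL
    if (!isFALSE(config$chromosomal)) {
      b1 <- heritTab[heritTab$response == "B1", , drop = FALSE]
      topTrait <- if (is.character(config$chromosomal)) {
        config$chromosomal
      } else {
        sig <- b1[b1$FDR < config$significance$fdrAlpha, , drop = FALSE]
        pick <- if (nrow(sig)) sig else b1
        pick$trait[which.max(pick$h2)]
      }
      logmsg("chromosomal partitioning for ", topTrait, " (B1)")
      grms <- partitionByChromosome(geno)
      traj <- alltraj[[topTrait]]
      idx <- match(traj$subject_id, ids)
      subgrms <- lapply(grms, .subsetGRM, idx = idx)
      X <- cbind(1, age = traj$mean_age, sex = sex[idx])
      cfit <- fitChromosomal(traj$B1, X, subgrms,
                             maxIter = config$maxIter)
      snpCounts <- vapply(grms, function(g) max(grmPairCounts(g)),
                          numeric(1))
      chromTab <- data.frame(
        trait = topTrait, response = "B1",
        chrom = names(grms), n_snps = snpCounts,
        h2_c = cfit@h2Components,
        sigma2g_c = cfit@sigma2g, status = cfit@status,
        stringsAsFactors = FALSE)
      corr <- tryCatch(
        chromosomeLengthCorrelation(cfit, snpCounts),
        error = function(e) list(r = NA_real_, p = NA_real_))
      .tsv(chromTab, file.path(config$outputDir,
                               "chromosomal_heritability.tsv"))
      manifest$stages$chromosomal <- list(
        trait = topTrait, length_correlation_r = corr$r,
        length_correlation_p = corr$p)
    }

    gwasTab <- NULL
    if (config$gwas) {
      logmsg("GWAS")
      gw <- list()
      pcsScores <- pcScores(pcs)
      for (tr in names(alltraj)) {
        traj <- alltraj[[tr]]
        idx <- match(traj$subject_id, ids)
        gsub <- .subsetGeno(geno, samples = idx)
        covar <- cbind(age = traj$mean_age, sex = sex[idx],
                       pcsScores[idx, , drop = FALSE])
        for (resp in c("B0", "B1")) {
          res <- runGWAS(traj[[resp]], gsub, covar, model = resp,
                         trait = tr)
          gw[[paste(tr, resp)]] <- res
        }
      }
      gwasTab <- classifyHits(do.call(rbind, gw), config$significance)
      rownames(gwasTab) <- NULL
      .tsv(gwasTab, file.path(config$outputDir, "gwas.tsv"))
      hits <- gwasTab[gwasTab$hit != "null", , drop = FALSE]
      .tsv(hits, file.path(config$outputDir, "gwas_hits.tsv"))
      .tsv(gwasTab[, c("CHR", "BP", "P", "trait", "model")],
           file.path(config$outputDir, "gwas_plotready.tsv"))
      manifest$stages$gwas <- list(
        tests = nrow(gwasTab),
        genome_wide = sum(gwasTab$hit == "genome-wide"),
        suggestive = sum(gwasTab$hit == "suggestive"))
    }
  }, warning = addWarn)

  jsonlite::write_json(manifest,
                       file.path(config$outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

.subsetGRM <- function(grm, idx) {
  methods::new("GRM",
               mat = grmMatrix(grm)[idx, idx, drop = FALSE],
               nPairs = grmPairCounts(grm)[idx, idx, drop = FALSE],
               ids = subjectIds(grm)[idx],
               component = grmComponent(grm))
}

#' Write a small coherent demo dataset
#'
#' Generates a synthetic cohort (default 300 subjects, 1000 SNPs over 22
#' chromosomes, 6 biennial periods) with four traits of mixed heritability
#' — one of them log-normal — plus ground-truth sidecars, in exactly the
#' formats [runFull()] consumes. A matching pipeline YAML config is
#' written alongside.
#'
#' @param outdir output directory.
#' @param seed integer seed.
#' @param nSubjects,nSnps cohort dimensions.
#' @return Invisibly, a list with the file paths and the per-trait true
#'   heritabilities.
#' @export
makeDemoDataset <- function(outdir, seed = 1L, nSubjects = 300,
                            nSnps = 1000) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  traitDefs <- data.frame(
    name = c("height", "weight", "ltg", "dbp"),
    transform = c("identity", "identity", "log", "identity"),
    group = c("anthropometric", "anthropometric", "biochemistry",
              "cardiopulmonary"),
    h2B0 = c(0.5, 0.3, 0.2, 0.0),
    h2B1 = c(0.1, 0.3, 0.0, 0.0),
    stringsAsFactors = FALSE
  )
  baseCfg <- simConfig(nSubjects = nSubjects, nSnps = nSnps, seed = seed)
  geno <- simulateGenotypes(baseCfg)
  prefix <- file.path(outdir, "demo")
  writePlink(geno, prefix)

  phenos <- list()
  truths <- list()
  for (i in seq_len(nrow(traitDefs))) {
    cfg <- simConfig(nSubjects = nSubjects, nSnps = nSnps,
                     h2B0 = traitDefs$h2B0[i], h2B1 = traitDefs$h2B1[i],
                     seed = seed + i * 1000L)
    sim <- simulateLongitudinalPhenotypes(geno, cfg,
                                          trait = traitDefs$name[i])
    ph <- sim$phenotypes
    if (traitDefs$transform[i] == "log") {
      # simulate on the log scale, publish on the natural scale
      ph$value <- exp(ph$value)
    }
    phenos[[i]] <- ph
    truths[[i]] <- sim$truth
    writeTrueEffects(sim$truth,
                     file.path(outdir, paste0("truth_",
                                              traitDefs$name[i], ".tsv")))
  }
  pheno <- do.call(rbind, phenos)
  phenoPath <- file.path(outdir, "phenotypes.tsv")
  writeLongPhenotypes(pheno, phenoPath)

  cfgPath <- file.path(outdir, "pipeline.yaml")
  yaml::write_yaml(list(
    genotypePrefix = prefix, phenotypeFile = phenoPath,
    outputDir = file.path(outdir, "results"),
    traits = lapply(seq_len(nrow(traitDefs)), function(i) {
      list(name = traitDefs$name[i], transform = traitDefs$transform[i],
           group = traitDefs$group[i])
    }),
    seed = as.integer(seed)
  ), cfgPath)

  invisible(list(genotypePrefix = prefix, phenotypeFile = phenoPath,
                 configFile = cfgPath,
                 traits = traitDefs,
                 truth = stats::setNames(truths, traitDefs$name)))
}
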