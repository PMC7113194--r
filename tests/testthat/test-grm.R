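test_that("single-SNP GRM entries match the closed-form estimator", {
  # two subjects, one SNP, dosages 2 and 0 -> sample p = 0.5
  g <- makeGeno(matrix(c(2L, 0L), nrow = 2))
  A <- grmMatrix(computeGRM(g))
  expect_equal(A[1, 2], (2 - 1) * (0 - 1) / 0.5)        # -2
  expect_equal(A[1, 1], 1 + (4 - 2 * 2 + 2 * 0.25) / 0.5)  # 2
  expect_equal(A[2, 2], 1 + (0 - 0 + 2 * 0.25) / 0.5)      # 2
  expect_equal(A[2, 1], A[1, 2])
})

test_that("GRM is invariant to allele-label swaps and handles missing pairwise", {
  set.seed(31)
  dos <- matrix(rbinom(40 * 120, 2, runif(120, 0.1, 0.5)), nrow = 40,
                byrow = TRUE)
  dos[sample(length(dos), 100)] <- NA
  g <- makeGeno(dos)
  A <- computeGRM(g)
  flip <- sample(120, 60)
  dosF <- dos
  dosF[, flip] <- 2L - dosF[, flip]
  AF <- computeGRM(makeGeno(dosF))
  expect_lt(max(abs(grmMatrix(A) - grmMatrix(AF))), 1e-12)
  expect_identical(grmPairCounts(A), grmPairCounts(AF))
  # pair counts reflect joint observation
  obs <- !is.na(dos)
  expect_equal(unname(grmPairCounts(A)[3, 7]), sum(obs[3, ] & obs[7, ]))
  expect_equal(unname(grmPairCounts(A)[5, 5]), sum(obs[5, ]))
})

test_that("monomorphic SNPs are excluded with a warning", {
  dos <- cbind(c(1L, 2L, 0L, 1L), rep(2L, 4))
  expect_warning(A <- computeGRM(makeGeno(dos)), "monomorphic")
  expect_equal(max(grmPairCounts(A)), 1)
  expect_error(suppressWarnings(computeGRM(makeGeno(matrix(2L, 4, 2)))),
               "polymorphic")
})

test_that("per-chromosome GRMs aggregate exactly to the genome-wide GRM", {
  set.seed(32)
  g <- simulateGenotypes(simConfig(nSubjects = 30, nSnps = 220, seed = 32))
  # a rare SNP may be monomorphic at n = 30; it drops out of both sides
  parts <- suppressWarnings(partitionByChromosome(g))
  expect_length(parts, 22)
  expect_true(all(vapply(parts, function(x) max(grmPairCounts(x)),
                         numeric(1)) == 10))
  full <- suppressWarnings(computeGRM(g))
  wavg <- Reduce(`+`, lapply(parts, function(x) {
    max(grmPairCounts(x)) * grmMatrix(x)
  })) / max(grmPairCounts(full))
  expect_lt(max(abs(wavg - grmMatrix(full))), 1e-12)

  # single-chromosome panel: partition equals the genome-wide GRM
  g1 <- simulateGenotypes(simConfig(nSubjects = 15, nSnps = 40,
                                    nChromosomes = 1, seed = 33))
  p1 <- partitionByChromosome(g1)
  expect_length(p1, 1)
  expect_equal(grmMatrix(p1[[1]]), grmMatrix(computeGRM(g1)))
})

test_that("GRM spectrum is real and reconstructs the matrix", {
  g <- simulateGenotypes(simConfig(nSubjects = 25, nSnps = 300, seed = 34))
  A <- grmMatrix(computeGRM(g))
  eg <- eigen(A, symmetric = TRUE)
  expect_true(all(Im(eg$values) == 0))
  recon <- eg$vectors %*% diag(eg$values) %*% t(eg$vectors)
  expect_lt(max(abs(recon - A)), 1e-8)
})

test_that("principal components recover known structure", {
  # rank-1 GRM A = v v': PC1 proportional to v with eigenvalue ||v||^2
  v <- c(3, -1, 2, 0.5, -2)
  A <- new("GRM", mat = v %o% v, nPairs = matrix(1L, 5, 5),
           ids = letters[1:5], component = "all")
  pc <- computePCs(A, k = 2)
  expect_equal(pcValues(pc)[1], sum(v^2))
  s1 <- pcScores(pc)[, 1]
  expect_lt(max(abs(abs(s1 / sqrt(sum(v^2))) - abs(v) / sqrt(sum(v^2)))),
            1e-8)
  # sign convention: largest-magnitude loading positive
  expect_gt(s1[which.max(abs(s1))], 0)
  expect_error(computePCs(A, k = 5), "at most")

  # two subpopulations with different allele frequencies separate on PC1
  set.seed(35)
  n <- 60
  grp <- rep(0:1, each = n / 2)
  p1 <- runif(200, 0.1, 0.5)
  p2 <- pmin(0.95, p1 + 0.3)
  dos <- t(vapply(grp, function(g) {
    rbinom(200, 2, if (g == 0) p1 else p2)
  }, numeric(200)))
  pcs <- computePCs(computeGRM(makeGeno(dos)), k = 2)
  expect_gt(abs(cor(pcScores(pcs)[, 1], grp)), 0.9)
})

test_that("GCTA GRM binaries round-trip at float32 precision", {
  g <- simulateGenotypes(simConfig(nSubjects = 13, nSnps = 80, seed = 36))
  A <- computeGRM(g)
  pre <- file.path(tempdir(), "grmrt")
  writeGRMBinary(A, pre)
  expect_equal(file.size(paste0(pre, ".grm.bin")), 4 * 13 * 14 / 2)
  B <- readGRMBinary(pre)
  expect_lt(max(abs(grmMatrix(A) - grmMatrix(B))),
            max(abs(grmMatrix(A))) * 2^-23)
  expect_identical(grmPairCounts(A), grmPairCounts(B))
  expect_identical(subjectIds(A), subjectIds(B))

  # three subjects -> exactly six floats
  g3 <- simulateGenotypes(simConfig(nSubjects = 3, nSnps = 10, seed = 37))
  pre3 <- file.path(tempdir(), "grm3")
  writeGRMBinary(computeGRM(g3), pre3)
  expect_equal(file.size(paste0(pre3, ".grm.bin")), 6 * 4)

  # id list inconsistent with the triangle size -> format error
  idf <- read.table(paste0(pre3, ".grm.id"))
  write.table(rbind(idf, c("F4", "S4")), paste0(pre3, ".grm.id"),
              row.names = FALSE, col.names = FALSE, quote = FALSE,
              sep = "\t")
  expect_error(readGRMBinary(pre3), "mismatch")
})
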