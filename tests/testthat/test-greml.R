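test_that("restricted likelihood matches the i.i.d. closed form and is
           translation invariant", {
  set.seed(51)
  n <- 40
  y <- rnorm(n, 2, 1.5)
  X <- cbind(1, rnorm(n))
  s2 <- 1.7
  # closed form for V = s2 I: -0.5[(n-p) log s2 + log|X'X| + RSS/s2]
  qrX <- qr(X)
  rss <- sum(qr.resid(qrX, y)^2)
  p <- ncol(X)
  closed <- -0.5 * ((n - p) * log(s2) +
                      determinant(crossprod(X))$modulus[1] + rss / s2)
  expect_equal(restrictedLogLik(y, X, list(), numeric(0), s2), closed,
               tolerance = 1e-10)

  # invariance to shifts in the column space of X
  A <- grmMatrix(computeGRM(simulateGenotypes(
    simConfig(nSubjects = n, nSnps = 100, seed = 51))))
  l1 <- restrictedLogLik(y, X, list(A), 0.5, 1)
  l2 <- restrictedLogLik(y + X %*% c(3, -2), X, list(A), 0.5, 1)
  expect_equal(l1, l2, tolerance = 1e-8)
})

test_that("restricted likelihood agrees with the eigen-rotation oracle for a
           diagonal covariance", {
  set.seed(52)
  n <- 30
  d <- runif(n, 0.2, 3)
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  s2g <- 0.8
  s2e <- 1.3
  # independent-observation oracle: each obs has variance s2g d_i + s2e
  v <- s2g * d + s2e
  xw <- sum(1 / v)
  bw <- sum(y / v) / xw
  oracle <- -0.5 * (sum(log(v)) + log(xw) + sum((y - bw)^2 / v))
  got <- restrictedLogLik(y, X, list(diag(d)), s2g, s2e)
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("AI-REML matches the brute-force likelihood-surface oracle on small
           instances", {
  set.seed(53)
  for (rep in 1:4) {
    n <- 50
    g <- simulateGenotypes(simConfig(nSubjects = n, nSnps = 150,
                                     seed = 530 + rep))
    A <- grmMatrix(computeGRM(g))
    sim <- polygenicResponse(g, h2 = 0.5)
    y <- sim$y
    X <- matrix(1, n, 1)
    fit <- fitGREML(y, X, A)
    oracle <- remlOracle(y, X, A)
    est <- c(fit@sigma2g, fit@sigma2e)
    floor <- 1e-6 * var(y)
    rel <- abs(est - oracle) / pmax(oracle, floor)
    expect_lt(max(rel), 1e-3)
    expect_equal(fit@logLik,
                 restrictedLogLik(y, X, list(A), fit@sigma2g, fit@sigma2e),
                 tolerance = 1e-8)
  }
})

test_that("null simulations give near-zero heritability estimates", {
  set.seed(54)
  h2s <- replicate(20, {
    g <- simulateGenotypes(simConfig(nSubjects = 300, nSnps = 500,
                                     seed = sample.int(1e6, 1)))
    A <- computeGRM(g)
    heritability(fitGREML(rnorm(300), grms = A))
  })
  expect_lt(mean(h2s), 0.05)
})

test_that("an identity GRM is reported as non-identifiable", {
  set.seed(55)
  y <- rnorm(60)
  fit <- fitGREML(y, grms = diag(60))
  expect_equal(fit@status, "non-identifiable")
  expect_false(fit@converged)
})

test_that("scale equivariance: variance components scale as c^2, h2 fixed", {
  set.seed(56)
  g <- simulateGenotypes(simConfig(nSubjects = 80, nSnps = 200, seed = 56))
  A <- computeGRM(g)
  y <- polygenicResponse(g, h2 = 0.4)$y
  f1 <- fitGREML(y, grms = A)
  f2 <- fitGREML(3 * y, grms = A)
  expect_equal(unname(f2@sigma2g / f1@sigma2g), 9, tolerance = 1e-4)
  expect_equal(f2@sigma2e / f1@sigma2e, 9, tolerance = 1e-4)
  expect_equal(f2@h2, f1@h2, tolerance = 1e-6)
})

test_that("misaligned inputs and id mismatches raise errors", {
  g <- simulateGenotypes(simConfig(nSubjects = 20, nSnps = 50, seed = 57))
  A <- computeGRM(g)
  expect_error(fitGREML(rnorm(10), grms = A), "misaligned")
  expect_error(fitGREML(rnorm(20), grms = A, ids = sprintf("X%d", 1:20)),
               "ids")
  expect_s4_class(fitGREML(rnorm(20), grms = A, ids = subjectIds(g)),
                  "GREMLFit")
})

test_that("mixture-null LRT p-values match chi-square tail oracles", {
  expect_equal(lrtPvalue(0, 0), 0.5)
  expect_equal(lrtPvalue(3.841 / 2, 0),
               0.5 * pchisq(3.841, 1, lower.tail = FALSE))
  expect_equal(round(lrtPvalue(3.841 / 2, 0), 3), 0.025)
  expect_equal(round(lrtPvalue(2.706 / 2, 0), 3), 0.05)
  expect_warning(p <- lrtPvalue(-1, 0), "clamped")
  expect_equal(p, 0.5)
})

test_that("joint chromosomal fit normalizes fractions and localizes signal", {
  set.seed(58)
  g <- simulateGenotypes(simConfig(nSubjects = 250, nSnps = 440,
                                   nChromosomes = 4, seed = 58))
  chr1 <- which(snpInfo(g)$chrom == 1)
  sim <- polygenicResponse(g, h2 = 0.6, snpSubset = chr1)
  grms <- partitionByChromosome(g)
  fit <- fitChromosomal(sim$y, NULL, grms)
  expect_equal(unname(sum(fit@h2Components) + fit@sigma2e /
                        (sum(fit@sigma2g) + fit@sigma2e)), 1,
               tolerance = 1e-8)
  expect_equal(unname(which.max(fit@h2Components)), 1L)

  # separate-fit mode returns one fit per chromosome
  fits <- fitChromosomal(sim$y, NULL, grms, joint = FALSE)
  expect_length(fits, 4)
  expect_s4_class(fits[[1]], "GREMLFit")
})

test_that("chromosome-length correlation behaves on closed-form cases", {
  sizes <- c(10, 20, 30, 40)
  res <- chromosomeLengthCorrelation(sizes / 100, sizes)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_error(chromosomeLengthCorrelation(rep(0.1, 4), sizes),
               "undefined")
  expect_error(chromosomeLengthCorrelation(c(0.1, 0.2), sizes), "one size")

  # permuting a monotone pairing shrinks |r| toward zero
  set.seed(59)
  h2c <- seq(0.01, 0.22, length.out = 22)
  r0 <- chromosomeLengthCorrelation(h2c, seq_len(22))$r
  perm <- replicate(100, {
    abs(chromosomeLengthCorrelation(sample(h2c), seq_len(22))$r)
  })
  expect_gt(mean(perm < r0), 0.95)
})
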