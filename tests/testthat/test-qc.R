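test_that("hweTest matches closed-form chi-square values and conventions", {
  # perfect HWE proportions at p = 0.5: statistic 0, p = 1
  expect_equal(hweTest(25, 50, 25), 1)
  # no heterozygotes at p = 0.5: expected 25/50/25, chi-square = 100
  expect_equal(hweTest(50, 0, 50),
               pchisq(100, df = 1, lower.tail = FALSE))
  # monomorphic convention
  expect_equal(hweTest(100, 0, 0), 1)
  expect_equal(hweTest(0, 0, 17), 1)
  expect_error(hweTest(0, 0, 0), "sum")
  expect_error(hweTest(-1, 2, 3), "non-negative")
})

test_that("exact HWE test is a valid, symmetric probability", {
  for (tr in list(c(25, 50, 25), c(10, 5, 3), c(3, 5, 10), c(9, 0, 9))) {
    p <- hweTest(tr[1], tr[2], tr[3], exact = TRUE)
    expect_gt(p, 0)
    expect_lte(p, 1)
    # swapping the homozygote classes swaps allele labels only
    expect_equal(p, hweTest(tr[3], tr[2], tr[1], exact = TRUE))
  }
  # probabilities over all heterozygote tables sum to one, so the most
  # extreme table's p equals its own point probability bound
  expect_lt(hweTest(10, 0, 10, exact = TRUE), 1e-5)
  expect_equal(hweTest(1, 2, 1, exact = TRUE), 1)
  # chi-square and exact agree decisively away from sparse tables
  expect_lt(hweTest(200, 0, 200), 1e-5)
  expect_lt(hweTest(200, 0, 200, exact = TRUE), 1e-5)
  expect_gt(hweTest(98, 204, 98), 0.05)
  expect_gt(hweTest(98, 204, 98, exact = TRUE), 0.05)
})

test_that("SNP filters enforce strict thresholds with HWE>MAF>call precedence", {
  set.seed(21)
  n <- 200
  good <- function() rbinom(n, 2, 0.3)
  dos <- cbind(
    good(),                         # clean
    rbinom(n, 2, 0.01),             # low MAF
    good(), good(),                 # clean
    good()                          # clean
  )
  g <- makeGeno(dos)
  res <- applySnpFilters(g)
  expect_equal(res$report$removed_maf, 1)
  expect_equal(res$report$removed_hwe, 0)
  expect_equal(res$report$removed_call_rate, 0)
  expect_equal(res$report$surviving_snps, 4)
  expect_equal(res$report$input_snps,
               res$report$surviving_snps + res$report$removed_hwe +
                 res$report$removed_maf + res$report$removed_call_rate)

  # all clean: report all zeros
  res2 <- applySnpFilters(makeGeno(cbind(good(), good())))
  expect_equal(res2$report$removed_maf + res2$report$removed_hwe +
                 res2$report$removed_call_rate, 0)

  # a SNP failing HWE *and* MAF *and* call rate counts once, under HWE
  hwe_bad <- c(rep(0L, 180), rep(2L, 9), rep(NA, 11))
  dos3 <- cbind(good(), hwe_bad)
  ss <- snpSummary(makeGeno(dos3))
  expect_lt(ss$hwe_p[2], 1e-5)
  expect_lt(ss$maf[2], 0.05)
  expect_lt(ss$call_rate[2], 0.95)
  res3 <- applySnpFilters(makeGeno(dos3))
  expect_equal(res3$report$removed_hwe, 1)
  expect_equal(res3$report$removed_maf, 0)
  expect_equal(res3$report$removed_call_rate, 0)
})

test_that("sample filter removes only subjects above the missingness bound", {
  set.seed(22)
  dos <- matrix(rbinom(6 * 100, 2, 0.4), nrow = 6)
  dos[1, 1:10] <- NA          # 10% missing: removed
  dos[2, 1:5] <- NA           # exactly 5%: retained (strict >)
  g <- makeGeno(dos)
  res <- applySampleFilters(g, missThr = 0.05)
  expect_equal(res$report$removed_missing, 1)
  expect_equal(res$report$surviving_samples, 5)
  expect_false("I1" %in% subjectIds(res$genotypes))
  expect_true("I2" %in% subjectIds(res$genotypes))

  # no missing data: nothing removed
  res2 <- applySampleFilters(makeGeno(matrix(rbinom(300, 2, 0.4), 3)))
  expect_equal(res2$report$removed_missing, 0)
})

test_that("filters are idempotent and conserve counts", {
  set.seed(23)
  dos <- matrix(rbinom(50 * 40, 2, runif(40, 0.02, 0.5)), nrow = 50,
                byrow = TRUE)
  dos[sample(length(dos), 80)] <- NA
  g <- makeGeno(dos)
  s1 <- applySampleFilters(g)
  f1 <- applySnpFilters(s1$genotypes)
  f2 <- applySnpFilters(f1$genotypes)
  expect_equal(f2$report$removed_hwe + f2$report$removed_maf +
                 f2$report$removed_call_rate, 0)
  expect_identical(dosages(f2$genotypes), dosages(f1$genotypes))
  expect_equal(f1$report$input_snps, 40)
  expect_equal(s1$report$input_samples,
               s1$report$surviving_samples + s1$report$removed_missing)
})

test_that("QC reports serialize to TSV and JSON", {
  rep <- list(input_snps = 10L, removed_maf = 2L, surviving_snps = 8L)
  pre <- file.path(tempdir(), "qcrep")
  writeQcReport(rep, pre)
  tsv <- read.delim(paste0(pre, ".tsv"))
  expect_equal(tsv$count[tsv$metric == "removed_maf"], 2)
  js <- jsonlite::read_json(paste0(pre, ".json"))
  expect_equal(js$surviving_snps, 8)
})
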