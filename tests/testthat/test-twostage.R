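makePheno <- function(subject, period, age, value, sex = 1, trait = "t") {
  data.frame(subject_id = as.character(subject), period = period, age = age,
             sex = sex, trait = trait, value = value,
             stringsAsFactors = FALSE)
}

test_that("trait transforms apply natural log exactly where flagged", {
  ph <- makePheno(c("a", "a", "b"), 1:3, 40:42, c(exp(2), 1, 0),
                  trait = "HDL")
  ph2 <- rbind(ph, makePheno("c", 1, 40, 7.25, trait = "height"))
  cfgs <- traitConfig(c("HDL", "height"), c("log", "identity"))
  expect_warning(out <- applyTraitTransforms(ph2, cfgs), "non-positive")
  expect_equal(out$value[1], 2)
  expect_equal(out$value[2], 0)        # log(1)
  expect_true(is.na(out$value[3]))     # zero under log flag -> missing
  expect_identical(out$value[4], 7.25) # identity untouched bitwise
  expect_error(traitConfig("x", "sqrt"), "transform")
})

test_that("sparse trait-periods are excluded under a strict 0.5 rule", {
  # 10 subjects; trait A misses 6/10 at period 2, trait B complete
  subj <- sprintf("s%d", 1:10)
  phA <- do.call(rbind, lapply(1:3, function(p) {
    makePheno(subj, p, 40 + p, rnorm(10), trait = "A")
  }))
  phA$value[phA$period == 2][1:6] <- NA
  phB <- do.call(rbind, lapply(1:3, function(p) {
    makePheno(subj, p, 40 + p, rnorm(10), trait = "B")
  }))
  res <- excludeSparseTraitPeriods(rbind(phA, phB))
  expect_equal(res$report$trait, "A")
  expect_equal(res$report$period, 2)
  expect_false(any(res$phenotypes$trait == "A" &
                     res$phenotypes$period == 2))
  expect_equal(sum(res$phenotypes$trait == "B"), 30)

  # exactly 50% missing is retained
  phC <- phA
  phC$value[phC$period == 2] <- c(rep(NA, 5), rnorm(5))
  resC <- excludeSparseTraitPeriods(phC)
  expect_equal(nrow(resC$report), 0)
  expect_equal(nrow(resC$phenotypes), nrow(phC))

  # fully observed data: nothing removed
  resB <- excludeSparseTraitPeriods(phB)
  expect_equal(nrow(resB$report), 0)
})

test_that("minimum-measurement rule keeps subjects per trait", {
  ph <- rbind(
    makePheno("a", c(1, 3, 5), c(40, 44, 48), rnorm(3)),
    makePheno("b", c(1, 2), c(50, 52), rnorm(2)),
    makePheno("c", 1:4, 60:63, c(rnorm(3), NA))
  )
  out <- filterMinMeasurements(ph, minObs = 3)
  expect_setequal(unique(out$subject_id), c("a", "c"))
  out1 <- filterMinMeasurements(ph, minObs = 1)
  expect_equal(nrow(out1), nrow(ph))
})

test_that("stage-1 weights recover known period noise and scale quadratically", {
  set.seed(41)
  n <- 500
  rows <- list()
  for (per in 1:3) {
    age <- runif(n, 40, 60)
    rows[[per]] <- makePheno(sprintf("s%d", 1:n), per, age,
                             3 * age + rnorm(n, sd = 2),
                             sex = rep(1:2, length.out = n))
  }
  ph <- do.call(rbind, rows)
  w <- estimatePeriodWeights(ph, NULL, "t")
  expect_equal(nrow(w), 3)
  expect_true(all(abs(w$w / 4 - 1) < 0.15))
  expect_equal(w$n, rep(n, 3))

  ph2 <- ph
  ph2$value <- 2 * ph2$value
  w2 <- estimatePeriodWeights(ph2, NULL, "t")
  expect_equal(w2$w, 4 * w$w, tolerance = 1e-10)

  # exactly linear trait -> degenerate-cell error
  phd <- ph
  phd$value <- 1 + 2 * phd$age + 0.5 * (phd$sex == 2)
  expect_error(estimatePeriodWeights(phd, NULL, "t"), "degenerate")
})

test_that("stage-1 regression adjusts for PC covariates per period", {
  set.seed(42)
  n <- 300
  pcs <- matrix(rnorm(n * 2), n, 2,
                dimnames = list(sprintf("s%d", 1:n), c("PC1", "PC2")))
  age <- runif(n, 40, 60)
  # trait driven by PC1; residual noise sd 1
  val <- 5 * pcs[, 1] + rnorm(n)
  ph <- makePheno(sprintf("s%d", 1:n), 1, age, val)
  w_adj <- estimatePeriodWeights(ph, pcs, "t")
  w_raw <- estimatePeriodWeights(ph, NULL, "t")
  expect_lt(w_adj$w, 2)      # PC effect removed
  expect_gt(w_raw$w, 20)     # PC effect left in the residual
})

test_that("subject trajectories match exact and weighted closed forms", {
  # perfect line: B0 = value at mean age, B1 = slope
  ph <- makePheno("a", 1:3, c(40, 42, 44), c(10, 12, 14))
  fit <- fitSubjectTrajectories(ph, NULL, "t")
  expect_equal(fit$B0, 12)
  expect_equal(fit$B1, 1)
  expect_equal(fit$mean_age, 42)
  expect_equal(fit$sigma2, 0)

  # adding a constant shifts B0 only
  ph2 <- ph
  ph2$value <- ph2$value + 7
  fit2 <- fitSubjectTrajectories(ph2, NULL, "t")
  expect_equal(fit2$B0, fit$B0 + 7)
  expect_equal(fit2$B1, fit$B1)

  # weighted normal-equations oracle, weights (1, 4, 1) on periods 1-3
  ph3 <- makePheno("a", 1:3, c(40, 42, 46), c(1, 5, 3))
  w <- data.frame(trait = "t", period = 1:3, w = c(1, 1 / 4, 1), n = 3)
  fit3 <- fitSubjectTrajectories(ph3, w, "t")  # inverse scheme -> (1,4,1)
  x <- ph3$age - mean(ph3$age)
  Wd <- diag(c(1, 4, 1))
  X <- cbind(1, x)
  beta <- solve(t(X) %*% Wd %*% X, t(X) %*% Wd %*% ph3$value)
  expect_equal(fit3$B0, beta[1], tolerance = 1e-12)
  expect_equal(fit3$B1, beta[2], tolerance = 1e-12)

  # literal scheme uses w itself
  fitL <- fitSubjectTrajectories(ph3, w, "t", weightScheme = "literal")
  WL <- diag(c(1, 1 / 4, 1))
  betaL <- solve(t(X) %*% WL %*% X, t(X) %*% WL %*% ph3$value)
  expect_equal(fitL$B1, betaL[2], tolerance = 1e-12)
})

test_that("equal weights reproduce OLS and time translation leaves B1 fixed", {
  set.seed(43)
  for (rep in 1:20) {
    nv <- sample(3:6, 1)
    age <- sort(40 + cumsum(runif(nv, 0.5, 3)))
    val <- rnorm(nv, 5, 2)
    ph <- makePheno("a", seq_len(nv), age, val)
    fit <- fitSubjectTrajectories(ph, NULL, "t")
    ols <- lm(val ~ I(age - mean(age)))
    expect_equal(fit$B0, unname(coef(ols)[1]), tolerance = 1e-10)
    expect_equal(fit$B1, unname(coef(ols)[2]), tolerance = 1e-10)

    phT <- ph
    phT$age <- phT$age + 13.5
    fitT <- fitSubjectTrajectories(phT, NULL, "t")
    expect_equal(fitT$B1, fit$B1, tolerance = 1e-10)
    expect_equal(fitT$B0, fit$B0, tolerance = 1e-10)
  }
})

test_that("degenerate subjects are dropped with a warning", {
  ph <- rbind(makePheno("a", 1:3, c(40, 40, 40), c(1, 2, 3)),
              makePheno("b", 1:3, c(40, 42, 44), c(1, 2, 3)))
  expect_warning(fit <- fitSubjectTrajectories(ph, NULL, "t"),
                 "distinct ages")
  expect_equal(fit$subject_id, "b")
})

test_that("true subject lines are recovered exactly without visit noise", {
  set.seed(44)
  n <- 50
  b0 <- rnorm(n)
  b1 <- rnorm(n, sd = 0.3)
  rows <- lapply(seq_len(n), function(i) {
    age <- 40 + i / 10 + c(0, 2, 4, 6)
    makePheno(sprintf("s%d", i), 1:4, age,
              b0[i] + b1[i] * (age - mean(age)))
  })
  fit <- fitSubjectTrajectories(do.call(rbind, rows), NULL, "t")
  ord <- match(sprintf("s%d", seq_len(n)), fit$subject_id)
  expect_lt(max(abs(fit$B0[ord] - b0)), 1e-8)
  expect_lt(max(abs(fit$B1[ord] - b1)), 1e-8)
})
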