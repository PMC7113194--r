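# Variance-component estimation on genetic relationship matrices.
#
# Model: y = X b + sum_c g_c + e,  Var(g_c) = A_c s2g[c],  Var(e) = I s2e.
# The restricted likelihood is maximized by average-information REML with
# one EM burn-in step, GCTA-style non-negativity clamping and step halving.

.asGrmMat <- function(g) {
  if (methods::is(g, "GRM")) grmMatrix(g) else as.matrix(g)
}

#' Restricted log-likelihood of a variance-component model
#'
#' Evaluates `-0.5 * (log|V| + log|X'V^-1 X| + y'Py)` with
#' `V = sum_c A_c sigma2g[c] + I sigma2e` and
#' `P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1`. The additive constant is
#' omitted consistently, so differences between models sharing `X` are
#' valid likelihood-ratio statistics.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (full column rank), including the
#'   intercept.
#' @param grms list of [GRM-class] objects or plain matrices (may be empty
#'   for a residual-only model).
#' @param sigma2g genetic variances, one per element of `grms`.
#' @param sigma2e residual variance (> 0).
#' @return Scalar restricted log-likelihood (constant omitted).
#' @export
restrictedLogLik <- function(y, X, grms, sigma2g, sigma2e) {
  X <- as.matrix(X)
  n <- length(y)
  if (length(grms) != length(sigma2g)) {
    stop("need one sigma2g per GRM")
  }
  V <- diag(sigma2e, n)
  for (i in seq_along(grms)) {
    V <- V + sigma2g[i] * .asGrmMat(grms[[i]])
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) stop("V is singular or not positive definite")
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  chX <- tryCatch(chol(XtVinvX), error = function(e) NULL)
  if (is.null(chX)) stop("X'V^-1X is singular; X must have full column rank")
  logdetX <- 2 * sum(log(diag(chX)))
  beta <- chol2inv(chX) %*% crossprod(VinvX, y)
  Py <- Vinv %*% y - VinvX %*% beta
  drop(-0.5 * (logdetV + logdetX + crossprod(y, Py)))
}

# one evaluation of everything AI-REML needs at the current components
.remlParts <- function(y, X, mats, s2, ridge = 0) {
  n <- length(y)
  V <- diag(s2[length(s2)] + ridge, n)
  for (i in seq_len(length(s2) - 1L)) V <- V + s2[i] * mats[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  chX <- tryCatch(chol(XtVinvX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  XtVinvXinv <- chol2inv(chX)
  P <- Vinv - VinvX %*% XtVinvXinv %*% t(VinvX)
  Py <- P %*% y
  logL <- drop(-0.5 * (logdetV + 2 * sum(log(diag(chX))) +
                         crossprod(y, Py)))
  list(P = P, Py = Py, logL = logL)
}

#' Fit a GREML variance-component model
#'
#' Average-information REML with one EM burn-in iteration. Components are
#' initialized at equal shares of the phenotypic variance; proposals that
#' go negative are clamped to `1e-6 *` phenotypic variance; steps that
#' decrease the restricted likelihood are halved. Convergence requires the
#' log-likelihood change below `tolLogLik` and the relative component
#' change below `tolComp`. The null model (all genetic components removed)
#' is refit analytically, and the likelihood-ratio test uses the 50:50
#' chi-square 0/1 mixture null via [lrtPvalue()]. Standard errors come
#' from the inverse average-information matrix; the heritability SE by the
#' delta method.
#'
#' A GRM equal (or numerically close) to the identity makes genetic and
#' residual variance indistinguishable; the fit then reports status
#' `"non-identifiable"` rather than an arbitrary interior estimate.
#'
#' @param y response vector (e.g. a trait's B0 or B1 across subjects).
#' @param X fixed-effect design matrix; default intercept only. Rows must
#'   align with `y` and the GRMs.
#' @param grms a single [GRM-class]/matrix or a list of them (one genetic
#'   variance component each).
#' @param ids optional subject ids for `y`; checked against GRM ids when
#'   both are available.
#' @param maxIter maximum AI iterations (default 100).
#' @param tolLogLik,tolComp convergence tolerances (1e-4 absolute logLik
#'   change, 1e-8 relative component change).
#' @param verbose print the component values and likelihood per iteration.
#' @return A [GREMLFit-class].
#' @examples
#' g <- simulateGenotypes(simConfig(nSubjects = 80, nSnps = 300, seed = 3))
#' A <- computeGRM(g)
#' y <- stats::rnorm(80)
#' fitGREML(y, grms = A)
#' @export
fitGREML <- function(y, X = NULL, grms, ids = NULL, maxIter = 100,
                     tolLogLik = 1e-4, tolComp = 1e-8, verbose = FALSE) {
  if (!is.list(grms)) grms <- list(grms)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X rows must match length(y)")
  mats <- lapply(grms, .asGrmMat)
  for (A in mats) {
    if (!all(dim(A) == n)) {
      stop("GRM dimensions misaligned with the response (", nrow(A),
           " vs ", n, " subjects)")
    }
  }
  if (!is.null(ids)) {
    for (g in grms) {
      if (methods::is(g, "GRM") && !identical(as.character(ids),
                                              subjectIds(g))) {
        stop("subject ids of the response do not match the GRM ids")
      }
    }
  }

  # guard against numerically non-PSD GRMs: ridge V if its chol fails
  ridge <- 0
  nc <- length(mats)
  vp <- stats::var(y)
  floorv <- 1e-6 * vp
  s2 <- rep(vp / (nc + 1), nc + 1)  # genetic components then residual

  parts <- .remlParts(y, X, mats, s2)
  if (is.null(parts)) {
    warning("V not positive definite at initialization; adding 1e-6 ridge")
    ridge <- 1e-6 * vp
    parts <- .remlParts(y, X, mats, s2, ridge)
    if (is.null(parts)) stop("V remains singular after ridging")
  }

  trPA <- function(P, A) sum(P * A)  # both symmetric
  status <- "failed"
  converged <- FALSE
  iter <- 0L
  AI <- NULL
  for (iter in seq_len(maxIter)) {
    P <- parts$P
    Py <- parts$Py
    APy <- vector("list", nc + 1L)
    for (c in seq_len(nc)) APy[[c]] <- mats[[c]] %*% Py
    APy[[nc + 1L]] <- Py
    quad <- vapply(APy, function(a) drop(crossprod(Py, a)), numeric(1))
    trs <- c(vapply(mats, function(A) trPA(P, A), numeric(1)), sum(diag(P)))

    if (iter == 1L) {
      # EM burn-in step, robust far from the optimum
      news2 <- s2 + s2^2 * (quad - trs) / n
    } else {
      score <- -0.5 * (trs - quad)
      PAPy <- lapply(APy, function(a) P %*% a)
      AI <- matrix(0, nc + 1L, nc + 1L)
      for (a in seq_len(nc + 1L)) {
        for (b in a:(nc + 1L)) {
          AI[a, b] <- 0.5 * drop(crossprod(APy[[a]], PAPy[[b]]))
          AI[b, a] <- AI[a, b]
        }
      }
      # Newton step in log-variance coordinates: multiplicative updates
      # cannot overshoot past zero and stay well conditioned when a
      # component is orders of magnitude smaller than the others.
      # Components hugging the non-negativity floor with a negative score
      # belong to the boundary: pin them there and solve the reduced
      # system, otherwise their diverging log-step drowns the free moves.
      pin <- s2 <= 100 * floorv & score < 0
      news2 <- s2
      news2[pin] <- floorv
      fr <- which(!pin)
      if (!length(fr)) {
        newparts <- .remlParts(y, X, mats, news2, ridge)
        if (is.null(newparts)) {
          status <- "failed"
          break
        }
        s2 <- news2
        parts <- newparts
        converged <- TRUE
        status <- "converged"
        break
      }
      scoreTh <- (s2 * score)[fr]
      AITh <- (outer(s2, s2) * AI)[fr, fr, drop = FALSE]
      dth <- tryCatch(solve(AITh, scoreTh), error = function(e) NULL)
      if (is.null(dth)) {
        status <- "non-identifiable"
        break
      }
      # limit the largest move to a factor e^3, rescaling the whole vector
      # so the step keeps the AI ascent direction (AI is positive
      # semi-definite; clipping single coordinates would not)
      mx <- max(abs(dth))
      if (mx > 3) dth <- dth * (3 / mx)
      news2[fr] <- s2[fr] * exp(dth)
    }
    news2[news2 < floorv] <- floorv

    newparts <- .remlParts(y, X, mats, news2, ridge)
    halvings <- 0L
    while ((is.null(newparts) || newparts$logL < parts$logL - 1e-10) &&
           halvings < 20L) {
      news2 <- sqrt(news2 * s2)  # halve the step in log space
      news2[news2 < floorv] <- floorv
      newparts <- .remlParts(y, X, mats, news2, ridge)
      halvings <- halvings + 1L
    }
    if (!is.null(newparts) && newparts$logL < parts$logL - 1e-10) {
      # damped Newton rejected; fall back to the monotone EM update
      news2 <- s2 + s2^2 * (quad - trs) / n
      news2[news2 < floorv] <- floorv
      emparts <- .remlParts(y, X, mats, news2, ridge)
      if (!is.null(emparts) && emparts$logL >= parts$logL - 1e-10) {
        newparts <- emparts
      } else {
        # no improving step found: either the optimum or a jam on the
        # feasibility boundary — let the simplex polish decide which
        status <- "stalled"
        break
      }
    }
    if (is.null(newparts)) {
      status <- "failed"
      break
    }
    if (verbose) {
      message(sprintf("iter %d: s2 = (%s), logL = %.6f, halvings = %d",
                      iter, paste(signif(news2, 4), collapse = ", "),
                      newparts$logL, halvings))
    }
    dl <- abs(newparts$logL - parts$logL)
    # components pinned at the non-negativity floor sit on the boundary;
    # their proposals keep oscillating below it, so judge convergence on
    # the free components only
    free <- news2 > floorv | s2 > floorv
    dc <- if (any(free)) {
      max(abs(news2[free] - s2[free]) / pmax(abs(s2[free]), floorv))
    } else 0
    s2 <- news2
    parts <- newparts
    # a heavily halved step is small because it was shrunk, not because
    # the optimum was reached; only a full step may declare convergence
    if (iter > 1L && dl < tolLogLik && dc < tolComp && halvings == 0L) {
      converged <- TRUE
      status <- "converged"
      break
    }
  }

  # Gradient on the log-variance scale at the final iterate; free (not
  # floored) components of a genuinely converged fit have this near zero
  scaledScore <- local({
    P <- parts$P
    Py <- parts$Py
    APy <- c(lapply(mats, function(A) A %*% Py), list(Py))
    quad <- vapply(APy, function(a) drop(crossprod(Py, a)), numeric(1))
    trsf <- c(vapply(mats, function(A) sum(P * A), numeric(1)),
              sum(diag(P)))
    sc <- s2 * (-0.5 * (trsf - quad))
    sc[s2 <= floorv] <- 0
    sc
  })

  # Fits whose optimum hugs the positive-definiteness boundary of V (an
  # indefinite GRM makes that boundary curved) can jam the AI line
  # search, or pass the step-size criterion because the average
  # information grossly overestimates the curvature along the boundary
  # ridge. Both leave a visibly nonzero gradient: polish such fits by
  # derivative-free maximization of the same restricted likelihood on the
  # floored log scale — the usual optimizer cascade for variance models.
  if ((status %in% c("failed", "stalled") ||
       max(abs(scaledScore)) > 1e-3) && nc <= 5L) {
    obj <- function(th) {
      s <- floorv + exp(th)
      val <- tryCatch(
        .remlParts(y, X, mats, s, ridge),
        error = function(e) NULL)
      if (is.null(val)) return(1e10)
      -val$logL
    }
    # simplex runs with restarts (single runs stall on ridges), from the
    # current iterate and — at small n, where these fits occur — from the
    # best point of a coarse grid, since a start on the feasibility
    # boundary leaves the initial simplex mostly infeasible
    starts <- list(log(pmax(s2 - floorv, floorv)))
    if (n <= 500L && nc <= 2L) {
      gr <- as.matrix(expand.grid(rep(list(c(0.05, 0.2, 0.5, 1, 1.5) * vp),
                                      nc + 1L)))
      gvals <- apply(gr, 1, function(s) obj(log(pmax(s - floorv, floorv))))
      starts <- c(starts,
                  list(log(pmax(gr[which.min(gvals), ] - floorv, floorv))))
    }
    opt <- NULL
    for (par in starts) {
      for (restart in 1:5) {
        nxt <- tryCatch(
          stats::optim(par, obj, method = "Nelder-Mead",
                       control = list(maxit = 3000, reltol = 1e-14)),
          error = function(e) NULL)
        if (is.null(nxt)) break
        improved <- is.null(opt) || nxt$value < opt$value - 1e-10
        if (is.null(opt) || nxt$value < opt$value) opt <- nxt
        par <- nxt$par
        if (!improved) break
      }
    }
    if (!is.null(opt) && is.finite(opt$value) && -opt$value > parts$logL) {
      cand <- floorv + exp(opt$par)
      candparts <- .remlParts(y, X, mats, cand, ridge)
      if (!is.null(candparts)) {
        s2 <- cand
        s2[s2 < floorv * (1 + 1e-6)] <- floorv
        parts <- candparts
        converged <- TRUE
        status <- "converged"
      }
    }
  }

  if (status == "stalled") {
    if (nc <= 5L) {
      # the simplex could not improve on the stall point: it is the
      # optimum within numerical resolution
      converged <- TRUE
      status <- "converged"
    } else {
      status <- "failed"
    }
  }

  s2g <- s2[seq_len(nc)]
  s2e <- s2[nc + 1L]
  tot <- sum(s2g) + s2e
  h2 <- sum(s2g) / tot
  h2c <- s2g / tot

  # SEs from the AI matrix at the final iterate (recompute if needed)
  seComp <- rep(NA_real_, nc + 1L)
  seH2 <- NA_real_
  aiOK <- FALSE
  P <- parts$P
  Py <- parts$Py
  APy <- c(lapply(mats, function(A) A %*% Py), list(Py))
  AI <- matrix(0, nc + 1L, nc + 1L)
  PAPy <- lapply(APy, function(a) P %*% a)
  for (a in seq_len(nc + 1L)) {
    for (b in a:(nc + 1L)) {
      AI[a, b] <- 0.5 * drop(crossprod(APy[[a]], PAPy[[b]]))
      AI[b, a] <- AI[a, b]
    }
  }
  covm <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(covm) && all(is.finite(covm))) {
    dg <- diag(covm)
    if (all(dg >= 0)) {
      seComp <- sqrt(dg)
      # delta method for h2 = sum(g)/(sum(g)+e)
      grad <- c(rep(s2e, nc), -sum(s2g)) / tot^2
      vh2 <- drop(t(grad) %*% covm %*% grad)
      if (is.finite(vh2) && vh2 >= 0) seH2 <- sqrt(vh2)
      aiOK <- TRUE
    }
  }
  if (!aiOK && status == "converged") status <- "non-identifiable"

  # analytic null: V = I s2e, REML variance = RSS / (n - p)
  qrX <- qr(X)
  res0 <- qr.resid(qrX, y)
  s2e0 <- sum(res0^2) / (n - qrX$rank)
  logL0 <- restrictedLogLik(y, X, list(), numeric(0), s2e0)

  lrt <- 2 * (parts$logL - logL0)
  if (lrt < 0) {
    # a boundary fit (sigma2g at the floor) sits a hair below the analytic
    # null optimum; only a substantive deficit merits a warning
    if (lrt < -1e-3) {
      warning("full-model likelihood below the null; LRT clamped to 0")
    }
    lrt <- 0
  }
  p <- suppressWarnings(lrtPvalue(parts$logL, logL0))

  methods::new("GREMLFit",
    sigma2g = stats::setNames(s2g, names(grms) %||%
                                paste0("g", seq_len(nc))),
    sigma2e = s2e, h2 = h2, h2Components = h2c,
    se = list(components = seComp, h2 = seH2),
    logLik = parts$logL, logLikNull = logL0, lrt = lrt, pvalue = p,
    converged = converged, status = status,
    iterations = iter, n = as.integer(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Likelihood-ratio p-value under the boundary mixture null
#'
#' Testing a variance component against zero places the null on the
#' boundary of the parameter space, so the LRT statistic follows a 50:50
#' mixture of a point mass at zero and chi-square with 1 df. The p-value
#' is `0.5 * P(chi2_1 > LRT)` for positive statistics and 0.5 when the
#' statistic is zero.
#'
#' @param logLikFull,logLikNull restricted log-likelihoods (same fixed
#'   effects, constants omitted consistently).
#' @return p-value.
#' @examples
#' lrtPvalue(0, 0)                 # 0.5
#' round(lrtPvalue(3.841 / 2, 0), 3)  # 0.025
#' @export
lrtPvalue <- function(logLikFull, logLikNull) {
  lrt <- 2 * (logLikFull - logLikNull)
  if (lrt < 0) {
    if (lrt < -1e-6) warning("logLikFull < logLikNull; LRT clamped to 0")
    lrt <- 0
  }
  0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
}

#' Chromosome-partitioned GREML
#'
#' Heritability attributed to each chromosome. By default all chromosome
#' GRMs enter one joint REML fit (22 genetic components plus residual);
#' `joint = FALSE` instead fits each chromosome separately against the
#' residual.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (default intercept).
#' @param grms named list of per-chromosome [GRM-class] objects, e.g. from
#'   [partitionByChromosome()].
#' @param joint single joint fit (default) or per-chromosome fits.
#' @param ... passed to [fitGREML()].
#' @return For `joint = TRUE`, a [GREMLFit-class] whose `h2Components` are
#'   the per-chromosome variance fractions. For `joint = FALSE`, a named
#'   list of single-component fits.
#' @export
fitChromosomal <- function(y, X = NULL, grms, joint = TRUE, ...) {
  if (joint) {
    fitGREML(y, X, grms, ...)
  } else {
    lapply(grms, function(g) fitGREML(y, X, g, ...))
  }
}

#' Correlation of per-chromosome heritability with chromosome length
#'
#' Pearson correlation between the per-chromosome variance fractions of a
#' joint chromosomal fit and a chromosome-size measure (SNP count or
#' physical length), with the two-sided t-test p-value.
#'
#' @param fit a joint [GREMLFit-class] from [fitChromosomal()], or a
#'   numeric vector of per-chromosome heritabilities.
#' @param chromSizes chromosome sizes in the same order.
#' @return list(r, p, n).
#' @export
chromosomeLengthCorrelation <- function(fit, chromSizes) {
  h2c <- if (methods::is(fit, "GREMLFit")) fit@h2Components else
    as.numeric(fit)
  if (length(h2c) != length(chromSizes)) {
    stop("need one size per chromosome component")
  }
  if (stats::sd(h2c) == 0 || stats::sd(chromSizes) == 0) {
    stop("correlation undefined: zero variance in heritabilities or sizes")
  }
  ct <- stats::cor.test(h2c, chromSizes)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(h2c))
}
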