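# Shared fixture builders and independent oracles.

# Build a GenotypeData straight from a dosage matrix (subjects x SNPs).
makeGeno <- function(dos, chrom = NULL, a1 = "A", a2 = "G", sex = NULL) {
  dos <- as.matrix(dos)
  storage.mode(dos) <- "integer"
  n <- nrow(dos)
  m <- ncol(dos)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(sex)) sex <- rep(1L, n)
  snps <- data.frame(id = sprintf("s%d", seq_len(m)),
                     chrom = as.integer(chrom),
                     pos = as.integer(seq_len(m)),
                     a1 = rep_len(a1, m), a2 = rep_len(a2, m),
                     stringsAsFactors = FALSE)
  samples <- data.frame(fid = sprintf("F%d", seq_len(n)),
                        iid = sprintf("I%d", seq_len(n)),
                        sex = as.integer(sex), stringsAsFactors = FALSE)
  rownames(dos) <- samples$iid
  colnames(dos) <- snps$id
  new("GenotypeData", dosages = dos, snps = snps, samples = samples)
}

# Brute-force REML oracle for one GRM: coarse grid over the variance
# components, then Nelder-Mead on a floor + exp(theta) parametrization so
# the non-negativity floor matches the fitted model's constraint.
remlOracle <- function(y, X, A, floor = 1e-6 * stats::var(y)) {
  vp <- stats::var(y)
  obj <- function(s) {
    tryCatch(restrictedLogLik(y, X, list(A), s[1], s[2]),
             error = function(e) -Inf)
  }
  grid <- expand.grid(g = seq(0.02, 2, length.out = 15) * vp,
                      e = seq(0.02, 2, length.out = 15) * vp)
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.max(vals), ])
  fn <- function(th) -obj(floor + exp(th))
  par <- log(pmax(best - floor, floor))
  opt <- NULL
  for (restart in 1:5) {  # simplex restarts: single runs stall on ridges
    nxt <- stats::optim(par, fn, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    improved <- is.null(opt) || nxt$value < opt$value - 1e-10
    opt <- nxt
    par <- nxt$par
    if (!improved) break
  }
  floor + exp(opt$par)
}

# Polygenic response on a genotype panel with exact in-sample genetic
# variance h2 (the generator's effect-scaling convention).
polygenicResponse <- function(geno, h2, snpSubset = NULL) {
  X <- dosages(geno)
  if (!is.null(snpSubset)) X <- X[, snpSubset, drop = FALSE]
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  W <- scale(X[, keep, drop = FALSE], center = 2 * p[keep],
             scale = sqrt(2 * p[keep] * (1 - p[keep])))
  g <- drop(W %*% stats::rnorm(ncol(W)))
  g <- g * sqrt(h2 / stats::var(g))
  e <- stats::rnorm(nrow(X), sd = sqrt(1 - h2))
  list(y = g + e, g = g)
}
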