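# shared fixtures and independent oracles

# small valid correlation matrix built from random time series
randomConnectivity <- function(p, t = 4 * p, seed = 1) {
  set.seed(seed)
  ts <- matrix(rnorm(t * p), t, p)
  gradientScope::correlateTimeSeries(ts)
}

# hand-built GradientSet with given score columns (orthogonalized)
toyGradients <- function(scores, aligned = TRUE) {
  scores <- as.matrix(scores)
  ev <- rep(1 / ncol(scores), ncol(scores))
  gradientScope::gradientSet(scores, ev, aligned = aligned)
}

toyPartition <- function(networks) {
  gradientScope::networkPartition(paste0("p", seq_along(networks)), networks)
}

# brute-force PCA oracle: eigendecomposition of the centred covariance
eigenPcaOracle <- function(a, nGradients) {
  xc <- sweep(a, 2, colMeans(a))
  cv <- crossprod(xc) / (nrow(a) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  scores <- xc %*% eg$vectors[, seq_len(nGradients), drop = FALSE]
  list(scores = scores,
       explained = eg$values[seq_len(nGradients)] / sum(pmax(eg$values, 0)))
}

# column-wise agreement up to sign
expect_equal_up_to_sign <- function(x, y, tol = 1e-8) {
  for (j in seq_len(ncol(x))) {
    d <- min(max(abs(x[, j] - y[, j])), max(abs(x[, j] + y[, j])))
    expect_lt(d, tol)
  }
}

# exact permutation p-value oracle for Spearman (two-sided, small n)
permutationSpearmanP <- function(x, y) {
  n <- length(x)
  perms <- asplit(gtoolsPermutations(n), 1)
  obs <- abs(cor(rank(x), rank(y)))
  stats <- vapply(perms, function(p) abs(cor(rank(x), rank(y[p]))), numeric(1))
  mean(stats >= obs - 1e-12)
}

# all permutations of 1..n (tiny n only)
gtoolsPermutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtoolsPermutations(n - 1)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  unname(out)
}

# dense-grid Gaussian KDE argmax oracle (Silverman bandwidth)
kdePeakOracle <- function(x, gridN = 10001) {
  h <- stats::bw.nrd0(x)
  grid <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = gridN)
  dens <- vapply(grid, function(g) mean(dnorm((g - x) / h)) / h, numeric(1))
  grid[which.max(dens)]
}

# small cohort spec used across tests (fast but non-trivial)
testCohortSpec <- function(n = 40L, p = 60L, seed = 101L, ...) {
  gradientScope::cohortSpec(nSubjects = n, nParcels = p, seed = seed, ...)
}
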