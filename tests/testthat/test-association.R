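test_that("spearman hits the bounds for monotone pairs", {
  up <- spearmanAssociation(1:10, (1:10)^3)
  expect_equal(up$rho, 1)
  expect_equal(up$p, 0)
  down <- spearmanAssociation(1:10, 10:1)
  expect_equal(down$rho, -1)
  expect_error(spearmanAssociation(1:5, rep(2, 5)), "constant")
  expect_error(spearmanAssociation(1:3, 3:1), "at least 4")
})

test_that("spearman matches the rank formula and exact permutation p", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  res <- spearmanAssociation(x, y)
  # brute-force rank formula: 1 - 6*sum(d^2)/(n(n^2-1)), d = (−1,1,−1,1,0)
  d <- rank(x) - rank(y)
  expect_equal(res$rho, 1 - 6 * sum(d^2) / (5 * 24), tolerance = 1e-12)
  expect_equal(res$rho, 0.8)
  # exact two-sided permutation oracle over all 120 permutations
  pExact <- permutationSpearmanP(x, y)
  expect_equal(pExact, 16 / 120)  # frozen from the enumeration oracle
  # the t approximation should be of the same order as the exact p
  expect_lt(abs(res$p - pExact), 0.08)
})

test_that("spearman agrees with cor.test and handles ties", {
  set.seed(10)
  for (rep in 1:5) {
    x <- sample(1:8, 30, replace = TRUE)  # heavy ties
    y <- x + rnorm(30, sd = 2)
    res <- spearmanAssociation(x, y)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-12)
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(12)
  x <- rnorm(40); y <- rnorm(40)
  base <- spearmanAssociation(x, y)
  expect_equal(spearmanAssociation(exp(x), y)$rho, base$rho)
  expect_equal(spearmanAssociation(x, y^3 + 5 * y)$rho, base$rho)
  expect_equal(spearmanAssociation(rank(x), y)$rho, base$rho)
})

test_that("covariate model recovers exact linear dependence", {
  n <- 50
  gsq <- rnorm(n, 50, 18)
  covs <- data.frame(aq = rep(0, n) + rnorm(n, sd = 1e-8), gsq = gsq,
                     age = rnorm(n, 21), gender = rbinom(n, 1, 0.3),
                     fd = abs(rnorm(n, 0.03, 0.01)), dvars = rnorm(n, 1))
  # exact fit: lm warns that the summary may be unreliable, which is the point
  fit <- suppressWarnings(fitCovariateModel(2 * gsq, covs))
  expect_equal(fit$beta[fit$term == "gsq"], 2, tolerance = 1e-6)
  expect_lt(fit$p[fit$term == "gsq"], 1e-12)
})

test_that("covariate model equals the normal-equations oracle", {
  set.seed(14)
  n <- 60
  covs <- data.frame(aq = rnorm(n), gsq = rnorm(n), age = rnorm(n),
                     gender = rbinom(n, 1, 0.5), fd = rnorm(n),
                     dvars = rnorm(n))
  y <- rnorm(n)
  fit <- fitCovariateModel(y, covs)
  X <- cbind(1, as.matrix(covs))
  betaOracle <- solve(crossprod(X), crossprod(X, y))
  expect_equal(fit$beta, as.numeric(betaOracle), tolerance = 1e-10)
  # residuals orthogonal to every design column
  expect_lt(max(abs(crossprod(X, attr(fit, "residuals")))), 1e-8)
})

test_that("collinear designs are rejected with the column named", {
  n <- 30
  covs <- data.frame(a = rnorm(n))
  covs$b <- 2 * covs$a
  expect_error(fitCovariateModel(rnorm(n), covs), "collinear.*b")
})

test_that("null-trait rejection rates converge to alpha", {
  set.seed(15)
  reps <- 400
  pSpear <- numeric(reps)
  for (r in seq_len(reps)) {
    y <- rnorm(60)
    trait <- rnorm(60)
    pSpear[r] <- spearmanAssociation(y, trait)$p
  }
  expect_lt(abs(mean(pSpear < 0.05) - 0.05), 0.025)
})

test_that("OLS type-I error for a null GSQ effect is near nominal", {
  set.seed(16)
  reps <- 300
  hits <- 0
  for (r in seq_len(reps)) {
    n <- 80
    covs <- data.frame(aq = rnorm(n), gsq = rnorm(n), age = rnorm(n),
                       gender = rbinom(n, 1, 0.5), fd = rnorm(n),
                       dvars = rnorm(n))
    fit <- fitCovariateModel(rnorm(n), covs)
    hits <- hits + (fit$p[fit$term == "gsq"] < 0.05)
  }
  expect_lt(abs(hits / reps - 0.05), 0.03)
})

test_that("bonferroni threshold arithmetic and display", {
  expect_equal(bonferroniThreshold(0.05, 1)$threshold, 0.05)
  b <- bonferroniThreshold(0.05, 42)
  expect_equal(b$threshold, 0.05 / 42, tolerance = 1e-15)
  expect_equal(b$displayed, 0.0012)
  # inverse identity
  for (n in c(2, 7, 21, 42)) {
    expect_equal(bonferroniThreshold(0.05, n)$threshold * n, 0.05,
                 tolerance = 1e-15)
  }
})

test_that("median split sends ties to the low group and conserves n", {
  s <- medianSplit(c(1, 2, 3, 4))
  expect_equal(s$threshold, 2.5)
  expect_equal(s$low_idx, c(1L, 2L))
  expect_equal(s$high_idx, c(3L, 4L))
  tied <- medianSplit(c(1, 5, 5, 5, 9, 10))
  expect_equal(tied$threshold, 5)
  expect_true(all(c(2, 3, 4) %in% tied$low_idx))  # ties at the median -> low
  set.seed(17)
  for (rep in 1:5) {
    v <- sample(0:50, 37, replace = TRUE)
    s <- medianSplit(v)
    expect_equal(length(s$low_idx) + length(s$high_idx), 37L)
  }
})

test_that("association grid has 21 pairs x 2 traits per pairwise family", {
  spec <- testCohortSpec(n = 12L, p = 60L)
  cohort <- simulateCohort(spec)
  cfg <- runConfig(nGradients = 5L)
  ref <- computeGradients(groupAverage(cohort$matrices), cfg)
  grads <- lapply(cohort$matrices, computeGradients, config = cfg,
                  reference = ref)
  rep <- segregationReport(grads, cohort$partition, cfg)
  grid <- runAssociationGrid(rep, cohort$participants)
  md <- grid[grid$metric == "median_distance", ]
  expect_equal(nrow(md), 42L)                       # 21 pairs x 2 traits
  expect_equal(length(unique(paste(md$network_a, md$network_b))), 21L)
  # two identical traits give identical grid halves
  tr2 <- cohort$participants
  tr2$aq_total <- tr2$gsq_total
  g2 <- runAssociationGrid(rep, tr2)
  expect_equal(g2$rho[g2$trait == "aq_total"],
               g2$rho[g2$trait == "gsq_total"])
  # bonferroni flags never pass cells above the corrected threshold
  expect_true(all(grid$p[grid$bonferroni] < 0.05 / 42))
  expect_error(runAssociationGrid(rep, cohort$participants["subject_id"]),
               "missing trait")
})

test_that("grid table reshapes to the lower-triangular layout", {
  spec <- testCohortSpec(n = 8L, p = 60L)
  cohort <- simulateCohort(spec)
  cfg <- runConfig(nGradients = 5L)
  ref <- computeGradients(groupAverage(cohort$matrices), cfg)
  grads <- lapply(cohort$matrices, computeGradients, config = cfg,
                  reference = ref)
  grid <- runAssociationGrid(segregationReport(grads, cohort$partition, cfg),
                             cohort$participants)
  nets <- networkNames(cohort$partition)
  tabl <- gridTable(grid, "median_distance", "gsq_total", nets)
  expect_equal(dim(tabl), c(6L, 6L))
  expect_true(all(tabl[upper.tri(tabl)] == ""))
  expect_true(all(tabl[lower.tri(tabl, diag = TRUE)] != ""))
})
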