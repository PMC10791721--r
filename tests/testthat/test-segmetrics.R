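test_that("network median distance matches hand-computed medians", {
  g <- toyGradients(cbind(c(1, 2, 3, -3, -2, -1)))
  part <- toyPartition(rep(c("A", "B"), each = 3))
  expect_equal(networkMedianDistance(g, part, "A", "B"), 4)  # |2 - (-2)|
  expect_equal(networkMedianDistance(g, part, "A", "B", signed = TRUE), 4)
  expect_equal(networkMedianDistance(g, part, "B", "A", signed = TRUE), -4)
  expect_error(networkMedianDistance(g, part, "A", "A"), "differ")
  expect_error(networkMedianDistance(g, part, "A", "Z"), "unknown")
})

test_that("identical score multisets give zero median distance", {
  g <- toyGradients(cbind(c(0.4, -1, 2, 2, -1, 0.4)))
  part <- toyPartition(rep(c("A", "B"), each = 3))
  expect_equal(networkMedianDistance(g, part, "A", "B"), 0)
})

test_that("median distance equals a brute-force sort oracle on random draws", {
  set.seed(21)
  part <- toyPartition(rep(c("A", "B"), each = 500))
  sortMedian <- function(x) {  # oracle: median via explicit sort
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  for (rep in 1:5) {
    x <- rnorm(1000)
    g <- toyGradients(cbind(x))
    expect_equal(networkMedianDistance(g, part, "A", "B"),
                 abs(sortMedian(x[1:500]) - sortMedian(x[501:1000])),
                 tolerance = 1e-12)
  }
})

test_that("gradient range and sd: hand values, zeros and homogeneity", {
  expect_equal(gradientRange(toyGradients(cbind(c(-1, 1, 0)))), 2)
  const <- toyGradients(cbind(rep(0.3, 5)))
  expect_equal(gradientRange(const), 0)
  expect_equal(gradientSD(const), 0)
  x <- rnorm(30)
  g <- toyGradients(cbind(x)); gc <- toyGradients(cbind(-2.5 * x))
  expect_equal(gradientRange(gc), 2.5 * gradientRange(g), tolerance = 1e-12)
  expect_equal(gradientSD(gc), 2.5 * gradientSD(g), tolerance = 1e-12)
  # sample (n-1) convention
  expect_equal(gradientSD(g), sd(x))
})

test_that("peak distance recovers well-separated cluster positions", {
  set.seed(31)
  a <- rnorm(60, -1, 0.03)
  b <- rnorm(60, 1, 0.03)
  g <- toyGradients(cbind(c(a, b)))
  part <- toyPartition(rep(c("A", "B"), each = 60))
  expect_equal(networkPeakDistance(g, part, "A", "B"), 2, tolerance = 0.05)
  # identical distributions -> 0
  g2 <- toyGradients(cbind(c(a, a)))
  expect_equal(networkPeakDistance(g2, part, "A", "B"), 0)
})

test_that("peak distance uses the dominant mode, matching a dense-grid oracle", {
  set.seed(32)
  # bimodal network: dominant mode near 0.8, minor near -0.6
  bimodal <- c(rnorm(80, 0.8, 0.05), rnorm(30, -0.6, 0.05))
  unimodal <- rnorm(90, -0.5, 0.05)
  g <- toyGradients(cbind(c(bimodal, unimodal)))
  part <- toyPartition(rep(c("A", "B"), times = c(110, 90)))
  d <- networkPeakDistance(g, part, "A", "B")
  expect_equal(d, 1.3, tolerance = 0.05)
  oracle <- abs(kdePeakOracle(bimodal) - kdePeakOracle(unimodal))
  expect_equal(d, oracle, tolerance = 0.01)
})

test_that("peak distance needs at least five parcels per network", {
  g <- toyGradients(cbind(rnorm(8)))
  part <- toyPartition(rep(c("A", "B"), times = c(4, 4)))
  expect_error(networkPeakDistance(g, part, "A", "B"), "fewer than 5")
})

test_that("eccentricity matches Pythagorean hand cases", {
  sc <- rbind(c(0, 0, 0), c(3, 4, 0), c(1, 0, 0), c(-1, 0, 0))
  g <- toyGradients(sc)
  part <- toyPartition(c("origin", "far", "pair", "pair"))
  expect_equal(eccentricity(g, part, "origin"), 0)
  expect_equal(eccentricity(g, part, "far"), 5)
  expect_equal(eccentricity(g, part, "pair"), 1)   # mean of norms 1 and 1
  expect_equal(eccentricity(g, part, "pair", aggregate = "sumsq"), 2)
  expect_equal(eccentricity(g), mean(c(0, 5, 1, 1)))  # global
  expect_error(eccentricity(g, part, "far", dims = 4), "dims")
})

test_that("within dispersion: hand cases and translation invariance", {
  sc <- rbind(c(1, 0, 0), c(-1, 0, 0), c(9, 9, 9))
  g <- toyGradients(sc)
  part <- toyPartition(c("A", "A", "B"))
  expect_equal(withinDispersion(g, part, "A"), 2)  # centroid at origin
  expect_equal(withinDispersion(g, part, "B"), 0)  # single-parcel network
  shift <- sweep(sc, 2, c(5, -7, 2), `+`)
  expect_equal(withinDispersion(toyGradients(shift), part, "A"), 2)
})

test_that("between dispersion: Pythagoras, symmetry zero, dims=1 identity", {
  sc <- rbind(c(0, 0, 0), c(0, 0, 0), c(3, 4, 0), c(3, 4, 0))
  g <- toyGradients(sc)
  part <- toyPartition(rep(c("A", "B"), each = 2))
  expect_equal(betweenDispersion(g, part, "A", "B"), 5)
  gg <- toyGradients(rbind(c(1, 2, 0), c(0, 1, 1), c(1, 2, 0), c(0, 1, 1)))
  expect_equal(betweenDispersion(gg, part, "A", "B"), 0)
  # exact definitional reduction at dims = 1
  set.seed(41)
  g3 <- toyGradients(matrix(rnorm(120), 40, 3))
  p3 <- toyPartition(sample(rep(c("X", "Y"), each = 20)))
  expect_identical(betweenDispersion(g3, p3, "X", "Y", dims = 1L),
                   networkMedianDistance(g3, p3, "X", "Y"))
})

test_that("all metrics are invariant to parcel relabeling within networks", {
  set.seed(43)
  g <- toyGradients(matrix(rnorm(90), 30, 3))
  nets <- rep(c("A", "B", "C"), each = 10)
  part <- toyPartition(nets)
  # permute parcels within each network
  perm <- unlist(lapply(split(seq_along(nets), nets), sample), use.names = FALSE)
  g2 <- toyGradients(gradientScores(g)[perm, ])
  part2 <- toyPartition(nets[perm])
  for (f in list(
    function(g, p) networkMedianDistance(g, p, "A", "B"),
    function(g, p) networkPeakDistance(g, p, "A", "C"),
    function(g, p) eccentricity(g, p, "B"),
    function(g, p) withinDispersion(g, p, "C"),
    function(g, p) betweenDispersion(g, p, "B", "C"),
    function(g, p) gradientRange(g))) {
    expect_equal(f(g2, part2), f(g, part), tolerance = 1e-12)
  }
})

test_that("binning conserves parcels and averages preserve totals", {
  # uniform scores on [0,1): exactly 10 per bin with 50 equal bins
  # (bin-centre offsets avoid float coincidence with the bin edges)
  g <- toyGradients(cbind((0:499 + 0.5) / 500))
  b <- binGradient(g, edges = seq(0, 1, length.out = 51))
  expect_length(b$counts, 50L)
  expect_true(all(b$counts == 10L))
  expect_equal(sum(b$counts), 500)
  # averaging identical distributions is idempotent
  avg <- averageBins(list(b, b, b))
  expect_equal(avg$counts, b$counts)
  # conservation at 400 parcels with stratification
  spec <- cohortSpec(nSubjects = 2L, nParcels = 400L, seed = 5L)
  part <- specPartition(spec)
  gg <- computeGradients(simulateConnectome(0.3, spec, seed = 2))
  bb <- binGradient(gg, nBins = 50L, partition = part)
  expect_equal(sum(bb$counts), 400)
  expect_equal(unname(rowSums(bb$network_counts)),
               unname(as.integer(spec@partitionSizes)))
  # edge mismatch on averaging is an error
  b2 <- binGradient(g, edges = seq(-0.5, 1.5, length.out = 51))
  expect_error(averageBins(list(b, b2)), "edges differ")
})

test_that("median distance never exceeds the gradient range", {
  spec <- testCohortSpec(n = 6L, p = 60L)
  cohort <- simulateCohort(spec)
  cfg <- runConfig(nGradients = 5L)
  ref <- computeGradients(groupAverage(cohort$matrices), cfg)
  for (m in cohort$matrices) {
    g <- computeGradients(m, cfg, reference = ref)
    expect_lte(networkMedianDistance(g, cohort$partition, "visual", "default"),
               gradientRange(g))
  }
})

test_that("median distance and 3D dispersion agree when axes 2-3 are small", {
  base <- cbind(c(-1, -0.5, -0.25, 0, 0.3, 0.6, 1),
                c(0.03, -0.03, 0.01, -0.01, 0.005, 0.01, -0.005),
                c(0.005, -0.025, 0.005, 0.025, -0.005, 0.005, -0.01))
  spec <- cohortSpec(nSubjects = 50L, nParcels = 70L, seed = 77L,
                     basePositions = base, sigmaParcel = 0.25)
  cohort <- simulateCohort(spec)
  cfg <- runConfig(nGradients = 5L)
  ref <- computeGradients(groupAverage(cohort$matrices), cfg)
  md <- bd <- numeric(length(cohort$matrices))
  for (i in seq_along(cohort$matrices)) {
    g <- computeGradients(cohort$matrices[[i]], cfg, reference = ref)
    md[i] <- networkMedianDistance(g, cohort$partition, "visual", "default")
    bd[i] <- betweenDispersion(g, cohort$partition, "visual", "default")
  }
  expect_gt(cor(md, bd, method = "spearman"), 0.9)
})

test_that("segregation report covers all pairs, networks and globals", {
  spec <- testCohortSpec(n = 3L, p = 60L)
  cohort <- simulateCohort(spec)
  cfg <- runConfig(nGradients = 5L)
  ref <- computeGradients(groupAverage(cohort$matrices), cfg)
  grads <- lapply(cohort$matrices, computeGradients, config = cfg,
                  reference = ref)
  rep <- segregationReport(grads, cohort$partition, cfg)
  tab <- metricsTable(rep)
  expect_equal(sum(tab$metric == "median_distance"), 3 * choose(7, 2))
  expect_equal(sum(tab$metric == "between_dispersion"), 3 * 21)
  expect_equal(sum(tab$metric == "eccentricity"), 3 * 7)
  expect_equal(sum(tab$metric == "global_eccentricity"), 3)
  expect_true(all(tab$value[tab$metric %in%
    c("median_distance", "between_dispersion", "peak_distance",
      "eccentricity", "within_dispersion")] >= 0))
})
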