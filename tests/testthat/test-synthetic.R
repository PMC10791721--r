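test_that("trait simulation is deterministic and respects degenerate limits", {
  spec <- testCohortSpec(n = 20L)
  t1 <- simulateTraits(spec)
  t2 <- simulateTraits(spec)
  expect_identical(t1$participants, t2$participants)
  expect_identical(t1$gsq_items, t2$gsq_items)
  # zero trait variance puts every subject at the mean
  spec0 <- cohortSpec(nSubjects = 15L, nParcels = 40L, gsqSD = 0, aqSD = 0,
                      seed = 3L)
  t0 <- simulateTraits(spec0)$participants
  expect_true(all(t0$gsq_total == 50))   # round(50.1)
  expect_true(all(t0$aq_total == 20))    # round(19.6)
})

test_that("trait moments match their targets at large n", {
  spec <- cohortSpec(nSubjects = 10000L, nParcels = 40L, seed = 5L)
  p <- simulateTraits(spec)$participants
  expect_lt(abs(mean(p$gsq_total) - 50.1) / 50.1, 0.02)
  expect_lt(abs(sd(p$gsq_total) - 18.2) / 18.2, 0.02)
  expect_lt(abs(mean(p$aq_total) - 19.6) / 19.6, 0.02)
  expect_lt(abs(sd(p$aq_total) - 5.3) / 5.3, 0.02)
  expect_true(all(p$gsq_total >= 0 & p$gsq_total <= 168))
  expect_true(all(p$aq_total >= 0 & p$aq_total <= 50))
  # planted copulas: trait-expansion Spearman near targets
  expect_lt(abs(cor(p$gsq_total, p$expansion, method = "spearman") - 0.4),
            0.03)
  expect_lt(abs(cor(p$aq_total, p$expansion, method = "spearman")), 0.03)
  expect_lt(abs(cor(p$aq_total, p$gsq_total) - 0.3), 0.05)
})

test_that("generated items always reconstruct totals and the GSQ layout", {
  spec <- testCohortSpec(n = 30L)
  tr <- simulateTraits(spec)
  p <- tr$participants
  expect_equal(p$gsq_hyper + p$gsq_hypo, p$gsq_total)
  mods <- paste0("gsq_", unique(gsqItemTable()$modality))
  expect_equal(unname(rowSums(as.matrix(p[, mods]))), p$gsq_total)
  expect_equal(p$gsq_no_vision, p$gsq_total - p$gsq_vision)
  expect_identical(unname(scoreAQ(tr$aq_items, tr$aq_key)), p$aq_total)
  expect_true(all(tr$gsq_items >= 0 & tr$gsq_items <= 4))
  expect_true(all(tr$aq_items %in% 1:4))
})

test_that("infeasible planted correlations are rejected", {
  expect_error(
    simulateTraits(cohortSpec(nSubjects = 5L, nParcels = 40L,
                              plantedRhoGSQ = 0.99, plantedRhoAQ = -0.99,
                              traitCor = 0.3)),
    "infeasible")
})

test_that("connectomes collapse to one matrix in the no-effect limit", {
  spec <- cohortSpec(nSubjects = 4L, nParcels = 30L, betaExpand = 0,
                     sigmaEdge = 1e-12, seed = 9L)
  lay <- specLayout(spec)
  m1 <- simulateConnectome(-1.3, spec, seed = 1, layout = lay)
  m2 <- simulateConnectome(2.1, spec, seed = 2, layout = lay)
  expect_equal(m1@values, m2@values, tolerance = 1e-9)
})

test_that("visual-default distance increases monotonically in the trait", {
  spec <- cohortSpec(nSubjects = 10L, nParcels = 60L, sigmaEdge = 1e-10,
                     seed = 13L)
  lay <- specLayout(spec)
  cfg <- runConfig(nGradients = 5L)
  part <- specPartition(spec)
  ref <- computeGradients(simulateConnectome(0, spec, seed = 1, layout = lay),
                          cfg)
  d <- vapply(seq(-2, 2, by = 0.5), function(e)
    networkMedianDistance(
      computeGradients(simulateConnectome(e, spec, seed = 1, layout = lay),
                       cfg, reference = ref),
      part, "visual", "default"),
    numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("a 2-network toy recovers the block split in gradient 1", {
  spec <- cohortSpec(nSubjects = 2L, nParcels = 20L,
                     networkNames = c("uni", "trans"),
                     partitionSizes = c(10L, 10L),
                     basePositions = cbind(c(-1, 1), 0, 0),
                     sigmaParcel = 0.15, seed = 21L)
  # at P = 20 keep 6 survivors per row (0.95 would leave only the diagonal)
  cfg <- runConfig(sparsity = 0.7, nGradients = 2L, eccentricityDims = 2L)
  g <- computeGradients(simulateConnectome(0, spec, seed = 2), cfg)
  s1 <- gradientScores(g)[, 1]
  expect_true(all(sign(s1[1:10]) == sign(s1[1])))
  expect_true(all(sign(s1[11:20]) == -sign(s1[1])))
  # eigen oracle agreement on the same affinity
  a <- cosineAffinity(sparsifyRows(simulateConnectome(0, spec, seed = 2),
                                   0.7))
  expect_equal_up_to_sign(gradientScores(g), eigenPcaOracle(a, 2L)$scores,
                          1e-8)
})

test_that("motion traces hit their FD and DVARS calibration targets", {
  spec <- testCohortSpec(n = 5L)
  md <- simulateMotion(spec, seed = 31, targetFD = 0)
  expect_equal(computeFD(md$traces), 0)
  # empirical mean FD within 10% of target over many draws
  fds <- vapply(1:300, function(s)
    computeFD(simulateMotion(spec, seed = s, targetFD = 0.03)$traces),
    numeric(1))
  expect_lt(abs(mean(fds) - 0.03) / 0.03, 0.1)
  dvs <- vapply(1:100, function(s)
    computeDVARS(simulateMotion(spec, seed = s)$voxels), numeric(1))
  expect_lt(abs(mean(dvs) - spec@targetDVARS) / spec@targetDVARS, 0.1)
  # different seeds, different traces
  expect_false(identical(simulateMotion(spec, seed = 1)$traces,
                         simulateMotion(spec, seed = 2)$traces))
})

test_that("cohorts are reproducible and FD spans a realistic band", {
  spec <- testCohortSpec(n = 12L, p = 40L)
  c1 <- simulateCohort(spec, motion = TRUE)
  c2 <- simulateCohort(spec, motion = TRUE)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$matrices[[5]]@values, c2$matrices[[5]]@values)
  expect_true(all(c1$participants$fd > 0))
  expect_true(all(c1$participants$fd < 0.15))
  expect_equal(sum(lengths(lapply(c1$matrices, parcelIds)) == 40L), 12L)
})

test_that("cohort round-trips through the on-disk layout", {
  spec <- testCohortSpec(n = 4L, p = 30L)
  cohort <- simulateCohort(spec, motion = TRUE)
  dir <- withr::local_tempdir()
  writeCohort(cohort, dir)
  part <- readNetworkPartition(file.path(dir, "partition.tsv"))
  expect_identical(networkOf(part), networkOf(cohort$partition))
  m <- readConnectivityMatrix(
    file.path(dir, "matrices", "sub-0002.tsv"), expectedParcels = 30)
  expect_identical(m@values, cohort$matrices[["sub-0002"]]@values)
  p <- readParticipantTable(file.path(dir, "participants.csv"))
  expect_equal(p$gsq_total, cohort$participants$gsq_total)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$planted_rho_gsq, spec@plantedRhoGSQ)
})
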