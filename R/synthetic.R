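#' Construct a CohortSpec
#'
#' Defaults describe the reference study shape: 370 subjects, 400 parcels
#' over 7 networks ordered along the latent unimodal-to-transmodal axis,
#' GSQ-like scores with mean 50.1 / SD 18.2, AQ-like scores with mean
#' 19.6 / SD 5.3, a planted trait-expansion Spearman correlation of 0.4
#' for the GSQ-like trait and 0 (null) for the AQ-like trait, and mean
#' framewise displacement around 0.03 mm.
#'
#' @param nSubjects cohort size.
#' @param nParcels parcel count P.
#' @param partitionSizes parcels per network (sums to P).
#' @param networkNames network names along the latent axis.
#' @param basePositions K x 3 matrix of latent network centres; NULL scales
#'   the default 7-network geometry to K networks.
#' @param betaExpand axis-1 expansion per unit standardized expansion score.
#' @param plantedRhoGSQ,plantedRhoAQ target Spearman correlations between
#'   each trait and the subject expansion score.
#' @param sigmaParcel within-network parcel scatter SD (latent units);
#'   network score distributions overlap along the axis, as real gradient
#'   histograms do.
#' @param sigmaEdge edge noise SD (correlation units).
#' @param baseline constant correlation offset on every edge.
#' @param lambda positive inverse gain of the latent Gram term.
#' @param blockBonus extra correlation on within-network edges.
#' @param gsqMean,gsqSD,aqMean,aqSD trait moments.
#' @param traitCor latent AQ-GSQ correlation.
#' @param ageMean,ageSD age moments (years).
#' @param maleFraction fraction of male participants.
#' @param targetFD mean framewise displacement (mm).
#' @param targetDVARS mean DVARS level (signal units).
#' @param nTimepoints simulated trace length.
#' @param nVoxels voxels in the simulated masked series.
#' @param seed root random seed.
#' @return a validated [CohortSpec-class].
#' @export
cohortSpec <- function(nSubjects = 370L, nParcels = 400L,
                       partitionSizes = NULL,
                       networkNames = c("visual", "somatomotor",
                                        "dorsal_attention",
                                        "salience_ventral_attention",
                                        "control", "limbic", "default"),
                       basePositions = NULL,
                       betaExpand = 0.2,
                       plantedRhoGSQ = 0.4, plantedRhoAQ = 0,
                       sigmaParcel = 0.3, sigmaEdge = 0.02,
                       baseline = 0.1, lambda = 2, blockBonus = 0.05,
                       gsqMean = 50.1, gsqSD = 18.2,
                       aqMean = 19.6, aqSD = 5.3, traitCor = 0.3,
                       ageMean = 21.05, ageSD = 1.29,
                       maleFraction = 99 / 370,
                       targetFD = 0.03, targetDVARS = 1,
                       nTimepoints = 200L, nVoxels = 50L, seed = 1L) {
  k <- length(networkNames)
  if (is.null(partitionSizes)) {
    if (k == 7L && nParcels == 400L) {
      # Schaefer-like 7-network sizes at 400 parcels
      partitionSizes <- c(61L, 77L, 46L, 47L, 52L, 26L, 91L)
    } else {
      partitionSizes <- rep(nParcels %/% k, k)
      partitionSizes[seq_len(nParcels - sum(partitionSizes))] <-
        partitionSizes[seq_len(nParcels - sum(partitionSizes))] + 1L
    }
  }
  if (is.null(basePositions)) {
    if (k == 7L) {
      basePositions <- cbind(
        axis1 = c(-1, -0.5, -0.25, 0, 0.3, 0.6, 1),
        axis2 = c(0.3, -0.3, 0.1, -0.1, 0.05, 0.1, -0.05),
        axis3 = c(0.05, -0.25, 0.05, 0.25, -0.05, 0.05, -0.1))
    } else {
      basePositions <- cbind(seq(-1, 1, length.out = k),
                             rep_len(c(0.2, -0.2), k),
                             rep_len(c(0.1, 0, -0.1), k))
    }
  }
  new("CohortSpec",
      nSubjects = as.integer(nSubjects), nParcels = as.integer(nParcels),
      partitionSizes = as.integer(partitionSizes),
      networkNames = networkNames,
      basePositions = unname(as.matrix(basePositions)),
      betaExpand = betaExpand,
      plantedRhoGSQ = plantedRhoGSQ, plantedRhoAQ = plantedRhoAQ,
      sigmaParcel = sigmaParcel, sigmaEdge = sigmaEdge,
      baseline = baseline, lambda = lambda, blockBonus = blockBonus,
      gsqMean = gsqMean, gsqSD = gsqSD, aqMean = aqMean, aqSD = aqSD,
      traitCor = traitCor, ageMean = ageMean, ageSD = ageSD,
      maleFraction = maleFraction,
      targetFD = targetFD, targetDVARS = targetDVARS,
      nTimepoints = as.integer(nTimepoints), nVoxels = as.integer(nVoxels),
      seed = as.integer(seed))
}

#' Network partition implied by a CohortSpec
#'
#' @param spec a [CohortSpec-class].
#' @return a [NetworkPartition-class] with contiguous network blocks.
#' @export
specPartition <- function(spec) {
  networkPartition(
    sprintf("p%03d", seq_len(spec@nParcels)),
    rep(spec@networkNames, times = spec@partitionSizes),
    networkOrder = spec@networkNames)
}

# bivariate-normal Pearson correlation that induces a given Spearman rho
spearmanToPearson <- function(rhoS) 2 * sin(pi * rhoS / 6)

# weights of the expansion score e = w1*zGSQ + w2*zAQ + w3*noise such that
# cor(e, zGSQ) = r1 and cor(e, zAQ) = r2 given cor(zGSQ, zAQ) = r12
expansionWeights <- function(r1, r2, r12) {
  den <- 1 - r12^2
  w1 <- (r1 - r12 * r2) / den
  w2 <- (r2 - r12 * r1) / den
  v <- 1 - (w1^2 + w2^2 + 2 * w1 * w2 * r12)
  if (v < -1e-12)
    stop("infeasible planted correlations: |combined effect| > 1")
  c(w1, w2, sqrt(max(v, 0)))
}

#' Simulate questionnaire traits for a cohort
#'
#' Draws correlated latent trait variables, maps them to GSQ-like totals
#' (truncated to [0, 168]) and AQ-like totals (truncated to [0, 50]), and
#' generates item-level responses whose scoring reproduces the totals
#' exactly: 42 GSQ items on the 0-4 scale laid out as 7 modalities x
#' (3 hyper + 3 hypo) items, and 50 AQ items on the 4-point agreement
#' scale with a randomly keyed scoring direction per item. Each subject
#' also receives a latent expansion score with the planted Spearman
#' correlations to the traits (Gaussian copula).
#'
#' @param spec a [CohortSpec-class].
#' @param seed optional seed; defaults to the spec's.
#' @return list with \code{participants} (data.frame: subject_id,
#'   aq_total, gsq_total, gsq_hyper, gsq_hypo, gsq_no_vision, per-modality
#'   subscales, age, gender, expansion), \code{gsq_items} (n x 42),
#'   \code{aq_items} (n x 50), \code{aq_key} (length 50).
#' @export
simulateTraits <- function(spec, seed = NULL) {
  set.seed(if (is.null(seed)) spec@seed else seed)
  n <- spec@nSubjects
  r12 <- spec@traitCor
  zG <- stats::rnorm(n)
  zA <- r12 * zG + sqrt(1 - r12^2) * stats::rnorm(n)
  w <- expansionWeights(spearmanToPearson(spec@plantedRhoGSQ),
                        spearmanToPearson(spec@plantedRhoAQ), r12)
  expansion <- w[1L] * zG + w[2L] * zA + w[3L] * stats::rnorm(n)
  gsq <- pmin(pmax(round(spec@gsqMean + spec@gsqSD * zG), 0L), 168L)
  aq <- pmin(pmax(round(spec@aqMean + spec@aqSD * zA), 0L), 50L)

  items <- gsqItemTable()
  gsqItems <- t(vapply(gsq, function(total)
    tabulate(sample(rep(seq_len(42L), 4L), total), nbins = 42L),
    integer(42L)))
  aqKey <- sample(c("agree", "disagree"), 50L, replace = TRUE)
  aqItems <- t(vapply(aq, function(total) {
    keyed <- seq_len(50L) %in% sample.int(50L, total)
    onPole <- sample(1:2, 50L, replace = TRUE)  # definitely/slightly
    ifelse(xor(aqKey == "agree", keyed), 2L + onPole, onPole)
  }, integer(50L)))

  modality <- items$modality
  modScores <- sapply(unique(modality), function(m)
    rowSums(gsqItems[, modality == m, drop = FALSE]))
  parts <- data.frame(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    aq_total = scoreAQ(aqItems, aqKey),
    gsq_total = scoreGSQ(gsqItems),
    gsq_hyper = scoreGSQ(gsqItems, polarity = "hyper"),
    gsq_hypo = scoreGSQ(gsqItems, polarity = "hypo"),
    gsq_no_vision = scoreGSQ(gsqItems, excludeModalities = "vision"),
    age = round(stats::rnorm(n, spec@ageMean, spec@ageSD), 1L),
    gender = ifelse(stats::runif(n) < spec@maleFraction, "male", "female"),
    expansion = expansion,
    stringsAsFactors = FALSE)
  colnames(modScores) <- paste0("gsq_", unique(modality))
  parts <- cbind(parts, as.data.frame(modScores))
  stopifnot(identical(parts$aq_total, unname(apply(aqItems, 1L, scoreAQ,
                                                   key = aqKey))),
            all(parts$gsq_total == rowSums(gsqItems)))
  list(participants = parts, gsq_items = gsqItems, aq_items = aqItems,
       aq_key = aqKey)
}

#' Latent parcel layout of a cohort
#'
#' Parcel coordinates on the three latent axes: the network's base
#' position plus within-network scatter of SD \code{sigmaParcel}. The
#' layout is a property of the parcellation, not of a subject -- it is
#' drawn deterministically from the spec's seed and shared by the whole
#' cohort, mirroring how a fixed atlas gives every subject the same
#' parcel topography. Network distributions overlap along axis 1, as
#' real gradient-score distributions do.
#'
#' @param spec a [CohortSpec-class].
#' @return P x 3 matrix of latent coordinates.
#' @export
specLayout <- function(spec) {
  rng <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(rng)) assign(".Random.seed", rng, globalenv()))
  set.seed(spec@seed)
  p <- spec@nParcels
  netIdx <- rep(seq_along(spec@partitionSizes), times = spec@partitionSizes)
  spec@basePositions[netIdx, , drop = FALSE] +
    matrix(stats::rnorm(p * 3L, sd = spec@sigmaParcel), p, 3L)
}

#' Simulate one subject's connectome
#'
#' Takes the cohort's fixed parcel layout (see [specLayout()]), expands
#' the axis-1 coordinates multiplicatively by
#' \code{1 + betaExpand * expansion}, and maps latent coordinates to edge
#' correlations through a low-rank Gram model in Fisher-z space:
#' \code{z_ij = baseline + <x_i, x_j> / lambda + blockBonus[same network]
#' + noise} and \code{r_ij = tanh(z_ij)}, symmetrized, unit diagonal.
#' Parcels whose connectivity profiles point the same way in latent space
#' are positively correlated, opposite ends anticorrelated -- the
#' structure PCA gradient embeddings assume. Axes 2-3 are stationary: the
#' planted effect is specific to the principal axis, and expansion enters
#' the Gram products quadratically so the embedded axis grows with it.
#' Subject-level variability enters through the expansion factor and the
#' additive edge noise.
#'
#' @param expansion subject's standardized expansion score.
#' @param spec a [CohortSpec-class].
#' @param seed optional per-subject seed.
#' @param layout optional precomputed [specLayout()] result (saves
#'   recomputation across subjects).
#' @return a [ConnectivityMatrix-class].
#' @export
simulateConnectome <- function(expansion, spec, seed = NULL, layout = NULL) {
  if (is.null(layout)) layout <- specLayout(spec)
  if (!is.null(seed)) set.seed(seed)
  p <- spec@nParcels
  netIdx <- rep(seq_along(spec@partitionSizes), times = spec@partitionSizes)
  coords <- layout
  coords[, 1L] <- coords[, 1L] * (1 + spec@betaExpand * expansion)
  z <- spec@baseline + tcrossprod(coords) / spec@lambda +
    spec@blockBonus * outer(netIdx, netIdx, "==")
  noise <- matrix(0, p, p)
  up <- upper.tri(noise)
  noise[up] <- stats::rnorm(sum(up), sd = spec@sigmaEdge)
  noise <- noise + t(noise)
  # edges live in Fisher-z space; tanh keeps r in (-1, 1) smoothly and
  # strictly monotone in the latent Gram term (no clipping plateau)
  r <- tanh(z + noise)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  connectivityMatrix(r, parcelIds = sprintf("p%03d", seq_len(p)))
}

#' Simulate motion traces and masked voxel series
#'
#' Realignment parameters are Gaussian random walks whose step size is
#' calibrated so the median absolute derivative equals the subject's
#' target framewise displacement (median of |N(0, s)| is s * qnorm(0.75)).
#' Voxel series are white noise scaled so the expected DVARS matches the
#' target (the derivative of white noise has SD s * sqrt(2)).
#'
#' @param spec a [CohortSpec-class].
#' @param seed optional seed.
#' @param targetFD,targetDVARS per-subject targets; default the spec's.
#' @return list with \code{traces} (T x 12) and \code{voxels} (T x V).
#' @export
simulateMotion <- function(spec, seed = NULL, targetFD = spec@targetFD,
                           targetDVARS = spec@targetDVARS) {
  if (!is.null(seed)) set.seed(seed)
  tl <- spec@nTimepoints
  stepSD <- targetFD / stats::qnorm(0.75)
  steps <- matrix(stats::rnorm((tl - 1L) * 12L, sd = stepSD), tl - 1L, 12L)
  traces <- rbind(0, apply(steps, 2L, cumsum))
  voxels <- matrix(stats::rnorm(tl * spec@nVoxels,
                                sd = targetDVARS / sqrt(2)),
                   tl, spec@nVoxels)
  list(traces = traces, voxels = voxels)
}

#' Simulate a full cohort
#'
#' Generates traits and items, one connectome per subject (trait-coupled
#' axis-1 expansion), and per-subject motion data with FD/DVARS summaries
#' added to the participant table. All randomness flows from the spec's
#' root seed through per-subject substreams drawn up front, so cohorts are
#' reproducible and subjects independent.
#'
#' @param spec a [CohortSpec-class].
#' @param motion simulate motion traces too (slower); FD/DVARS columns are
#'   filled either way (from traces if TRUE, from the target levels with
#'   lognormal between-subject spread if FALSE).
#' @return list with \code{spec}, \code{partition}, \code{participants},
#'   \code{matrices} (list of [ConnectivityMatrix-class]),
#'   \code{gsq_items}, \code{aq_items}, \code{aq_key}, and \code{motion}
#'   (list per subject or NULL).
#' @export
simulateCohort <- function(spec, motion = FALSE) {
  set.seed(spec@seed)
  n <- spec@nSubjects
  subjectSeeds <- sample.int(2147483646L, 2L * n)
  tr <- simulateTraits(spec, seed = sample.int(2147483646L, 1L))
  parts <- tr$participants
  fdTargets <- spec@targetFD * exp(stats::rnorm(n, sd = 0.3))
  dvTargets <- spec@targetDVARS * exp(stats::rnorm(n, sd = 0.2))
  layout <- specLayout(spec)
  matrices <- vector("list", n)
  motionData <- if (motion) vector("list", n) else NULL
  fd <- dv <- numeric(n)
  for (i in seq_len(n)) {
    matrices[[i]] <- simulateConnectome(parts$expansion[i], spec,
                                        seed = subjectSeeds[i],
                                        layout = layout)
    if (motion) {
      md <- simulateMotion(spec, seed = subjectSeeds[n + i],
                           targetFD = fdTargets[i],
                           targetDVARS = dvTargets[i])
      motionData[[i]] <- md
      fd[i] <- computeFD(md$traces)
      dv[i] <- computeDVARS(md$voxels)
    } else {
      fd[i] <- fdTargets[i]
      dv[i] <- dvTargets[i]
    }
  }
  parts$fd <- fd
  parts$dvars <- dv
  names(matrices) <- parts$subject_id
  if (motion) names(motionData) <- parts$subject_id
  list(spec = spec, partition = specPartition(spec), participants = parts,
       matrices = matrices, gsq_items = tr$gsq_items,
       aq_items = tr$aq_items, aq_key = tr$aq_key, motion = motionData)
}

#' Write a simulated cohort to disk
#'
#' Emits the on-disk layout the pipeline consumes: one TSV matrix per
#' subject under matrices/, partition.tsv, participants.csv, item-level
#' CSVs with the AQ scoring-key sidecar, optional motion traces, and a
#' manifest.json recording the seed and ground-truth generator parameters.
#'
#' @param cohort output of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$matrices))
    writeConnectivityMatrix(cohort$matrices[[id]],
                            file.path(dir, "matrices", paste0(id, ".tsv")))
  writeNetworkPartition(cohort$partition, file.path(dir, "partition.tsv"))
  writeParticipantTable(cohort$participants, file.path(dir, "participants.csv"))
  utils::write.csv(cohort$gsq_items, file.path(dir, "gsq_items.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$aq_items, file.path(dir, "aq_items.csv"),
                   row.names = FALSE)
  utils::write.csv(gsqItemTable(), file.path(dir, "gsq_item_meta.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(item = seq_len(50L), keyed = cohort$aq_key),
                   file.path(dir, "aq_key.csv"), row.names = FALSE)
  if (!is.null(cohort$motion)) {
    dir.create(file.path(dir, "motion"), showWarnings = FALSE)
    for (id in names(cohort$motion)) {
      utils::write.table(cohort$motion[[id]]$traces,
                         file.path(dir, "motion", paste0(id, "_motion.tsv")),
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  spec <- cohort$spec
  manifest <- list(
    seed = spec@seed, n_subjects = spec@nSubjects,
    n_parcels = spec@nParcels,
    networks = as.list(stats::setNames(as.integer(spec@partitionSizes),
                                       spec@networkNames)),
    beta_expand = spec@betaExpand,
    planted_rho_gsq = spec@plantedRhoGSQ,
    planted_rho_aq = spec@plantedRhoAQ,
    sigma_parcel = spec@sigmaParcel, sigma_edge = spec@sigmaEdge,
    baseline = spec@baseline, lambda = spec@lambda,
    block_bonus = spec@blockBonus)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Estimate the planted trait-expansion effect from a cohort
#'
#' Runs the gradient pipeline on a simulated cohort (group-average
#' gradients, Procrustes-aligned individual gradients) and returns the
#' Spearman correlation between the GSQ-like trait and each subject's
#' visual-default network median distance on the principal gradient -- the
#' headline statistic of the analysis.
#'
#' @param spec a [CohortSpec-class].
#' @param config a [RunConfig-class].
#' @param netA,netB the network pair, defaults visual vs default.
#' @param trait participant column to correlate, default gsq_total.
#' @return list with \code{rho}, \code{p}, \code{n} and the per-subject
#'   \code{distances}.
#' @export
cohortEffectEstimate <- function(spec, config = runConfig(),
                                 netA = "visual", netB = "default",
                                 trait = "gsq_total") {
  cohort <- simulateCohort(spec)
  ref <- computeGradients(groupAverage(cohort$matrices), config)
  part <- cohort$partition
  dists <- vapply(cohort$matrices, function(m) {
    g <- computeGradients(m, config, reference = ref)
    networkMedianDistance(g, part, netA, netB)
  }, numeric(1))
  res <- spearmanAssociation(dists, cohort$participants[[trait]])
  res$distances <- dists
  res
}
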