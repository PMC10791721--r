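#' @import methods
NULL

#' NetworkPartition: parcel-to-network assignment
#'
#' Maps each cortical parcel to exactly one functional network. The canonical
#' use case is a 400-parcel scheme assigned to 7 large-scale networks
#' (visual, somatomotor, dorsal attention, salience/ventral attention,
#' control, limbic, default), but any K >= 2 non-empty networks are accepted.
#'
#' @slot parcelIds character vector of parcel identifiers, in matrix order.
#' @slot networks character vector, same length, naming each parcel's network.
#' @slot networkOrder character vector giving the canonical display order of
#'   the K distinct network names.
#'
#' @seealso [networkPartition()] for the user-facing constructor,
#'   [readNetworkPartition()] to read one from a two-column TSV.
#' @exportClass NetworkPartition
setClass("NetworkPartition",
  slots = c(
    parcelIds = "character",
    networks = "character",
    networkOrder = "character"
  )
)

setValidity("NetworkPartition", function(object) {
  msgs <- character()
  if (length(object@parcelIds) != length(object@networks))
    msgs <- c(msgs, "parcelIds and networks must have equal length")
  if (anyDuplicated(object@parcelIds))
    msgs <- c(msgs, "duplicate parcel ids")
  nets <- unique(object@networks)
  if (length(nets) < 2L)
    msgs <- c(msgs, "a partition needs at least 2 networks")
  if (!setequal(nets, object@networkOrder))
    msgs <- c(msgs, "networkOrder must list exactly the networks present")
  if (anyDuplicated(object@networkOrder))
    msgs <- c(msgs, "networkOrder contains duplicates")
  if (any(tabulate(factor(object@networks, levels = object@networkOrder)) == 0L))
    msgs <- c(msgs, "every network must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' ConnectivityMatrix: parcel-by-parcel Pearson correlation structure
#'
#' The substrate of the gradient pipeline: a symmetric P x P matrix of
#' Pearson correlations between parcel time courses, with unit diagonal.
#' Off-diagonal entries lie in [-1, 1]; the diagonal is stored as 1 but is
#' excluded from Fisher-z transforms downstream (atanh(1) is infinite).
#'
#' @slot values numeric P x P matrix of correlations.
#' @slot parcelIds character vector of parcel identifiers aligned to rows
#'   and columns.
#'
#' @seealso [connectivityMatrix()], [correlateTimeSeries()], [groupAverage()]
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix",
  slots = c(
    values = "matrix",
    parcelIds = "character"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v))
    msgs <- c(msgs, "matrix must be square")
  if (length(object@parcelIds) != nrow(v))
    msgs <- c(msgs, "parcelIds length must equal matrix dimension")
  if (anyNA(v))
    msgs <- c(msgs, "matrix contains NA/NaN cells")
  else {
    if (max(abs(v - t(v))) > 1e-10)
      msgs <- c(msgs, "matrix is not symmetric within 1e-10")
    off <- v[row(v) != col(v)]
    if (length(off) && (min(off) < -1 || max(off) > 1))
      msgs <- c(msgs, "off-diagonal correlations must lie in [-1, 1]")
    if (max(abs(diag(v) - 1)) > 1e-8)
      msgs <- c(msgs, "diagonal must be 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' GradientSet: connectivity gradient scores with explained variance
#'
#' A P x G matrix of gradient scores (embedding coordinates of each parcel
#' along G components) plus the fraction of affinity variance each component
#' explains. Unaligned sets come straight from PCA and have mutually
#' orthogonal columns; Procrustes-aligned sets are rotated into the
#' reference frame, where orthogonality and the explained-variance ordering
#' are no longer guaranteed (component order is fixed by the reference).
#'
#' @slot scores numeric P x G matrix of gradient scores.
#' @slot explainedVariance numeric length-G vector of variance fractions.
#' @slot aligned logical; TRUE after Procrustes alignment to a reference.
#'
#' @seealso [pcaGradients()], [procrustesAlign()], [computeGradients()]
#' @exportClass GradientSet
setClass("GradientSet",
  slots = c(
    scores = "matrix",
    explainedVariance = "numeric",
    aligned = "logical"
  )
)

setValidity("GradientSet", function(object) {
  msgs <- character()
  if (length(object@explainedVariance) != ncol(object@scores))
    msgs <- c(msgs, "explainedVariance length must equal number of components")
  if (any(object@explainedVariance < -1e-12, na.rm = TRUE))
    msgs <- c(msgs, "explained variance fractions must be >= 0")
  if (length(object@aligned) != 1L)
    msgs <- c(msgs, "aligned must be a single logical")
  if (isFALSE(object@aligned) && ncol(object@scores) > 1L) {
    cp <- crossprod(object@scores)
    d <- sqrt(pmax(diag(cp), .Machine$double.eps))
    scaled <- abs(cp) / outer(d, d)
    diag(scaled) <- 0
    if (max(scaled) > 1e-8)
      msgs <- c(msgs, "columns of an unaligned GradientSet must be orthogonal")
  }
  if (length(msgs)) msgs else TRUE
})

#' RunConfig: pipeline parameters
#'
#' Bundles every tunable of the gradient pipeline. The defaults reproduce
#' the reference analysis settings: row sparsity 0.95, cosine affinity
#' kernel, ten gradients, eccentricity/dispersion in the first three
#' gradient dimensions, 50 histogram bins, alpha 0.05.
#'
#' @slot sparsity fraction of each connectome row zeroed before the affinity
#'   kernel (in [0, 1)).
#' @slot kernel affinity kernel name; only "cosine" is implemented.
#' @slot nGradients number of gradients to extract.
#' @slot eccentricityDims number of leading gradients spanning the space in
#'   which eccentricity and dispersion are measured.
#' @slot eccentricityAggregate "mean" (mean Euclidean norm per network) or
#'   "sumsq" (sum of squared norms).
#' @slot nBins histogram bin count for gradient-score distributions.
#' @slot alpha nominal significance level before multiplicity correction.
#' @slot signedMedianDistance report signed rather than absolute network
#'   median distances.
#' @slot genderLevels length-2 character; first level codes 0, second codes 1
#'   in linear models.
#' @slot seed integer random seed recorded in run manifests.
#'
#' @seealso [runConfig()], [readRunConfig()], [runPipeline()]
#' @exportClass RunConfig
setClass("RunConfig",
  slots = c(
    sparsity = "numeric",
    kernel = "character",
    nGradients = "integer",
    eccentricityDims = "integer",
    eccentricityAggregate = "character",
    nBins = "integer",
    alpha = "numeric",
    signedMedianDistance = "logical",
    genderLevels = "character",
    seed = "integer"
  ),
  prototype = list(
    sparsity = 0.95,
    kernel = "cosine",
    nGradients = 10L,
    eccentricityDims = 3L,
    eccentricityAggregate = "mean",
    nBins = 50L,
    alpha = 0.05,
    signedMedianDistance = FALSE,
    genderLevels = c("female", "male"),
    seed = 1L
  )
)

setValidity("RunConfig", function(object) {
  msgs <- character()
  if (object@sparsity < 0 || object@sparsity >= 1)
    msgs <- c(msgs, "sparsity must lie in [0, 1)")
  if (!object@kernel %in% "cosine")
    msgs <- c(msgs, "kernel must be 'cosine'")
  if (object@nGradients < 1L)
    msgs <- c(msgs, "nGradients must be >= 1")
  if (object@eccentricityDims < 1L)
    msgs <- c(msgs, "eccentricityDims must be >= 1")
  if (object@eccentricityDims > object@nGradients)
    msgs <- c(msgs, "eccentricityDims cannot exceed nGradients")
  if (!object@eccentricityAggregate %in% c("mean", "sumsq"))
    msgs <- c(msgs, "eccentricityAggregate must be 'mean' or 'sumsq'")
  if (object@nBins < 1L)
    msgs <- c(msgs, "nBins must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    msgs <- c(msgs, "alpha must lie in (0, 1)")
  if (length(object@genderLevels) != 2L)
    msgs <- c(msgs, "genderLevels must have exactly two levels")
  if (length(msgs)) msgs else TRUE
})

#' SegregationReport: per-subject integration/segregation metrics
#'
#' Tidy container for every metric computed from one subject's aligned
#' gradients: pairwise network median distances, peak distances and
#' between-network dispersions; per-network eccentricity and within-network
#' dispersion; global gradient range, standard deviation, global
#' eccentricity and the principal explained-variance fraction.
#'
#' @slot table data.frame with columns subject, metric, network_a,
#'   network_b, dims, value. Global metrics carry NA network columns.
#'
#' @seealso [segregationReport()], [metricsTable()]
#' @exportClass SegregationReport
setClass("SegregationReport",
  slots = c(table = "data.frame")
)

setValidity("SegregationReport", function(object) {
  need <- c("subject", "metric", "network_a", "network_b", "dims", "value")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Describes a synthetic study population: cohort size, parcellation shape,
#' latent network geometry along the first three embedding axes, the
#' trait-coupled expansion of axis 1, questionnaire score distributions,
#' and motion levels. The defaults mirror a 370-subject, 400-parcel,
#' 7-network cohort with GSQ-like scores of mean 50.1 and SD 18.2 and
#' AQ-like scores of mean 19.6 and SD 5.3.
#'
#' @slot nSubjects cohort size.
#' @slot nParcels number of parcels P.
#' @slot partitionSizes integer vector of parcels per network (sums to P).
#' @slot networkNames names of the K networks, ordered along the latent
#'   unimodal-to-transmodal axis.
#' @slot basePositions K x 3 matrix of network centre coordinates on latent
#'   axes 1-3. Axis 1 carries the unimodal-to-transmodal hierarchy.
#' @slot betaExpand multiplicative expansion of axis-1 positions per unit of
#'   the standardized expansion score.
#' @slot plantedRhoGSQ target Spearman correlation between the GSQ-like
#'   trait and the subject expansion score (Gaussian copula).
#' @slot plantedRhoAQ same for the AQ-like trait (0 = null).
#' @slot sigmaParcel SD of within-network parcel jitter around the network
#'   centre, in latent coordinate units.
#' @slot sigmaEdge SD of additive edge noise, in correlation units.
#' @slot baseline constant correlation offset shared by all edges.
#' @slot lambda positive inverse gain of the Gram term: edge correlations
#'   are baseline + <x_i, x_j> / lambda (+ block bonus + noise).
#' @slot blockBonus correlation added to within-network edges.
#' @slot gsqMean,gsqSD,aqMean,aqSD moments of the trait distributions
#'   (truncated normals within [0, 168] and [0, 50]).
#' @slot traitCor latent correlation between the two traits.
#' @slot ageMean,ageSD age distribution (years).
#' @slot maleFraction fraction of male participants.
#' @slot targetFD target mean framewise displacement (mm).
#' @slot targetDVARS target DVARS level (signal units).
#' @slot nTimepoints length of simulated motion/voxel traces.
#' @slot nVoxels voxels in the simulated brain-masked series.
#' @slot seed root random seed; per-subject streams are derived from it.
#'
#' @seealso [cohortSpec()], [simulateCohort()]
#' @exportClass CohortSpec
setClass("CohortSpec",
  slots = c(
    nSubjects = "integer",
    nParcels = "integer",
    partitionSizes = "integer",
    networkNames = "character",
    basePositions = "matrix",
    betaExpand = "numeric",
    plantedRhoGSQ = "numeric",
    plantedRhoAQ = "numeric",
    sigmaParcel = "numeric",
    sigmaEdge = "numeric",
    baseline = "numeric",
    lambda = "numeric",
    blockBonus = "numeric",
    gsqMean = "numeric",
    gsqSD = "numeric",
    aqMean = "numeric",
    aqSD = "numeric",
    traitCor = "numeric",
    ageMean = "numeric",
    ageSD = "numeric",
    maleFraction = "numeric",
    targetFD = "numeric",
    targetDVARS = "numeric",
    nTimepoints = "integer",
    nVoxels = "integer",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (sum(object@partitionSizes) != object@nParcels)
    msgs <- c(msgs, "partition sizes must sum to nParcels")
  if (length(object@partitionSizes) != length(object@networkNames))
    msgs <- c(msgs, "one partition size per network name")
  if (nrow(object@basePositions) != length(object@networkNames) ||
      ncol(object@basePositions) != 3L)
    msgs <- c(msgs, "basePositions must be K x 3")
  if (object@sigmaParcel <= 0 || object@sigmaEdge <= 0)
    msgs <- c(msgs, "noise SDs must be positive")
  if (object@lambda <= 0)
    msgs <- c(msgs, "lambda must be positive")
  if (abs(object@plantedRhoGSQ) > 1 || abs(object@plantedRhoAQ) > 1)
    msgs <- c(msgs, "planted trait-expansion Spearman must lie in [-1, 1]")
  if (abs(object@traitCor) > 1)
    msgs <- c(msgs, "trait correlation must lie in [-1, 1]")
  if (length(msgs)) msgs else TRUE
})
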