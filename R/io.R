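#' Construct a NetworkPartition
#'
#' @param parcelIds character vector of parcel identifiers (matrix order).
#' @param networks character vector naming each parcel's network.
#' @param networkOrder optional canonical display order; defaults to order
#'   of first appearance.
#' @return a validated [NetworkPartition-class] object.
#' @examples
#' networkPartition(paste0("p", 1:6), rep(c("A", "B", "C"), each = 2))
#' @export
networkPartition <- function(parcelIds, networks, networkOrder = NULL) {
  if (is.null(networkOrder)) networkOrder <- unique(networks)
  new("NetworkPartition",
      parcelIds = as.character(parcelIds),
      networks = as.character(networks),
      networkOrder = as.character(networkOrder))
}

#' Construct a ConnectivityMatrix
#'
#' Symmetrizes tiny numerical asymmetry (up to 1e-8) and validates bounds;
#' larger asymmetry is an error, not silently averaged away.
#'
#' @param values numeric square matrix of Pearson correlations.
#' @param parcelIds optional parcel identifiers; defaults to rownames or
#'   \code{p1..pP}.
#' @return a validated [ConnectivityMatrix-class] object.
#' @export
connectivityMatrix <- function(values, parcelIds = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("connectivity matrix must be square, got ",
         nrow(values), " x ", ncol(values))
  if (anyNA(values))
    stop("connectivity matrix contains NaN/NA cells")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-8)
    stop("matrix asymmetry ", format(asym), " exceeds tolerance 1e-8")
  if (asym > 0) values <- (values + t(values)) / 2
  if (is.null(parcelIds)) {
    parcelIds <- rownames(values)
    if (is.null(parcelIds)) parcelIds <- paste0("p", seq_len(nrow(values)))
  }
  dimnames(values) <- NULL
  new("ConnectivityMatrix", values = values, parcelIds = as.character(parcelIds))
}

#' Construct a GradientSet
#'
#' @param scores numeric P x G matrix of gradient scores.
#' @param explainedVariance numeric length-G variance fractions.
#' @param aligned logical; TRUE if Procrustes-aligned.
#' @return a validated [GradientSet-class] object.
#' @export
gradientSet <- function(scores, explainedVariance, aligned = FALSE) {
  new("GradientSet", scores = as.matrix(scores),
      explainedVariance = as.numeric(explainedVariance),
      aligned = isTRUE(aligned))
}

#' Construct a RunConfig
#'
#' All arguments default to the reference analysis settings.
#'
#' @param sparsity row sparsification fraction, default 0.95.
#' @param kernel affinity kernel, default "cosine".
#' @param nGradients gradients to extract, default 10.
#' @param eccentricityDims gradient dimensions for eccentricity/dispersion,
#'   default 3.
#' @param eccentricityAggregate "mean" or "sumsq", default "mean".
#' @param nBins histogram bins, default 50.
#' @param alpha significance level, default 0.05.
#' @param signedMedianDistance keep the sign of median differences,
#'   default FALSE.
#' @param genderLevels two labels; the first codes 0, the second 1.
#' @param seed integer seed recorded in manifests.
#' @return a validated [RunConfig-class] object.
#' @examples
#' runConfig()
#' runConfig(sparsity = 0.9, nGradients = 5)
#' @export
runConfig <- function(sparsity = 0.95, kernel = "cosine", nGradients = 10L,
                      eccentricityDims = 3L, eccentricityAggregate = "mean",
                      nBins = 50L, alpha = 0.05,
                      signedMedianDistance = FALSE,
                      genderLevels = c("female", "male"), seed = 1L) {
  new("RunConfig", sparsity = sparsity, kernel = kernel,
      nGradients = as.integer(nGradients),
      eccentricityDims = as.integer(eccentricityDims),
      eccentricityAggregate = eccentricityAggregate,
      nBins = as.integer(nBins), alpha = alpha,
      signedMedianDistance = isTRUE(signedMedianDistance),
      genderLevels = genderLevels, seed = as.integer(seed))
}

#' Read a connectivity matrix from tab-delimited text
#'
#' The file dialect is tab-delimited, no header, row-major; parcel order is
#' defined solely by the accompanying partition file. Matrices asymmetric
#' beyond 1e-8 or containing NaN are rejected.
#'
#' @param path file path.
#' @param expectedParcels optional parcel count to enforce.
#' @param parcelIds optional parcel identifiers.
#' @return a [ConnectivityMatrix-class].
#' @seealso [writeConnectivityMatrix()]
#' @export
readConnectivityMatrix <- function(path, expectedParcels = NULL,
                                   parcelIds = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t",
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m))
    stop("file ", path, " is not square: ", nrow(m), " x ", ncol(m))
  if (!is.null(expectedParcels) && nrow(m) != expectedParcels)
    stop("expected ", expectedParcels, " parcels, file has ", nrow(m))
  connectivityMatrix(m, parcelIds = parcelIds)
}

#' Write a connectivity matrix as tab-delimited text
#'
#' Values are written at full precision (17 significant digits) so that a
#' write/read round trip is bit-identical.
#'
#' @param x a [ConnectivityMatrix-class] or numeric matrix.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeConnectivityMatrix <- function(x, path) {
  m <- if (is(x, "ConnectivityMatrix")) x@values else as.matrix(x)
  lines <- apply(m, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parcel-to-network partition table
#'
#' Expects a two-column tab-delimited table (parcel_id, network) with a
#' header line. Parcel order in the file defines matrix row order.
#'
#' @param path file path.
#' @return a [NetworkPartition-class].
#' @seealso [writeNetworkPartition()]
#' @export
readNetworkPartition <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2L)
    stop("partition file must have two columns: parcel_id, network")
  if (anyDuplicated(tab[[1L]]))
    stop("duplicate parcel ids in ", path)
  networkPartition(tab[[1L]], tab[[2L]])
}

#' Write a partition table
#'
#' @param x a [NetworkPartition-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeNetworkPartition <- function(x, path) {
  utils::write.table(
    data.frame(parcel_id = x@parcelIds, network = x@networks),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a participant table
#'
#' Comma-separated table with one row per subject. Expected columns include
#' subject_id, aq_total, gsq_total, age, gender, fd, dvars; extra columns
#' (e.g. GSQ subscales) are kept. Score totals are validated against their
#' closed ranges (AQ 0-50, GSQ 0-168).
#'
#' @param path CSV file path.
#' @return data.frame of participants.
#' @export
readParticipantTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateParticipantTable(tab)
}

#' Validate a participant table
#'
#' @param tab data.frame with at least subject_id; aq_total/gsq_total are
#'   range-checked when present.
#' @return the validated data.frame, invisibly unchanged.
#' @export
validateParticipantTable <- function(tab) {
  if (!"subject_id" %in% names(tab))
    stop("participant table needs a subject_id column")
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject ids")
  if ("aq_total" %in% names(tab) &&
      any(tab$aq_total < 0 | tab$aq_total > 50, na.rm = TRUE))
    stop("aq_total outside [0, 50]")
  if ("gsq_total" %in% names(tab) &&
      any(tab$gsq_total < 0 | tab$gsq_total > 168, na.rm = TRUE))
    stop("gsq_total outside [0, 168]")
  tab
}

#' Write a participant table
#'
#' @param tab data.frame of participants.
#' @param path CSV output path.
#' @return invisibly, the path.
#' @export
writeParticipantTable <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a RunConfig to YAML or JSON
#'
#' @param config a [RunConfig-class].
#' @param path output path ending in .yaml, .yml or .json.
#' @return invisibly, the path.
#' @export
writeRunConfig <- function(config, path) {
  lst <- list(
    sparsity = config@sparsity, kernel = config@kernel,
    n_gradients = config@nGradients,
    eccentricity_dims = config@eccentricityDims,
    eccentricity_aggregate = config@eccentricityAggregate,
    n_bins = config@nBins, alpha = config@alpha,
    signed_median_distance = config@signedMedianDistance,
    gender_levels = config@genderLevels, seed = config@seed)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' Read a RunConfig from YAML or JSON
#'
#' Fields absent from the file keep their defaults.
#'
#' @param path .yaml/.yml or .json file written by [writeRunConfig()].
#' @return a [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- runConfig()
  pick <- function(key, default) if (is.null(lst[[key]])) default else lst[[key]]
  runConfig(
    sparsity = pick("sparsity", defaults@sparsity),
    kernel = pick("kernel", defaults@kernel),
    nGradients = pick("n_gradients", defaults@nGradients),
    eccentricityDims = pick("eccentricity_dims", defaults@eccentricityDims),
    eccentricityAggregate = pick("eccentricity_aggregate",
                                 defaults@eccentricityAggregate),
    nBins = pick("n_bins", defaults@nBins),
    alpha = pick("alpha", defaults@alpha),
    signedMedianDistance = pick("signed_median_distance",
                                defaults@signedMedianDistance),
    genderLevels = pick("gender_levels", defaults@genderLevels),
    seed = pick("seed", defaults@seed))
}

#' Write a GradientSet as TSV plus a JSON sidecar
#'
#' Scores go to \code{path} (P rows x G tab-separated columns, no header);
#' explained variance and the alignment flag go to \code{<path>.json}.
#'
#' @param g a [GradientSet-class].
#' @param path TSV output path.
#' @return invisibly, the path.
#' @export
writeGradientSet <- function(g, path) {
  lines <- apply(g@scores, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  writeLines(lines, path)
  jsonlite::write_json(
    list(explained_variance = g@explainedVariance, aligned = g@aligned),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GradientSet written by [writeGradientSet()]
#'
#' @param path TSV path; the \code{<path>.json} sidecar must exist.
#' @return a [GradientSet-class].
#' @export
readGradientSet <- function(path) {
  scores <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  dimnames(scores) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  gradientSet(scores, side$explained_variance, aligned = isTRUE(side$aligned))
}

#' Write a SegregationReport as tidy TSV
#'
#' One row per subject x metric with columns (subject, metric, network_a,
#' network_b, dims, value).
#'
#' @param report a [SegregationReport-class].
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeSegregationReport <- function(report, path) {
  utils::write.table(report@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
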