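#' Parcel identifiers of an object
#'
#' @param x a NetworkPartition, ConnectivityMatrix or GradientSet.
#' @return character vector of parcel ids.
#' @export
setGeneric("parcelIds", function(x) standardGeneric("parcelIds"))

#' Number of parcels
#'
#' @param x a NetworkPartition, ConnectivityMatrix or GradientSet.
#' @return integer parcel count.
#' @export
setGeneric("nParcels", function(x) standardGeneric("nParcels"))

#' Network membership of each parcel
#'
#' @param x a NetworkPartition.
#' @return character vector naming each parcel's network, parallel to
#'   \code{parcelIds(x)}.
#' @export
setGeneric("networkOf", function(x) standardGeneric("networkOf"))

#' Canonical network names
#'
#' @param x a NetworkPartition.
#' @return character vector of the K network names in display order.
#' @export
setGeneric("networkNames", function(x) standardGeneric("networkNames"))

#' Gradient score matrix
#'
#' @param x a GradientSet.
#' @return numeric P x G matrix of gradient scores.
#' @export
setGeneric("gradientScores", function(x) standardGeneric("gradientScores"))

#' Explained-variance fractions
#'
#' @param x a GradientSet.
#' @return numeric vector of variance fractions, one per component.
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' Whether a GradientSet has been Procrustes-aligned
#'
#' @param x a GradientSet.
#' @return logical flag.
#' @export
setGeneric("isAligned", function(x) standardGeneric("isAligned"))

#' Tidy metric table of a SegregationReport
#'
#' @param x a SegregationReport.
#' @return data.frame with columns subject, metric, network_a, network_b,
#'   dims, value.
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))

#' @describeIn parcelIds parcel ids of a partition
setMethod("parcelIds", "NetworkPartition", function(x) x@parcelIds)

#' @describeIn parcelIds parcel ids aligned to matrix rows
setMethod("parcelIds", "ConnectivityMatrix", function(x) x@parcelIds)

#' @describeIn nParcels parcels in a partition
setMethod("nParcels", "NetworkPartition", function(x) length(x@parcelIds))

#' @describeIn nParcels matrix dimension
setMethod("nParcels", "ConnectivityMatrix", function(x) nrow(x@values))

#' @describeIn nParcels rows of the score matrix
setMethod("nParcels", "GradientSet", function(x) nrow(x@scores))

#' @describeIn networkOf per-parcel network names
setMethod("networkOf", "NetworkPartition", function(x) {
  stats::setNames(x@networks, x@parcelIds)
})

#' @describeIn networkNames display-order network names
setMethod("networkNames", "NetworkPartition", function(x) x@networkOrder)

#' @describeIn gradientScores score matrix accessor
setMethod("gradientScores", "GradientSet", function(x) x@scores)

#' @describeIn explainedVariance variance-fraction accessor
setMethod("explainedVariance", "GradientSet", function(x) x@explainedVariance)

#' @describeIn isAligned alignment flag accessor
setMethod("isAligned", "GradientSet", function(x) x@aligned)

#' @describeIn metricsTable tidy table accessor
setMethod("metricsTable", "SegregationReport", function(x) x@table)

#' Coerce a ConnectivityMatrix to a base matrix
#'
#' @param x a ConnectivityMatrix.
#' @param ... ignored.
#' @return the underlying numeric matrix with parcel ids as dimnames.
#' @export
setMethod("as.matrix", "ConnectivityMatrix", function(x, ...) {
  m <- x@values
  dimnames(m) <- list(x@parcelIds, x@parcelIds)
  m
})

setMethod("show", "NetworkPartition", function(object) {
  sizes <- table(factor(object@networks, levels = object@networkOrder))
  cat("NetworkPartition:", length(object@parcelIds), "parcels over",
      length(object@networkOrder), "networks\n")
  cat(paste0("  ", names(sizes), " (", as.integer(sizes), ")", collapse = "\n"),
      "\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix:", nrow(object@values), "x", ncol(object@values),
      "Pearson correlations\n")
  off <- object@values[row(object@values) != col(object@values)]
  cat(sprintf("  off-diagonal range [%.3f, %.3f]\n", min(off), max(off)))
})

setMethod("show", "GradientSet", function(object) {
  cat("GradientSet:", nrow(object@scores), "parcels x",
      ncol(object@scores), "gradients",
      if (object@aligned) "(Procrustes-aligned)" else "(unaligned)", "\n")
  ev <- object@explainedVariance
  cat("  explained variance:",
      paste(sprintf("%.3f", ev[seq_len(min(5L, length(ev)))]), collapse = " "),
      if (length(ev) > 5L) "..." else "", "\n")
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: sparsity", object@sparsity, "| kernel", object@kernel,
      "|", object@nGradients, "gradients | dims", object@eccentricityDims,
      "|", object@nBins, "bins | alpha", object@alpha, "\n")
})

setMethod("show", "SegregationReport", function(object) {
  cat("SegregationReport:", nrow(object@table), "metric values for",
      length(unique(object@table$subject)), "subject(s)\n")
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nSubjects, "subjects,", object@nParcels,
      "parcels,", length(object@networkNames), "networks\n")
  cat("  planted trait-expansion Spearman: GSQ", object@plantedRhoGSQ,
      "| AQ", object@plantedRhoAQ, "\n")
})
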