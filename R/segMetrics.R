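#' @keywords internal
#' @noRd
networkScores <- function(g, partition, network, dims = NULL) {
  nets <- if (is(partition, "NetworkPartition")) partition@networks else partition
  if (!network %in% nets)
    stop("unknown network: ", network)
  s <- gradientScores(g)
  if (is.null(dims)) return(s[nets == network, 1L, drop = TRUE])
  if (dims > ncol(s))
    stop("dims = ", dims, " exceeds available gradients (", ncol(s), ")")
  s[nets == network, seq_len(dims), drop = FALSE]
}

#' Network median distance along one gradient
#'
#' The absolute difference between the median gradient scores of two
#' networks, by default on the principal gradient. This is the primary
#' proxy for compression/expansion of the connectome hierarchy: the larger
#' the value, the more segregated the two networks are along that axis.
#'
#' @param g a [GradientSet-class].
#' @param partition a [NetworkPartition-class].
#' @param netA,netB network names (must differ).
#' @param component gradient index, default 1 (the principal gradient).
#' @param signed if TRUE return median(netA) - median(netB) without the
#'   absolute value.
#' @return non-negative distance (signed difference when \code{signed}).
#' @export
networkMedianDistance <- function(g, partition, netA, netB, component = 1L,
                                  signed = FALSE) {
  if (identical(netA, netB))
    stop("netA and netB must differ")
  s <- gradientScores(g)
  if (component > ncol(s))
    stop("component out of range")
  nets <- partition@networks
  if (!netA %in% nets) stop("unknown network: ", netA)
  if (!netB %in% nets) stop("unknown network: ", netB)
  d <- stats::median(s[nets == netA, component]) -
       stats::median(s[nets == netB, component])
  if (signed) d else abs(d)
}

#' Gradient range and standard deviation
#'
#' Global spread measures of the principal gradient: \code{gradientRange}
#' is max - min of the scores, \code{gradientSD} their sample (n-1)
#' standard deviation. Both ignore network structure.
#'
#' @param g a [GradientSet-class].
#' @param component gradient index, default 1.
#' @return non-negative scalar.
#' @export
gradientRange <- function(g, component = 1L) {
  s <- gradientScores(g)[, component]
  max(s) - min(s)
}

#' @rdname gradientRange
#' @export
gradientSD <- function(g, component = 1L) {
  stats::sd(gradientScores(g)[, component])
}

# KDE peak location: Gaussian kernel, Silverman bandwidth, argmax on a
# 512-point grid over [min - 3h, max + 3h]; ties go to the lower score.
kdePeak <- function(x) {
  h <- stats::bw.nrd0(x)
  den <- stats::density(x, bw = h, kernel = "gaussian", n = 512L,
                        from = min(x) - 3 * h, to = max(x) + 3 * h)
  den$x[which.max(den$y)]
}

#' Network peak distance along the principal gradient
#'
#' The absolute difference between the dominant-mode locations of two
#' networks' gradient-score distributions. The mode is located as the
#' argmax of a Gaussian kernel density estimate (Silverman bandwidth,
#' 512-point grid spanning [min - 3h, max + 3h]); ties resolve to the
#' lower score. Peaks of flat distributions are poorly determined, which
#' is the metric's known weakness.
#'
#' @inheritParams networkMedianDistance
#' @return non-negative distance.
#' @export
networkPeakDistance <- function(g, partition, netA, netB, component = 1L) {
  if (identical(netA, netB))
    stop("netA and netB must differ")
  s <- gradientScores(g)
  nets <- partition@networks
  for (net in c(netA, netB)) {
    if (!net %in% nets) stop("unknown network: ", net)
    if (sum(nets == net) < 5L)
      stop("network ", net, " has fewer than 5 parcels; density peak unreliable")
  }
  abs(kdePeak(s[nets == netA, component]) - kdePeak(s[nets == netB, component]))
}

#' Network eccentricity in gradient space
#'
#' Distance of a network from the origin of the space spanned by the first
#' \code{dims} gradients: each parcel's Euclidean norm over those
#' coordinates, aggregated per network. High eccentricity indicates a
#' segregated network, low values an integrated one. The default
#' aggregate is the mean norm; \code{aggregate = "sumsq"} returns the sum
#' of squared norms instead.
#'
#' @param g a [GradientSet-class].
#' @param partition a [NetworkPartition-class], or NULL with
#'   \code{network = NULL} for the global value.
#' @param network network name, or NULL for the global (all-parcel) value.
#' @param dims leading gradient dimensions, default 3.
#' @param aggregate "mean" or "sumsq".
#' @return non-negative scalar.
#' @export
eccentricity <- function(g, partition = NULL, network = NULL, dims = 3L,
                         aggregate = c("mean", "sumsq")) {
  aggregate <- match.arg(aggregate)
  s <- gradientScores(g)
  if (dims > ncol(s))
    stop("dims = ", dims, " exceeds available gradients (", ncol(s), ")")
  x <- if (is.null(network)) s[, seq_len(dims), drop = FALSE]
       else networkScores(g, partition, network, dims)
  norms <- sqrt(rowSums(x^2))
  if (aggregate == "mean") mean(norms) else sum(norms^2)
}

# coordinate-wise median centroid over the first `dims` gradients
networkCentroid <- function(g, partition, network, dims) {
  x <- networkScores(g, partition, network, dims)
  apply(x, 2L, stats::median)
}

#' Within-network dispersion
#'
#' Sum of squared Euclidean distances of a network's parcels from the
#' network centroid (the coordinate-wise median of its gradient scores)
#' in the space of the first \code{dims} gradients. Captures how
#' differentiated the connectivity profiles within one network are.
#'
#' @inheritParams eccentricity
#' @param network network name.
#' @return non-negative squared distance.
#' @export
withinDispersion <- function(g, partition, network, dims = 3L) {
  x <- networkScores(g, partition, network, dims)
  ctr <- apply(x, 2L, stats::median)
  sum(sweep(x, 2L, ctr)^2)
}

#' Between-network dispersion
#'
#' Euclidean distance between two network centroids (coordinate-wise
#' medians) in the space of the first \code{dims} gradients. At
#' \code{dims = 1} this reduces exactly to [networkMedianDistance()].
#'
#' @inheritParams networkMedianDistance
#' @param dims leading gradient dimensions, default 3.
#' @return non-negative distance.
#' @export
betweenDispersion <- function(g, partition, netA, netB, dims = 3L) {
  if (identical(netA, netB))
    stop("netA and netB must differ")
  d <- networkCentroid(g, partition, netA, dims) -
       networkCentroid(g, partition, netB, dims)
  sqrt(sum(d^2))
}

#' Bin principal-gradient scores into a histogram
#'
#' Divides the gradient-1 scores into \code{nBins} equal-width bins (51
#' edges for the default 50 bins) spanning the observed range, or uses the
#' supplied edges. Counts conserve the parcel total. With a partition,
#' counts are additionally stratified by network.
#'
#' @param g a [GradientSet-class].
#' @param nBins bin count, default 50.
#' @param edges optional explicit vector of bin edges (length nBins + 1);
#'   overrides \code{nBins}. Needed to average histograms across subjects.
#' @param partition optional [NetworkPartition-class] for per-network
#'   stratification.
#' @param component gradient index, default 1.
#' @return list with \code{edges}, \code{counts}, and (if stratified)
#'   \code{network_counts} (K x nBins matrix).
#' @export
binGradient <- function(g, nBins = 50L, edges = NULL, partition = NULL,
                        component = 1L) {
  s <- gradientScores(g)[, component]
  if (is.null(edges)) {
    edges <- seq(min(s), max(s), length.out = nBins + 1L)
  }
  if (min(s) < edges[1L] || max(s) > edges[length(edges)])
    stop("scores fall outside the supplied bin edges")
  # left-closed bins [e_k, e_{k+1}); the top edge is included in the last bin
  idx <- .bincode(s, edges, right = FALSE, include.lowest = TRUE)
  nb <- length(edges) - 1L
  counts <- tabulate(idx, nbins = nb)
  out <- list(edges = edges, counts = counts)
  if (!is.null(partition)) {
    nets <- networkNames(partition)
    nc <- t(vapply(nets, function(net)
      tabulate(idx[partition@networks == net], nbins = nb),
      integer(nb)))
    rownames(nc) <- nets
    out$network_counts <- nc
  }
  out
}

#' Average binned distributions across participants
#'
#' Element-wise mean of per-subject bin counts computed on identical
#' edges. The average preserves the total count (parcels per subject).
#'
#' @param bins list of results from [binGradient()] sharing edges.
#' @return a binned distribution with averaged (fractional) counts.
#' @export
averageBins <- function(bins) {
  if (!length(bins)) stop("need at least one binned distribution")
  edges <- bins[[1L]]$edges
  for (b in bins) {
    if (length(b$edges) != length(edges) ||
        max(abs(b$edges - edges)) > 1e-12)
      stop("bin edges differ across participants; rebin on common edges")
  }
  counts <- Reduce(`+`, lapply(bins, `[[`, "counts")) / length(bins)
  out <- list(edges = edges, counts = counts)
  if (!is.null(bins[[1L]]$network_counts)) {
    out$network_counts <-
      Reduce(`+`, lapply(bins, `[[`, "network_counts")) / length(bins)
  }
  out
}

#' All segregation metrics for one or more subjects
#'
#' Computes the full metric battery from aligned gradients: pairwise
#' network median distance, peak distance and between-network dispersion
#' for all K(K-1)/2 network pairs; eccentricity (network and global),
#' within-network dispersion and median score per network; and global
#' gradient range, SD and the principal explained-variance fraction.
#'
#' @param gradients a [GradientSet-class] or named list of them (one per
#'   subject).
#' @param partition a [NetworkPartition-class].
#' @param config a [RunConfig-class]; supplies eccentricity dims/aggregate
#'   and the signed-distance flag.
#' @param peaks compute the KDE peak distance as well (slowest metric).
#' @return a [SegregationReport-class].
#' @export
segregationReport <- function(gradients, partition, config = runConfig(),
                              peaks = TRUE) {
  if (is(gradients, "GradientSet")) gradients <- list(s1 = gradients)
  if (is.null(names(gradients)))
    names(gradients) <- paste0("s", seq_along(gradients))
  nets <- networkNames(partition)
  pairs <- utils::combn(nets, 2L)
  dims <- config@eccentricityDims
  rows <- vector("list", length(gradients))
  for (si in seq_along(gradients)) {
    g <- gradients[[si]]
    id <- names(gradients)[si]
    tabs <- list()
    npairs <- ncol(pairs)
    md <- pd <- bd <- numeric(npairs)
    for (k in seq_len(npairs)) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      md[k] <- networkMedianDistance(g, partition, a, b,
                                     signed = config@signedMedianDistance)
      bd[k] <- betweenDispersion(g, partition, a, b, dims = dims)
      pd[k] <- if (peaks) networkPeakDistance(g, partition, a, b) else NA_real_
    }
    tabs$pairs <- data.frame(
      subject = id,
      metric = rep(c("median_distance", "between_dispersion", "peak_distance"),
                   each = npairs),
      network_a = rep(pairs[1L, ], 3L),
      network_b = rep(pairs[2L, ], 3L),
      dims = rep(c(1L, dims, 1L), each = npairs),
      value = c(md, bd, pd))
    ecc <- vapply(nets, function(n)
      eccentricity(g, partition, n, dims = dims,
                   aggregate = config@eccentricityAggregate), numeric(1))
    wd <- vapply(nets, function(n)
      withinDispersion(g, partition, n, dims = dims), numeric(1))
    meds <- vapply(nets, function(n)
      stats::median(networkScores(g, partition, n)), numeric(1))
    tabs$nets <- data.frame(
      subject = id,
      metric = rep(c("eccentricity", "within_dispersion", "median_score"),
                   each = length(nets)),
      network_a = rep(nets, 3L),
      network_b = NA_character_,
      dims = rep(c(dims, dims, 1L), each = length(nets)),
      value = c(ecc, wd, meds))
    tabs$globals <- data.frame(
      subject = id,
      metric = c("gradient_range", "gradient_sd", "global_eccentricity",
                 "variance_explained_g1"),
      network_a = NA_character_, network_b = NA_character_,
      dims = c(1L, 1L, dims, 1L),
      value = c(gradientRange(g), gradientSD(g),
                eccentricity(g, dims = dims,
                             aggregate = config@eccentricityAggregate),
                varianceExplained(g, 1L)))
    rows[[si]] <- do.call(rbind, tabs)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("SegregationReport", table = tab)
}
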