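#' Pearson correlation matrix of a parcellated time series
#'
#' Builds the subject-level connectome: the parcel-by-parcel Pearson
#' correlation of a T x P time-series matrix (T timepoints, P parcel-mean
#' BOLD signals). Columns with zero variance make the correlation
#' undefined and raise an error naming the parcel.
#'
#' @param ts numeric T x P matrix, T >= 3.
#' @param parcelIds optional parcel identifiers; defaults to colnames.
#' @return a [ConnectivityMatrix-class].
#' @examples
#' ts <- matrix(rnorm(60), nrow = 20)
#' correlateTimeSeries(ts)
#' @export
correlateTimeSeries <- function(ts, parcelIds = NULL) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L)
    stop("need at least 3 timepoints, got ", nrow(ts))
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    ids <- if (!is.null(colnames(ts))) colnames(ts)[bad] else bad
    stop("zero-variance parcel time series: ",
         paste(ids, collapse = ", "))
  }
  r <- stats::cor(ts)
  # clamp rounding spill past +/-1 and force exact unit diagonal
  r[r > 1] <- 1
  r[r < -1] <- -1
  r <- (r + t(r)) / 2
  diag(r) <- 1
  if (is.null(parcelIds)) parcelIds <- colnames(ts)
  connectivityMatrix(r, parcelIds = parcelIds)
}

#' Residualize parcel time series on motion traces
#'
#' Ordinary-least-squares nuisance regression: each parcel time course is
#' replaced by its residual after regressing on the supplied motion trace
#' columns (plus an intercept). Exactly the supplied columns are used; no
#' derivatives or squared terms are added.
#'
#' @param ts numeric T x P parcel time-series matrix.
#' @param motion numeric T x M matrix of realignment traces.
#' @return residual T x P matrix.
#' @export
regressMotion <- function(ts, motion) {
  ts <- as.matrix(ts); motion <- as.matrix(motion)
  if (nrow(ts) != nrow(motion))
    stop("time series and motion traces disagree on T: ",
         nrow(ts), " vs ", nrow(motion))
  stats::lm.fit(cbind(1, motion), ts)$residuals
}

#' Fisher r-to-z transform
#'
#' z = atanh(r), making correlations approximately additive so they can be
#' averaged across subjects. Undefined at |r| = 1, which is why matrix
#' diagonals are excluded from the transform.
#'
#' @param r correlations with |r| < 1.
#' @return z values.
#' @examples
#' fisherZ(0.5)          # 0.5493061
#' fisherZInverse(fisherZ(0.73))  # 0.73
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1))
    stop("fisher z undefined for |r| >= 1")
  atanh(r)
}

#' Fisher z-to-r back-transform
#'
#' @param z z values.
#' @return correlations tanh(z).
#' @rdname fisherZ
#' @export
fisherZInverse <- function(z) tanh(z)

#' Fisher-z group average of connectivity matrices
#'
#' Off-diagonal entries are z-transformed, averaged element-wise across
#' subjects, and the mean back-transformed to r; the diagonal is restored
#' to 1. Off-diagonal values with |r| >= 1 - 1e-12 (degenerate duplicated
#' signals) are clipped to that bound with a warning rather than failing.
#'
#' @param matrices list of [ConnectivityMatrix-class] with identical parcel
#'   order.
#' @return the group-average [ConnectivityMatrix-class].
#' @export
groupAverage <- function(matrices) {
  if (!length(matrices))
    stop("need at least one matrix")
  ids <- parcelIds(matrices[[1L]])
  p <- length(ids)
  zsum <- matrix(0, p, p)
  clipped <- 0L
  bound <- 1 - 1e-12
  for (m in matrices) {
    if (!identical(parcelIds(m), ids))
      stop("parcel order mismatch across subjects")
    v <- m@values
    off <- row(v) != col(v)
    nclip <- sum(abs(v[off]) > bound)
    if (nclip > 0L) {
      clipped <- clipped + nclip
      v[off & v > bound] <- bound
      v[off & v < -bound] <- -bound
    }
    diag(v) <- 0
    zsum <- zsum + atanh(v)
  }
  if (clipped > 0L)
    warning(clipped, " off-diagonal |r| >= 1 - 1e-12 value(s) clipped before z-transform")
  avg <- tanh(zsum / length(matrices))
  diag(avg) <- 1
  connectivityMatrix(avg, parcelIds = ids)
}
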