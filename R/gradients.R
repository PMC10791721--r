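#' Row-wise sparsification of a connectome
#'
#' Within each row, the smallest \code{floor(sparsity * P)} entries by
#' signed value are set to zero (negatives are removed first) and the
#' survivors keep their values. Ties are broken deterministically: among
#' equal values, the lower parcel index is zeroed first. The result is not
#' re-symmetrized; the affinity kernel consumes rows as connectivity
#' profiles.
#'
#' @param m a [ConnectivityMatrix-class] or numeric square matrix.
#' @param sparsity fraction in [0, 1) of each row to zero; 0.95 keeps the
#'   top 5 percent of connections per parcel.
#' @return numeric P x P row-sparsified matrix.
#' @examples
#' m <- matrix(runif(400), 20, 20); m <- (m + t(m)) / 2; diag(m) <- 1
#' s <- sparsifyRows(m, 0.95)
#' rowSums(s != 0)  # one survivor per row at P = 20
#' @export
sparsifyRows <- function(m, sparsity = 0.95) {
  if (length(sparsity) != 1L || is.na(sparsity) || sparsity < 0 || sparsity >= 1)
    stop("sparsity must lie in [0, 1)")
  v <- if (is(m, "ConnectivityMatrix")) m@values else as.matrix(m)
  p <- ncol(v)
  k <- floor(sparsity * p)
  if (k == 0L) return(v)
  out <- v
  for (i in seq_len(nrow(v))) {
    ord <- order(v[i, ], seq_len(p))  # ascending value, ties by lower index
    out[i, ord[seq_len(k)]] <- 0
  }
  out
}

#' Cosine affinity of connectivity profiles
#'
#' affinity[i, j] = <row_i, row_j> / (||row_i|| ||row_j||) on the (usually
#' sparsified) connectome rows. All-zero rows have no direction and raise
#' an error naming the parcel.
#'
#' @param m numeric P x P matrix, typically the output of [sparsifyRows()].
#' @return symmetric P x P affinity matrix with unit diagonal.
#' @export
cosineAffinity <- function(m) {
  m <- as.matrix(m)
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0))
    stop("all-zero connectivity row(s) for parcel(s): ",
         paste(which(norms == 0), collapse = ", "))
  a <- tcrossprod(m / norms)
  a <- (a + t(a)) / 2
  a[a > 1] <- 1
  a[a < -1] <- -1
  diag(a) <- 1
  a
}

#' PCA gradients of an affinity matrix
#'
#' Columns of the affinity are mean-centred and the rows projected onto the
#' top \code{nGradients} principal axes (via singular value decomposition).
#' Each component's explained variance is its eigenvalue as a fraction of
#' the total variance. PCA signs are arbitrary; a deterministic convention
#' is applied: the element of largest absolute score in each component is
#' made positive.
#'
#' @param a symmetric P x P affinity matrix.
#' @param nGradients number of components to keep (<= P).
#' @return an unaligned [GradientSet-class].
#' @export
pcaGradients <- function(a, nGradients = 10L) {
  a <- as.matrix(a)
  p <- nrow(a)
  if (nGradients > p)
    stop("nGradients (", nGradients, ") exceeds parcel count (", p, ")")
  if (!all(is.finite(a)))
    stop("affinity contains non-finite values")
  xc <- sweep(a, 2L, colMeans(a))
  total <- sum(xc^2)
  if (total < .Machine$double.eps * p * p)
    stop("affinity has zero variance after centring (all rows identical?)")
  sv <- svd(xc, nu = nGradients, nv = 0L)
  rank <- sum(sv$d > max(sv$d) * p * .Machine$double.eps)
  if (rank < nGradients)
    stop("affinity rank ", rank, " is below nGradients = ", nGradients,
         "; request fewer gradients")
  d <- sv$d[seq_len(nGradients)]
  scores <- sv$u %*% diag(d, nGradients, nGradients)
  scores <- fixComponentSigns(scores)
  gradientSet(scores, d^2 / sum(sv$d^2), aligned = FALSE)
}

# sign convention: largest-|score| element of each column made positive;
# ties resolved to the first (lowest) index by which.max
fixComponentSigns <- function(scores) {
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  scores
}

#' Explained-variance fraction of one gradient
#'
#' @param g a [GradientSet-class].
#' @param component 1-based component index.
#' @return fraction in [0, 1].
#' @export
varianceExplained <- function(g, component = 1L) {
  ev <- explainedVariance(g)
  if (component < 1L || component > length(ev))
    stop("component ", component, " out of range 1..", length(ev))
  ev[[component]]
}

#' Procrustes alignment of gradients to a reference
#'
#' Finds the orthogonal matrix R (rotation and/or reflection, no scaling,
#' no translation) minimizing the Frobenius distance
#' \code{||scores %*% R - reference||} and returns the rotated scores.
#' This brings individual embeddings into the group reference frame so
#' that gradient scores are comparable across subjects. When the
#' individual equals the reference times an orthogonal matrix, recovery
#' is exact.
#'
#' @param individual a [GradientSet-class] (or score matrix) to align.
#' @param reference a [GradientSet-class] (or score matrix), same P and G.
#' @return an aligned [GradientSet-class] carrying the individual's
#'   explained variance.
#' @export
procrustesAlign <- function(individual, reference) {
  x <- if (is(individual, "GradientSet")) individual@scores else as.matrix(individual)
  ref <- if (is(reference, "GradientSet")) reference@scores else as.matrix(reference)
  if (!all(dim(x) == dim(ref)))
    stop("shape mismatch: individual is ", nrow(x), "x", ncol(x),
         ", reference is ", nrow(ref), "x", ncol(ref))
  sv <- svd(crossprod(x, ref))
  rot <- sv$u %*% t(sv$v)
  ev <- if (is(individual, "GradientSet")) individual@explainedVariance
        else rep(NA_real_, ncol(x))
  gradientSet(x %*% rot, ev, aligned = TRUE)
}

#' Full gradient extraction from a connectome
#'
#' Convenience wrapper chaining [sparsifyRows()], [cosineAffinity()] and
#' [pcaGradients()], optionally Procrustes-aligning the result to a
#' reference GradientSet.
#'
#' @param m a [ConnectivityMatrix-class] or numeric matrix.
#' @param config a [RunConfig-class]; sparsity and nGradients are taken
#'   from it.
#' @param reference optional [GradientSet-class] to align to.
#' @return a [GradientSet-class], aligned iff a reference was given.
#' @export
computeGradients <- function(m, config = runConfig(), reference = NULL) {
  g <- pcaGradients(cosineAffinity(sparsifyRows(m, config@sparsity)),
                    config@nGradients)
  if (!is.null(reference)) {
    ev <- g@explainedVariance
    g <- procrustesAlign(g, reference)
    g@explainedVariance <- ev
  }
  g
}
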