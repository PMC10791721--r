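#' Spearman rank correlation with a two-sided p-value
#'
#' Tie-corrected Spearman coefficient (Pearson correlation of mid-ranks)
#' with a two-sided p-value from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
#' The approximation is the default for all n; exact permutation
#' enumeration is practical only for very small samples and is used as a
#' test oracle, not here.
#'
#' @param x,y numeric vectors of equal length n >= 4.
#' @return list with \code{rho}, \code{p} and \code{n}.
#' @examples
#' spearmanAssociation(1:10, (1:10)^3)  # rho = 1
#' @export
spearmanAssociation <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L)
    stop("need at least 4 observations, got ", n)
  if (anyNA(x) || anyNA(y))
    stop("missing values in inputs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}

#' Covariate-adjusted linear model for a segregation metric
#'
#' Ordinary least squares of the metric on trait scores and nuisance
#' covariates (age, gender, FD, DVARS), with an intercept, all on their
#' raw scales. Returns the coefficient table with two-sided t-test
#' p-values. Collinear designs are rejected with the offending columns
#' named.
#'
#' @param metric numeric response vector (one value per subject).
#' @param covariates data.frame of predictors (e.g. aq_total, gsq_total,
#'   age, gender01, fd, dvars); all columns are entered as given.
#' @return data.frame with columns term, beta, se, t, p plus attributes
#'   \code{n} and \code{r_squared}.
#' @export
fitCovariateModel <- function(metric, covariates) {
  covariates <- as.data.frame(covariates)
  n <- length(metric)
  if (nrow(covariates) != n)
    stop("metric and covariates disagree on n")
  if (n <= ncol(covariates) + 1L)
    stop("need n > number of covariates + 1")
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("collinear design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(metric ~ ., data = covariates)
  coefs <- summary(fit)$coefficients
  out <- data.frame(term = rownames(coefs), beta = coefs[, 1L],
                    se = coefs[, 2L], t = coefs[, 3L], p = coefs[, 4L],
                    row.names = NULL)
  attr(out, "n") <- n
  attr(out, "r_squared") <- summary(fit)$r.squared
  attr(out, "residuals") <- stats::residuals(fit)
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' alpha / nTests at full precision, with the 4-decimal display value the
#' tables quote (0.05 over 42 tests prints as 0.0012).
#'
#' @param alpha family-wise level, default 0.05.
#' @param nTests number of tests in the family (e.g. 21 network pairs x 2
#'   traits = 42).
#' @return list with \code{threshold} (full precision) and
#'   \code{displayed} (rounded to 4 decimals).
#' @examples
#' bonferroniThreshold(0.05, 42)
#' @export
bonferroniThreshold <- function(alpha = 0.05, nTests) {
  if (nTests < 1L) stop("nTests must be >= 1")
  thr <- alpha / nTests
  list(threshold = thr, displayed = round(thr, 4L))
}

#' Median split of a trait
#'
#' Splits subjects at the sample median: values <= threshold form the low
#' group, values > threshold the high group (ties go to the low group,
#' which is what makes tied samples split unevenly).
#'
#' @param values numeric trait values, n >= 2.
#' @return list with \code{threshold}, logical \code{high} membership,
#'   and the \code{low}/\code{high} index vectors.
#' @export
medianSplit <- function(values) {
  if (length(values) < 2L)
    stop("need at least 2 values")
  thr <- stats::median(values)
  high <- values > thr
  list(threshold = thr, high = high,
       low_idx = which(!high), high_idx = which(high))
}

#' Association grid of segregation metrics against traits
#'
#' For each pairwise metric family (median distance, between-network
#' dispersion, peak distance) computes the Spearman correlation of the
#' per-subject metric against each trait over all K(K-1)/2 network pairs,
#' and for the per-network families (eccentricity, within-network
#' dispersion) over the K networks plus the global value. Each family is
#' Bonferroni-flagged at alpha / (pairs x traits), the correction the
#' headline analysis applied (42 tests for K = 7 and two traits).
#'
#' @param report a [SegregationReport-class] covering all subjects.
#' @param traits data.frame with subject_id plus one column per trait
#'   (e.g. aq_total, gsq_total).
#' @param traitCols names of the trait columns, default
#'   \code{c("aq_total", "gsq_total")}.
#' @param alpha family-wise level, default 0.05.
#' @return data.frame with one row per metric x network(-pair) x trait:
#'   columns metric, network_a, network_b, trait, rho, p, n, bonferroni
#'   (logical), stars ("", "*", "**", "***" at 0.05/0.01/0.001).
#' @export
runAssociationGrid <- function(report, traits,
                               traitCols = c("aq_total", "gsq_total"),
                               alpha = 0.05) {
  tab <- metricsTable(report)
  missing <- setdiff(traitCols, names(traits))
  if (length(missing))
    stop("missing trait column(s): ", paste(missing, collapse = ", "))
  pairFams <- intersect(c("median_distance", "between_dispersion",
                          "peak_distance"), tab$metric)
  netFams <- intersect(c("eccentricity", "within_dispersion"), tab$metric)
  rows <- list()
  addRow <- function(metric, a, b, trait, vals, subj, nTests) {
    ord <- match(traits$subject_id, subj)
    if (anyNA(ord)) stop("subjects in traits missing from report")
    res <- spearmanAssociation(vals[ord], traits[[trait]])
    data.frame(metric = metric, network_a = a, network_b = b,
               trait = trait, rho = res$rho, p = res$p, n = res$n,
               bonferroni = res$p < alpha / nTests,
               stars = if (res$p < 0.001) "***" else if (res$p < 0.01) "**"
                       else if (res$p < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  }
  for (fam in pairFams) {
    sub <- tab[tab$metric == fam & !is.na(tab$value), ]
    pairKeys <- unique(sub[, c("network_a", "network_b")])
    nTests <- nrow(pairKeys) * length(traitCols)
    for (k in seq_len(nrow(pairKeys))) {
      sel <- sub$network_a == pairKeys$network_a[k] &
             sub$network_b == pairKeys$network_b[k]
      for (tr in traitCols) {
        rows[[length(rows) + 1L]] <-
          addRow(fam, pairKeys$network_a[k], pairKeys$network_b[k], tr,
                 sub$value[sel], sub$subject[sel], nTests)
      }
    }
  }
  for (fam in netFams) {
    sub <- tab[tab$metric == fam, ]
    nets <- unique(sub$network_a)
    glob <- if (fam == "eccentricity") "global_eccentricity" else NULL
    nTests <- (length(nets) + length(glob)) * length(traitCols)
    for (net in nets) {
      sel <- sub$network_a == net
      for (tr in traitCols) {
        rows[[length(rows) + 1L]] <-
          addRow(fam, net, NA_character_, tr,
                 sub$value[sel], sub$subject[sel], nTests)
      }
    }
    if (!is.null(glob)) {
      gsub <- tab[tab$metric == glob, ]
      for (tr in traitCols) {
        rows[[length(rows) + 1L]] <-
          addRow(glob, "global", NA_character_, tr,
                 gsub$value, gsub$subject, nTests)
      }
    }
  }
  for (fam in intersect(c("gradient_range", "gradient_sd",
                          "variance_explained_g1"), tab$metric)) {
    sub <- tab[tab$metric == fam, ]
    for (tr in traitCols) {
      rows[[length(rows) + 1L]] <-
        addRow(fam, NA_character_, NA_character_, tr,
               sub$value, sub$subject, length(traitCols))
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  # a Bonferroni flag can never pass a cell whose raw p exceeds alpha/nTests
  stopifnot(all(!grid$bonferroni | grid$p < alpha))
  grid
}

#' Lower-triangular table of a pairwise metric family
#'
#' Reshapes grid rows of one metric family and one trait into the K x K
#' lower-triangular layout used for reporting, with significance stars.
#'
#' @param grid output of [runAssociationGrid()].
#' @param metric metric family name (e.g. "median_distance").
#' @param trait trait column name.
#' @param networks network names in display order.
#' @return character matrix (K-1) x (K-1), lower triangle filled with
#'   "rho stars".
#' @export
gridTable <- function(grid, metric, trait, networks) {
  sub <- grid[grid$metric == metric & grid$trait == trait, ]
  k <- length(networks)
  out <- matrix("", k - 1L, k - 1L,
                dimnames = list(networks[-1L], networks[-k]))
  for (i in seq_len(nrow(sub))) {
    a <- sub$network_a[i]; b <- sub$network_b[i]
    ia <- match(a, networks); ib <- match(b, networks)
    lo <- networks[max(ia, ib)]; hi <- networks[min(ia, ib)]
    out[lo, hi] <- paste0(formatC(sub$rho[i], digits = 3, format = "f"),
                          sub$stars[i])
  }
  out
}
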