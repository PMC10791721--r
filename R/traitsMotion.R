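#' Score the 50-item AQ questionnaire
#'
#' Responses are on a 4-point agreement scale (1 = definitely agree,
#' 2 = slightly agree, 3 = slightly disagree, 4 = definitely disagree) and
#' are binarized for scoring: an item contributes 1 point iff the response
#' falls (slightly or definitely) on the item's keyed pole, so totals range
#' from 0 to 50. The scoring key (which pole is the trait-directed one per
#' item) is supplied as data, not hard-coded.
#'
#' @param responses integer vector of 50 responses in 1..4, or an n x 50
#'   matrix/data.frame (one row per subject).
#' @param key character vector of 50 entries, each "agree" or "disagree",
#'   naming the keyed pole of the item.
#' @return integer total in [0, 50], or a vector of totals for a matrix.
#' @export
scoreAQ <- function(responses, key) {
  if (length(key) != 50L || !all(key %in% c("agree", "disagree")))
    stop("key must be 50 entries of 'agree'/'disagree'")
  if (is.matrix(responses) || is.data.frame(responses)) {
    responses <- as.matrix(responses)
    if (ncol(responses) != 50L)
      stop("expected 50 AQ items, got ", ncol(responses))
    return(apply(responses, 1L, scoreAQ, key = key))
  }
  if (length(responses) != 50L)
    stop("expected 50 AQ items, got ", length(responses))
  if (anyNA(responses))
    stop("missing AQ item response(s): ", paste(which(is.na(responses)),
                                                collapse = ", "))
  if (!all(responses %in% 1:4))
    stop("AQ responses must be integers 1..4")
  agrees <- responses <= 2L
  sum(ifelse(key == "agree", agrees, !agrees))
}

#' GSQ item metadata table
#'
#' The 42-item layout: six items per sensory modality (vision, hearing,
#' olfaction, taste, touch, proprioception, vestibular), half targeting
#' hypersensitivity and half hyposensitivity (21 items each).
#'
#' @return data.frame with columns item, modality, polarity.
#' @export
gsqItemTable <- function() {
  modalities <- c("vision", "hearing", "olfaction", "taste", "touch",
                  "proprioception", "vestibular")
  data.frame(
    item = seq_len(42L),
    modality = rep(modalities, each = 6L),
    polarity = rep(rep(c("hyper", "hypo"), each = 3L), times = 7L),
    stringsAsFactors = FALSE)
}

#' Score the 42-item GSQ questionnaire
#'
#' Responses are on a 0-4 frequency scale (never = 0 ... always = 4); the
#' total is the sum over retained items, so the full-scale maximum is 168,
#' each polarity subscale (hyper/hypo) maxes at 84 and excluding one
#' modality leaves a maximum of 144.
#'
#' @param responses integer vector of 42 responses in 0..4, or an n x 42
#'   matrix/data.frame.
#' @param excludeModalities character vector of modalities to drop (e.g.
#'   "vision" for the vision-removed robustness score).
#' @param polarity "both" (default), "hyper" or "hypo".
#' @param items item metadata as from [gsqItemTable()].
#' @return integer total over the retained items.
#' @export
scoreGSQ <- function(responses, excludeModalities = character(),
                     polarity = c("both", "hyper", "hypo"),
                     items = gsqItemTable()) {
  polarity <- match.arg(polarity)
  if (is.matrix(responses) || is.data.frame(responses)) {
    responses <- as.matrix(responses)
    if (ncol(responses) != 42L)
      stop("expected 42 GSQ items, got ", ncol(responses))
    return(apply(responses, 1L, scoreGSQ,
                 excludeModalities = excludeModalities,
                 polarity = polarity, items = items))
  }
  if (length(responses) != 42L)
    stop("expected 42 GSQ items, got ", length(responses))
  if (anyNA(responses))
    stop("missing GSQ item response(s)")
  if (!all(responses %in% 0:4))
    stop("GSQ responses must be integers 0..4")
  keep <- !(items$modality %in% excludeModalities)
  if (polarity != "both") keep <- keep & items$polarity == polarity
  sum(responses[keep])
}

#' Framewise displacement from realignment parameters
#'
#' Per parameter trace, takes first differences over time, their absolute
#' values, and the median over timepoints; the subject summary is the mean
#' of the twelve per-parameter medians. A conventional alternative
#' (mean over time of the summed absolute differences) is available via
#' \code{method = "sum"}.
#'
#' @param traces numeric T x 12 matrix of realignment parameters, T >= 2.
#' @param method "median_mean" (default) or "sum".
#' @return framewise displacement in the traces' units (mm).
#' @export
computeFD <- function(traces, method = c("median_mean", "sum")) {
  method <- match.arg(method)
  traces <- as.matrix(traces)
  if (ncol(traces) != 12L)
    stop("expected 12 realignment parameter columns, got ", ncol(traces))
  if (nrow(traces) < 2L)
    stop("need at least 2 timepoints")
  ad <- abs(diff(traces))
  if (method == "median_mean") {
    mean(apply(ad, 2L, stats::median))
  } else {
    mean(rowSums(ad))
  }
}

#' DVARS from brain-masked time courses
#'
#' Volume-to-volume root mean square (over voxels) of the temporal
#' derivative of the masked time courses, summarizing high-amplitude
#' global signal change; the per-subject summary is the mean over volume
#' pairs.
#'
#' @param ts numeric T x V matrix (T volumes, V in-mask voxels), T >= 2.
#' @param summarize if FALSE return the length T-1 per-pair series.
#' @return mean DVARS (or the per-pair series).
#' @export
computeDVARS <- function(ts, summarize = TRUE) {
  ts <- as.matrix(ts)
  if (ncol(ts) == 0L)
    stop("empty brain mask: no voxels")
  if (nrow(ts) < 2L)
    stop("need at least 2 volumes")
  series <- sqrt(rowMeans(diff(ts)^2))
  if (summarize) mean(series) else series
}
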