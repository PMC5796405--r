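## Disorder scoring from predicted angle-bin distributions: normalized
## Shannon entropy per residue, sliding-window averaging, and rank-based
## AUC evaluation against binary disorder labels.

#' Normalized Shannon entropy of a bin distribution
#'
#' H = -sum(p * log p) with natural logarithm and 0*log(0) = 0, divided by
#' log(K) (the entropy of the uniform distribution over the K bins) so the
#' result lies in [0, 1]: 0 for a one-hot distribution, 1 for uniform.
#'
#' @param dist probability vector; entries >= 0 summing to 1 within 1e-6.
#' @return normalized entropy in [0, 1].
#' @export
normalizedEntropy <- function(dist) {
  if (any(dist < -1e-12) || abs(sum(dist) - 1) > 1e-6)
    stop("'dist' must be a probability vector summing to 1 within 1e-6",
         call. = FALSE)
  p <- dist[dist > 0]
  (-sum(p * log(p))) / log(length(dist))
}

#' Per-residue entropy track of one angle kind
#'
#' @param profile a \linkS4class{ProbabilityProfile}.
#' @param kind one of "phi", "psi", "theta", "tau".
#' @return numeric vector of normalized entropies, one per residue.
#' @export
entropyTrack <- function(profile, kind) {
  stopifnot(is(profile, "ProbabilityProfile"))
  block <- angleBlock(profile, checkKind(kind))
  apply(block, 1L, normalizedEntropy)
}

#' Sliding-window mean with terminal shrinkage
#'
#' Mean over all available positions within (window - 1)/2 of each
#' residue; near the termini the window shrinks rather than padding with
#' artificial values.
#'
#' @param track numeric per-residue values.
#' @param window odd window size; default 21.
#' @return smoothed track of the same length.
#' @export
windowAverage <- function(track, window = 21L) {
  window <- as.integer(window)
  if (window %% 2L != 1L || window < 1L)
    stop("'window' must be a positive odd integer", call. = FALSE)
  n <- length(track)
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(track))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Rank-based AUC for disorder discrimination
#'
#' Area under the ROC curve computed as the Mann-Whitney U statistic with
#' midrank tie handling, under the convention that higher scores indicate
#' disorder (label 1).
#'
#' @param scores numeric per-residue scores.
#' @param labels binary labels (1 = disordered); both classes must occur.
#' @return AUC in [0, 1]; NA with a warning if only one class is present.
#' @export
disorderAUC <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ", call. = FALSE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("labels contain a single class; AUC undefined", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full disorder score track of one angle kind
#'
#' Combines the raw entropy, its normalized form and the window-averaged
#' score into one table per residue.
#'
#' @param profile a \linkS4class{ProbabilityProfile}.
#' @param kind one of "phi", "psi", "theta", "tau"; "tau" (the most
#'   discriminative angle) is the default.
#' @param window smoothing window; default 21.
#' @return data.frame with columns residue, rawEntropy,
#'   normalizedEntropy, score (window-averaged normalized entropy), plus
#'   attributes \code{kind} and \code{window}.
#' @export
disorderTrack <- function(profile, kind = "tau", window = 21L) {
  kind <- checkKind(kind)
  K <- profile@scheme@bins[[kind]]
  hn <- entropyTrack(profile, kind)
  out <- data.frame(residue = seq_along(hn),
                    rawEntropy = hn * log(K),
                    normalizedEntropy = hn,
                    score = windowAverage(hn, window))
  attr(out, "kind") <- kind
  attr(out, "window") <- as.integer(window)
  out
}

#' Mean-of-four combined disorder score
#'
#' Averages the window-averaged entropy tracks of the four angle kinds.
#' No combined score was validated against disorder annotations, so this
#' is refused unless \code{unvalidated = TRUE}; per-angle tracks are the
#' supported interface.
#'
#' @param profile a \linkS4class{ProbabilityProfile}.
#' @param window smoothing window; default 21.
#' @param unvalidated set TRUE to acknowledge the caveat.
#' @return numeric per-residue combined score.
#' @export
combinedDisorderScore <- function(profile, window = 21L,
                                  unvalidated = FALSE) {
  if (!isTRUE(unvalidated))
    stop("the mean-of-four combined score is unvalidated; pass ",
         "unvalidated = TRUE to use it anyway", call. = FALSE)
  tracks <- vapply(ANGLE_KINDS, function(k)
    windowAverage(entropyTrack(profile, k), window),
    numeric(nResidues(profile)))
  rowMeans(tracks)
}
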