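## Evaluation metrics for binned angle prediction.

## argmax with ties broken by the lowest bin index (which.max semantics)
blockArgmax <- function(block) max.col(block, ties.method = "first")

trueBins <- function(truth, kind) {
  block <- angleBlock(truth, kind)
  hit <- block == 1
  idx <- rep(NA_integer_, nrow(block))
  any1 <- rowSums(hit) > 0
  idx[any1] <- max.col(hit, ties.method = "first")[any1]
  idx
}

metricResidues <- function(pred, truth, kind) {
  stopifnot(is(pred, "ProbabilityProfile"), is(truth, "TargetMatrix"))
  if (nResidues(pred) != nResidues(truth))
    stop("prediction and truth residue counts differ", call. = FALSE)
  if (!isTRUE(all.equal(pred@scheme@bins, truth@scheme@bins)))
    stop("prediction and truth bin schemes differ", call. = FALSE)
  which(definedMask(truth, kind))
}

#' Bin accuracy
#'
#' Fraction of residues (with a defined true angle) whose true bin is the
#' highest-probability predicted bin. Argmax ties go to the lowest index.
#'
#' @param pred a \linkS4class{ProbabilityProfile}.
#' @param truth a \linkS4class{TargetMatrix} on the same scheme.
#' @param kind one of "phi", "psi", "theta", "tau".
#' @return fraction in [0, 1]; NA with a warning if no residue has a
#'   defined true angle of this kind.
#' @export
binAccuracy <- function(pred, truth, kind) {
  kind <- checkKind(kind)
  ok <- metricResidues(pred, truth, kind)
  if (!length(ok)) {
    warning("no defined residues for kind '", kind, "'; accuracy undefined",
            call. = FALSE)
    return(NA_real_)
  }
  predBin <- blockArgmax(angleBlock(pred, kind))[ok]
  mean(predBin == trueBins(truth, kind)[ok])
}

#' Top-k accuracy
#'
#' Fraction of residues whose true bin is among the k highest-probability
#' predicted bins (k distinct bins; ties broken by the lowest index).
#'
#' @inheritParams binAccuracy
#' @param k number of top bins to match against; default 5.
#' @return fraction in [0, 1]; NA with a warning when undefined.
#' @export
topkAccuracy <- function(pred, truth, kind, k = 5L) {
  kind <- checkKind(kind)
  K <- pred@scheme@bins[[kind]]
  if (k < 1L || k > K)
    stop(sprintf("'k' must be in 1..%d for %s", K, kind), call. = FALSE)
  ok <- metricResidues(pred, truth, kind)
  if (!length(ok)) {
    warning("no defined residues for kind '", kind, "'; accuracy undefined",
            call. = FALSE)
    return(NA_real_)
  }
  block <- angleBlock(pred, kind)[ok, , drop = FALSE]
  tb <- trueBins(truth, kind)[ok]
  hit <- vapply(seq_along(tb), function(i) {
    top <- order(-block[i, ], seq_len(K))[seq_len(k)]
    tb[i] %in% top
  }, logical(1L))
  mean(hit)
}

#' Two-state split of a dihedral
#'
#' Coarse two-state classification of phi and psi used to judge large
#' angle errors: phi is state "A" on [0, 150] and "B" elsewhere; psi is
#' "A" on [-100, 60] and "B" elsewhere. Boundaries are closed on the
#' first-listed interval.
#'
#' @param angle numeric vector of angles in degrees (wrapped to
#'   [-180, 180)).
#' @param kind "phi" or "psi".
#' @return character vector of "A"/"B", NA where the angle is NA.
#' @export
twoState <- function(angle, kind) {
  if (length(kind) != 1L || !kind %in% c("phi", "psi"))
    stop("two-state split is defined for phi and psi only", call. = FALSE)
  a <- ifelse(is.na(angle), NA_real_, wrapTo180(angle))
  inA <- if (kind == "phi") a >= 0 & a <= 150 else a >= -100 & a <= 60
  ifelse(is.na(a), NA_character_, ifelse(inA, "A", "B"))
}

#' Two-state accuracy of a profile
#'
#' Converts the argmax predicted bin to its center angle and compares its
#' two-state class with that of the true angle.
#'
#' @param pred a \linkS4class{ProbabilityProfile}.
#' @param angles the true \linkS4class{AngleTable}.
#' @param kind "phi" or "psi".
#' @return fraction in [0, 1]; NA with a warning when undefined.
#' @export
twoStateAccuracy <- function(pred, angles, kind) {
  if (!kind %in% c("phi", "psi"))
    stop("two-state split is defined for phi and psi only", call. = FALSE)
  stopifnot(is(pred, "ProbabilityProfile"), is(angles, "AngleTable"))
  ok <- which(definedMask(angles, kind))
  if (!length(ok)) {
    warning("no defined residues for kind '", kind, "'; accuracy undefined",
            call. = FALSE)
    return(NA_real_)
  }
  predAngle <- binCenter(blockArgmax(angleBlock(pred, kind))[ok], kind,
                         pred@scheme)
  mean(twoState(predAngle, kind) == twoState(angleValues(angles, kind)[ok],
                                             kind))
}
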