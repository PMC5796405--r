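## Fixed-width discretization of the four backbone angles.
##
## Dihedrals (phi, psi, tau) are binned on [-180, 180) and theta on
## [0, 180]; bins are half-open [lo, lo + width) except the final theta
## bin, which is closed at 180 so every attainable value has a bin.

#' Create an angle-bin scheme
#'
#' At width 5 the dihedrals get 72 bins each and theta 36, for a total
#' output dimension of 252; at width 10 the total is 126.
#'
#' @param width bin width in degrees; must divide both 360 and 180.
#' @return a \linkS4class{BinScheme}.
#' @export
#' @examples
#' makeScheme(5)   # 72/72/36/72 bins, total 252
#' makeScheme(10)  # total 126
makeScheme <- function(width = 5) {
  if (length(width) != 1L || !is.finite(width) || width <= 0 ||
      abs(360 / width - round(360 / width)) > 1e-9 ||
      abs(180 / width - round(180 / width)) > 1e-9)
    stop("'width' must be a positive divisor of both 360 and 180",
         call. = FALSE)
  lower <- c(phi = -180, psi = -180, theta = 0, tau = -180)
  upper <- c(phi = 180, psi = 180, theta = 180, tau = 180)
  bins <- as.integer(round((upper - lower) / width))
  names(bins) <- ANGLE_KINDS
  new("BinScheme", width = width, bins = bins, lower = lower, upper = upper,
      total = sum(bins))
}

#' Map angles to bin indices
#'
#' Bin i of a dihedral covers [-180 + i*width, -180 + (i+1)*width), using
#' 0-based indices internally; this function returns 1-based indices as is
#' conventional in R. theta = 180 maps to the last theta bin. NA angles
#' (undefined) map to NA.
#'
#' @param angle numeric vector of angles in degrees.
#' @param kind one of "phi", "psi", "theta", "tau".
#' @param scheme a \linkS4class{BinScheme}.
#' @return integer vector of 1-based bin indices, NA where undefined.
#' @export
angleToBin <- function(angle, kind, scheme) {
  kind <- checkKind(kind)
  stopifnot(is(scheme, "BinScheme"))
  lo <- scheme@lower[[kind]]
  hi <- scheme@upper[[kind]]
  K <- scheme@bins[[kind]]
  a <- angle
  if (kind == "theta") {
    bad <- !is.na(a) & (a < lo | a > hi)
    if (any(bad)) stop("theta values outside [0, 180]", call. = FALSE)
  } else {
    a <- ifelse(is.na(a), a, wrapTo180(a))
  }
  idx <- as.integer(floor((a - lo) / scheme@width)) + 1L
  idx[!is.na(idx) & idx > K] <- K  # theta == 180 falls in the closed last bin
  idx
}

#' Bin center in degrees
#'
#' The midpoint of a bin; \code{angleToBin(binCenter(i))} recovers i.
#'
#' @param index 1-based bin index (vectorized).
#' @param kind one of "phi", "psi", "theta", "tau".
#' @param scheme a \linkS4class{BinScheme}.
#' @return numeric vector of bin midpoints in degrees.
#' @export
binCenter <- function(index, kind, scheme) {
  kind <- checkKind(kind)
  stopifnot(is(scheme, "BinScheme"))
  K <- scheme@bins[[kind]]
  if (any(!is.na(index) & (index < 1L | index > K)))
    stop(sprintf("bin index out of range 1..%d for %s", K, kind),
         call. = FALSE)
  scheme@lower[[kind]] + (index - 0.5) * scheme@width
}

#' One-hot encode an angle table
#'
#' Each residue becomes a concatenated row of four one-hot blocks (one per
#' angle kind). Undefined angles give an all-zero block and a FALSE mask.
#'
#' @param angles an \linkS4class{AngleTable}.
#' @param scheme a \linkS4class{BinScheme}.
#' @return a \linkS4class{TargetMatrix}.
#' @export
encodeTargets <- function(angles, scheme) {
  stopifnot(is(angles, "AngleTable"), is(scheme, "BinScheme"))
  n <- nResidues(angles)
  enc <- matrix(0, n, scheme@total)
  blocks <- schemeBlocks(scheme)
  for (k in ANGLE_KINDS) {
    bin <- angleToBin(angles@angles[, k], k, scheme)
    ok <- which(angles@defined[, k] & !is.na(bin))
    if (length(ok))
      enc[cbind(ok, blocks[[k]][1L] - 1L + bin[ok])] <- 1
  }
  new("TargetMatrix", encoding = enc, defined = angles@defined,
      scheme = scheme)
}

#' Merge a fine probability profile into coarser bins
#'
#' Sums the probabilities of \code{factor} adjacent bins within each
#' per-angle block, e.g. turning a 5-degree profile into a 10-degree one.
#' Used to evaluate a fine-grid model at a coarser grid.
#'
#' @param pred a \linkS4class{ProbabilityProfile}.
#' @param factor number of adjacent bins to combine; must divide every
#'   per-angle bin count. Default 2.
#' @return a \linkS4class{ProbabilityProfile} at width \code{width * factor}.
#' @export
mergeToCoarse <- function(pred, factor = 2L) {
  stopifnot(is(pred, "ProbabilityProfile"))
  factor <- as.integer(factor)
  if (factor < 1L || any(pred@scheme@bins %% factor != 0L))
    stop("'factor' must divide every per-angle bin count", call. = FALSE)
  coarse <- makeScheme(pred@scheme@width * factor)
  blocks <- schemeBlocks(pred@scheme)
  out <- matrix(0, nrow(pred@probs), coarse@total)
  cblocks <- schemeBlocks(coarse)
  for (k in ANGLE_KINDS) {
    fine <- pred@probs[, blocks[[k]], drop = FALSE]
    Kc <- coarse@bins[[k]]
    grp <- rep(seq_len(Kc), each = factor)
    merged <- fine %*% outer(grp, seq_len(Kc), "==")
    out[, cblocks[[k]]] <- merged
  }
  new("ProbabilityProfile", probs = out, scheme = coarse)
}
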