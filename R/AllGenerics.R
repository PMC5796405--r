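## Column index ranges of the four per-angle blocks inside a concatenated
## (target or probability) row, in canonical phi/psi/theta/tau order.
schemeBlocks <- function(scheme) {
  ends <- cumsum(scheme@bins)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- lapply(seq_along(ANGLE_KINDS), function(i) seq.int(starts[i], ends[i]))
  names(out) <- ANGLE_KINDS
  out
}

checkKind <- function(kind) {
  if (length(kind) != 1L || !kind %in% ANGLE_KINDS)
    stop("'kind' must be one of ", paste(ANGLE_KINDS, collapse = ", "),
         call. = FALSE)
  kind
}

#' Number of residues in an object
#' @param x a BackboneChain, AngleTable, TargetMatrix or ProbabilityProfile.
#' @return integer residue count.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname nResidues
#' @export
setMethod("nResidues", "BackboneChain", function(x) length(x@residueIds))
#' @rdname nResidues
#' @export
setMethod("nResidues", "AngleTable", function(x) nrow(x@angles))
#' @rdname nResidues
#' @export
setMethod("nResidues", "TargetMatrix", function(x) nrow(x@encoding))
#' @rdname nResidues
#' @export
setMethod("nResidues", "ProbabilityProfile", function(x) nrow(x@probs))

#' Per-residue angle values of one kind
#' @param x an AngleTable.
#' @param kind one of "phi", "psi", "theta", "tau".
#' @return numeric vector in degrees, NA where undefined.
#' @export
angleValues <- function(x, kind) {
  stopifnot(is(x, "AngleTable"))
  x@angles[, checkKind(kind)]
}

#' Defined-ness mask of one angle kind
#' @inheritParams angleValues
#' @return logical vector, TRUE where the angle is defined.
#' @export
definedMask <- function(x, kind) {
  stopifnot(is(x, "AngleTable") || is(x, "TargetMatrix"))
  x@defined[, checkKind(kind)]
}

#' Per-angle bin counts of a scheme
#' @param scheme a BinScheme.
#' @return named integer vector (phi, psi, theta, tau).
#' @export
binCounts <- function(scheme) {
  stopifnot(is(scheme, "BinScheme"))
  scheme@bins
}

#' Total output dimension of a scheme
#' @param scheme a BinScheme.
#' @return integer, e.g. 252 at width 5.
#' @export
schemeTotal <- function(scheme) {
  stopifnot(is(scheme, "BinScheme"))
  scheme@total
}

#' Extract the probability block of one angle kind
#' @param x a ProbabilityProfile or TargetMatrix.
#' @param kind one of "phi", "psi", "theta", "tau".
#' @return numeric matrix, residues x bins of that kind.
#' @export
angleBlock <- function(x, kind) {
  kind <- checkKind(kind)
  idx <- schemeBlocks(if (is(x, "ProbabilityProfile")) x@scheme else x@scheme)
  m <- if (is(x, "ProbabilityProfile")) x@probs else x@encoding
  m[, idx[[kind]], drop = FALSE]
}

#' Alpha-carbon coordinates of a chain
#' @param x a BackboneChain.
#' @return n x 3 matrix of CA coordinates in Angstrom.
#' @export
caCoords <- function(x) {
  stopifnot(is(x, "BackboneChain"))
  x@coordsCA
}

#' Residue identifiers of a chain
#' @param x a BackboneChain.
#' @return integer vector of residue numbers.
#' @export
residueIds <- function(x) {
  stopifnot(is(x, "BackboneChain"))
  x@residueIds
}

#' Row (residue) subsetting of per-residue containers
#'
#' @param x an AngleTable, TargetMatrix or ProbabilityProfile.
#' @param i residue indices (integer or logical).
#' @param j,...,drop ignored; present for generic compatibility.
#' @return an object of the same class restricted to the chosen residues.
#' @rdname subsetResidues
#' @export
setMethod("[", "AngleTable", function(x, i, j, ..., drop = FALSE)
  new("AngleTable", angles = x@angles[i, , drop = FALSE],
      defined = x@defined[i, , drop = FALSE]))

#' @rdname subsetResidues
#' @export
setMethod("[", "TargetMatrix", function(x, i, j, ..., drop = FALSE)
  new("TargetMatrix", encoding = x@encoding[i, , drop = FALSE],
      defined = x@defined[i, , drop = FALSE], scheme = x@scheme))

#' @rdname subsetResidues
#' @export
setMethod("[", "ProbabilityProfile", function(x, i, j, ..., drop = FALSE)
  new("ProbabilityProfile", probs = x@probs[i, , drop = FALSE],
      scheme = x@scheme))

setMethod("show", "BinScheme", function(object) {
  cat(sprintf("BinScheme: width %g deg | bins %s | total %d\n",
              object@width,
              paste(sprintf("%s=%d", ANGLE_KINDS, object@bins), collapse = " "),
              object@total))
})

setMethod("show", "BackboneChain", function(object) {
  cat(sprintf("BackboneChain '%s': %d residues (%d-%d)\n", object@chainId,
              nResidues(object), min(object@residueIds), max(object@residueIds)))
})

setMethod("show", "AngleTable", function(object) {
  nd <- colSums(object@defined)
  cat(sprintf("AngleTable: %d residues | defined %s\n", nrow(object@angles),
              paste(sprintf("%s=%d", ANGLE_KINDS, nd), collapse = " ")))
})

setMethod("show", "TargetMatrix", function(object) {
  cat(sprintf("TargetMatrix: %d residues x %d bins (width %g deg)\n",
              nrow(object@encoding), ncol(object@encoding), object@scheme@width))
})

setMethod("show", "ProbabilityProfile", function(object) {
  cat(sprintf("ProbabilityProfile: %d residues x %d bins (width %g deg)\n",
              nrow(object@probs), ncol(object@probs), object@scheme@width))
})

setMethod("show", "BackgroundDistribution", function(object) {
  cat(sprintf("BackgroundDistribution: width %g deg, pseudocount %g\n",
              object@scheme@width, object@pseudocount))
})

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf("NetworkConfig: hidden [%s] | pretrain lr %g x %d epochs | finetune lr [%s] x %d epochs | batch %d | seed %d\n",
              paste(object@hidden, collapse = ", "), object@pretrainLR,
              object@pretrainEpochs, paste(object@finetuneLR, collapse = ", "),
              object@epochs, object@batchSize, object@seed))
})

setMethod("show", "NetworkModel", function(object) {
  sizes <- c(object@inputDim, vapply(object@weights, ncol, 1L))
  cat(sprintf("NetworkModel: %s (width %g deg)\n",
              paste(sizes, collapse = " -> "), object@scheme@width))
})
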