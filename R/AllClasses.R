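#' @import methods
#' @importFrom stats rnorm runif rbinom rgamma setNames sd cor median predict
#' @importFrom utils read.table write.table head tail
NULL

## Canonical order of the four backbone angle kinds used throughout the
## package: two bond-rotation dihedrals (phi, psi) and the two CA-trace
## angles (theta: planar, tau: dihedral).
ANGLE_KINDS <- c("phi", "psi", "theta", "tau")

#' Sequence profile from a position-specific scoring matrix
#'
#' One row of 20 substitution scores per residue, as produced by iterative
#' profile search (PSI-BLAST ASCII PSSM, log-odds columns).
#'
#' @slot sequence character vector of 1-letter residue codes.
#' @slot scores n x 20 numeric matrix of log-odds scores, columns named by
#'   the PSSM's residue alphabet.
#' @exportClass PssmProfile
setClass("PssmProfile",
  representation(sequence = "character", scores = "matrix"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@scores) != length(object@sequence))
      msg <- c(msg, "score rows must align 1:1 with the sequence")
    if (ncol(object@scores) != 20L)
      msg <- c(msg, "scores must have 20 columns")
    if (!all(is.finite(object@scores)))
      msg <- c(msg, "scores must be finite")
    if (length(msg)) msg else TRUE
  })

#' Angle-bin discretization scheme
#'
#' Describes the fixed-width binning of the four backbone angles. Dihedrals
#' (phi, psi, tau) live on [-180, 180) and the planar angle theta on
#' [0, 180]. At the default 5-degree width this gives 72 + 72 + 36 + 72 =
#' 252 bins in total, the output dimension of the network.
#'
#' @slot width bin width in degrees.
#' @slot bins named integer vector of per-angle bin counts.
#' @slot lower named numeric vector of per-angle range lower bounds (degrees).
#' @slot upper named numeric vector of per-angle range upper bounds (degrees).
#' @slot total total output dimension (sum of bins).
#' @exportClass BinScheme
setClass("BinScheme",
  representation(width = "numeric", bins = "integer",
                 lower = "numeric", upper = "numeric", total = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@width) != 1L || object@width <= 0)
      msg <- c(msg, "width must be a single positive number")
    for (nm in list(object@bins, object@lower, object@upper))
      if (!identical(names(nm), ANGLE_KINDS))
        msg <- c(msg, "per-angle slots must be named phi, psi, theta, tau")
    span <- object@upper - object@lower
    if (!all(abs(object@bins * object@width - span) < 1e-9))
      msg <- c(msg, "bin count times width must equal the range span")
    if (object@total != sum(object@bins))
      msg <- c(msg, "total must equal sum of per-angle bin counts")
    if (length(msg)) msg else TRUE
  })

#' Backbone chain coordinates
#'
#' Ordered N/CA/C coordinates for one polypeptide chain. Residues missing
#' any of the three backbone atoms are dropped at parse time, so the three
#' coordinate matrices always align row-for-row with \code{residueIds}.
#'
#' @slot chainId single chain identifier.
#' @slot residueIds ordered integer residue numbers.
#' @slot residueNames three-letter residue codes.
#' @slot coordsN,coordsCA,coordsC n x 3 coordinate matrices in Angstrom.
#' @exportClass BackboneChain
setClass("BackboneChain",
  representation(chainId = "character", residueIds = "integer",
                 residueNames = "character", coordsN = "matrix",
                 coordsCA = "matrix", coordsC = "matrix"),
  validity = function(object) {
    n <- length(object@residueIds)
    msg <- character()
    if (n < 1L) msg <- c(msg, "chain must contain at least one residue")
    for (slotnm in c("coordsN", "coordsCA", "coordsC")) {
      m <- slot(object, slotnm)
      if (!is.numeric(m) || ncol(m) != 3L || nrow(m) != n)
        msg <- c(msg, sprintf("%s must be a numeric %d x 3 matrix", slotnm, n))
      else if (!all(is.finite(m)))
        msg <- c(msg, sprintf("%s contains non-finite coordinates", slotnm))
    }
    if (length(object@residueNames) != n)
      msg <- c(msg, "residueNames length must match residueIds")
    if (length(msg)) msg else TRUE
  })

#' Per-residue backbone angle table
#'
#' Holds phi, psi, theta and tau in degrees together with defined-ness
#' masks. Undefined entries (chain termini, chain breaks, degenerate
#' geometry) are NA in \code{angles} and FALSE in \code{defined}.
#'
#' @slot angles n x 4 numeric matrix, columns phi/psi/theta/tau, degrees.
#' @slot defined n x 4 logical mask, TRUE where the angle is defined.
#' @exportClass AngleTable
setClass("AngleTable",
  representation(angles = "matrix", defined = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!identical(colnames(object@angles), ANGLE_KINDS) ||
        !identical(colnames(object@defined), ANGLE_KINDS))
      msg <- c(msg, "columns must be phi, psi, theta, tau")
    if (!identical(dim(object@angles), dim(object@defined)))
      msg <- c(msg, "angles and defined must have identical dimensions")
    def <- object@defined
    ang <- object@angles
    if (any(def & !is.finite(ang)))
      msg <- c(msg, "defined angles must be finite")
    ok <- TRUE
    for (k in c("phi", "psi", "tau")) {
      v <- ang[def[, k], k]
      if (length(v) && (any(v < -180) || any(v >= 180))) ok <- FALSE
    }
    v <- ang[def[, "theta"], "theta"]
    if (length(v) && (any(v < 0) || any(v > 180))) ok <- FALSE
    if (!ok) msg <- c(msg, "angles out of range: dihedrals in [-180,180), theta in [0,180]")
    if (length(msg)) msg else TRUE
  })

#' One-hot training targets over angle bins
#'
#' Per residue, one concatenated row of four one-hot blocks (one per angle
#' kind, block widths given by the scheme). Rows of undefined angles are
#' all-zero in their block and masked out of training and evaluation.
#'
#' @slot encoding n x total 0/1 matrix of concatenated one-hot blocks.
#' @slot defined n x 4 logical mask per angle kind.
#' @slot scheme the \linkS4class{BinScheme} used for encoding.
#' @exportClass TargetMatrix
setClass("TargetMatrix",
  representation(encoding = "matrix", defined = "matrix", scheme = "BinScheme"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@encoding) != object@scheme@total)
      msg <- c(msg, "encoding width must equal the scheme's total dimension")
    if (nrow(object@encoding) != nrow(object@defined))
      msg <- c(msg, "encoding and defined row counts differ")
    if (!identical(colnames(object@defined), ANGLE_KINDS))
      msg <- c(msg, "defined columns must be phi, psi, theta, tau")
    if (length(msg)) msg else TRUE
  })

#' Predicted per-residue bin probabilities
#'
#' The network output: for each residue, four probability vectors (one per
#' angle kind) concatenated into a single row. Each per-angle block sums
#' to 1 within 1e-6.
#'
#' @slot probs n x total numeric matrix of concatenated per-angle blocks.
#' @slot scheme the \linkS4class{BinScheme} defining block widths.
#' @exportClass ProbabilityProfile
setClass("ProbabilityProfile",
  representation(probs = "matrix", scheme = "BinScheme"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@probs) != object@scheme@total)
      msg <- c(msg, "probs width must equal the scheme's total dimension")
    if (any(object@probs < -1e-12))
      msg <- c(msg, "probabilities must be non-negative")
    idx <- schemeBlocks(object@scheme)
    for (k in ANGLE_KINDS) {
      s <- rowSums(object@probs[, idx[[k]], drop = FALSE])
      if (any(abs(s - 1) > 1e-6))
        msg <- c(msg, sprintf("%s block rows must sum to 1 within 1e-6", k))
    }
    if (length(msg)) msg else TRUE
  })

#' Background (expected) bin frequencies
#'
#' Pseudocounted bin frequencies of each angle kind estimated from a corpus
#' of observed angle tables; the reference distribution P0 of the PE-score.
#'
#' @slot freq list of four per-angle probability vectors, all entries > 0.
#' @slot pseudocount the pseudocount added to every bin.
#' @slot scheme the \linkS4class{BinScheme} used to histogram the corpus.
#' @exportClass BackgroundDistribution
setClass("BackgroundDistribution",
  representation(freq = "list", pseudocount = "numeric", scheme = "BinScheme"),
  validity = function(object) {
    msg <- character()
    if (!identical(names(object@freq), ANGLE_KINDS))
      msg <- c(msg, "freq must be a list named phi, psi, theta, tau")
    else for (k in ANGLE_KINDS) {
      v <- object@freq[[k]]
      if (length(v) != object@scheme@bins[[k]])
        msg <- c(msg, sprintf("%s frequency length must match the scheme", k))
      if (abs(sum(v) - 1) > 1e-9) msg <- c(msg, sprintf("%s must sum to 1", k))
      if (object@pseudocount > 0 && any(v <= 0))
        msg <- c(msg, sprintf("%s must be strictly positive", k))
    }
    if (length(msg)) msg else TRUE
  })

#' Network hyperparameter configuration
#'
#' Defaults follow the architecture used for grid-based angle prediction:
#' three hidden layers of 150 sigmoid units, autoencoder pretraining at
#' learning rate 0.05, and per-layer fine-tuning rates 1.0/0.5/0.2/0.05
#' applied to hidden-1/hidden-2/hidden-3/output respectively.
#'
#' @slot hidden integer vector of hidden layer sizes.
#' @slot pretrainLR pretraining learning rate.
#' @slot finetuneLR per-layer fine-tuning learning rates, length
#'   \code{length(hidden) + 1}.
#' @slot pretrainEpochs,epochs epochs for pretraining and fine-tuning.
#' @slot batchSize minibatch size.
#' @slot sparsityTarget target mean activation of the sparse autoencoder.
#' @slot sparsityWeight weight of the KL sparsity penalty.
#' @slot weightDecay L2 weight decay.
#' @slot seed integer seed fixing all randomness.
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(hidden = "integer", pretrainLR = "numeric",
                 finetuneLR = "numeric", pretrainEpochs = "integer",
                 epochs = "integer", batchSize = "integer",
                 sparsityTarget = "numeric", sparsityWeight = "numeric",
                 weightDecay = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@hidden < 1L)) msg <- c(msg, "hidden layer sizes must be positive")
    if (length(object@finetuneLR) != length(object@hidden) + 1L)
      msg <- c(msg, "finetuneLR must have one rate per hidden layer plus the output layer")
    if (any(c(object@pretrainLR, object@finetuneLR) <= 0))
      msg <- c(msg, "learning rates must be positive")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@sparsityTarget <= 0 || object@sparsityTarget >= 1)
      msg <- c(msg, "sparsityTarget must be in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Trained angle-probability network
#'
#' Weights and biases of the feedforward network mapping per-residue
#' feature vectors to concatenated per-angle softmax blocks.
#'
#' @slot weights list of weight matrices (inputs x units per layer).
#' @slot biases list of bias vectors.
#' @slot inputDim expected feature dimension.
#' @slot scheme \linkS4class{BinScheme} defining the output blocks.
#' @slot config the \linkS4class{NetworkConfig} used for training.
#' @slot meta list of training metadata (data fingerprint, loss curve).
#' @exportClass NetworkModel
setClass("NetworkModel",
  representation(weights = "list", biases = "list", inputDim = "integer",
                 scheme = "BinScheme", config = "NetworkConfig", meta = "list"),
  validity = function(object) {
    msg <- character()
    L <- length(object@weights)
    if (length(object@biases) != L)
      msg <- c(msg, "weights and biases must have the same number of layers")
    if (L > 0) {
      if (nrow(object@weights[[1L]]) != object@inputDim)
        msg <- c(msg, "first weight matrix must match inputDim")
      out <- ncol(object@weights[[L]])
      if (out != object@scheme@total)
        msg <- c(msg, "output dimension must equal the scheme's total dimension")
      for (l in seq_len(L))
        if (length(object@biases[[l]]) != ncol(object@weights[[l]]))
          msg <- c(msg, sprintf("bias length mismatch in layer %d", l))
    }
    if (length(msg)) msg else TRUE
  })
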