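## The grid-based angle predictor: a feedforward network mapping
## per-residue feature vectors to four concatenated softmax blocks (one
## per angle kind). Hidden layers use sigmoid units initialised by greedy
## stacked sparse-autoencoder pretraining; fine-tuning is minibatch SGD on
## the summed per-block cross-entropy with per-layer learning rates.

#' Create a network configuration
#'
#' Defaults: three hidden layers of 150 units, autoencoder pretraining at
#' learning rate 0.05 for 30 epochs, fine-tuning rates 1.0/0.5/0.2/0.05
#' for the three hidden layers and the output layer over 100 epochs,
#' minibatches of 64, KL sparsity penalty toward a mean activation of
#' 0.05, and L2 weight decay 1e-4.
#'
#' @param hidden hidden layer sizes.
#' @param pretrainLR autoencoder learning rate.
#' @param finetuneLR per-layer fine-tuning learning rates (hidden layers
#'   first, output layer last).
#' @param pretrainEpochs,epochs pretraining and fine-tuning epochs.
#' @param batchSize minibatch size.
#' @param sparsityTarget,sparsityWeight target mean activation and penalty
#'   weight of the sparse autoencoder.
#' @param weightDecay L2 penalty on all weights.
#' @param seed integer seed fixing initialisation and shuffling.
#' @return a \linkS4class{NetworkConfig}.
#' @export
networkConfig <- function(hidden = c(150L, 150L, 150L), pretrainLR = 0.05,
                          finetuneLR = c(1.0, 0.5, 0.2, 0.05),
                          pretrainEpochs = 30L, epochs = 100L,
                          batchSize = 64L, sparsityTarget = 0.05,
                          sparsityWeight = 0.1, weightDecay = 1e-4,
                          seed = 1L) {
  new("NetworkConfig", hidden = as.integer(hidden), pretrainLR = pretrainLR,
      finetuneLR = as.numeric(finetuneLR),
      pretrainEpochs = as.integer(pretrainEpochs), epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), sparsityTarget = sparsityTarget,
      sparsityWeight = sparsityWeight, weightDecay = weightDecay,
      seed = as.integer(seed))
}

## Evaluate expr with a deterministic RNG stream, restoring the caller's.
withSeed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Glorot uniform initialisation with the x4 gain recommended for
## sigmoid units (the sigmoid's slope at 0 is 1/4, so plain Glorot
## ranges let the signal vanish across stacked sigmoid layers).
initLayer <- function(fanIn, fanOut, gain = 4) {
  r <- gain * sqrt(6 / (fanIn + fanOut))
  matrix(runif(fanIn * fanOut, -r, r), fanIn, fanOut)
}

activate <- function(z, activation) {
  if (activation == "linear") z else sigmoid(z)
}

#' Greedy layerwise sparse-autoencoder pretraining
#'
#' Trains one autoencoder per hidden layer on the activations of the
#' previous layer: sigmoid (or linear) encoder, linear decoder, squared
#' reconstruction error, L2 weight decay and a KL penalty pulling the mean
#' encoder activation toward \code{sparsityTarget}. The learned encoders
#' initialise the supervised network.
#'
#' @param features numeric matrix, residues x feature dimension.
#' @param config a \linkS4class{NetworkConfig}.
#' @param activation hidden activation, "sigmoid" (default) or "linear".
#' @return list with \code{weights}, \code{biases} (one per hidden layer)
#'   and \code{losses}, the per-epoch full-data reconstruction error of
#'   each layer's autoencoder.
#' @export
pretrainNetwork <- function(features, config, activation = "sigmoid") {
  stopifnot(is(config, "NetworkConfig"))
  X <- as.matrix(features)
  if (nrow(X) < 1L) stop("at least one training row is required", call. = FALSE)
  withSeed(config@seed, {
    H <- X
    Ws <- list(); bs <- list(); losses <- list()
    for (l in seq_along(config@hidden)) {
      h <- config@hidden[l]
      d <- ncol(H)
      W <- initLayer(d, h);  b <- numeric(h)
      Wd <- initLayer(h, d); bd <- numeric(d)
      lcurve <- numeric(config@pretrainEpochs)
      n <- nrow(H)
      for (ep in seq_len(config@pretrainEpochs)) {
        ord <- sample.int(n)
        for (start in seq(1L, n, by = config@batchSize)) {
          sel <- ord[start:min(start + config@batchSize - 1L, n)]
          Hb <- H[sel, , drop = FALSE]
          m <- nrow(Hb)
          A <- activate(Hb %*% W + rep(b, each = m), activation)
          R <- A %*% Wd + rep(bd, each = m)
          dR <- (R - Hb) / m
          gWd <- crossprod(A, dR) + config@weightDecay * Wd
          gbd <- colSums(dR)
          dA <- tcrossprod(dR, Wd)
          if (config@sparsityWeight > 0 && activation == "sigmoid") {
            rho <- config@sparsityTarget
            rhoHat <- pmin(pmax(colMeans(A), 1e-8), 1 - 1e-8)
            sgrad <- (-rho / rhoHat + (1 - rho) / (1 - rhoHat)) / m
            dA <- dA + config@sparsityWeight *
              matrix(sgrad, m, length(sgrad), byrow = TRUE)
          }
          dZ <- if (activation == "linear") dA else dA * A * (1 - A)
          gW <- crossprod(Hb, dZ) + config@weightDecay * W
          gb <- colSums(dZ)
          W <- W - config@pretrainLR * gW
          b <- b - config@pretrainLR * gb
          Wd <- Wd - config@pretrainLR * gWd
          bd <- bd - config@pretrainLR * gbd
        }
        A <- activate(H %*% W + rep(b, each = n), activation)
        R <- A %*% Wd + rep(bd, each = n)
        lcurve[ep] <- mean((R - H)^2)
      }
      Ws[[l]] <- W; bs[[l]] <- b; losses[[l]] <- lcurve
      H <- activate(H %*% W + rep(b, each = nrow(H)), activation)
    }
    list(weights = Ws, biases = bs, losses = losses)
  })
}

## Per-block softmax over the concatenated output row.
blockSoftmax <- function(Z, blocks) {
  P <- Z
  for (idx in blocks) {
    zb <- Z[, idx, drop = FALSE]
    zb <- zb - apply(zb, 1L, max)
    eb <- exp(zb)
    P[, idx] <- eb / rowSums(eb)
  }
  P
}

## Forward pass; returns activations of every layer plus block softmax.
netForward <- function(weights, biases, X, blocks, activation = "sigmoid") {
  L <- length(weights)
  H <- vector("list", L + 1L)
  H[[1L]] <- X
  for (l in seq_len(L - 1L))
    H[[l + 1L]] <- activate(H[[l]] %*% weights[[l]] +
                              rep(biases[[l]], each = nrow(X)), activation)
  Z <- H[[L]] %*% weights[[L]] + rep(biases[[L]], each = nrow(X))
  list(H = H, Z = Z, P = blockSoftmax(Z, blocks))
}

## Loss and analytic gradients of the masked summed cross-entropy.
## Y: one-hot target rows; mask: n x 4 logical (per block); loss averaged
## over rows, summed over the four blocks.
netForwardBackward <- function(weights, biases, X, Y, mask, blocks,
                               weightDecay, activation = "sigmoid") {
  n <- nrow(X)
  fw <- netForward(weights, biases, X, blocks, activation)
  P <- fw$P
  dZ <- matrix(0, n, ncol(P))
  loss <- 0
  for (bi in seq_along(blocks)) {
    idx <- blocks[[bi]]
    mk <- mask[, bi]
    if (!any(mk)) next
    Pb <- P[mk, idx, drop = FALSE]
    Yb <- Y[mk, idx, drop = FALSE]
    loss <- loss - sum(Yb * log(pmax(Pb, 1e-300))) / n
    dZ[mk, idx] <- (Pb - Yb) / n
  }
  L <- length(weights)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dZ
  for (l in L:1) {
    gW[[l]] <- crossprod(fw$H[[l]], delta) + weightDecay * weights[[l]]
    gb[[l]] <- colSums(delta)
    loss <- loss + weightDecay / 2 * sum(weights[[l]]^2)
    if (l > 1L) {
      dH <- tcrossprod(delta, weights[[l]])
      delta <- if (activation == "linear") dH
               else dH * fw$H[[l]] * (1 - fw$H[[l]])
    }
  }
  list(loss = loss, gW = gW, gb = gb, P = P)
}

#' Train the angle-probability network
#'
#' Initialises the hidden layers by sparse-autoencoder pretraining (unless
#' \code{pretrained} is supplied), then fine-tunes all layers by minibatch
#' SGD on the cross-entropy summed over the four per-angle softmax blocks.
#' Residues with an undefined angle contribute no loss or gradient for
#' that angle's block; the other blocks still train. Fully deterministic
#' given the configuration seed.
#'
#' @param features numeric matrix, residues x feature dimension.
#' @param targets a \linkS4class{TargetMatrix} aligned with the rows.
#' @param config a \linkS4class{NetworkConfig}.
#' @param pretrained optional result of \code{pretrainNetwork}.
#' @param activation hidden activation, "sigmoid" (default) or "linear".
#' @return a \linkS4class{NetworkModel} whose \code{meta} records the
#'   full-data loss curve (element 1 = before the first update).
#' @export
trainNetwork <- function(features, targets, config = networkConfig(),
                         pretrained = NULL, activation = "sigmoid") {
  stopifnot(is(targets, "TargetMatrix"), is(config, "NetworkConfig"))
  X <- as.matrix(features)
  Y <- targets@encoding
  mask <- targets@defined
  if (nrow(X) != nrow(Y))
    stop("feature and target row counts differ", call. = FALSE)
  if (!any(mask)) stop("all target rows are masked", call. = FALSE)
  scheme <- targets@scheme
  blocks <- schemeBlocks(scheme)
  if (is.null(pretrained))
    pretrained <- pretrainNetwork(X, config, activation)
  nL <- length(config@hidden)
  withSeed(config@seed + 1L, {
    weights <- c(pretrained$weights, list(initLayer(config@hidden[nL],
                                                    scheme@total)))
    biases <- c(pretrained$biases, list(numeric(scheme@total)))
    n <- nrow(X)
    lrs <- config@finetuneLR
    lossCurve <- numeric(config@epochs + 1L)
    lossCurve[1L] <- netForwardBackward(weights, biases, X, Y, mask, blocks,
                                        config@weightDecay, activation)$loss
    for (ep in seq_len(config@epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config@batchSize)) {
        sel <- ord[start:min(start + config@batchSize - 1L, n)]
        g <- netForwardBackward(weights, biases, X[sel, , drop = FALSE],
                                Y[sel, , drop = FALSE],
                                mask[sel, , drop = FALSE], blocks,
                                config@weightDecay, activation)
        for (l in seq_along(weights)) {
          weights[[l]] <- weights[[l]] - lrs[l] * g$gW[[l]]
          biases[[l]] <- biases[[l]] - lrs[l] * g$gb[[l]]
        }
      }
      lossCurve[ep + 1L] <- netForwardBackward(weights, biases, X, Y, mask,
                                               blocks, config@weightDecay,
                                               activation)$loss
    }
    new("NetworkModel", weights = weights, biases = biases,
        inputDim = ncol(X), scheme = scheme, config = config,
        meta = list(lossCurve = lossCurve, activation = activation,
                    nTrain = n,
                    dataFingerprint = c(nrow(X), ncol(X), sum(X))))
  })
}

#' Predict per-residue angle-bin probabilities
#'
#' Pure forward pass: each per-angle output block is a softmax, so every
#' block row sums to 1.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param features numeric matrix with \code{inputDim} columns.
#' @return a \linkS4class{ProbabilityProfile}.
#' @export
predictProfile <- function(model, features) {
  stopifnot(is(model, "NetworkModel"))
  X <- as.matrix(features)
  if (ncol(X) != model@inputDim)
    stop(sprintf("feature dimension %d does not match model input %d",
                 ncol(X), model@inputDim), call. = FALSE)
  act <- model@meta$activation
  if (is.null(act)) act <- "sigmoid"
  fw <- netForward(model@weights, model@biases, X,
                   schemeBlocks(model@scheme), act)
  new("ProbabilityProfile", probs = fw$P, scheme = model@scheme)
}

#' @rdname predictProfile
#' @param object a \linkS4class{NetworkModel} (generic dispatch).
#' @param ... passed on; the first element is taken as \code{features}.
#' @export
setMethod("predict", "NetworkModel", function(object, ...)
  predictProfile(object, ..1))

#' Chain-wise k-fold cross-validation
#'
#' Splits whole chains (never residues) into folds, trains on all but one
#' fold and evaluates bin and top-5 accuracy on the held-out fold. The
#' pooled summary is computed from total correct counts over all folds,
#' i.e. it equals the residue-weighted mean of the per-fold accuracies.
#'
#' @param features numeric matrix, residues x feature dimension.
#' @param targets a \linkS4class{TargetMatrix}.
#' @param chains vector assigning each residue row to a chain.
#' @param folds number of folds; default 10.
#' @param config a \linkS4class{NetworkConfig}.
#' @param angles optional \linkS4class{AngleTable} of the true angles; when
#'   given, two-state accuracy is reported for phi and psi (NA otherwise).
#' @return list with \code{folds} (per-fold, per-kind data.frame) and
#'   \code{pooled} (per-kind data.frame of pooled accuracies).
#' @export
crossValidate <- function(features, targets, chains, folds = 10L,
                          config = networkConfig(), angles = NULL) {
  X <- as.matrix(features)
  uc <- unique(chains)
  if (folds > length(uc))
    stop("more folds than chains", call. = FALSE)
  assign <- withSeed(config@seed + 2L,
                     sample(rep(seq_len(folds), length.out = length(uc))))
  names(assign) <- as.character(uc)
  rows <- list(); pooledCorrect <- list()
  perFold <- NULL
  for (f in seq_len(folds)) {
    test <- chains %in% uc[assign == f]
    sub <- subsetTargets(targets, !test)
    model <- trainNetwork(X[!test, , drop = FALSE], sub, config)
    pred <- predictProfile(model, X[test, , drop = FALSE])
    tsub <- subsetTargets(targets, test)
    asub <- if (is.null(angles)) NULL else
      new("AngleTable", angles = angles@angles[test, , drop = FALSE],
          defined = angles@defined[test, , drop = FALSE])
    for (k in ANGLE_KINDS) {
      nk <- sum(definedMask(tsub, k))
      ba <- if (nk) binAccuracy(pred, tsub, k) else NA_real_
      t5 <- if (nk) topkAccuracy(pred, tsub, k, 5L) else NA_real_
      ts <- if (!is.null(asub) && k %in% c("phi", "psi") && nk)
        twoStateAccuracy(pred, asub, k) else NA_real_
      perFold <- rbind(perFold,
                       data.frame(fold = f, kind = k, n = nk,
                                  binAccuracy = ba, top5Accuracy = t5,
                                  twoStateAccuracy = ts))
    }
  }
  pooled <- do.call(rbind, lapply(ANGLE_KINDS, function(k) {
    sub <- perFold[perFold$kind == k & perFold$n > 0, ]
    data.frame(kind = k, n = sum(sub$n),
               binAccuracy = sum(sub$binAccuracy * sub$n) / sum(sub$n),
               top5Accuracy = sum(sub$top5Accuracy * sub$n) / sum(sub$n))
  }))
  list(folds = perFold, pooled = pooled)
}

subsetTargets <- function(targets, keep) targets[keep]
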