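## Synthetic inputs for building and testing every other module without
## external data: ideal-geometry backbone fragments with known torsions,
## a learnable deterministic sequence-to-angle training set, disorder-
## labelled probability profiles, and noise-graded decoy structures.

## Ideal backbone internal coordinates (Angstrom / degrees). These are
## the standard textbook values for building idealised polypeptides; the
## fragments exist to exercise the geometry code, not to model physics.
IDEAL_GEOM <- list(bNCa = 1.458, bCaC = 1.525, bCN = 1.329,
                   aNCaC = 111.0, aCaCN = 116.6, aCNCa = 121.7,
                   omega = 180)

## Place atom D given three predecessors A-B-C, the C-D bond length, the
## B-C-D bond angle and the A-B-C-D torsion (natural extension reference
## frame).
placeAtom <- function(A, B, C, len, angleDeg, torsionDeg) {
  ang <- angleDeg * pi / 180
  tor <- torsionDeg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- crossProd3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- crossProd3(n, bc)
  d2 <- c(-len * cos(ang), len * sin(ang) * cos(tor), len * sin(ang) * sin(tor))
  as.numeric(C + cbind(bc, m, n) %*% d2)
}

#' Build an ideal-geometry backbone fragment
#'
#' Constructs N/CA/C coordinates from fixed bond lengths and angles with
#' per-residue (phi, psi) set by secondary structure: helix "H" uses
#' (-57, -47), strand "E" uses (-120, 120), and coil "C" draws both
#' uniformly from [-175, 175] under the seed. omega is fixed at 180.
#' Recomputing angles from the built coordinates recovers the generating
#' torsions to well under half a degree.
#'
#' @param ss secondary-structure string over {H, E, C}, length >= 4.
#' @param seed integer seed (used by coil residues).
#' @return a \linkS4class{BackboneChain}.
#' @export
buildFragment <- function(ss, seed = 1L) {
  states <- strsplit(ss, "")[[1L]]
  if (length(states) < 4L) stop("fragment must have length >= 4", call. = FALSE)
  if (!all(states %in% c("H", "E", "C")))
    stop("secondary-structure string may contain only H, E, C", call. = FALSE)
  n <- length(states)
  withSeed(seed, {
    phi <- numeric(n); psi <- numeric(n)
    for (i in seq_len(n)) {
      if (states[i] == "H") { phi[i] <- -57; psi[i] <- -47 }
      else if (states[i] == "E") { phi[i] <- -120; psi[i] <- 120 }
      else { phi[i] <- runif(1, -175, 175); psi[i] <- runif(1, -175, 175) }
    }
    g <- IDEAL_GEOM
    N <- CA <- C <- matrix(NA_real_, n, 3L)
    N[1L, ] <- c(0, 0, 0)
    CA[1L, ] <- c(g$bNCa, 0, 0)
    a <- g$aNCaC * pi / 180
    C[1L, ] <- CA[1L, ] + g$bCaC * c(-cos(a), sin(a), 0)
    for (i in 2:n) {
      N[i, ] <- placeAtom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                          g$bCN, g$aCaCN, psi[i - 1L])
      CA[i, ] <- placeAtom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                           g$bNCa, g$aCNCa, g$omega)
      C[i, ] <- placeAtom(C[i - 1L, ], N[i, ], CA[i, ],
                          g$bCaC, g$aNCaC, phi[i])
    }
    new("BackboneChain", chainId = "A", residueIds = seq_len(n),
        residueNames = rep("ALA", n), coordsN = N, coordsCA = CA,
        coordsC = C)
  })
}

#' Generate a learnable sequence-to-angle training set
#'
#' Residue classes are drawn uniformly and each class maps
#' deterministically to one (phi, psi, theta, tau) quadruple lying in
#' distinct bins, so a capable classifier can reach perfect bin accuracy.
#' Features are the one-hot class indicator embedded in the M1 layout
#' (27 x window columns) plus Gaussian noise.
#'
#' @param nChains number of chains.
#' @param chainLen residues per chain.
#' @param seed integer seed.
#' @param nClasses number of residue classes; default 6.
#' @param noise feature noise standard deviation; default 0.05.
#' @param width bin width of the target scheme; default 5.
#' @param featureDim feature dimension; default 351 (the M1 layout).
#' @return list with \code{features} (matrix), \code{targets}
#'   (\linkS4class{TargetMatrix}), \code{chains} (chain id per row),
#'   \code{classes}, \code{angles} (the generating
#'   \linkS4class{AngleTable}) and \code{classAngles} (the class map).
#' @export
makeTrainingSet <- function(nChains = 20L, chainLen = 100L, seed = 1L,
                            nClasses = 6L, noise = 0.05, width = 5,
                            featureDim = 351L) {
  stopifnot(nChains >= 1L, chainLen >= 1L, nClasses >= 2L,
            featureDim >= nClasses)
  scheme <- makeScheme(width)
  step360 <- 360 / nClasses
  step180 <- 180 / nClasses
  classAngles <- cbind(
    phi = -180 + (seq_len(nClasses) - 0.5) * step360,
    psi = wrapTo180(-180 + (seq_len(nClasses) - 0.5) * step360 + step360 / 2),
    theta = (seq_len(nClasses) - 0.5) * step180,
    tau = wrapTo180(-180 + (nClasses - seq_len(nClasses) + 0.5) * step360))
  n <- nChains * chainLen
  withSeed(seed, {
    classes <- sample.int(nClasses, n, replace = TRUE)
    X <- matrix(rnorm(n * featureDim, 0, noise), n, featureDim)
    X[cbind(seq_len(n), classes)] <- X[cbind(seq_len(n), classes)] + 1
    colnames(X) <- sprintf("f%03d", seq_len(featureDim))
    ang <- classAngles[classes, , drop = FALSE]
    colnames(ang) <- ANGLE_KINDS
    angles <- new("AngleTable", angles = ang,
                  defined = matrix(TRUE, n, 4L,
                                   dimnames = list(NULL, ANGLE_KINDS)))
    list(features = X, targets = encodeTargets(angles, scheme),
         chains = rep(seq_len(nChains), each = chainLen),
         classes = classes, angles = angles, classAngles = classAngles)
  })
}

## Dirichlet draw via normalised gammas
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[1L] <- 1
  g / sum(g)
}

## Discretised wrapped Gaussian over K bins centered at `center`
peakedDist <- function(K, center, sdBins) {
  d <- abs(seq_len(K) - center)
  d <- pmin(d, K - d)  # wrap
  w <- exp(-0.5 * (d / sdBins)^2)
  w / sum(w)
}

#' Generate disorder-labelled probability profiles
#'
#' Disorder occurs in contiguous segments (as in real annotations).
#' Disordered residues receive near-uniform bin distributions (symmetric
#' Dirichlet, concentration 5); ordered residues receive a mixture that
#' interpolates, with weight \code{separation}, between the same
#' near-uniform draw and a sharply peaked distribution around a
#' per-segment angle bin. At separation 0 the two classes are identically
#' distributed; at 1 ordered residues are maximally concentrated.
#'
#' @param nRes number of residues.
#' @param fracDisordered expected fraction of disordered residues;
#'   default 0.3.
#' @param separation class-separation parameter in [0, 1].
#' @param seed integer seed.
#' @param width bin width of the scheme; default 5.
#' @return list with \code{profile} (\linkS4class{ProbabilityProfile}) and
#'   \code{labels} (integer 0/1 per residue, 1 = disordered).
#' @export
makeDisorderProfiles <- function(nRes, fracDisordered = 0.3, separation = 1,
                                 seed = 1L, width = 5) {
  if (separation < 0 || separation > 1)
    stop("'separation' must lie in [0, 1]", call. = FALSE)
  scheme <- makeScheme(width)
  withSeed(seed, {
    labels <- integer(0)
    segId <- integer(0)
    s <- 0L
    while (length(labels) < nRes) {
      s <- s + 1L
      len <- sample(10:30, 1L)
      lab <- rbinom(1L, 1L, fracDisordered)
      labels <- c(labels, rep(lab, len))
      segId <- c(segId, rep(s, len))
    }
    labels <- labels[seq_len(nRes)]
    segId <- segId[seq_len(nRes)]
    blocks <- schemeBlocks(scheme)
    probs <- matrix(0, nRes, scheme@total)
    for (k in ANGLE_KINDS) {
      K <- scheme@bins[[k]]
      segCenter <- sample.int(K, max(segId), replace = TRUE)
      for (i in seq_len(nRes)) {
        base <- rdirichlet1(rep(5, K))
        p <- if (labels[i] == 1L) base
             else (1 - separation) * base +
               separation * peakedDist(K, segCenter[segId[i]], 1.5)
        probs[i, blocks[[k]]] <- p
      }
    }
    list(profile = new("ProbabilityProfile", probs = probs, scheme = scheme),
         labels = labels)
  })
}

#' Concentrated probability profile around known angles
#'
#' Builds a \linkS4class{ProbabilityProfile} whose mass is a discretised
#' wrapped Gaussian (sd \code{sdBins} bins) around each residue's true
#' angle bin; residues with undefined angles get a uniform block. Emulates
#' a confident predictor for end-to-end experiments.
#'
#' @param angles an \linkS4class{AngleTable}.
#' @param scheme a \linkS4class{BinScheme}.
#' @param sdBins spread of the per-residue peak, in bins; default 2.
#' @return a \linkS4class{ProbabilityProfile}.
#' @export
profileFromAngles <- function(angles, scheme, sdBins = 2) {
  stopifnot(is(angles, "AngleTable"), is(scheme, "BinScheme"))
  n <- nResidues(angles)
  probs <- matrix(0, n, scheme@total)
  blocks <- schemeBlocks(scheme)
  for (k in ANGLE_KINDS) {
    K <- scheme@bins[[k]]
    bins <- angleToBin(angleValues(angles, k), k, scheme)
    def <- definedMask(angles, k) & !is.na(bins)
    for (i in seq_len(n)) {
      probs[i, blocks[[k]]] <- if (def[i]) peakedDist(K, bins[i], sdBins)
                               else rep(1 / K, K)
    }
  }
  new("ProbabilityProfile", probs = probs, scheme = scheme)
}

## Random proper rotation matrix
randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Generate noise-graded decoy structures
#'
#' Each decoy is the native chain with isotropic Gaussian noise of the
#' given standard deviation added to every backbone atom coordinate,
#' followed by a random rigid motion (so superposition is exercised).
#'
#' @param native a \linkS4class{BackboneChain}.
#' @param sigmas positive noise levels in Angstrom.
#' @param nPerSigma decoys per noise level; default 5.
#' @param seed integer seed.
#' @return list with \code{decoys} (list of \linkS4class{BackboneChain})
#'   and \code{sigma} (the noise level of each decoy).
#' @export
makeDecoys <- function(native, sigmas = c(0.5, 1, 2, 4, 8), nPerSigma = 5L,
                       seed = 1L) {
  stopifnot(is(native, "BackboneChain"))
  if (any(sigmas <= 0)) stop("'sigmas' must be positive", call. = FALSE)
  n <- nResidues(native)
  withSeed(seed, {
    decoys <- list(); sig <- numeric(0)
    for (s in sigmas) for (j in seq_len(nPerSigma)) {
      R <- randomRotation()
      tr <- runif(3, -10, 10)
      jitter <- function(m) sweep((m + matrix(rnorm(n * 3L, 0, s), n, 3L)) %*% R,
                                  2L, tr, "+")
      decoys[[length(decoys) + 1L]] <-
        new("BackboneChain", chainId = native@chainId,
            residueIds = native@residueIds,
            residueNames = native@residueNames,
            coordsN = jitter(native@coordsN),
            coordsCA = jitter(native@coordsCA),
            coordsC = jitter(native@coordsC))
      sig <- c(sig, s)
    }
    list(decoys = decoys, sigma = sig)
  })
}

#' Generate a synthetic PSSM profile for a sequence
#'
#' Integer log-odds scores favouring the observed residue (its own column
#' raised, others drawn around zero), sufficient to exercise the feature
#' builders and file round trips.
#'
#' @param sequence character vector of 1-letter codes (or a single string).
#' @param seed integer seed.
#' @return a \linkS4class{PssmProfile}.
#' @export
makePssm <- function(sequence, seed = 1L) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1L]]
  alpha <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  n <- length(sequence)
  withSeed(seed, {
    scores <- matrix(as.numeric(sample(-3:3, n * 20L, replace = TRUE)), n, 20L,
                     dimnames = list(NULL, alpha))
    hit <- match(toupper(sequence), alpha)
    ok <- !is.na(hit)
    scores[cbind(which(ok), hit[ok])] <- scores[cbind(which(ok), hit[ok])] + 6
    new("PssmProfile", sequence = toupper(sequence), scores = scores)
  })
}
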