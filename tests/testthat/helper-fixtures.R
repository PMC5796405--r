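## Shared fixtures and independent oracles, all built in code.

KINDS <- c("phi", "psi", "theta", "tau")

## Toy 3-residue PDB text with full N/CA/C backbone (idealised but fake
## coordinates; only parsing behaviour matters).
toyPdbText <- function() {
  paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.004   1.424   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       4.049   2.796   0.100  1.00  0.00           C",
    "ATOM      6  C   GLY A   2       5.495   2.600   0.480  1.00  0.00           C",
    "ATOM      7  N   SER A   3       6.300   3.660   0.440  1.00  0.00           N",
    "ATOM      8  CA  SER A   3       7.730   3.600   0.720  1.00  0.00           C",
    "ATOM      9  C   SER A   3       8.480   4.900   0.500  1.00  0.00           C",
    "END",
    sep = "\n")
}

## A valid random ProbabilityProfile on a scheme.
randomProfile <- function(n, scheme = makeScheme(5), seed = 1) {
  set.seed(seed)
  probs <- matrix(0, n, schemeTotal(scheme))
  off <- 0L
  for (K in binCounts(scheme)) {
    block <- matrix(rexp(n * K), n, K)
    probs[, off + seq_len(K)] <- block / rowSums(block)
    off <- off + K
  }
  new("ProbabilityProfile", probs = probs, scheme = scheme)
}

## AngleTable with all angles defined, drawn uniformly in range.
randomAngleTable <- function(n, seed = 1) {
  set.seed(seed)
  ang <- cbind(phi = runif(n, -180, 180 - 1e-9),
               psi = runif(n, -180, 180 - 1e-9),
               theta = runif(n, 0, 180),
               tau = runif(n, -180, 180 - 1e-9))
  new("AngleTable", angles = ang,
      defined = matrix(TRUE, n, 4L, dimnames = list(NULL, KINDS)))
}

## Independent dihedral oracle: atan2(|b2| * b1.(b2 x b3), (b1 x b2).(b2 x b3))
oracleDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  y <- sqrt(sum(b2^2)) * sum(b1 * cr(b2, b3))
  x <- sum(cr(b1, b2) * cr(b2, b3))
  d <- atan2(y, x) * 180 / pi
  ((d + 180) %% 360) - 180
}

oraclePlanar <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

## Brute-force bin lookup by scanning bin edges.
oracleBin <- function(angle, kind, scheme) {
  lo <- scheme@lower[[kind]]
  K <- binCounts(scheme)[[kind]]
  w <- scheme@width
  for (i in seq_len(K)) {
    lo_i <- lo + (i - 1) * w
    hi_i <- lo + i * w
    closed <- kind == "theta" && i == K
    if (angle >= lo_i && (angle < hi_i || (closed && angle <= hi_i)))
      return(i)
  }
  NA_integer_
}

randomRigidMotion <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = runif(3, -20, 20))
}

applyRigid <- function(chain, R, t) {
  new("BackboneChain", chainId = chain@chainId,
      residueIds = chain@residueIds, residueNames = chain@residueNames,
      coordsN = sweep(chain@coordsN %*% R, 2, t, "+"),
      coordsCA = sweep(chain@coordsCA %*% R, 2, t, "+"),
      coordsC = sweep(chain@coordsC %*% R, 2, t, "+"))
}

## tiny fast network config for unit tests
tinyConfig <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(hidden = c(16L, 16L, 16L), pretrainEpochs = 2L,
                   epochs = 25L, batchSize = 32L, seed = seed)
  do.call(networkConfig, utils::modifyList(defaults, args))
}

subsetTargets <- torsionGrid:::subsetTargets
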