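test_that("bin schemes have the canonical counts and reject bad widths", {
  s5 <- makeScheme(5)
  expect_equal(binCounts(s5), c(phi = 72L, psi = 72L, theta = 36L,
                                tau = 72L))
  expect_equal(schemeTotal(s5), 252L)
  s10 <- makeScheme(10)
  expect_equal(schemeTotal(s10), 126L)
  expect_equal(binCounts(s10)[["theta"]], 18L)
  expect_error(makeScheme(7), "divisor")
  expect_error(makeScheme(0), "divisor")
})

test_that("angleToBin matches an exhaustive edge-scan oracle", {
  for (w in c(5, 10)) {
    s <- makeScheme(w)
    set.seed(w)
    for (k in KINDS) {
      lo <- if (k == "theta") 0 else -180
      hi <- if (k == "theta") 180 else 180 - 1e-9
      a <- c(runif(500, lo, hi), lo, hi,
             lo + s@width, lo + s@width - 1e-9)  # interior edges
      got <- angleToBin(a, k, s)
      want <- vapply(a, oracleBin, integer(1), kind = k, scheme = s)
      expect_identical(got, want)
    }
  }
})

test_that("bin boundaries follow the half-open convention with closed theta top", {
  s <- makeScheme(5)
  expect_identical(angleToBin(-180, "phi", s), 1L)
  expect_identical(angleToBin(179.9, "phi", s), 72L)
  expect_identical(angleToBin(180, "phi", s), 1L)    # wraps to -180
  expect_identical(angleToBin(180, "theta", s), 36L) # closed last bin
  expect_identical(angleToBin(0, "theta", s), 1L)
  expect_true(is.na(angleToBin(NA_real_, "phi", s)))
})

test_that("binCenter round-trips through angleToBin for every bin of every kind", {
  for (w in c(5, 10)) {
    s <- makeScheme(w)
    for (k in KINDS) {
      idx <- seq_len(binCounts(s)[[k]])
      expect_identical(angleToBin(binCenter(idx, k, s), k, s), idx)
    }
  }
  s <- makeScheme(5)
  expect_equal(binCenter(1L, "phi", s), -177.5)
  expect_equal(binCenter(36L, "theta", s), 177.5)
  expect_error(binCenter(73L, "phi", s), "out of range")
})

test_that("encodeTargets produces one-hot rows with masked zero blocks", {
  at <- randomAngleTable(40, seed = 3)
  at@defined[5, "psi"] <- FALSE
  s <- makeScheme(5)
  tm <- encodeTargets(at, s)
  expect_equal(ncol(tm@encoding), 252L)
  for (k in KINDS) {
    block <- angleBlock(tm, k)
    rs <- rowSums(block)
    expect_true(all(rs[definedMask(tm, k)] == 1))
    expect_true(all(rs[!definedMask(tm, k)] == 0))
  }
  ## phi = -57 goes in the 25th 5-degree bin (edge-scan oracle agrees)
  at2 <- randomAngleTable(1)
  at2@angles[1, "phi"] <- -57
  tm2 <- encodeTargets(at2, s)
  expect_equal(which(angleBlock(tm2, "phi")[1, ] == 1), 25L)
  expect_identical(oracleBin(-57, "phi", s), 25L)
})

test_that("merging 5-degree encodings equals direct 10-degree encoding", {
  at <- randomAngleTable(300, seed = 8)
  f5 <- encodeTargets(at, makeScheme(5))
  ## one-hot rows are valid probability rows, so reuse them directly
  p5 <- new("ProbabilityProfile", probs = f5@encoding, scheme = makeScheme(5))
  merged <- mergeToCoarse(p5, 2L)
  direct <- encodeTargets(at, makeScheme(10))
  expect_equal(merged@probs, direct@encoding, ignore_attr = TRUE)
})

test_that("mergeToCoarse preserves mass and maps one-hots to the parent bin", {
  prof <- randomProfile(50, seed = 5)
  merged <- mergeToCoarse(prof, 2L)
  for (k in KINDS) {
    expect_equal(rowSums(angleBlock(merged, k)), rep(1, 50))
    ## pairwise-sum oracle
    fine <- angleBlock(prof, k)
    K <- ncol(fine)
    want <- fine[, seq(1, K, 2)] + fine[, seq(2, K, 2)]
    expect_equal(angleBlock(merged, k), want, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  ## one-hot at fine bin 7 -> coarse bin 4 (1-based ceiling of 7/2)
  s <- makeScheme(5)
  onehot <- matrix(0, 1, 252); onehot[1, 7] <- 1
  onehot[1, 72 + 1] <- 1; onehot[1, 144 + 1] <- 1; onehot[1, 180 + 1] <- 1
  p <- new("ProbabilityProfile", probs = onehot, scheme = s)
  m <- mergeToCoarse(p, 2L)
  expect_equal(which(angleBlock(m, "phi")[1, ] == 1), 4L)
  ## uniform stays uniform
  u <- new("ProbabilityProfile",
           probs = matrix(rep(1 / binCounts(s)[KINDS],
                              times = binCounts(s)[KINDS]), 1, 252),
           scheme = s)
  mu <- mergeToCoarse(u, 2L)
  expect_equal(angleBlock(mu, "phi")[1, ], rep(1 / 36, 36))
  expect_error(mergeToCoarse(prof, 5L), "divide")
})

test_that("bin and top-k accuracy equal naive per-residue oracles", {
  n <- 120
  prof <- randomProfile(n, seed = 2)
  at <- randomAngleTable(n, seed = 4)
  at@defined[sample(n, 10), "phi"] <- FALSE
  tm <- encodeTargets(at, makeScheme(5))
  for (k in KINDS) {
    block <- angleBlock(prof, k)
    truth <- angleBlock(tm, k)
    def <- which(definedMask(tm, k))
    naiveBin <- mean(vapply(def, function(i)
      which.max(block[i, ]) == which(truth[i, ] == 1), logical(1)))
    expect_equal(binAccuracy(prof, tm, k), naiveBin)
    for (kk in c(1L, 5L)) {
      naiveTop <- mean(vapply(def, function(i) {
        ranks <- rank(-block[i, ], ties.method = "first")
        ranks[which(truth[i, ] == 1)] <= kk
      }, logical(1)))
      expect_equal(topkAccuracy(prof, tm, k, kk), naiveTop)
    }
  }
})

test_that("accuracy edge cases: perfect prediction, ties, k = bin count", {
  at <- randomAngleTable(30, seed = 9)
  s <- makeScheme(5)
  tm <- encodeTargets(at, s)
  perfect <- new("ProbabilityProfile", probs = tm@encoding, scheme = s)
  expect_equal(binAccuracy(perfect, tm, "tau"), 1.0)
  expect_equal(topkAccuracy(perfect, tm, "tau", 72L), 1.0)
  ## uniform prediction: argmax tie-breaks to bin 1
  u <- new("ProbabilityProfile",
           probs = matrix(rep(1 / binCounts(s)[KINDS],
                              times = binCounts(s)[KINDS]), 30, 252,
                          byrow = TRUE), scheme = s)
  frac1 <- mean(angleBlock(tm, "phi")[, 1] == 1)
  expect_equal(binAccuracy(u, tm, "phi"), frac1)
  expect_equal(topkAccuracy(u, tm, "phi", 72L), 1.0)
  ## truth ranked exactly 5th counts for k=5, not k=4
  probs <- matrix(0, 1, 252)
  probs[1, 1:72] <- c(6:2, rep(1, 67)) / sum(c(6:2, rep(1, 67)))
  for (off in c(72, 144, 180)) probs[1, off + 1] <- 1
  p1 <- new("ProbabilityProfile", probs = probs, scheme = s)
  at1 <- randomAngleTable(1)
  at1@angles[1, "phi"] <- binCenter(5L, "phi", s)
  tm1 <- encodeTargets(at1, s)
  expect_equal(topkAccuracy(p1, tm1, "phi", 5L), 1.0)
  expect_equal(topkAccuracy(p1, tm1, "phi", 4L), 0.0)
  ## undefined-metric signal
  at1@defined[, "psi"] <- FALSE
  tm0 <- encodeTargets(at1, s)
  expect_warning(res <- binAccuracy(p1, tm0, "psi"), "undefined")
  expect_true(is.na(res))
})

test_that("two-state split follows the stated intervals with closed boundaries", {
  expect_identical(twoState(90, "phi"), "A")
  expect_identical(twoState(100, "psi"), "B")
  expect_identical(twoState(150, "phi"), "A")
  expect_identical(twoState(150.01, "phi"), "B")
  expect_identical(twoState(-1e-9, "phi"), "B")
  expect_identical(twoState(c(-100, 60), "psi"), c("A", "A"))
  expect_identical(twoState(c(-100.01, 60.01), "psi"), c("B", "B"))
  expect_error(twoState(10, "theta"), "phi and psi")
})
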