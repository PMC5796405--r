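test_that("background estimation equals a naive histogram with pseudocounts", {
  at <- randomAngleTable(500, seed = 31)
  s <- makeScheme(5)
  bg <- estimateBackground(at, s, pseudocount = 1)
  for (k in KINDS) {
    bins <- angleToBin(angleValues(at, k), k, s)
    K <- binCounts(s)[[k]]
    naive <- (tabulate(bins, K) + 1) / (length(bins) + K)
    expect_equal(bg@freq[[k]], naive, tolerance = 1e-12)
    expect_true(all(bg@freq[[k]] > 0))
    expect_equal(sum(bg@freq[[k]]), 1, tolerance = 1e-12)
  }
  ## all mass in one bin with pseudocount 0
  at1 <- randomAngleTable(50, seed = 32)
  at1@angles[, "phi"] <- -57
  bg0 <- estimateBackground(at1, s, pseudocount = 0)
  expect_equal(bg0@freq[["phi"]][25], 1)
  expect_error(estimateBackground(list(), s), "empty")
})

test_that("PE-score anchors: background profile gives 0, doubled probability gives ln 2", {
  s <- makeScheme(5)
  at <- randomAngleTable(20, seed = 33)
  bg <- estimateBackground(randomAngleTable(1000, seed = 34), s)
  ## profile equal to the background at every bin
  bgRow <- unlist(bg@freq[KINDS], use.names = FALSE)
  prof <- new("ProbabilityProfile",
              probs = matrix(bgRow, 20, 252, byrow = TRUE), scheme = s)
  expect_equal(as.numeric(peScore(prof, at, bg, "phi")), 0,
               tolerance = 1e-9)
  ## single residue with P = 2 * P0 at its occupied bin
  at1 <- randomAngleTable(1, seed = 35)
  bin <- angleToBin(angleValues(at1, "phi"), "phi", s)
  row <- bgRow
  extra <- bg@freq[["phi"]][bin]
  row[bin] <- 2 * extra
  row[1:72] <- row[1:72] / sum(row[1:72])  # renormalise the phi block
  scale <- 1 + extra
  prof1 <- new("ProbabilityProfile", probs = matrix(row, 1, 252,
                                                    byrow = TRUE),
               scheme = s)
  expect_equal(as.numeric(peScore(prof1, at1, bg, "phi")),
               log(2 / scale), tolerance = 1e-9)
})

test_that("PE-score equals a naive per-residue loop, floors zero probabilities, respects masks", {
  s <- makeScheme(5)
  prof <- randomProfile(40, seed = 36)
  at <- randomAngleTable(40, seed = 37)
  at@defined[1:5, "tau"] <- FALSE
  bg <- estimateBackground(randomAngleTable(800, seed = 38), s)
  got <- peScore(prof, at, bg, "tau")
  block <- angleBlock(prof, "tau")
  naive <- 0
  for (i in 6:40) {
    b <- angleToBin(angleValues(at, "tau")[i], "tau", s)
    naive <- naive + log(max(block[i, b], 1e-8) / bg@freq[["tau"]][b])
  }
  expect_equal(as.numeric(got), naive, tolerance = 1e-9)
  expect_equal(attr(got, "n"), 35L)
  expect_equal(as.numeric(peScore(prof, at, bg, "tau", perResidue = TRUE)),
               naive / 35, tolerance = 1e-9)
  ## zero probability at an occupied bin is floored and counted
  prof0 <- prof
  bins <- angleToBin(angleValues(at, "tau"), "tau", s)
  tauOffset <- 72 + 72 + 36
  prof0@probs[cbind(6, tauOffset + bins[6])] <- 0
  got0 <- peScore(prof0, at, bg, "tau")
  expect_equal(attr(got0, "nFloored"), 1L)
  ## combined = sum of the four per-angle scores
  all4 <- peScoreAll(prof, at, bg)
  expect_equal(all4[["combined"]],
               sum(all4[KINDS]), tolerance = 1e-12)
})

test_that("Kabsch superposition recovers rigid motions and applied rotations", {
  chain <- buildFragment("HHHHEEEECCCCHHHH", seed = 41)
  ca <- caCoords(chain)
  ident <- kabschSuperpose(ca, ca)
  expect_equal(ident$d, rep(0, nrow(ca)), tolerance = 1e-9)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-9)
  shifted <- sweep(ca, 2, c(5, 0, 0), "+")
  sup <- kabschSuperpose(shifted, ca)
  expect_equal(sup$d, rep(0, nrow(ca)), tolerance = 1e-9)
  ## known rotation + small noise: rotation recovered, RMSD near sigma
  set.seed(42)
  rm <- randomRigidMotion(42)
  sigma <- 0.1
  noisy <- sweep(ca %*% rm$R, 2, rm$t, "+") +
    matrix(rnorm(length(ca), 0, sigma), nrow(ca), 3)
  sup2 <- kabschSuperpose(noisy, ca)
  expect_equal(sup2$rotation, t(rm$R), tolerance = 1e-2)
  expect_lt(abs(sup2$rmsd - sigma * sqrt(3) * sqrt(1 - 6 / (2 * nrow(ca)))),
            3 * sigma)
  ## superposed model reproduces the distances from the returned transform
  fitted <- sweep(noisy %*% sup2$rotation, 2, sup2$translation, "+")
  expect_equal(sqrt(rowSums((fitted - ca)^2)), sup2$d, tolerance = 1e-9)
  expect_error(kabschSuperpose(ca[1:2, ], ca[1:2, ]), "at least 3")
})

test_that("Kabsch RMSD matches bio3d's least-squares fit", {
  skip_if_not_installed("bio3d")
  chain <- buildFragment("HHHHHHEEEEEECCC", seed = 43)
  ca <- caCoords(chain)
  dec <- makeDecoys(chain, sigmas = 2, nPerSigma = 1, seed = 43)
  mob <- caCoords(dec$decoys[[1]])
  ours <- kabschSuperpose(mob, ca)
  inds <- seq_len(3 * nrow(ca))
  ref <- bio3d::fit.xyz(fixed = as.numeric(t(ca)),
                        mobile = as.numeric(t(mob)),
                        fixed.inds = inds, mobile.inds = inds)
  refd <- sqrt(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - ca)^2))
  expect_equal(ours$rmsd, sqrt(mean(refd^2)), tolerance = 1e-6)
})

test_that("superposition is invariant to pre-rotations and never increases RMSD", {
  chain <- buildFragment("HHHHEEEECCCC", seed = 44)
  ca <- caCoords(chain)
  dec <- makeDecoys(chain, sigmas = 1, nPerSigma = 1, seed = 44)
  mob <- caCoords(dec$decoys[[1]])
  base <- kabschSuperpose(mob, ca)
  for (s in 1:3) {
    rm <- randomRigidMotion(100 + s)
    sup <- kabschSuperpose(sweep(mob %*% rm$R, 2, rm$t, "+"), ca)
    expect_equal(sup$d, base$d, tolerance = 1e-6)
  }
  rmsdBefore <- sqrt(mean(rowSums((mob - ca)^2)))
  expect_lte(base$rmsd, rmsdBefore + 1e-9)
})

test_that("S-score and GDT-like score follow their closed forms", {
  expect_equal(sScore(0), 1.0)
  expect_equal(sScore(3), 0.5)
  expect_equal(sScore(6), 0.2)
  expect_error(sScore(-1), "non-negative")
  d <- seq(0, 10, by = 0.1)
  expect_true(all(diff(sScore(d)) < 0))
  expect_equal(gdtLike(rep(0, 10)), 1.0)
  expect_equal(gdtLike(rep(10, 10)), 0.0)
  expect_equal(gdtLike(c(rep(0.5, 5), rep(5, 5))), (0.5 + 0.5 + 0.5 + 1) / 4)
  ## unmodeled residues penalise via the native-length denominator
  expect_equal(gdtLike(rep(0, 5), lNative = 10), 0.5)
  expect_error(gdtLike(numeric(0)), "empty")
})

test_that("rankModels reproduces the textbook correlation and flags zero variance", {
  q <- c(0.9, 0.7, 0.5, 0.3, 0.2)
  d <- data.frame(target = "t", pe = q, quality = q)
  expect_equal(rankModels(d)$perTarget$pcc, 1.0)
  d$pe <- -q
  expect_equal(rankModels(d)$perTarget$pcc, -1.0)
  set.seed(45)
  pe <- rnorm(10); quality <- rnorm(10)
  d2 <- data.frame(target = "t", pe = pe, quality = quality)
  textbook <- sum((pe - mean(pe)) * (quality - mean(quality))) /
    sqrt(sum((pe - mean(pe))^2) * sum((quality - mean(quality))^2))
  expect_equal(rankModels(d2)$perTarget$pcc, textbook, tolerance = 1e-12)
  d3 <- data.frame(target = rep(c("a", "b"), each = 5),
                   pe = c(1:5, rep(1, 5)), quality = c(1:5, 1:5))
  expect_warning(rk <- rankModels(d3), "zero variance")
  expect_equal(rk$perTarget$pcc[rk$perTarget$target == "a"], 1.0)
  expect_true(is.na(rk$perTarget$pcc[rk$perTarget$target == "b"]))
  expect_equal(rk$meanPCC, 1.0)
})
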