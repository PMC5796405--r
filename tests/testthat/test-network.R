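test_that("pretraining is deterministic, seed-initialised at zero epochs, and reduces reconstruction error", {
  ts <- makeTrainingSet(nChains = 2L, chainLen = 30L, seed = 5L,
                        featureDim = 25L)
  cfg <- tinyConfig(seed = 5L)
  a <- pretrainNetwork(ts$features, cfg)
  b <- pretrainNetwork(ts$features, cfg)
  expect_identical(a$weights, b$weights)
  expect_identical(a$biases, b$biases)
  ## zero epochs: weights equal the seeded initialisation (same RNG stream)
  cfg0 <- tinyConfig(seed = 5L, pretrainEpochs = 0L)
  z <- pretrainNetwork(ts$features, cfg0)
  init <- torsionGrid:::withSeed(5L, {
    W1 <- torsionGrid:::initLayer(25L, 16L)
    W1
  })
  expect_identical(z$weights[[1]], init)
  ## full-batch linear autoencoder: loss decreases monotonically
  cfgLin <- networkConfig(hidden = 8L, finetuneLR = c(1, 0.05),
                          pretrainLR = 0.01, pretrainEpochs = 15L,
                          batchSize = 60L, sparsityWeight = 0,
                          weightDecay = 0, seed = 2L)
  lin <- pretrainNetwork(ts$features, cfgLin, activation = "linear")
  expect_true(all(diff(lin$losses[[1]]) <= 1e-12))
})

test_that("training is deterministic, lowers the loss, and errors on bad input", {
  ts <- makeTrainingSet(nChains = 3L, chainLen = 30L, seed = 6L,
                        featureDim = 25L)
  cfg <- tinyConfig(seed = 6L, epochs = 10L)
  m1 <- trainNetwork(ts$features, ts$targets, cfg)
  m2 <- trainNetwork(ts$features, ts$targets, cfg)
  expect_identical(m1@weights, m2@weights)
  lc <- m1@meta$lossCurve
  expect_lt(lc[length(lc)], lc[1])
  expect_error(trainNetwork(ts$features[1:10, ], ts$targets, cfg),
               "row counts differ")
  masked <- ts$targets
  masked@defined[] <- FALSE
  expect_error(trainNetwork(ts$features, masked, cfg), "masked")
})

test_that("the network learns the deterministic class-to-bin mapping", {
  ts <- makeTrainingSet(nChains = 6L, chainLen = 50L, seed = 8L,
                        featureDim = 40L)
  test <- ts$chains > 5
  model <- trainNetwork(ts$features[!test, , drop = FALSE],
                        subsetTargets(ts$targets, !test),
                        tinyConfig(seed = 8L, epochs = 40L))
  pred <- predictProfile(model, ts$features[test, , drop = FALSE])
  held <- subsetTargets(ts$targets, test)
  for (k in KINDS) expect_gte(binAccuracy(pred, held, k), 0.9)
})

test_that("predictions are pure, normalised softmax blocks of the right sizes", {
  ts <- makeTrainingSet(nChains = 2L, chainLen = 20L, seed = 9L,
                        featureDim = 25L)
  model <- trainNetwork(ts$features, ts$targets,
                        tinyConfig(seed = 9L, epochs = 2L))
  p1 <- predictProfile(model, ts$features)
  p2 <- predictProfile(model, ts$features)
  expect_identical(p1@probs, p2@probs)
  expect_equal(vapply(KINDS, function(k) ncol(angleBlock(p1, k)),
                      integer(1)),
               c(phi = 72L, psi = 72L, theta = 36L, tau = 72L))
  for (k in KINDS) {
    expect_equal(rowSums(angleBlock(p1, k)), rep(1, 40), tolerance = 1e-6)
    expect_true(all(angleBlock(p1, k) >= 0))
  }
  expect_error(predictProfile(model, ts$features[, 1:10]),
               "does not match")
})

test_that("analytic gradients match central finite differences", {
  set.seed(17)
  X <- matrix(rnorm(6 * 9), 6, 9)
  at <- randomAngleTable(6, seed = 17)
  at@defined[2, "psi"] <- FALSE  # exercise the mask path
  tg <- encodeTargets(at, makeScheme(90))
  blocks <- torsionGrid:::schemeBlocks(tg@scheme)
  w <- list(torsionGrid:::initLayer(9, 7), torsionGrid:::initLayer(7, 14))
  b <- list(rnorm(7, sd = 0.1), rnorm(14, sd = 0.1))
  g <- torsionGrid:::netForwardBackward(w, b, X, tg@encoding, tg@defined,
                                        blocks, weightDecay = 1e-4)
  eps <- 1e-6
  lossAt <- function(w, b) torsionGrid:::netForwardBackward(
    w, b, X, tg@encoding, tg@defined, blocks, weightDecay = 1e-4)$loss
  for (l in 1:2) {
    for (j in sample(length(w[[l]]), 15)) {
      wp <- w; wp[[l]][j] <- wp[[l]][j] + eps
      wm <- w; wm[[l]][j] <- wm[[l]][j] - eps
      fd <- (lossAt(wp, b) - lossAt(wm, b)) / (2 * eps)
      expect_equal(g$gW[[l]][j], fd, tolerance = 1e-5)
    }
    for (j in sample(length(b[[l]]), 5)) {
      bp <- b; bp[[l]][j] <- bp[[l]][j] + eps
      bm <- b; bm[[l]][j] <- bm[[l]][j] - eps
      fd <- (lossAt(w, bp) - lossAt(w, bm)) / (2 * eps)
      expect_equal(g$gb[[l]][j], fd, tolerance = 1e-5)
    }
  }
})

test_that("masked angle blocks contribute no gradient", {
  set.seed(18)
  X <- matrix(rnorm(4 * 6), 4, 6)
  at <- randomAngleTable(4, seed = 18)
  tg <- encodeTargets(at, makeScheme(90))
  blocks <- torsionGrid:::schemeBlocks(tg@scheme)
  w <- list(torsionGrid:::initLayer(6, 5), torsionGrid:::initLayer(5, 14))
  b <- list(numeric(5), numeric(14))
  gFull <- torsionGrid:::netForwardBackward(w, b, X, tg@encoding,
                                            tg@defined, blocks, 0)
  ## masking psi everywhere zeroes the psi block of the output gradient
  tgm <- tg; tgm@defined[, "psi"] <- FALSE
  gMask <- torsionGrid:::netForwardBackward(w, b, X, tgm@encoding,
                                            tgm@defined, blocks, 0)
  psiCols <- blocks[["psi"]]
  expect_true(all(gMask$gW[[2]][, psiCols] == 0))
  expect_false(all(gFull$gW[[2]][, psiCols] == 0))
})

test_that("cross-validation splits by chain and pools by residue weight", {
  ts <- makeTrainingSet(nChains = 10L, chainLen = 15L, seed = 10L,
                        featureDim = 25L)
  cv <- crossValidate(ts$features, ts$targets, ts$chains, folds = 10L,
                      config = tinyConfig(seed = 10L, epochs = 3L),
                      angles = ts$angles)
  ## 10 identical-size chains over 10 folds: each fold holds out one chain
  perFold <- cv$folds[cv$folds$kind == "phi", ]
  expect_equal(nrow(perFold), 10L)
  expect_true(all(perFold$n == 15L))
  ## pooled equals the residue-weighted mean of the folds
  for (k in KINDS) {
    sub <- cv$folds[cv$folds$kind == k, ]
    expect_equal(cv$pooled$binAccuracy[cv$pooled$kind == k],
                 sum(sub$binAccuracy * sub$n) / sum(sub$n))
  }
  expect_true(all(c("binAccuracy", "top5Accuracy", "twoStateAccuracy")
                  %in% names(cv$folds)))
  expect_true(all(is.na(cv$folds$twoStateAccuracy[cv$folds$kind == "tau"])))
  expect_false(anyNA(cv$folds$twoStateAccuracy[cv$folds$kind == "phi"]))
  ## reproducible
  cv2 <- crossValidate(ts$features, ts$targets, ts$chains, folds = 10L,
                       config = tinyConfig(seed = 10L, epochs = 3L),
                       angles = ts$angles)
  expect_identical(cv$folds, cv2$folds)
  expect_error(crossValidate(ts$features, ts$targets, ts$chains,
                             folds = 11L), "more folds than chains")
})
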