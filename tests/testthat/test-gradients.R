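# Localized backpropagation: closed forms, finite-difference agreement,
# isolation, additivity, and the post hoc (no-modification) contract.

test_that("the gradient seed matches the single-parameter logistic closed form", {
  # p = sigmoid(w) at w = 0: T = p log(2p), dT/dw = (log(2p) + 1) p (1 - p)
  # equals 1/4 at the symmetric point p = 1/2.
  p <- 1 / (1 + exp(0))
  dTdp <- gradUQ:::targetGradient(p, 2L, "kl")
  sigmoidPrime <- p * (1 - p)
  expect_equal(abs(dTdp * sigmoidPrime), 0.25)
  # and the same chain through the two-logit softmax parameterization:
  # p = softmax(z)_1, dp/dz_1 = p(1-p)
  expect_equal(dTdp * p * (1 - p), 0.25)
})

test_that("backprop agrees with the central finite-difference oracle", {
  fix <- tinyModelImage()
  groups <- listParameterGroups(fix$model)
  set.seed(13)
  for (draw in 1:6) {
    vox <- sample(256L, sample(3:20, 1))
    g <- sample(groups, sample(1:2, 1))
    tg <- sample(c("kl", "mp"), 1)
    lg <- localGradientsScore(fix$model, fix$image, vox, tg, g)
    fd <- finiteDifferenceOracle(fix$model, fix$image, vox, tg, g)
    expect_equal(lg, fd, tolerance = 1e-3)
    expect_gte(lg, 0)
  }
})

test_that("L1 aggregation is additive over disjoint groups and monotone", {
  fix <- tinyModelImage()
  vox <- 33:48
  nA <- localGradientsScore(fix$model, fix$image, vox, "kl", "Block_1-0")
  nB <- localGradientsScore(fix$model, fix$image, vox, "kl", "Block_1-1")
  nAB <- localGradientsScore(fix$model, fix$image, vox, "kl",
                             c("Block_1-0", "Block_1-1"))
  expect_equal(nAB, nA + nB, tolerance = 1e-12)
  # adding a group never decreases the score
  n3 <- localGradientsScore(fix$model, fix$image, vox, "kl",
                            c("Block_1-0", "Block_1-1", "Block_0-0"))
  expect_gte(n3, nAB)
})

test_that("per-region scores are isolated and the model is untouched", {
  fix <- tinyModelImage()
  model <- fix$model
  weightsBefore <- model@params
  lmBefore <- predictLabelMap(model, fix$image)

  # five disjoint regions
  vox <- list(1:10, 31:38, 61:70, 101:104, 200:220)
  rsAll <- new("RegionSet",
               regions = lapply(seq_along(vox), function(i) {
                 list(id = i, label = 1L, voxels = as.integer(vox[[i]]),
                      nVoxels = length(vox[[i]]),
                      volumeCm3 = length(vox[[i]]) * 16 / 1000)
               }),
               dim = c(16L, 16L), spacing = c(4, 4), connectivity = "face")
  tabAll <- scoreRegions(model, fix$image, rsAll)
  for (i in seq_along(vox)) {
    alone <- localGradientsScore(model, fix$image, vox[[i]])
    expect_equal(tabAll$lg[i], alone, tolerance = 1e-10)
  }

  # post hoc contract: weights and predictions bit-identical after scoring
  expect_identical(model@params, weightsBefore)
  expect_identical(voxelValues(predictLabelMap(model, fix$image)),
                   voxelValues(lmBefore))
})

test_that("scoring all regions matches independent single-region calls", {
  fix <- tinyModelImage()
  lm <- predictLabelMap(fix$model, fix$image)
  rs <- extractRegions(lm, minVolumeCm3 = 0)
  tab <- scoreRegions(fix$model, fix$image, rs)
  expect_equal(nrow(tab), nRegions(rs))
  if (nrow(tab) > 0L) {
    for (i in seq_len(nrow(tab))) {
      r <- rs@regions[[i]]
      expect_equal(tab$lg[i], localGradientsScore(fix$model, fix$image, r$voxels),
                   tolerance = 1e-12)
      C <- fix$model@arch$classes
      p <- gradUQ:::unetForward(fix$model, fix$image)$p
      cls <- r$label + 1L
      expect_equal(tab$kld[i], klTarget(p[r$voxels, cls], C), tolerance = 1e-12)
    }
  }
  # zero regions -> empty table with the full schema
  emptySet <- extractRegions(LabelMap(matrix(0L, 16, 16), c(4, 4)))
  emptyTab <- scoreRegions(fix$model, fix$image, emptySet)
  expect_equal(nrow(emptyTab), 0L)
  expect_true(all(c("region_id", "lg", "mp", "kld") %in% names(emptyTab)))
})

test_that("invalid group lists and off-grid regions are rejected", {
  fix <- tinyModelImage()
  expect_error(localGradientsScore(fix$model, fix$image, 1:4, groups = character(0)),
               "empty group")
  expect_error(localGradientsScore(fix$model, fix$image, 1:4, groups = "Block_9-0"),
               "unknown parameter group")
  expect_error(localGradientsScore(fix$model, fix$image, c(1L, 400L)), "off")
  expect_error(regionGradientNorms(fix$model, fix$image, integer(0)), "empty region")
})
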