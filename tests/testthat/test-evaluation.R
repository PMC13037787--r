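# Assessment computations: percent differences, AUC, FPR95, rank tests,
# uncertainty tracks, block sweep.

test_that("track percent differences follow the closed forms", {
  expect_equal(percentDiffTrack(list(baseline_u = 1, per_magnitude_u = c(1, 1, 1))),
               c(0, 0, 0))
  expect_equal(percentDiffTrack(list(baseline_u = 1, per_magnitude_u = c(1, 1.2)))[2L],
               20)
  expect_error(percentDiffTrack(list(baseline_u = 0, per_magnitude_u = 1)),
               "baseline is 0")
  expect_error(percentDiffTrack(list(baseline_u = 1,
                                     per_magnitude_u = c(1, NA))),
               "missing")
})

test_that("split regions combine by a volume-weighted average", {
  # baseline: one 5-voxel bar; degraded: 2-voxel and 3-voxel fragments.
  base <- matrix(0L, 10, 10)
  base[3, 3:7] <- 1L
  deg <- matrix(0L, 10, 10)
  deg[3, 3:4] <- 1L   # fragment A, 2 voxels
  deg[3, 6:8] <- 1L   # fragment B, 3 voxels (overlaps baseline at 6:7)
  spacing <- c(10, 10) # voxel "volume" 0.1 cm^3: volumes 0.2 and 0.3
  rsBase <- extractRegions(LabelMap(base, spacing))
  rsDeg <- extractRegions(LabelMap(deg, spacing))
  tabBase <- data.frame(region_id = 1L, volume_cm3 = 0.5, u = 1.0)
  tabDeg <- data.frame(region_id = c(1L, 2L), volume_cm3 = c(0.2, 0.3),
                       u = c(1.0, 2.0))
  tracks <- uncertaintyTracks(list(rsBase, rsDeg), list(tabBase, tabDeg),
                              valueColumn = "u")
  expect_length(tracks, 1L)
  expect_true(tracks[[1L]]$persisting)
  # weighted value (0.2*1 + 0.3*2) / 0.5 = 1.6 -> +60 %
  expect_equal(tracks[[1L]]$per_magnitude_u[2L], 1.6)
  expect_equal(percentDiffTrack(tracks[[1L]])[2L], 60)
})

test_that("non-persisting tracks are flagged when a match disappears", {
  base <- matrix(0L, 10, 10)
  base[3, 3:5] <- 1L
  base[8, 8] <- 1L
  gone <- matrix(0L, 10, 10)
  gone[3, 3:5] <- 1L
  rsBase <- extractRegions(LabelMap(base, c(10, 10)))
  rsGone <- extractRegions(LabelMap(gone, c(10, 10)))
  tb <- function(rs) data.frame(region_id = regionIds(rs),
                                volume_cm3 = regionTable(rs)$volume_cm3,
                                u = 1)
  tracks <- uncertaintyTracks(list(rsBase, rsGone), list(tb(rsBase), tb(rsGone)),
                              valueColumn = "u")
  expect_equal(vapply(tracks, `[[`, logical(1), "persisting"), c(TRUE, FALSE))
})

test_that("group percent difference uses the median-of-groups form", {
  expect_equal(percentDiffGroups(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(percentDiffGroups(c(1.5, 1.5), c(1, 1)), 50)
  set.seed(31)
  a <- rnorm(11, 5); b <- rnorm(9, 4)
  sortMedian <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
  }
  expect_equal(percentDiffGroups(a, b),
               100 * (sortMedian(a) - sortMedian(b)) / sortMedian(b))
  expect_error(percentDiffGroups(numeric(0), 1), "empty")
  expect_error(percentDiffGroups(1, c(-1, 1)), "median")
})

test_that("AUC matches the Mann-Whitney definition and brute force", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(rocAuc(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)), 0.5)
  expect_equal(rocAuc(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(17)
  for (rep in 1:8) {
    n <- sample(5:50, 1)
    scores <- round(rnorm(n), 1) # force ties
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    expect_identical(rocAuc(scores, pos), bruteAuc(scores, pos))
    # invariance under strictly monotone transforms
    expect_equal(rocAuc(exp(scores), pos), rocAuc(scores, pos))
  }
})

test_that("FPR95 matches the exhaustive threshold scan", {
  expect_equal(fprAtSensitivity(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_equal(fprAtSensitivity(rep(2, 8), rep(c(TRUE, FALSE), 4)), 1)

  set.seed(23)
  for (rep in 1:8) {
    n <- 20L
    scores <- round(rnorm(n), 1)
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    expect_identical(fprAtSensitivity(scores, pos), bruteFpr(scores, pos))
    expect_equal(fprAtSensitivity(scores * 3 + 2, pos),
                 fprAtSensitivity(scores, pos))
  }
})

test_that("rank tests behave per the standard definitions", {
  a <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.0, 3.3, 1.1, 0.5, 2.8)
  expect_identical(rankTest(a, a, paired = TRUE), 1)
  expect_lt(rankTest(a, a + 50, paired = TRUE), 0.01)

  # exact permutation enumeration for a small untied unpaired case
  x <- c(1.1, 2.3, 3.7, 9.2)
  y <- c(0.4, 4.8, 5.9, 7.1)
  got <- rankTest(x, y, paired = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  obsW <- sum(r[1:4]) - 4 * 5 / 2 # Mann-Whitney U of group x
  combos <- utils::combn(8L, 4L)
  Ws <- apply(combos, 2L, function(idx) sum(r[idx]) - 4 * 5 / 2)
  pLow <- mean(Ws <= obsW)
  pHigh <- mean(Ws >= obsW)
  oracle <- min(1, 2 * min(pLow, pHigh))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("fpFilterMetrics bundles AUC, FPR95 and the rank-sum p-value", {
  scores <- c(3, 2.5, 2, 0.5, 0.4, 0.3, 0.2, 0.1)
  isTP <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  m <- fpFilterMetrics(scores, isTP)
  expect_equal(m$auc, 1)
  expect_equal(m$fpr95, 0)
  expect_lt(m$p_value, 0.05)
  expect_true(m$p_value > 0 && m$p_value <= 1)
})

test_that("block sweep rows equal independent single-configuration runs", {
  fx <- fixtureSweep()
  imgs <- fx$phantoms$images[1:16]
  truth <- fx$phantoms$truth[1:16]
  cfgs <- list("Block_4-0", c("Block_4-0", "Block_4-1"), "Block_2-1")
  sw <- blockSensitivitySweep(fx$model, imgs, truth, configs = cfgs)
  expect_equal(nrow(sw), 2L + 2L * length(cfgs))
  expect_equal(sum(!sw$gradient), 2L)

  # independent recomputation of one gradient row
  cfg <- cfgs[[2L]]
  scores <- numeric(0); isTP <- logical(0)
  for (i in seq_along(imgs)) {
    lm <- predictLabelMap(fx$model, imgs[[i]])
    rs <- extractRegions(lm, minVolumeCm3 = 0.25)
    if (nRegions(rs) == 0L) next
    fl <- classifyDetections(rs, truth[[i]])
    for (r in rs@regions) {
      scores <- c(scores, localGradientsScore(fx$model, imgs[[i]], r$voxels,
                                              "kl", cfg))
      isTP <- c(isTP, fl$is_tp[fl$region_id == r$id])
    }
  }
  want <- fpFilterMetrics(scores, isTP)
  row <- sw[sw$blocks == paste(cfg, collapse = "+") & sw$target == "kl", ]
  expect_equal(row$auc, want$auc, tolerance = 1e-12)
  expect_equal(row$fpr95, want$fpr95, tolerance = 1e-12)
  expect_equal(row$p_value, want$p_value, tolerance = 1e-12)
})
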