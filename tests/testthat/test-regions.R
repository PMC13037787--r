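# Region localization, volume filtering, truth labelling and matching.

blobMap <- function(dims, blobs, spacing) {
  arr <- array(0L, dim = dims)
  for (b in blobs) arr[b$voxels] <- b$label
  LabelMap(arr, spacing)
}

test_that("connected components are extracted with physical volume filtering", {
  # two disjoint 30-voxel blobs of label 1 at 2.5 mm iso survive a 0.25 cm^3 filter
  arr <- array(0L, dim = c(12L, 12L, 6L))
  arr[2:6, 2:3, 2:4] <- 1L
  arr[9:11, 8:9, 2:6] <- 1L
  lm <- LabelMap(arr, c(2.5, 2.5, 2.5))
  rs <- extractRegions(lm, minVolumeCm3 = 0.25)
  expect_equal(nRegions(rs), 2L)
  expect_equal(sort(regionTable(rs)$n_voxels), c(30L, 30L))
  expect_equal(regionTable(rs)$volume_cm3,
               regionTable(rs)$n_voxels * 2.5^3 / 1000)

  # all-zero map -> empty set
  empty <- extractRegions(LabelMap(array(0L, c(8L, 8L)), c(1, 1)))
  expect_equal(nRegions(empty), 0L)

  # 10-voxel blob (0.15625 cm^3) removed, 20-voxel blob (0.3125 cm^3) kept
  arr <- array(0L, dim = c(16L, 16L, 4L))
  arr[2:6, 2, 2:3] <- 1L          # 10 voxels
  arr[10:14, 10:11, 2:3] <- 1L    # 20 voxels
  rs <- extractRegions(LabelMap(arr, c(2.5, 2.5, 2.5)), minVolumeCm3 = 0.25)
  expect_equal(nRegions(rs), 1L)
  expect_equal(rs@regions[[1L]]$nVoxels, 20L)
  expect_equal(rs@regions[[1L]]$volumeCm3, 0.3125)
})

test_that("face vs face-edge-corner connectivity splits or joins diagonals", {
  m <- matrix(0L, 6, 6)
  m[2, 2] <- 1L
  m[3, 3] <- 1L
  lm <- LabelMap(m, c(1, 1))
  expect_equal(nRegions(extractRegions(lm, connectivity = "face")), 2L)
  expect_equal(nRegions(extractRegions(lm, connectivity = "face-edge-corner")), 1L)
})

test_that("extraction conserves voxels and is idempotent under rasterization", {
  set.seed(7)
  for (rep in 1:5) {
    arr <- array(sample(0:2, 16^3, replace = TRUE, prob = c(0.93, 0.04, 0.03)),
                 dim = c(16L, 16L, 16L))
    lm <- LabelMap(arr, c(2, 2, 2))
    rs <- extractRegions(lm, minVolumeCm3 = 0)
    expect_equal(sum(regionTable(rs)$n_voxels), sum(arr != 0L))
    rs2 <- extractRegions(rasterizeRegions(rs), minVolumeCm3 = 0)
    expect_equal(lapply(rs2@regions, `[[`, "voxels"),
                 lapply(rs@regions, `[[`, "voxels"))
    expect_equal(regionTable(rs2), regionTable(rs))
  }
})

test_that("region ids follow first-voxel row-major order", {
  m <- matrix(0L, 6, 6)
  m[5, 1] <- 1L  # row-major rank 25
  m[1, 4] <- 1L  # row-major rank 4 -> must get id 1
  rs <- extractRegions(LabelMap(m, c(1, 1)))
  expect_equal(rs@regions[[1L]]$voxels, which(as.vector(m) != 0L)[2L])
})

test_that("TP/FP classification matches the definition and a brute-force oracle", {
  truth <- matrix(0L, 8, 8)
  truth[4:6, 4:6] <- 1L
  tlm <- LabelMap(truth, c(1, 1))

  pred <- matrix(0L, 8, 8)
  pred[2:4, 2:4] <- 1L  # overlaps truth by exactly one voxel (4,4) -> TP
  pred[7:8, 1:2] <- 1L  # zero overlap -> FP
  rs <- extractRegions(LabelMap(pred, c(1, 1)))
  flags <- classifyDetections(rs, tlm)
  overlap1 <- length(intersect(rs@regions[[1L]]$voxels, which(truth != 0L)))
  expect_equal(overlap1, 1L)
  expect_true(flags$is_tp[1L])
  expect_false(flags$is_tp[2L])

  # property: agreement with exhaustive per-voxel intersection on random 16^3 maps
  set.seed(11)
  for (rep in 1:5) {
    parr <- array(0L, dim = c(16L, 16L, 16L))
    for (b in 1:5) {
      c0 <- sample(3:14, 3, replace = TRUE)
      parr[c0[1] + (-1:1), c0[2] + (-1:1), c0[3] + (-1:1)] <- 1L
    }
    tarr <- array(sample(0:1, 16^3, replace = TRUE, prob = c(0.9, 0.1)),
                  dim = c(16L, 16L, 16L))
    rs <- extractRegions(LabelMap(parr, c(1, 1, 1)))
    flags <- classifyDetections(rs, LabelMap(tarr, c(1, 1, 1)))
    oracle <- vapply(rs@regions, function(r) {
      length(intersect(r$voxels, which(as.vector(tarr) != 0L))) >= 1L
    }, logical(1))
    expect_equal(flags$is_tp, oracle)
  }
})

test_that("majority truth class vote excludes background and breaks ties low", {
  truth <- matrix(0L, 6, 6)
  truth[1:3, 1:3] <- 2L
  tlm <- LabelMap(truth, c(1, 1))
  region <- list(voxels = which(as.vector(truth) == 2L))
  expect_equal(majorityTruthClass(region, tlm), 2L)

  truth2 <- matrix(0L, 6, 6)
  truth2[1:3, 1] <- 1L     # 3 voxels class 1
  truth2[1:2, 2] <- 3L     # 2 voxels class 3
  region <- list(voxels = c(1:3, 7:8, 13L))  # includes one background voxel
  expect_equal(majorityTruthClass(region, LabelMap(truth2, c(1, 1))), 1L)

  truth3 <- matrix(0L, 6, 6)
  truth3[1:2, 1] <- 1L
  truth3[1:2, 2] <- 3L
  region <- list(voxels = c(1:2, 7:8))  # 2 vs 2 -> smallest class wins
  expect_equal(majorityTruthClass(region, LabelMap(truth3, c(1, 1))), 1L)

  region <- list(voxels = c(30L, 31L))  # background only -> unmatched
  expect_true(is.na(majorityTruthClass(region, LabelMap(truth3, c(1, 1)))))
})

test_that("region matching enumerates all overlaps, including splits", {
  m <- matrix(0L, 8, 8)
  m[2:4, 2:4] <- 1L
  m[6:7, 6:7] <- 1L
  a <- extractRegions(LabelMap(m, c(1, 1)))

  idMatch <- matchRegions(a, a)
  expect_equal(vapply(idMatch, function(x) x$target_ids, integer(1)), c(1L, 2L))
  expect_equal(vapply(idMatch, function(x) x$overlap_voxels, integer(1)), c(9L, 4L))

  m2 <- matrix(0L, 8, 8)
  m2[1, 8] <- 1L
  b <- extractRegions(LabelMap(m2, c(1, 1)))
  none <- matchRegions(a, b)
  expect_equal(lengths(lapply(none, `[[`, "target_ids")), c(0L, 0L))

  # one baseline blob splitting into two
  m3 <- matrix(0L, 8, 8)
  m3[2, 2:4] <- 1L
  m3[4, 2:4] <- 1L
  split <- extractRegions(LabelMap(m3, c(1, 1)))
  res <- matchRegions(a, split)
  expect_equal(res[[1L]]$target_ids, c(1L, 2L))
  expect_equal(res[[1L]]$overlap_voxels, c(3L, 3L))

  # brute-force overlap table on random maps
  set.seed(3)
  for (rep in 1:4) {
    ra <- array(sample(0:1, 12^2, TRUE, prob = c(0.7, 0.3)), dim = c(12L, 12L))
    rb <- array(sample(0:1, 12^2, TRUE, prob = c(0.7, 0.3)), dim = c(12L, 12L))
    A <- extractRegions(LabelMap(ra, c(1, 1)))
    B <- extractRegions(LabelMap(rb, c(1, 1)))
    res <- matchRegions(A, B)
    for (i in seq_along(res)) {
      srcVox <- A@regions[[i]]$voxels
      oracle <- lapply(B@regions, function(t) length(intersect(srcVox, t$voxels)))
      hits <- which(unlist(oracle) > 0L)
      expect_equal(res[[i]]$target_ids, as.integer(hits))
      expect_equal(res[[i]]$overlap_voxels, as.integer(unlist(oracle)[hits]))
    }
  }
})

test_that("grid mismatches and invalid inputs raise errors", {
  m <- matrix(0L, 6, 6); m[2, 2] <- 1L
  rs <- extractRegions(LabelMap(m, c(1, 1)))
  truthBig <- LabelMap(array(0L, c(8L, 8L)), c(1, 1))
  expect_error(classifyDetections(rs, truthBig), "different grids")
  expect_error(matchRegions(rs, extractRegions(truthBig)), "different grids")
  expect_error(LabelMap(matrix(0.5, 4, 4), c(1, 1)), "integers")
  expect_error(LabelMap(matrix(0L, 4, 4), c(1, -1)))
  expect_error(extractRegions(LabelMap(m, c(1, 1)), minVolumeCm3 = -1))
})

test_that("RegionSet JSON round-trips with 0-based half-open conventions", {
  m <- matrix(0L, 8, 8)
  m[2:3, 2:4] <- 1L
  m[6, 7] <- 2L
  rs <- extractRegions(LabelMap(m, c(2.5, 2.5)))
  path <- tempfile(fileext = ".json")
  writeRegionSetJSON(rs, path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(j$regions[[1L]]$bbox_lo, list(1L, 1L))
  expect_equal(j$regions[[1L]]$bbox_hi, list(3L, 4L))
  back <- readRegionSetJSON(path)
  expect_equal(lapply(back@regions, `[[`, "voxels"),
               lapply(rs@regions, `[[`, "voxels"))
  expect_equal(regionTable(back), regionTable(rs))
})
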