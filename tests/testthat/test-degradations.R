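# Degradation operators: identities, determinism, moments, kernels, sweeps.

constImage <- function(value, n = 32L) ScanImage(matrix(value, n, n), c(1, 1))

test_that("zero magnitude is a bit-exact identity for all operators", {
  set.seed(5)
  img <- ScanImage(matrix(rnorm(32 * 32), 32, 32), c(2, 2))
  expect_identical(gaussianNoise(img, 0, 1), img)
  expect_identical(speckleNoise(img, 0, 1), img)
  expect_identical(gaussianSmooth(img, 0), img)
})

test_that("noise operators are deterministic per seed and image-independent", {
  set.seed(6)
  img1 <- ScanImage(matrix(rnorm(16 * 16), 16, 16), c(1, 1))
  img2 <- ScanImage(matrix(rnorm(16 * 16, 100), 16, 16), c(1, 1))
  a <- gaussianNoise(img1, 5, seed = 42L)
  b <- gaussianNoise(img1, 5, seed = 42L)
  expect_identical(voxelValues(a), voxelValues(b))
  c2 <- gaussianNoise(img1, 5, seed = 43L)
  expect_false(identical(voxelValues(a), voxelValues(c2)))
  # the additive noise field does not depend on image content, so the
  # operator commutes with translation in distribution
  w1 <- voxelValues(gaussianNoise(img1, 5, seed = 7L)) - voxelValues(img1)
  w2 <- voxelValues(gaussianNoise(img2, 5, seed = 7L)) - voxelValues(img2)
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("noise moments match their nominal parameters", {
  zero <- constImage(0, 64L)
  out <- voxelValues(gaussianNoise(zero, 10, seed = 3L))
  n <- length(out)
  seMean <- 10 / sqrt(n)
  expect_lt(abs(mean(out)), 3 * seMean)
  seSd <- 10 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(out) - 10), 3 * seSd)

  # speckle: all-zero image is a fixed point; constant image scales the noise
  expect_identical(voxelValues(speckleNoise(zero, 0.8, seed = 1L)),
                   voxelValues(zero))
  cimg <- constImage(50, 64L)
  outS <- voxelValues(speckleNoise(cimg, 0.3, seed = 9L))
  expect_lt(abs(sd(outS) - 50 * 0.3), 3 * (50 * 0.3) / sqrt(2 * (n - 1)))
})

test_that("Gaussian smoothing conserves constants and reproduces the kernel", {
  cimg <- constImage(7.5, 24L)
  out <- voxelValues(gaussianSmooth(cimg, 1.5))
  expect_lt(max(abs(out - 7.5)), 1e-9)

  # unit impulse at the centre of a large zero image
  n <- 49L
  arr <- matrix(0, n, n)
  arr[25, 25] <- 1
  sm <- voxelValues(gaussianSmooth(ScanImage(arr, c(1, 1)), 1.2))
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  k <- exp(-((-5):5)^2 / (2 * 1.2^2))
  k <- k / sum(k)
  expected <- outer(k, k)
  got <- sm[20:30, 20:30]
  expect_lt(max(abs(got - expected)), 1e-6)

  expect_error(gaussianSmooth(cimg, -1), ">= 0")
  expect_error(gaussianNoise(cimg, -0.1), ">= 0")
})

test_that("sweeps use the stated 11-step grids and reproduce bit-exactly", {
  gn <- degradationSpec("gaussian_noise", seed = 12L)
  expect_equal(gn@sigmaGrid, seq(0, 70, by = 7))
  gs <- degradationSpec("gaussian_smooth")
  expect_equal(gs@sigmaGrid, seq(0, 4, by = 0.4))
  sn <- degradationSpec("speckle_noise")
  expect_equal(sn@sigmaGrid, seq(0, 1, by = 0.1))
  expect_length(gn@sigmaGrid, 11L)

  set.seed(8)
  img <- ScanImage(matrix(rnorm(16 * 16), 16, 16), c(1, 1))
  s1 <- degradationSweep(img, gn)
  s2 <- degradationSweep(img, gn)
  expect_length(s1, 11L)
  expect_identical(voxelValues(s1[[1L]]), voxelValues(img)) # sigma = 0 first
  for (m in seq_along(s1)) {
    expect_identical(voxelValues(s1[[m]]), voxelValues(s2[[m]]))
  }
  # different magnitudes draw independent fields
  w2 <- voxelValues(s1[[2L]]) - voxelValues(img)
  w3 <- (voxelValues(s1[[3L]]) - voxelValues(img))
  expect_gt(max(abs(w2 / sd(w2) - w3 / sd(w3))), 1e-3)
})

test_that("smoothing works on 3-D volumes", {
  arr <- array(0, c(12, 12, 12))
  arr[6, 6, 6] <- 1
  sm <- voxelValues(gaussianSmooth(ScanImage(arr, c(1, 1, 1)), 1))
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_equal(which.max(sm), 6L + 5L * 12L + 5L * 144L)
})
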