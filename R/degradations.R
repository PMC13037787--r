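#' @include containers.R
NULL

#' Construct a DegradationSpec
#'
#' Default magnitude grids follow the standard sweep: 11 evenly spaced
#' steps from 0 to 70 (additive Gaussian noise, intensity units), 0 to 1
#' (speckle noise, relative units) or 0 to 4 (Gaussian smoothing, voxels).
#'
#' @param kind `"gaussian_noise"`, `"speckle_noise"` or
#'   `"gaussian_smooth"`.
#' @param sigmaMax largest magnitude; defaults to 70, 1 or 4 by kind.
#' @param steps number of grid points including 0 (default 11).
#' @param seed integer RNG seed for the sweep.
#' @return a [DegradationSpec-class].
#' @export
degradationSpec <- function(kind = c("gaussian_noise", "speckle_noise", "gaussian_smooth"),
                            sigmaMax = NULL, steps = 11L, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(sigmaMax)) {
    sigmaMax <- switch(kind, gaussian_noise = 70, speckle_noise = 1, gaussian_smooth = 4)
  }
  new("DegradationSpec", kind = kind,
      sigmaGrid = seq(0, sigmaMax, length.out = as.integer(steps)),
      seed = as.integer(seed))
}

#' Additive Gaussian noise
#'
#' `I + W` with `W ~ N(0, sigma)` drawn elementwise; bit-identical output
#' for identical seed, and the input itself when `sigma = 0`.
#'
#' @param image a [ScanImage-class].
#' @param sigma noise standard deviation (intensity units), >= 0.
#' @param seed integer RNG seed.
#' @return a degraded [ScanImage-class] of the same shape and spacing.
#' @export
gaussianNoise <- function(image, sigma, seed = 1L) {
  stopifnot(is(image, "ScanImage"))
  stopifnotScalar(sigma, "sigma")
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(image)
  v <- image@values
  w <- withSeed(seed, stats::rnorm(length(v), mean = 0, sd = sigma))
  ScanImage(array(as.vector(v) + w, dim = dim(v)), image@spacing)
}

#' Additive speckle noise
#'
#' Multiplicative noise `I + W * I = I (1 + W)` with `W ~ N(0, sigma)`;
#' an all-zero image maps to itself at any magnitude.
#'
#' @inheritParams gaussianNoise
#' @param sigma relative noise standard deviation, >= 0.
#' @export
speckleNoise <- function(image, sigma, seed = 1L) {
  stopifnot(is(image, "ScanImage"))
  stopifnotScalar(sigma, "sigma")
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(image)
  v <- image@values
  w <- withSeed(seed, stats::rnorm(length(v), mean = 0, sd = sigma))
  ScanImage(array(as.vector(v) * (1 + w), dim = dim(v)), image@spacing)
}

# 1-D normalized Gaussian kernel, truncated at 4 sigma.
gaussKernel1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Axis smoothing matrix with reflective boundaries: row i holds the kernel
# centred at i with out-of-range taps reflected back inside.
axisSmoothingMatrix <- function(n, sigma) {
  k <- gaussKernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (t in seq_along(k)) {
      j <- i + t - r - 1L
      # reflect (mirror without repeating the edge sample)
      while (j < 1L || j > n) {
        if (j < 1L) j <- 2L - j
        if (j > n) j <- 2L * n - j
      }
      S[i, j] <- S[i, j] + k[t]
    }
  }
  S
}

#' Gaussian smoothing
#'
#' Separable convolution with a normalized Gaussian kernel of standard
#' deviation `sigma` voxels, truncated at 4 sigma, reflective boundary
#' handling. `sigma = 0` returns the input unchanged; a constant image is
#' preserved exactly (the kernel sums to 1).
#'
#' @inheritParams gaussianNoise
#' @param sigma spatial standard deviation in voxels, >= 0.
#' @export
gaussianSmooth <- function(image, sigma) {
  stopifnot(is(image, "ScanImage"))
  stopifnotScalar(sigma, "sigma")
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(image)
  v <- image@values
  dims <- dim(v)
  nd <- length(dims)
  for (axis in seq_len(nd)) {
    S <- axisSmoothingMatrix(dims[axis], sigma)
    perm <- c(axis, setdiff(seq_len(nd), axis))
    vp <- aperm(v, perm)
    m <- matrix(vp, nrow = dims[axis])
    m <- S %*% m
    vp <- array(m, dim = dims[perm])
    v <- aperm(vp, order(perm))
  }
  ScanImage(v, image@spacing)
}

#' Apply a full degradation sweep to one image
#'
#' Produces one image per grid magnitude; the first (sigma = 0) is the
#' input itself, bit-exactly. Noise fields at different magnitudes are
#' independent draws whose seeds derive deterministically from the sweep
#' seed, so the whole series is reproducible from `(image, spec)`.
#'
#' @param image a [ScanImage-class].
#' @param spec a [DegradationSpec-class].
#' @return list of [ScanImage-class], one per magnitude, in grid order.
#' @export
degradationSweep <- function(image, spec) {
  stopifnot(is(image, "ScanImage"), is(spec, "DegradationSpec"))
  validObject(spec)
  lapply(seq_along(spec@sigmaGrid), function(i) {
    sigma <- spec@sigmaGrid[i]
    switch(spec@kind,
      gaussian_noise = gaussianNoise(image, sigma, deriveSeed(spec@seed, i)),
      speckle_noise = speckleNoise(image, sigma, deriveSeed(spec@seed, i)),
      gaussian_smooth = gaussianSmooth(image, sigma)
    )
  })
}
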