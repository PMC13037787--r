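#' @include containers.R
NULL

#' Construct a PhantomSpec
#'
#' Defaults describe the standard fixture: 200 images of 48 x 48 voxels at
#' 4 mm isotropic spacing, one to three soft-edged lesion blobs per image
#' with peak contrast 120-300 intensity units over a zero-mean background
#' with Gaussian noise of standard deviation 20 (a CT-like intensity
#' scale, which makes the default additive-noise sweep 0-70 a meaningful
#' degradation range). Half of the images additionally contain one
#' smaller distractor blob drawn from the same contrast distribution but
#' labelled background in the truth; the size ranges of lesions and
#' distractors overlap slightly, so a trained model produces genuine
#' false positives rather than artificial label noise.
#'
#' @param nImages number of image/truth pairs.
#' @param dim integer grid (2-D default, 3-D supported).
#' @param spacing voxel spacing in mm per axis.
#' @param nLesions `(min, max)` lesions per image.
#' @param contrast `(min, max)` lesion peak contrast.
#' @param lesionRadius `(min, max)` lesion radius in voxels.
#' @param distractorRate per-image probability of one distractor blob.
#' @param distractorRadius `(min, max)` distractor radius in voxels; the
#'   default upper end slightly overlaps the lesion range, which is what
#'   makes distractors an honest source of false positives.
#' @param noiseSigma background noise standard deviation.
#' @param nClasses output classes including background; lesion classes
#'   `1..nClasses-1` get disjoint contrast sub-bands so they are
#'   learnable.
#' @param seed integer RNG seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(nImages = 200L, dim = c(48L, 48L), spacing = NULL,
                        nLesions = c(1L, 3L), contrast = c(120, 300),
                        lesionRadius = c(3.2, 6), distractorRate = 0.5,
                        distractorRadius = c(2.2, 3.4), noiseSigma = 20,
                        nClasses = 2L, seed = 1L) {
  if (is.null(spacing)) spacing <- rep(4, length(dim))
  new("PhantomSpec",
      nImages = as.integer(nImages), dim = as.integer(dim),
      spacing = as.numeric(spacing), nLesions = as.integer(nLesions),
      contrast = as.numeric(contrast), lesionRadius = as.numeric(lesionRadius),
      distractorRate = as.numeric(distractorRate),
      distractorRadius = as.numeric(distractorRadius),
      noiseSigma = as.numeric(noiseSigma), nClasses = as.integer(nClasses),
      seed = as.integer(seed))
}

# Squared distance of every voxel to a centre, in voxel units.
distanceSq <- function(dims, centre) {
  nd <- length(dims)
  coords <- arrayInd(seq_len(prod(dims)), .dim = dims)
  d2 <- numeric(prod(dims))
  for (a in seq_len(nd)) d2 <- d2 + (coords[, a] - centre[a])^2
  d2
}

# Add one blob: sigmoid-edged intensity profile, optional truth label.
paintBlob <- function(intensity, truth, dims, centre, radius, contrast, label) {
  d <- sqrt(distanceSq(dims, centre))
  intensity <- intensity + contrast / (1 + exp((d - radius) / 0.8))
  if (label > 0L) truth[d <= radius] <- label
  list(intensity = intensity, truth = truth)
}

#' Generate a seeded phantom dataset
#'
#' @param spec a [PhantomSpec-class] from [phantomSpec()].
#' @return list with `images` (list of [ScanImage-class]), `truth` (list
#'   of [LabelMap-class]) and `manifest` (data frame: per image the lesion
#'   and distractor counts). Bit-reproducible for a fixed spec.
#' @examples
#' ph <- generatePhantoms(phantomSpec(nImages = 2, seed = 3))
#' ph$manifest
#' @export
generatePhantoms <- function(spec = phantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  dims <- spec@dim
  nd <- length(dims)
  maxLesionR <- spec@lesionRadius[2L]
  if (any(dims < 4 * maxLesionR)) {
    stop("grid too small for the requested blobs", call. = FALSE)
  }
  nFgClasses <- spec@nClasses - 1L
  # contrast sub-band per lesion class so multi-class labels are learnable
  bandEdges <- seq(spec@contrast[1L], spec@contrast[2L], length.out = nFgClasses + 1L)
  images <- vector("list", spec@nImages)
  truths <- vector("list", spec@nImages)
  nLes <- integer(spec@nImages)
  nDis <- integer(spec@nImages)
  for (i in seq_len(spec@nImages)) {
    gen <- withSeed(deriveSeed(spec@seed, i), {
      intensity <- array(stats::rnorm(prod(dims), 0, spec@noiseSigma), dim = dims)
      truth <- array(0L, dim = dims)
      margin <- 8
      placed <- matrix(numeric(0), 0, nd + 1L) # centre..., radius
      placeCentre <- function(radius) {
        for (try in seq_len(50L)) {
          centre <- vapply(dims, function(d) stats::runif(1, margin, d - margin + 1), numeric(1))
          if (nrow(placed) == 0L) return(centre)
          dists <- sqrt(rowSums((placed[, seq_len(nd), drop = FALSE] -
                                   matrix(centre, nrow(placed), nd, byrow = TRUE))^2))
          if (all(dists > placed[, nd + 1L] + radius + 2)) return(centre)
        }
        NULL
      }
      k <- sample(spec@nLesions[1L]:spec@nLesions[2L], 1L)
      placedLesions <- 0L
      for (b in seq_len(k)) {
        radius <- stats::runif(1, spec@lesionRadius[1L], spec@lesionRadius[2L])
        cls <- if (nFgClasses > 1L) sample.int(nFgClasses, 1L) else 1L
        contrast <- stats::runif(1, bandEdges[cls], bandEdges[cls + 1L])
        centre <- placeCentre(radius)
        if (is.null(centre)) next
        res <- paintBlob(intensity, truth, dims, centre, radius, contrast, cls)
        intensity <- res$intensity
        truth <- res$truth
        placed <- rbind(placed, c(centre, radius))
        placedLesions <- placedLesions + 1L
      }
      if (placedLesions == 0L) {
        # guarantee at least one true lesion voxel per image
        centre <- dims / 2
        res <- paintBlob(intensity, truth, dims, centre, 4.5,
                         mean(spec@contrast), 1L)
        intensity <- res$intensity
        truth <- res$truth
        placed <- rbind(placed, c(centre, 4.5))
        placedLesions <- 1L
      }
      nDistract <- 0L
      if (stats::runif(1) < spec@distractorRate) {
        radius <- stats::runif(1, spec@distractorRadius[1L], spec@distractorRadius[2L])
        contrast <- stats::runif(1, spec@contrast[1L], spec@contrast[2L])
        centre <- placeCentre(radius)
        if (!is.null(centre)) {
          res <- paintBlob(intensity, truth, dims, centre, radius, contrast, 0L)
          intensity <- res$intensity
          nDistract <- 1L
        }
      }
      list(intensity = intensity, truth = truth,
           nLesions = placedLesions, nDistractors = nDistract)
    })
    images[[i]] <- ScanImage(gen$intensity, spec@spacing)
    truths[[i]] <- LabelMap(gen$truth, spec@spacing)
    nLes[i] <- gen$nLesions
    nDis[i] <- gen$nDistractors
  }
  list(images = images, truth = truths,
       manifest = data.frame(image = seq_len(spec@nImages),
                             n_lesions = nLes, n_distractors = nDis))
}
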