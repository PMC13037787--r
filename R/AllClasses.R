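#' @import methods
NULL

#' Intensity image with voxel-spacing metadata
#'
#' A 2-D or 3-D numeric array of voxel intensities plus the physical edge
#' length of a voxel along each axis (millimetres). Spacing is required
#' metadata: the region volume filter is physical (cm^3), so images without
#' spacing cannot enter the pipeline.
#'
#' @slot values numeric array (2-D or 3-D) of intensities.
#' @slot spacing numeric vector, mm per axis, strictly positive, one entry
#'   per array dimension.
#' @exportClass ScanImage
setClass("ScanImage", representation(values = "array", spacing = "numeric"))

setValidity("ScanImage", function(object) {
  d <- dim(object@values)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) {
    return("'values' must be a 2-D or 3-D array")
  }
  if (length(object@spacing) != length(d)) {
    return("'spacing' must have one entry per image axis")
  }
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0)) {
    return("'spacing' must be strictly positive on every axis")
  }
  if (!is.numeric(object@values)) {
    return("'values' must be numeric")
  }
  TRUE
})

#' Integer label map (0 = background) with voxel-spacing metadata
#'
#' @slot values integer-valued array (2-D or 3-D); 0 denotes background.
#' @slot spacing numeric vector, mm per axis, strictly positive.
#' @exportClass LabelMap
setClass("LabelMap", representation(values = "array", spacing = "numeric"))

setValidity("LabelMap", function(object) {
  d <- dim(object@values)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) {
    return("'values' must be a 2-D or 3-D array")
  }
  if (length(object@spacing) != length(d)) {
    return("'spacing' must have one entry per image axis")
  }
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0)) {
    return("'spacing' must be strictly positive on every axis")
  }
  v <- object@values
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
    return("labels must be non-negative integers")
  }
  TRUE
})

#' Set of localized regions extracted from a label map
#'
#' Each region is a connected component of one nonzero label, stored as
#' 1-based column-major linear voxel indices on the originating grid.
#' Region identifiers are assigned deterministically in order of each
#' component's first voxel in row-major order.
#'
#' @slot regions list; each element has fields `id`, `label`, `voxels`
#'   (integer linear indices), `nVoxels`, `volumeCm3`.
#' @slot dim integer grid dimensions of the originating map.
#' @slot spacing numeric voxel spacing (mm) of the originating map.
#' @slot connectivity character, `"face"` or `"face-edge-corner"`.
#' @exportClass RegionSet
setClass("RegionSet", representation(
  regions = "list", dim = "integer", spacing = "numeric",
  connectivity = "character"
))

setValidity("RegionSet", function(object) {
  n <- prod(object@dim)
  for (r in object@regions) {
    if (!all(c("id", "label", "voxels", "nVoxels", "volumeCm3") %in% names(r))) {
      return("each region needs id, label, voxels, nVoxels, volumeCm3")
    }
    if (length(r$voxels) == 0L) return("regions must be non-empty")
    if (any(r$voxels < 1L) || any(r$voxels > n)) {
      return("region voxel indices off-grid")
    }
    vol <- length(r$voxels) * prod(object@spacing) / 1000
    if (abs(vol - r$volumeCm3) > 1e-9 * max(1, vol)) {
      return("volumeCm3 inconsistent with voxel count and spacing")
    }
  }
  TRUE
})

#' Percentile normalization constant for one uncertainty measure
#'
#' Holds the 95th percentile (by default) of raw scores computed on a
#' reference set of regions with a-priori assumed low uncertainty, used to
#' put all uncertainty measures on a comparable scale.
#'
#' @slot measure `"lg"`, `"mp"` or `"kld"`.
#' @slot p95 positive scalar normalization constant.
#' @slot percentile the percentile actually used (default 95).
#' @slot source free-text description of the reference set.
#' @slot nScores number of reference scores the constant was computed from.
#' @exportClass CalibrationReference
setClass("CalibrationReference", representation(
  measure = "character", p95 = "numeric", percentile = "numeric",
  source = "character", nScores = "integer"
))

setValidity("CalibrationReference", function(object) {
  if (!(object@measure %in% c("lg", "mp", "kld"))) {
    return("measure must be one of 'lg', 'mp', 'kld'")
  }
  if (length(object@p95) != 1L || !is.finite(object@p95) || object@p95 <= 0) {
    return("p95 must be a positive scalar")
  }
  if (object@percentile <= 0 || object@percentile > 100) {
    return("percentile must lie in (0, 100]")
  }
  if (object@nScores < 1L) return("nScores must be >= 1")
  TRUE
})

#' Specification of one image-degradation sweep
#'
#' Eleven evenly spaced magnitudes (including 0) of one degradation
#' operator, with a seed from which per-magnitude noise-field seeds are
#' derived deterministically.
#'
#' @slot kind `"gaussian_noise"`, `"speckle_noise"` or `"gaussian_smooth"`.
#' @slot sigmaGrid ascending numeric magnitudes, first element 0.
#' @slot seed integer RNG seed for the sweep.
#' @exportClass DegradationSpec
setClass("DegradationSpec", representation(
  kind = "character", sigmaGrid = "numeric", seed = "integer"
))

setValidity("DegradationSpec", function(object) {
  if (!(object@kind %in% c("gaussian_noise", "speckle_noise", "gaussian_smooth"))) {
    return("unknown degradation kind")
  }
  g <- object@sigmaGrid
  if (length(g) < 1L || g[1L] != 0 || is.unsorted(g, strictly = FALSE)) {
    return("sigmaGrid must be ascending and start at 0")
  }
  if (any(g < 0)) return("sigma magnitudes must be non-negative")
  TRUE
})

#' Specification of a synthetic phantom dataset
#'
#' Defines blob-like lesions of varying contrast on a noisy background plus
#' smaller distractor blobs that share the lesion intensity signature but
#' are background in the truth, so that a trained model produces genuine
#' false positives.
#'
#' @slot nImages number of image/truth pairs.
#' @slot dim integer grid dimensions (2-D default).
#' @slot spacing voxel spacing in mm.
#' @slot nLesions integer range (min, max) of true lesions per image.
#' @slot contrast numeric range of lesion peak contrast over background.
#' @slot lesionRadius numeric range (min, max) of lesion radii, voxels.
#' @slot distractorRate per-image probability of one distractor blob.
#' @slot distractorRadius numeric range (min, max) of distractor radii,
#'   voxels; overlap with `lesionRadius` controls how confusable the
#'   distractors are.
#' @slot noiseSigma background Gaussian noise standard deviation.
#' @slot nClasses number of model output classes including background.
#' @slot seed integer RNG seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
  nImages = "integer", dim = "integer", spacing = "numeric",
  nLesions = "integer", contrast = "numeric", lesionRadius = "numeric",
  distractorRate = "numeric", distractorRadius = "numeric",
  noiseSigma = "numeric", nClasses = "integer", seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  if (object@nImages < 1L) return("nImages must be positive")
  if (!(length(object@dim) %in% c(2L, 3L)) || any(object@dim < 16L)) {
    return("grid must be 2-D or 3-D with every axis >= 16")
  }
  if (length(object@spacing) != length(object@dim) || any(object@spacing <= 0)) {
    return("spacing must be positive, one entry per axis")
  }
  if (length(object@nLesions) != 2L || object@nLesions[1L] < 1L ||
      object@nLesions[2L] < object@nLesions[1L]) {
    return("nLesions must be a positive (min, max) pair")
  }
  if (object@distractorRate < 0 || object@distractorRate > 1) {
    return("distractorRate must lie in [0, 1]")
  }
  for (rng in list(object@lesionRadius, object@distractorRadius)) {
    if (length(rng) != 2L || any(rng <= 0) || rng[2L] < rng[1L]) {
      return("radius ranges must be positive (min, max) pairs")
    }
  }
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  TRUE
})

#' Specification of the toy encoder-decoder segmentation network
#'
#' @slot levels number of resolution levels (>= 2); the decoder exposes two
#'   convolutional blocks per level named `Block_<level>-<pair>`.
#' @slot channels base channel count of the first encoder stage.
#' @slot classes number of output classes (>= 2, including background).
#' @slot seed integer seed for deterministic weight initialization.
#' @exportClass ToyModelSpec
setClass("ToyModelSpec", representation(
  levels = "integer", channels = "integer", classes = "integer",
  seed = "integer"
))

setValidity("ToyModelSpec", function(object) {
  if (object@levels < 2L) return("levels must be >= 2")
  if (object@channels < 1L) return("channels must be >= 1")
  if (object@classes < 2L) return("classes must be >= 2")
  TRUE
})

#' Tiny differentiable U-Net-style segmentation model
#'
#' An encoder-decoder network with skip connections, 3x3 convolutions,
#' ReLU activations, 2x2 max pooling and nearest-neighbour upsampling,
#' implemented with explicit forward and backward passes so that gradients
#' of any scalar with respect to any named parameter group are available.
#' Decoder blocks are named `Block_<level>-<pair>` with level 0 adjacent to
#' the bottleneck, matching the convention for targeting gradient
#' information.
#'
#' @slot params named list of parameter matrices/vectors, names of the form
#'   `<block>.<W|b>` or `<block>.c<k>.<W|b>`.
#' @slot arch list with fields `levels`, `channels`, `classes`.
#' @slot seed integer initialization seed.
#' @exportClass ToyUNet
setClass("ToyUNet", representation(params = "list", arch = "list", seed = "integer"))

setValidity("ToyUNet", function(object) {
  if (length(object@params) == 0L) return("empty parameter registry")
  if (!all(c("levels", "channels", "classes") %in% names(object@arch))) {
    return("arch must define levels, channels, classes")
  }
  TRUE
})
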