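#' @include AllGenerics.R
NULL

#' Construct a ScanImage
#'
#' @param values numeric 2-D or 3-D array (a plain matrix is accepted).
#' @param spacing voxel edge lengths in mm, one per axis.
#' @return a [ScanImage-class] object.
#' @examples
#' img <- ScanImage(matrix(rnorm(16), 4, 4), spacing = c(2.5, 2.5))
#' gridDim(img)
#' @export
ScanImage <- function(values, spacing) {
  values <- as.array(values)
  storage.mode(values) <- "double"
  new("ScanImage", values = values, spacing = as.numeric(spacing))
}

#' Construct a LabelMap
#'
#' @param values integer-valued 2-D or 3-D array; 0 is background.
#' @param spacing voxel edge lengths in mm, one per axis.
#' @return a [LabelMap-class] object.
#' @export
LabelMap <- function(values, spacing) {
  values <- as.array(values)
  if (is.double(values)) {
    if (any(values != round(values), na.rm = TRUE)) {
      stop("label map values must be integers", call. = FALSE)
    }
  }
  storage.mode(values) <- "integer"
  new("LabelMap", values = values, spacing = as.numeric(spacing))
}

#' @describeIn voxelValues values of a ScanImage
#' @export
setMethod("voxelValues", "ScanImage", function(x) x@values)

#' @describeIn voxelValues values of a LabelMap
#' @export
setMethod("voxelValues", "LabelMap", function(x) x@values)

#' @describeIn voxelSpacing spacing of a ScanImage
#' @export
setMethod("voxelSpacing", "ScanImage", function(x) x@spacing)

#' @describeIn voxelSpacing spacing of a LabelMap
#' @export
setMethod("voxelSpacing", "LabelMap", function(x) x@spacing)

#' @describeIn voxelSpacing spacing of the grid a RegionSet lives on
#' @export
setMethod("voxelSpacing", "RegionSet", function(x) x@spacing)

#' @describeIn gridDim dimensions of a ScanImage
#' @export
setMethod("gridDim", "ScanImage", function(x) dim(x@values))

#' @describeIn gridDim dimensions of a LabelMap
#' @export
setMethod("gridDim", "LabelMap", function(x) dim(x@values))

#' @describeIn gridDim dimensions of the grid a RegionSet lives on
#' @export
setMethod("gridDim", "RegionSet", function(x) x@dim)

setMethod("show", "ScanImage", function(object) {
  cat(sprintf(
    "ScanImage: %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
    paste(dim(object@values), collapse = "x"),
    paste(format(object@spacing), collapse = "x"),
    min(object@values), max(object@values)
  ))
})

setMethod("show", "LabelMap", function(object) {
  labs <- sort(unique(as.vector(object@values)))
  labs <- labs[labs != 0L]
  cat(sprintf(
    "LabelMap: %s voxels, spacing %s mm, %d nonzero label(s)%s\n",
    paste(dim(object@values), collapse = "x"),
    paste(format(object@spacing), collapse = "x"),
    length(labs),
    if (length(labs)) paste0(" {", paste(labs, collapse = ","), "}") else ""
  ))
})

setMethod("show", "RegionSet", function(object) {
  cat(sprintf(
    "RegionSet: %d region(s) on a %s grid (%s connectivity)\n",
    length(object@regions), paste(object@dim, collapse = "x"),
    object@connectivity
  ))
  if (length(object@regions)) {
    tab <- regionTable(object)
    print(utils::head(tab, 5L))
    if (nrow(tab) > 5L) cat(sprintf("... and %d more\n", nrow(tab) - 5L))
  }
})

setMethod("show", "CalibrationReference", function(object) {
  cat(sprintf(
    "CalibrationReference[%s]: P%g = %.6g (n = %d, source: %s)\n",
    object@measure, object@percentile, object@p95, object@nScores,
    if (nzchar(object@source)) object@source else "unspecified"
  ))
})

setMethod("show", "DegradationSpec", function(object) {
  cat(sprintf(
    "DegradationSpec[%s]: %d magnitudes in [0, %g], seed %d\n",
    object@kind, length(object@sigmaGrid), max(object@sigmaGrid), object@seed
  ))
})

setMethod("show", "ToyUNet", function(object) {
  cat(sprintf(
    "ToyUNet: %d levels, %d classes, %d parameters, %d decoder blocks\n",
    object@arch$levels, object@arch$classes, nParameters(object),
    length(listParameterGroups(object))
  ))
})

#' @describeIn nRegions number of regions
#' @export
setMethod("nRegions", "RegionSet", function(x) length(x@regions))

#' @describeIn regionIds region identifiers in id order
#' @export
setMethod("regionIds", "RegionSet", function(x) {
  vapply(x@regions, function(r) r$id, integer(1))
})

#' Summarize a RegionSet as a data frame
#'
#' @param x a `RegionSet`.
#' @return data frame with one row per region: `region_id`, `label`,
#'   `n_voxels`, `volume_cm3`.
#' @export
regionTable <- function(x) {
  stopifnot(is(x, "RegionSet"))
  data.frame(
    region_id = vapply(x@regions, function(r) r$id, integer(1)),
    label = vapply(x@regions, function(r) r$label, integer(1)),
    n_voxels = vapply(x@regions, function(r) r$nVoxels, integer(1)),
    volume_cm3 = vapply(x@regions, function(r) r$volumeCm3, numeric(1))
  )
}

#' Voxel indices of one region
#'
#' @param x a `RegionSet`.
#' @param id region identifier.
#' @return integer vector of 1-based column-major linear voxel indices.
#' @export
regionVoxels <- function(x, id) {
  stopifnot(is(x, "RegionSet"))
  for (r in x@regions) if (r$id == id) return(r$voxels)
  stop(sprintf("no region with id %s", id), call. = FALSE)
}
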