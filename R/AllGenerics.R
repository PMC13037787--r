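#' @include AllClasses.R
NULL

#' Voxel values of an image or label map
#' @param x a `ScanImage` or `LabelMap`.
#' @return the underlying array.
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' Voxel spacing (mm per axis)
#' @param x a `ScanImage`, `LabelMap` or `RegionSet`.
#' @return numeric vector of voxel edge lengths in mm.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Grid dimensions
#' @param x a `ScanImage`, `LabelMap` or `RegionSet`.
#' @return integer vector of grid dimensions.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Number of regions in a `RegionSet`
#' @param x a `RegionSet`.
#' @return integer count.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' Region identifiers
#' @param x a `RegionSet`.
#' @return integer vector of region ids.
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' Ordered decoder parameter-group names of a differentiable model
#'
#' Group names follow the `Block_<level>-<pair>` convention, ordered from
#' the bottleneck (`Block_0-0`) towards the output
#' (`Block_<levels-1>-1`).
#'
#' @param model a model object exposing a parameter-group registry.
#' @return character vector of unique group names.
#' @export
setGeneric("listParameterGroups", function(model) standardGeneric("listParameterGroups"))
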