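#' @include containers.R
NULL

# Neighbourhood offsets (in coordinates) for a given connectivity and
# dimensionality. "face" is the 4-neighbourhood in 2-D, 6 in 3-D;
# "face-edge-corner" is 8 in 2-D, 26 in 3-D.
connectivityOffsets <- function(nd, connectivity) {
  steps <- switch(nd, NULL, expand.grid(dx = -1:1, dy = -1:1),
                  expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  steps <- as.matrix(steps)
  steps <- steps[rowSums(abs(steps)) > 0L, , drop = FALSE]
  if (connectivity == "face") {
    steps <- steps[rowSums(abs(steps)) == 1L, , drop = FALSE]
  } else if (connectivity != "face-edge-corner") {
    stop("connectivity must be 'face' or 'face-edge-corner'", call. = FALSE)
  }
  steps
}

#' Extract localized regions from a label map
#'
#' Decomposes every nonzero label of a predicted (or ground-truth) label
#' map into connected components and removes components whose physical
#' volume falls below `minVolumeCm3`, mirroring the standard small-region
#' post-processing filter (0.25 cm^3). Region identifiers are assigned
#' deterministically: components are numbered by the row-major rank of
#' their first voxel.
#'
#' @param labelMap a [LabelMap-class].
#' @param minVolumeCm3 non-negative volume threshold in cm^3; components
#'   strictly below it are discarded. Default 0 (keep everything).
#' @param connectivity `"face"` (default; 4/6-neighbourhood) or
#'   `"face-edge-corner"` (8/26-neighbourhood).
#' @return a [RegionSet-class].
#' @examples
#' m <- matrix(0L, 8, 8); m[2:3, 2:3] <- 1L; m[6:7, 6:7] <- 1L
#' rs <- extractRegions(LabelMap(m, c(2.5, 2.5)))
#' nRegions(rs)
#' @export
extractRegions <- function(labelMap, minVolumeCm3 = 0, connectivity = c("face", "face-edge-corner")) {
  stopifnot(is(labelMap, "LabelMap"))
  connectivity <- match.arg(connectivity)
  stopifnotScalar(minVolumeCm3, "minVolumeCm3")
  if (minVolumeCm3 < 0) stop("minVolumeCm3 must be >= 0", call. = FALSE)

  vals <- labelMap@values
  dims <- dim(vals)
  nd <- length(dims)
  n <- prod(dims)
  offsets <- connectivityOffsets(nd, connectivity)
  strides <- gridStrides(dims)

  fg <- which(vals != 0L)
  regions <- list()
  if (length(fg)) {
    coords <- arrayInd(fg, .dim = dims)
    coordOf <- matrix(0L, nrow = n, ncol = nd)
    coordOf[fg, ] <- coords
    rank <- rowMajorRank(dims)
    seeds <- fg[order(rank[fg])]
    comp <- integer(n)
    vlab <- as.vector(vals)
    voxelVol <- prod(labelMap@spacing) / 1000

    nextId <- 0L
    for (s in seeds) {
      if (comp[s] != 0L) next
      nextId <- nextId + 1L
      lab <- vlab[s]
      comp[s] <- nextId
      frontier <- s
      members <- s
      while (length(frontier)) {
        fc <- coordOf[frontier, , drop = FALSE]
        cand <- integer(0)
        for (k in seq_len(nrow(offsets))) {
          nc <- fc + matrix(offsets[k, ], nrow(fc), nd, byrow = TRUE)
          ok <- rep(TRUE, nrow(nc))
          for (a in seq_len(nd)) ok <- ok & nc[, a] >= 1L & nc[, a] <= dims[a]
          if (!any(ok)) next
          lin <- as.vector((nc[ok, , drop = FALSE] - 1L) %*% strides) + 1L
          cand <- c(cand, lin)
        }
        cand <- unique(cand)
        cand <- cand[comp[cand] == 0L & vlab[cand] == lab]
        if (length(cand)) {
          comp[cand] <- nextId
          members <- c(members, cand)
        }
        frontier <- cand
      }
      regions[[nextId]] <- list(
        id = nextId, label = as.integer(lab),
        voxels = sort(as.integer(members)),
        nVoxels = length(members),
        volumeCm3 = length(members) * voxelVol
      )
    }
    keep <- vapply(regions, function(r) r$volumeCm3 >= minVolumeCm3, logical(1))
    regions <- regions[keep]
    # re-id after filtering so ids stay dense and deterministic
    for (i in seq_along(regions)) regions[[i]]$id <- i
  }
  new("RegionSet",
      regions = regions, dim = as.integer(dims),
      spacing = as.numeric(labelMap@spacing), connectivity = connectivity)
}

#' Rasterize a RegionSet back to a label map
#'
#' @param x a `RegionSet`.
#' @param useIds if `TRUE`, paint region ids instead of class labels.
#' @return a [LabelMap-class] on the originating grid.
#' @export
rasterizeRegions <- function(x, useIds = FALSE) {
  stopifnot(is(x, "RegionSet"))
  arr <- array(0L, dim = x@dim)
  for (r in x@regions) arr[r$voxels] <- if (useIds) r$id else r$label
  LabelMap(arr, x@spacing)
}

#' Flag predicted regions as true or false positives
#'
#' A predicted region is a false positive iff it shares zero voxels with
#' any nonzero voxel of the ground truth; a single overlapping voxel makes
#' it a true positive.
#'
#' @param predicted a `RegionSet` of predicted regions.
#' @param truth a `LabelMap` of ground-truth labels on the same grid.
#' @return data frame with `region_id` and logical `is_tp`.
#' @export
classifyDetections <- function(predicted, truth) {
  stopifnot(is(predicted, "RegionSet"), is(truth, "LabelMap"))
  if (!identical(as.integer(predicted@dim), as.integer(dim(truth@values)))) {
    stop("predicted regions and truth are on different grids", call. = FALSE)
  }
  tv <- as.vector(truth@values)
  data.frame(
    region_id = vapply(predicted@regions, function(r) r$id, integer(1)),
    is_tp = vapply(predicted@regions, function(r) any(tv[r$voxels] != 0L), logical(1))
  )
}

#' Majority ground-truth class inside a region
#'
#' When a predicted region overlaps several ground-truth classes, the class
#' with the most voxels inside the region wins; background voxels do not
#' vote when any nonzero class is present. Ties are broken towards the
#' smallest class index. A region that lies entirely on background returns
#' `NA` ("unmatched").
#'
#' @param region a single region (an element of a `RegionSet`, or a
#'   `RegionSet` together with `id`).
#' @param truth a `LabelMap` on the same grid.
#' @param id region identifier when `region` is a `RegionSet`.
#' @return integer class, or `NA_integer_` if unmatched.
#' @export
majorityTruthClass <- function(region, truth, id = NULL) {
  stopifnot(is(truth, "LabelMap"))
  if (is(region, "RegionSet")) {
    if (is.null(id)) stop("supply 'id' when passing a RegionSet", call. = FALSE)
    voxels <- regionVoxels(region, id)
    if (!identical(as.integer(region@dim), as.integer(dim(truth@values)))) {
      stop("region and truth are on different grids", call. = FALSE)
    }
  } else {
    voxels <- region$voxels
  }
  classes <- as.vector(truth@values)[voxels]
  classes <- classes[classes != 0L]
  if (!length(classes)) return(NA_integer_)
  counts <- table(classes)
  best <- max(counts)
  as.integer(names(counts)[counts == best][1L]) # names sorted ascending: smallest wins
}

#' Match regions of one set against another by voxel overlap
#'
#' Greedy full-overlap enumeration: each baseline region is matched to
#' every region of `other` it overlaps by at least one voxel (one-to-many,
#' which accommodates regions splitting under image degradation). Baseline
#' regions with no overlap are unmatched ("non-persisting").
#'
#' @param baseline,other `RegionSet`s on the same grid.
#' @return a list with one element per baseline region:
#'   `source_id`, `target_ids` (integer, possibly empty),
#'   `overlap_voxels` (same length as `target_ids`).
#' @export
matchRegions <- function(baseline, other) {
  stopifnot(is(baseline, "RegionSet"), is(other, "RegionSet"))
  if (!identical(as.integer(baseline@dim), as.integer(other@dim))) {
    stop("region sets are on different grids", call. = FALSE)
  }
  idMap <- integer(prod(other@dim))
  for (r in other@regions) idMap[r$voxels] <- r$id
  lapply(baseline@regions, function(r) {
    hits <- idMap[r$voxels]
    hits <- hits[hits != 0L]
    if (length(hits)) {
      tab <- table(hits)
      ids <- as.integer(names(tab))
      ord <- order(ids)
      list(source_id = r$id, target_ids = ids[ord],
           overlap_voxels = as.integer(tab)[ord])
    } else {
      list(source_id = r$id, target_ids = integer(0), overlap_voxels = integer(0))
    }
  })
}

#' Serialize a RegionSet to JSON
#'
#' Voxel coordinates are written 0-based; bounding boxes are half-open
#' (`[lo, hi)` per axis, 0-based), as stated in the manifest convention.
#'
#' @param x a `RegionSet`.
#' @param path output file path.
#' @export
writeRegionSetJSON <- function(x, path) {
  stopifnot(is(x, "RegionSet"))
  dims <- x@dim
  out <- list(
    grid_dim = dims, spacing_mm = x@spacing, connectivity = x@connectivity,
    coordinate_convention = "0-based voxel coordinates, half-open bounding boxes",
    regions = lapply(x@regions, function(r) {
      coords <- arrayInd(r$voxels, .dim = dims) - 1L
      list(
        region_id = r$id, label = r$label, n_voxels = r$nVoxels,
        volume_cm3 = r$volumeCm3,
        bbox_lo = as.integer(apply(coords, 2L, min)),
        bbox_hi = as.integer(apply(coords, 2L, max) + 1L),
        voxels = coords
      )
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a RegionSet from JSON written by [writeRegionSetJSON()]
#'
#' @param path input file path.
#' @return a [RegionSet-class].
#' @export
readRegionSetJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  dims <- as.integer(unlist(j$grid_dim))
  strides <- gridStrides(dims)
  regions <- lapply(j$regions, function(r) {
    coords <- do.call(rbind, lapply(r$voxels, function(v) as.integer(unlist(v))))
    vox <- sort(as.integer(coords %*% strides) + 1L)
    list(id = as.integer(r$region_id), label = as.integer(r$label),
         voxels = vox, nVoxels = length(vox),
         volumeCm3 = as.numeric(r$volume_cm3))
  })
  new("RegionSet", regions = regions, dim = dims,
      spacing = as.numeric(unlist(j$spacing_mm)),
      connectivity = as.character(j$connectivity))
}
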