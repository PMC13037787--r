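#' @include unet.R targets.R
NULL

# Seed gradient at the logits for one region: the regional target is a
# function of the predicted-class softmax probability p_i at each region
# voxel, with the class channel frozen to the region's (unperturbed)
# predicted label. dT/dz_k = dT/dp_i * p_c (delta_{kc} - p_k) per voxel.
regionLogitSeed <- function(p, voxels, classIdx, nClasses, target) {
  pvec <- p[voxels, classIdx]
  dTdp <- targetGradient(pvec, nClasses, target)
  dZ <- matrix(0, nrow(p), ncol(p))
  rows <- p[voxels, , drop = FALSE]
  block <- -rows * (dTdp * pvec)
  block[, classIdx] <- block[, classIdx] + dTdp * pvec
  dZ[voxels, ] <- block
  dZ
}

# L1 norm of the gradient per parameter group (named vector over all
# decoder blocks), from one backward pass.
groupL1FromGrads <- function(model, grads, groups) {
  vapply(groups, function(g) {
    nms <- paramsInGroups(model, g)
    sum(vapply(nms, function(nm) sum(abs(grads[[nm]])), numeric(1)))
  }, numeric(1))
}

#' Per-group gradient L1 norms for one region
#'
#' Backpropagates the regional target once and reports the L1 norm of the
#' resulting gradient separately for every decoder convolutional block.
#' [localGradientsScore()] is the sum over the selected blocks; the
#' block-sensitivity sweep reuses these norms so one backward pass serves
#' all block configurations.
#'
#' @param model a [ToyUNet-class].
#' @param image the input [ScanImage-class] (or matrix).
#' @param voxels integer linear voxel indices of the region on the output
#'   grid (e.g. from [regionVoxels()]).
#' @param target `"kl"` (KL-divergence target) or `"mp"` (mean
#'   probability).
#' @param fwd optional precomputed forward pass (internal reuse).
#' @return named numeric vector, one non-negative L1 norm per decoder
#'   block.
#' @export
regionGradientNorms <- function(model, image, voxels, target = c("kl", "mp"),
                                fwd = NULL) {
  target <- match.arg(target)
  if (is.null(fwd)) fwd <- unetForward(model, image)
  n <- prod(fwd$dims)
  voxels <- as.integer(voxels)
  if (length(voxels) == 0L) stop("empty region", call. = FALSE)
  if (any(voxels < 1L) || any(voxels > n)) {
    stop("region voxels lie off the model output grid", call. = FALSE)
  }
  cls <- max.col(fwd$p[voxels, , drop = FALSE], ties.method = "first")
  classIdx <- as.integer(stats::median(cls))
  dZ <- regionLogitSeed(fwd$p, voxels, classIdx, model@arch$classes, target)
  grads <- unetBackward(model, fwd, dZ)
  groupL1FromGrads(model, grads, listParameterGroups(model))
}

#' Local Gradients score of one region
#'
#' The regional target (voxel-averaged KL divergence against the uniform
#' reference, or the regional mean probability) is computed from a forward
#' pass on the full image, backpropagated, and the L1 norm of the
#' concatenated gradients of the named decoder blocks is returned. The
#' model is not modified in any way (post hoc contract): weights, and
#' therefore predictions, are identical before and after scoring.
#'
#' @inheritParams regionGradientNorms
#' @param groups character vector of decoder block names to aggregate
#'   (default: the two blocks nearest the output).
#' @return non-negative scalar LG score.
#' @export
localGradientsScore <- function(model, image, voxels, target = c("kl", "mp"),
                                groups = defaultTargetGroups(model), fwd = NULL) {
  target <- match.arg(target)
  groups <- as.character(groups)
  if (length(groups) == 0L) stop("empty group list", call. = FALSE)
  registry <- listParameterGroups(model)
  if (!all(groups %in% registry)) {
    stop(sprintf("unknown parameter group(s): %s",
                 paste(setdiff(groups, registry), collapse = ", ")), call. = FALSE)
  }
  norms <- regionGradientNorms(model, image, voxels, target, fwd = fwd)
  sum(norms[groups])
}

#' Score every region of an image
#'
#' One forward pass on the full image, then one independent backward pass
#' per region. Each record carries the raw regional targets (`kld`, `mp`)
#' computed from the same forward pass and the Local Gradients score `lg`
#' over the selected blocks. Per-region scores are independent of which
#' other regions are present.
#'
#' @param model a [ToyUNet-class].
#' @param image the input [ScanImage-class].
#' @param regions a [RegionSet-class] on the model output grid (typically
#'   extracted from [predictLabelMap()] output).
#' @param target `"kl"` or `"mp"`: the target backpropagated for `lg`.
#' @param groups decoder block names aggregated into `lg`.
#' @return data frame with one row per region: `region_id`, `label`,
#'   `n_voxels`, `volume_cm3`, `t_r` (the target actually backpropagated),
#'   `kld`, `mp`, `lg`, `target_used`, `groups_used`.
#' @export
scoreRegions <- function(model, image, regions, target = c("kl", "mp"),
                         groups = defaultTargetGroups(model)) {
  target <- match.arg(target)
  stopifnot(is(regions, "RegionSet"))
  fwd <- unetForward(model, image)
  if (!identical(as.integer(regions@dim), as.integer(fwd$dims))) {
    stop("regions are not on the model output grid", call. = FALSE)
  }
  C <- model@arch$classes
  rows <- lapply(regions@regions, function(r) {
    cls <- max.col(fwd$p[r$voxels, , drop = FALSE], ties.method = "first")
    classIdx <- as.integer(stats::median(cls))
    pvec <- fwd$p[r$voxels, classIdx]
    data.frame(
      region_id = r$id, label = r$label, n_voxels = r$nVoxels,
      volume_cm3 = r$volumeCm3,
      t_r = if (target == "kl") klTarget(pvec, C) else meanProbability(pvec, C),
      kld = klTarget(pvec, C),
      mp = meanProbability(pvec, C),
      lg = localGradientsScore(model, image, r$voxels, target, groups, fwd = fwd),
      target_used = target,
      groups_used = paste(groups, collapse = "+")
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(
      region_id = integer(0), label = integer(0), n_voxels = integer(0),
      volume_cm3 = numeric(0), t_r = numeric(0), kld = numeric(0),
      mp = numeric(0), lg = numeric(0), target_used = character(0),
      groups_used = character(0)
    ))
  }
  do.call(rbind, rows)
}

#' Finite-difference oracle for the Local Gradients score
#'
#' Independently recomputes the gradient of the regional target with
#' respect to every parameter of the selected blocks by central
#' differences, `(T(w+h) - T(w-h)) / (2h)`, and returns the L1 norm of
#' that vector. Exact agreement with [localGradientsScore()] (to the
#' finite-difference truncation error) validates the backward pass. Only
#' practical for small models.
#'
#' @inheritParams localGradientsScore
#' @param h central-difference step size. The default 1e-5 is small enough
#'   that perturbations rarely cross ReLU or max-pooling kinks (where the
#'   network is not differentiable and central differences are biased) yet
#'   large enough that double-precision cancellation stays orders of
#'   magnitude below the comparison tolerance.
#' @return non-negative scalar: the finite-difference estimate of LG.
#' @export
finiteDifferenceOracle <- function(model, image, voxels, target = c("kl", "mp"),
                                   groups = defaultTargetGroups(model), h = 1e-5) {
  target <- match.arg(target)
  if (h <= 0) stop("h must be positive", call. = FALSE)
  # freeze region class channel from the unperturbed model
  fwd0 <- unetForward(model, image)
  cls <- max.col(fwd0$p[voxels, , drop = FALSE], ties.method = "first")
  classIdx <- as.integer(stats::median(cls))
  C <- model@arch$classes
  evalTarget <- function(params) {
    mdl <- new("ToyUNet", params = params, arch = model@arch, seed = model@seed)
    p <- unetForward(mdl, image)$p
    pvec <- p[voxels, classIdx]
    val <- if (target == "kl") klTarget(pvec, C) else meanProbability(pvec, C)
    if (!is.finite(val)) stop("non-finite target under perturbation", call. = FALSE)
    val
  }
  total <- 0
  for (nm in paramsInGroups(model, groups)) {
    w <- model@params[[nm]]
    for (idx in seq_along(w)) {
      pPlus <- model@params
      pPlus[[nm]][idx] <- w[idx] + h
      pMinus <- model@params
      pMinus[[nm]][idx] <- w[idx] - h
      total <- total + abs((evalTarget(pPlus) - evalTarget(pMinus)) / (2 * h))
    }
  }
  total
}
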