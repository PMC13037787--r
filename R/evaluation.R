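#' @include gradients.R calibration.R degradations.R regions.R
NULL

#' Per-magnitude percent difference of an uncertainty track
#'
#' `100 * (U_sigma - U_0) / U_0` for every magnitude of a degradation
#' sweep, relative to the non-degraded baseline. Only persisting tracks
#' (a value at every magnitude) qualify; non-persisting regions are
#' excluded upstream.
#'
#' @param track list (or data frame row) with `baseline_u` (scalar at
#'   sigma = 0, nonzero) and `per_magnitude_u` (ordered numeric, one per
#'   magnitude).
#' @return numeric vector of percent differences, one per magnitude.
#' @export
percentDiffTrack <- function(track) {
  u0 <- track$baseline_u
  us <- track$per_magnitude_u
  if (length(u0) != 1L || !is.finite(u0)) stop("invalid baseline", call. = FALSE)
  if (u0 == 0) stop("undefined percent difference: baseline is 0", call. = FALSE)
  if (any(!is.finite(us))) stop("track has missing magnitudes", call. = FALSE)
  100 * (us - u0) / u0
}

#' Percent difference between the medians of two groups
#'
#' `100 * (median(U_A) - median(U_B)) / median(U_B)`, the group-median
#' form used for unpaired class comparisons.
#'
#' @param uA,uB non-empty numeric vectors of uncertainty values.
#' @return scalar percent difference.
#' @export
percentDiffGroups <- function(uA, uB) {
  if (!length(uA) || !length(uB)) stop("empty group", call. = FALSE)
  mB <- stats::median(uB)
  if (mB == 0) stop("undefined percent difference: median(uB) is 0", call. = FALSE)
  100 * (stats::median(uA) - mB) / mB
}

#' ROC AUC for separating false from true positives
#'
#' The probability that a randomly chosen positive (FP region, expected to
#' carry high uncertainty) outscores a randomly chosen negative (TP
#' region), with ties credited 1/2 — the Mann-Whitney formulation,
#' computed via ranks.
#'
#' @param scores numeric uncertainty scores.
#' @param isPositive logical, `TRUE` for the positive class (FP regions).
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(scores, isPositive) {
  isPositive <- as.logical(isPositive)
  if (length(scores) != length(isPositive)) stop("length mismatch", call. = FALSE)
  nPos <- sum(isPositive)
  nNeg <- sum(!isPositive)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[isPositive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' False positive rate at fixed sensitivity (FPR95)
#'
#' Flags regions whose uncertainty is at or above a threshold. The
#' threshold is the highest score value that still captures at least
#' `sensitivity` of the positives (FP regions); the return value is the
#' fraction of negatives (TP regions) wrongly flagged at that threshold.
#'
#' @inheritParams rocAuc
#' @param sensitivity required recall on the positive class (default
#'   0.95).
#' @return FPR in `[0, 1]`.
#' @export
fprAtSensitivity <- function(scores, isPositive, sensitivity = 0.95) {
  isPositive <- as.logical(isPositive)
  if (length(scores) != length(isPositive)) stop("length mismatch", call. = FALSE)
  nPos <- sum(isPositive)
  nNeg <- sum(!isPositive)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present", call. = FALSE)
  thresholds <- sort(unique(scores[isPositive]), decreasing = TRUE)
  for (th in thresholds) {
    if (mean(scores[isPositive] >= th) >= sensitivity) {
      return(mean(scores[!isPositive] >= th))
    }
  }
  1 # every candidate threshold misses the sensitivity target: flag all
}

#' Wilcoxon rank test (thin contract)
#'
#' Two-sided p-value of the Wilcoxon signed-rank test (`paired = TRUE`)
#' or rank-sum test (`paired = FALSE`), delegating to
#' [stats::wilcox.test()] (exact small-sample distribution when there are
#' no ties, normal approximation otherwise — the function's standard
#' behaviour). The degenerate paired case in which every difference is
#' zero has no signed ranks and returns the documented sentinel p = 1.
#'
#' @param a,b numeric samples (equal length when paired).
#' @param paired logical.
#' @return two-sided p-value in `(0, 1]`.
#' @export
rankTest <- function(a, b, paired = FALSE) {
  if (paired) {
    if (length(a) != length(b)) stop("paired samples must have equal length", call. = FALSE)
    if (all(a == b)) return(1)
  }
  suppressWarnings(stats::wilcox.test(a, b, paired = paired)$p.value)
}

#' FP-filtering metrics for one set of scored regions
#'
#' @param scores per-region uncertainty values.
#' @param isTP logical, `TRUE` for true-positive regions. FP regions form
#'   the positive class of the detector.
#' @return list with `auc`, `fpr95` and two-sided rank-sum `p_value`
#'   (FP vs TP scores).
#' @export
fpFilterMetrics <- function(scores, isTP) {
  isTP <- as.logical(isTP)
  list(
    auc = rocAuc(scores, !isTP),
    fpr95 = fprAtSensitivity(scores, !isTP),
    p_value = rankTest(scores[!isTP], scores[isTP], paired = FALSE)
  )
}

# ---------------------------------------------------------------------------
# Degradation-response bookkeeping

#' Build uncertainty tracks across a degradation sweep
#'
#' Matches the regions predicted on the non-degraded image (first sweep
#' element) against the regions predicted at every magnitude and collects
#' one uncertainty value per magnitude and baseline region. When a region
#' splits, the split parts' values are combined by a volume-weighted
#' average. A track is persisting when a match exists at every magnitude.
#'
#' @param regionSets list of [RegionSet-class], one per magnitude, the
#'   first being the non-degraded baseline.
#' @param valueTables list of data frames aligned with `regionSets`, each
#'   with columns `region_id` and the column named by `valueColumn`.
#' @param valueColumn name of the uncertainty column to track (e.g.
#'   `"u_lg"` or `"lg"`).
#' @return list with one element per baseline region, each a list with
#'   `region_id`, `persisting`, `baseline_u` and the numeric vector
#'   `per_magnitude_u` (NA where unmatched).
#' @export
uncertaintyTracks <- function(regionSets, valueTables, valueColumn = "u_lg") {
  stopifnot(length(regionSets) == length(valueTables), length(regionSets) >= 1L)
  for (tb in valueTables) {
    if (!valueColumn %in% names(tb)) {
      stop(sprintf("value column '%s' missing from a score table", valueColumn),
           call. = FALSE)
    }
  }
  buildTracks(regionSets, valueTables, valueColumn)
}

#' Degradation response of an uncertainty measure
#'
#' Runs a full degradation sweep on each test image, predicts and scores
#' regions at every magnitude, builds matched uncertainty tracks, and
#' summarizes the response as the median percent difference (over
#' persisting tracks) against the non-degraded baseline at each
#' magnitude.
#'
#' @param model a trained [ToyUNet-class].
#' @param images list of [ScanImage-class] test images.
#' @param spec a [DegradationSpec-class].
#' @param refs calibration references as for [applyCalibration()]; must
#'   cover the tracked measure.
#' @param measure which normalized measure to track: `"u_lg"`, `"u_mp"`
#'   or `"u_kld"`.
#' @param target,groups passed to [scoreRegions()].
#' @param minVolumeCm3 region volume filter applied to every prediction.
#' @return list with `summary` (data frame: `sigma`,
#'   `median_percent_diff`, `iqr_lo`, `iqr_hi`, `n_tracks`) and `tracks`
#'   (list of per-track percent-difference vectors).
#' @export
degradationResponse <- function(model, images, spec, refs,
                                measure = c("u_lg", "u_mp", "u_kld"),
                                target = "kl", groups = defaultTargetGroups(model),
                                minVolumeCm3 = 0.25) {
  measure <- match.arg(measure)
  sigmas <- spec@sigmaGrid
  allPD <- list()
  for (img in images) {
    series <- degradationSweep(img, spec)
    regionSets <- vector("list", length(series))
    tables <- vector("list", length(series))
    for (m in seq_along(series)) {
      lm <- predictLabelMap(model, series[[m]])
      rs <- extractRegions(lm, minVolumeCm3 = minVolumeCm3)
      regionSets[[m]] <- rs
      tb <- scoreRegions(model, series[[m]], rs, target = target, groups = groups)
      tables[[m]] <- applyCalibration(tb, refs)
    }
    if (nRegions(regionSets[[1L]]) == 0L) next
    tr <- buildTracks(regionSets, tables, measure)
    for (t in tr) {
      if (t$persisting && t$baseline_u != 0) {
        allPD[[length(allPD) + 1L]] <- percentDiffTrack(t)
      }
    }
  }
  if (length(allPD) == 0L) {
    return(list(summary = data.frame(sigma = sigmas,
                                     median_percent_diff = NA_real_,
                                     iqr_lo = NA_real_, iqr_hi = NA_real_,
                                     n_tracks = 0L),
                tracks = list()))
  }
  pdMat <- do.call(rbind, allPD)
  list(
    summary = data.frame(
      sigma = sigmas,
      median_percent_diff = apply(pdMat, 2L, stats::median),
      iqr_lo = apply(pdMat, 2L, stats::quantile, probs = 0.25, names = FALSE),
      iqr_hi = apply(pdMat, 2L, stats::quantile, probs = 0.75, names = FALSE),
      n_tracks = nrow(pdMat)
    ),
    tracks = allPD
  )
}

# Internal: one track per baseline region as a plain list.
buildTracks <- function(regionSets, valueTables, valueColumn) {
  baseline <- regionSets[[1L]]
  nMag <- length(regionSets)
  matchesPerMag <- lapply(regionSets, function(rs) matchRegions(baseline, rs))
  lapply(seq_along(baseline@regions), function(i) {
    us <- rep(NA_real_, nMag)
    for (m in seq_len(nMag)) {
      match1 <- matchesPerMag[[m]][[i]]
      tids <- match1$target_ids
      if (length(tids)) {
        tb <- valueTables[[m]]
        sel <- match(tids, tb$region_id)
        vals <- tb[[valueColumn]][sel]
        wts <- tb$volume_cm3[sel]
        us[m] <- sum(vals * wts) / sum(wts)
      }
    }
    list(region_id = baseline@regions[[i]]$id,
         persisting = !anyNA(us),
         baseline_u = us[1L],
         per_magnitude_u = us)
  })
}

# ---------------------------------------------------------------------------
# Decoder-block sensitivity sweep

#' Default block configurations for the sensitivity sweep
#'
#' Each decoder block alone plus the pair at each level, ordered from the
#' output level downwards (for a 5-level decoder this is the 15-row
#' layout: 4-0, 4-1, \{4-0, 4-1\}, 3-0, ...).
#'
#' @param model a [ToyUNet-class].
#' @return list of character vectors of group names.
#' @export
defaultBlockConfigs <- function(model) {
  L <- model@arch$levels
  configs <- list()
  for (l in rev(0:(L - 1L))) {
    b0 <- sprintf("Block_%d-0", l)
    b1 <- sprintf("Block_%d-1", l)
    configs <- c(configs, list(b0, b1, c(b0, b1)))
  }
  configs
}

#' Decoder-block sensitivity sweep for FP filtering
#'
#' Evaluates FP-vs-TP separation (rank-sum p-value, ROC AUC, FPR95) of
#' the gradient uncertainty measure for every block configuration and
#' both regional target functions, plus the two no-gradient baseline rows
#' (raw MP and raw KLD, scale-reversed so that high values mean high
#' uncertainty). One backward pass per region and target serves all
#' configurations.
#'
#' @param model a trained [ToyUNet-class].
#' @param images list of [ScanImage-class] test images.
#' @param truthMaps list of ground-truth [LabelMap-class], aligned with
#'   `images`.
#' @param configs list of block-name vectors (default
#'   [defaultBlockConfigs()]).
#' @param targets character subset of `c("kl", "mp")`.
#' @param minVolumeCm3 region volume filter for predictions.
#' @return data frame with columns `blocks` (`"none"` for the baseline
#'   rows), `target`, `gradient` (logical), `p_value`, `auc`, `fpr95`,
#'   `n_tp`, `n_fp`.
#' @export
blockSensitivitySweep <- function(model, images, truthMaps,
                                  configs = defaultBlockConfigs(model),
                                  targets = c("kl", "mp"),
                                  minVolumeCm3 = 0.25) {
  stopifnot(length(images) == length(truthMaps))
  targets <- match.arg(targets, c("kl", "mp"), several.ok = TRUE)
  registry <- listParameterGroups(model)
  for (cfg in configs) {
    if (!all(cfg %in% registry)) stop("config outside the group registry", call. = FALSE)
  }
  # collect per-region: per-group gradient norms per target, raw mp/kld, TP flag
  normsByTarget <- stats::setNames(
    lapply(targets, function(t) list()), targets)
  rawMP <- numeric(0)
  rawKLD <- numeric(0)
  isTP <- logical(0)
  for (i in seq_along(images)) {
    fwd <- unetForward(model, images[[i]])
    lm <- predictLabelMap(model, images[[i]])
    rs <- extractRegions(lm, minVolumeCm3 = minVolumeCm3)
    if (nRegions(rs) == 0L) next
    flags <- classifyDetections(rs, truthMaps[[i]])
    C <- model@arch$classes
    for (r in rs@regions) {
      cls <- max.col(fwd$p[r$voxels, , drop = FALSE], ties.method = "first")
      classIdx <- as.integer(stats::median(cls))
      pvec <- fwd$p[r$voxels, classIdx]
      rawMP <- c(rawMP, meanProbability(pvec, C))
      rawKLD <- c(rawKLD, klTarget(pvec, C))
      isTP <- c(isTP, flags$is_tp[flags$region_id == r$id])
      for (t in targets) {
        normsByTarget[[t]][[length(normsByTarget[[t]]) + 1L]] <-
          regionGradientNorms(model, images[[i]], r$voxels, t, fwd = fwd)
      }
    }
  }
  if (!length(isTP) || all(isTP) || !any(isTP)) {
    stop("sweep needs both TP and FP regions among the predictions", call. = FALSE)
  }
  rows <- list()
  addRow <- function(blocks, target, gradient, scores) {
    m <- fpFilterMetrics(scores, isTP)
    rows[[length(rows) + 1L]] <<- data.frame(
      blocks = blocks, target = target, gradient = gradient,
      p_value = m$p_value, auc = m$auc, fpr95 = m$fpr95,
      n_tp = sum(isTP), n_fp = sum(!isTP)
    )
  }
  if ("mp" %in% targets) addRow("none", "mp", FALSE, -rawMP)
  if ("kl" %in% targets) addRow("none", "kl", FALSE, -rawKLD)
  for (cfg in configs) {
    for (t in targets) {
      norms <- normsByTarget[[t]]
      scores <- vapply(norms, function(nv) sum(nv[cfg]), numeric(1))
      addRow(paste(cfg, collapse = "+"), t, TRUE, scores)
    }
  }
  do.call(rbind, rows)
}
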