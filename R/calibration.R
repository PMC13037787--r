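#' @include containers.R
NULL

#' Calibrate a normalization constant from low-uncertainty scores
#'
#' Computes the 95th percentile (linear interpolation between order
#' statistics, the `stats::quantile` type-7 convention) of raw scores from
#' regions with a-priori assumed low uncertainty. The constant puts each
#' uncertainty measure on a comparable scale: a score equal to the
#' constant maps to magnitude 1.
#'
#' @param scores non-empty numeric vector of raw scores (LG, MP or KLD).
#' @param measure which measure the scores belong to: `"lg"`, `"mp"` or
#'   `"kld"`.
#' @param percentile percentile in (0, 100]; default 95.
#' @param source free-text description of the reference set (e.g.
#'   "non-degraded validation predictions" or "TP regions").
#' @return a [CalibrationReference-class].
#' @examples
#' ref <- calibrateReference(c(1, 2, 3, 4), "lg")
#' normalizeLG(2, ref)
#' @export
calibrateReference <- function(scores, measure = c("lg", "mp", "kld"),
                               percentile = 95, source = "") {
  measure <- match.arg(measure)
  if (length(scores) == 0L) stop("empty score list", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (percentile <= 0 || percentile > 100) {
    stop("percentile must lie in (0, 100]", call. = FALSE)
  }
  p95 <- as.numeric(stats::quantile(scores, percentile / 100, type = 7, names = FALSE))
  if (p95 <= 0) {
    stop("degenerate calibration: percentile of scores is not positive", call. = FALSE)
  }
  new("CalibrationReference", measure = measure, p95 = p95,
      percentile = as.numeric(percentile), source = as.character(source),
      nScores = length(scores))
}

#' Normalize a Local Gradients score
#'
#' `U_LG = LG / P95(LG_low)`. Large values signal high uncertainty.
#'
#' @param lg raw Local Gradients score(s).
#' @param ref a [CalibrationReference-class] with `measure == "lg"`.
#' @return normalized uncertainty value(s).
#' @export
normalizeLG <- function(lg, ref) {
  stopifnot(is(ref, "CalibrationReference"))
  if (ref@measure != "lg") stop("reference is not an LG calibration", call. = FALSE)
  lg / ref@p95
}

#' Normalize and scale-reverse a non-gradient measure
#'
#' Mean probability and the raw KL-divergence baseline run opposite to
#' uncertainty (large when the model is confident), so their normalized
#' forms are negated: `U = -score / P95(score_low)`. After reversal all
#' three measures are direction-aligned: small for low-uncertainty
#' regions, large for high-uncertainty ones.
#'
#' @param score raw MP or KLD value(s).
#' @param ref a [CalibrationReference-class] with `measure` `"mp"` or
#'   `"kld"`.
#' @return normalized, scale-reversed uncertainty value(s).
#' @export
normalizeReversed <- function(score, ref) {
  stopifnot(is(ref, "CalibrationReference"))
  if (!(ref@measure %in% c("mp", "kld"))) {
    stop("reference must be an MP or KLD calibration", call. = FALSE)
  }
  -score / ref@p95
}

#' Attach normalized uncertainty columns to a score table
#'
#' @param records data frame from [scoreRegions()] with raw `lg`, `mp`,
#'   `kld` columns.
#' @param refs named list with any of `lg`, `mp`, `kld` set to a matching
#'   [CalibrationReference-class]; present measures gain a `u_lg`, `u_mp`
#'   or `u_kld` column.
#' @return `records` with normalized columns appended.
#' @export
applyCalibration <- function(records, refs) {
  stopifnot(is.data.frame(records))
  if (!is.null(refs$lg)) records$u_lg <- normalizeLG(records$lg, refs$lg)
  if (!is.null(refs$mp)) records$u_mp <- normalizeReversed(records$mp, refs$mp)
  if (!is.null(refs$kld)) records$u_kld <- normalizeReversed(records$kld, refs$kld)
  records
}

#' Persist a CalibrationReference as JSON
#' @param ref a [CalibrationReference-class].
#' @param path output `.json` path.
#' @export
writeCalibration <- function(ref, path) {
  stopifnot(is(ref, "CalibrationReference"))
  jsonlite::write_json(
    list(measure = ref@measure, p95 = ref@p95, percentile = ref@percentile,
         source = ref@source, n_scores = ref@nScores),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a CalibrationReference written by [writeCalibration()]
#' @param path input `.json` path.
#' @return a [CalibrationReference-class].
#' @export
readCalibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationReference", measure = j$measure, p95 = as.numeric(j$p95),
      percentile = as.numeric(j$percentile), source = as.character(j$source),
      nScores = as.integer(j$n_scores))
}
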