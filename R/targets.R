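#' @include utils.R
NULL

checkRegionProbs <- function(p, nClasses) {
  if (length(p) < 1L) stop("empty region: no probabilities to aggregate", call. = FALSE)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must be finite and lie in [0, 1]", call. = FALSE)
  }
  if (length(nClasses) != 1L || nClasses < 2L) {
    stop("nClasses must be a single integer >= 2", call. = FALSE)
  }
  invisible(TRUE)
}

#' Regional KL-divergence target
#'
#' The voxel-averaged KL divergence of the predicted-class softmax
#' probabilities inside one localized region against a uniform reference
#' `q = 1/C`:
#' \deqn{T_R = \frac{1}{N} \sum_{i=1}^{N} p_i \,\ln\!\frac{p_i}{1/C}.}
#' Natural logarithm; probabilities are clamped to `[1e-12, 1]` before the
#' log. For argmax-class inputs (`p_i >= 1/C`) the target is non-negative,
#' zero exactly when every voxel sits at the uniform reference, and large
#' for confidently predicted regions. It is the backpropagation seed of
#' the Local Gradients score and doubles, unchanged, as the no-gradient
#' KLD baseline.
#'
#' @param p numeric vector of per-voxel predicted-class probabilities.
#' @param nClasses number of output classes `C` (>= 2).
#' @return scalar target value.
#' @examples
#' klTarget(rep(0.5, 10), 2)  # uniform reference -> 0
#' klTarget(rep(1, 10), 2)    # fully confident   -> log(2)
#' @export
klTarget <- function(p, nClasses) {
  checkRegionProbs(p, nClasses)
  pc <- clampProb(p)
  mean(pc * log(pc * nClasses))
}

#' Regional mean-probability target
#'
#' The mean of the predicted-class softmax probability over the voxels of
#' one region, `MP = (1/N) sum p_i`. Serves both as the no-gradient
#' mean-probability baseline and as an alternative regional target for the
#' gradient measure.
#'
#' @inheritParams klTarget
#' @return scalar mean probability.
#' @export
meanProbability <- function(p, nClasses = 2L) {
  checkRegionProbs(p, nClasses)
  mean(p)
}

# Derivative of the regional target with respect to each p_i, used to seed
# the backward pass. The 1/N voxel-average is included.
targetGradient <- function(p, nClasses, target = c("kl", "mp")) {
  target <- match.arg(target)
  n <- length(p)
  if (target == "mp") return(rep(1 / n, n))
  pc <- clampProb(p)
  (log(pc * nClasses) + 1) / n
}
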