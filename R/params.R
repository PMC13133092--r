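#' @include AllClasses.R
NULL

#' Construct pipeline parameters
#'
#' @param alpha positive proportionality constant for vertex perturbations;
#'   the perturbation along axis i is `max(alpha * |x_i|, epsilon)`. `alpha`
#'   rescales hull volumes monotonically and does not affect barycenter
#'   distances.
#' @param epsilon positive minimal perturbation safeguard.
#' @param nComponents number of leading principal components used for
#'   barycenter distances and hull projection (default 3).
#' @param distanceThresholds three strictly increasing reals; dbary below the
#'   first is high concordance, at or above the last extreme discordance.
#' @param volumeQuantiles two probabilities in (0,1) for the data-driven
#'   volume tiers.
#' @param symmetryBands two reals > 1; a symmetrized volume ratio at or below
#'   the first is Symmetric, above the second Strong asymmetric.
#' @param nPermutations permutation replicates B.
#' @param seed integer seed.
#' @param pvalueTransform `"neglog10"` (default) or `"raw"` strength encoding.
#' @param strengthCap ceiling applied to -log10(p) (default 300).
#' @param entropyLogBase `"natural"` (default) or `"base2"`.
#' @param scaleColumns divide columns by their standard deviation before PCA;
#'   set `FALSE` for the centering-only robustness variant.
#' @param volumeSpace `"projected3d"` (default) or `"latent18"`.
#' @param tierStatistic `"geometric_mean"` (default), `"mean"` or `"max"`.
#' @param immuneMap named numeric mapping immune classes to signed codes.
#'
#' @return a validated [SigPolytopeParam-class] object.
#' @examples
#' SigPolytopeParam(seed = 7, nPermutations = 99L)
#' @export
SigPolytopeParam <- function(alpha = 1,
                             epsilon = 0.05,
                             nComponents = 3L,
                             distanceThresholds = c(0.5, 1.5, 2.5),
                             volumeQuantiles = c(1 / 3, 2 / 3),
                             symmetryBands = c(1.5, 3.0),
                             nPermutations = 500L,
                             seed = 1L,
                             pvalueTransform = c("neglog10", "raw"),
                             strengthCap = 300,
                             entropyLogBase = c("natural", "base2"),
                             scaleColumns = TRUE,
                             volumeSpace = c("projected3d", "latent18"),
                             tierStatistic = c("geometric_mean", "mean", "max"),
                             immuneMap = c(hot = 1, cold = -1,
                                           excluded = 0, intermediate = 0)) {
  new("SigPolytopeParam",
      alpha = as.numeric(alpha),
      epsilon = as.numeric(epsilon),
      nComponents = as.integer(nComponents),
      distanceThresholds = as.numeric(distanceThresholds),
      volumeQuantiles = as.numeric(volumeQuantiles),
      symmetryBands = as.numeric(symmetryBands),
      nPermutations = as.integer(nPermutations),
      seed = as.integer(seed),
      pvalueTransform = match.arg(pvalueTransform),
      strengthCap = as.numeric(strengthCap),
      entropyLogBase = match.arg(entropyLogBase),
      scaleColumns = isTRUE(scaleColumns),
      volumeSpace = match.arg(volumeSpace),
      tierStatistic = match.arg(tierStatistic),
      immuneMap = immuneMap)
}

setValidity("SigPolytopeParam", function(object) {
  msg <- character(0)
  if (length(object@alpha) != 1 || !is.finite(object@alpha) || object@alpha <= 0)
    msg <- c(msg, "alpha must be a positive real")
  if (length(object@epsilon) != 1 || !is.finite(object@epsilon) ||
      object@epsilon <= 0)
    msg <- c(msg, "epsilon must be a positive real")
  if (object@nComponents < 1L || object@nComponents > 18L)
    msg <- c(msg, "nComponents must be in 1..18")
  dt <- object@distanceThresholds
  if (length(dt) != 3 || any(!is.finite(dt)) || any(diff(dt) <= 0))
    msg <- c(msg, "distanceThresholds must be three strictly increasing reals")
  vq <- object@volumeQuantiles
  if (length(vq) != 2 || any(vq <= 0) || any(vq >= 1) || diff(vq) < 0)
    msg <- c(msg, "volumeQuantiles must be two non-decreasing probabilities in (0,1)")
  sb <- object@symmetryBands
  if (length(sb) != 2 || any(sb <= 1) || diff(sb) <= 0)
    msg <- c(msg, "symmetryBands must be two increasing reals > 1")
  if (object@nPermutations < 1L)
    msg <- c(msg, "nPermutations must be >= 1")
  if (object@strengthCap <= 0)
    msg <- c(msg, "strengthCap must be positive")
  im <- object@immuneMap
  if (!all(c("hot", "cold", "excluded", "intermediate") %in% names(im)))
    msg <- c(msg, "immuneMap must name all four immune classes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SigPolytopeParam", function(object) {
  cat("SigPolytopeParam\n")
  cat("  alpha =", object@alpha, "| epsilon =", object@epsilon,
      "| components =", object@nComponents, "\n")
  cat("  distance thresholds:",
      paste(object@distanceThresholds, collapse = " / "), "\n")
  cat("  volume quantiles:",
      paste(signif(object@volumeQuantiles, 4), collapse = ", "),
      "| symmetry bands:", paste(object@symmetryBands, collapse = ", "), "\n")
  cat("  permutations B =", object@nPermutations, "| seed =", object@seed, "\n")
  cat("  strength:", object@pvalueTransform, "(cap", object@strengthCap, ")",
      "| scaling:", object@scaleColumns,
      "| volume space:", object@volumeSpace, "\n")
})
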