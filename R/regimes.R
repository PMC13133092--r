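#' @include AllClasses.R
NULL

.DISTANCE_REGIMES <- c("high_concordance", "moderate_discordance",
                       "strong_discordance", "extreme_discordance")
.VOLUME_TIERS <- c("Low", "Intermediate", "High")
.SYMMETRY_CLASSES <- c("Symmetric", "Mod asymmetric", "Strong asymmetric")
.JOINT_PHENOTYPES <- c("concordant_low_dim", "concordant_high_dim",
                       "discordant_low_dim", "discordant_high_dim_asymmetric")
.CONCORDANCE_CLASSES <- c("Only Convergent", "Only Divergent", "Mixed",
                          "Indeterminate")

#' Classify barycenter distances into discordance regimes
#'
#' Half-open binning with boundary values assigned to the upper bin: dbary
#' below the first threshold is high concordance; at or above the last,
#' extreme discordance. Defaults are 0.5 / 1.5 / 2.5.
#'
#' @param dbary non-negative numeric vector.
#' @param thresholds three strictly increasing thresholds.
#' @return factor with levels high_concordance, moderate_discordance,
#'   strong_discordance, extreme_discordance.
#' @examples
#' classifyDistanceRegime(c(0.20, 0.5, 1.49, 2.5, 7.16))
#' @export
classifyDistanceRegime <- function(dbary, thresholds = c(0.5, 1.5, 2.5)) {
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0))
    stop("thresholds must be three strictly increasing reals", call. = FALSE)
  if (any(!is.finite(dbary)) || any(dbary < 0))
    stop("domain error: dbary must be finite and non-negative", call. = FALSE)
  cut(dbary, breaks = c(-Inf, thresholds, Inf), right = FALSE,
      labels = .DISTANCE_REGIMES)
}

#' Data-driven volume tier thresholds
#'
#' Empirical quantiles (type 7, the documented convention) of the pooled
#' finite positive hull volumes; degenerate flagged-zero volumes must be
#' excluded by the caller.
#'
#' @param volumes positive finite volumes (pooled over sig and int sides).
#' @param probs two quantile probabilities (default 1/3, 2/3).
#' @return numeric(2) thresholds `(v1, v2)`, `v1 <= v2`.
#' @export
volumeTierThresholds <- function(volumes, probs = c(1 / 3, 2 / 3)) {
  v <- volumes[is.finite(volumes) & volumes > 0]
  if (length(v) < 3)
    stop("insufficient data: need >= 3 finite positive volumes", call. = FALSE)
  if (length(probs) != 2 || any(probs <= 0) || any(probs >= 1))
    stop("probs must be two probabilities in (0,1)", call. = FALSE)
  q <- stats::quantile(v, probs = sort(probs), type = 7, names = FALSE)
  q
}

#' Classify the nine volume classes
#'
#' The size tier (Low / Intermediate / High) comes from a scalar size summary
#' of the two side volumes (default: their geometric mean) compared against
#' the data-driven tier thresholds, with boundary values tiering upward.
#' The symmetry state comes from the symmetrized ratio `m = max(r, 1/r)`:
#' Symmetric when `m <= s1`, Mod asymmetric when `s1 < m <= s2`, Strong
#' asymmetric when `m > s2`. Degenerate circuitries (either volume zero or
#' non-finite) fall in the Low tier and are labelled Symmetric by convention.
#'
#' @param volSig,volInt numeric vectors of side volumes.
#' @param tiers numeric(2) from [volumeTierThresholds()].
#' @param symmetryBands numeric(2) bands `(s1, s2)`, both > 1.
#' @param tierStatistic `"geometric_mean"`, `"mean"` or `"max"`.
#' @return data.frame with columns `tier`, `symmetry`, `volumeClass`.
#' @export
classifyVolumeClass <- function(volSig, volInt, tiers,
                                symmetryBands = c(1.5, 3.0),
                                tierStatistic = "geometric_mean") {
  if (length(symmetryBands) != 2 || any(symmetryBands <= 1) ||
      diff(symmetryBands) <= 0)
    stop("config error: symmetry bands must be increasing and > 1",
         call. = FALSE)
  if (length(tiers) != 2 || tiers[1] > tiers[2])
    stop("config error: invalid tier thresholds", call. = FALSE)
  ok <- is.finite(volSig) & is.finite(volInt) & volSig > 0 & volInt > 0
  size <- rep(NA_real_, length(volSig))
  size[ok] <- switch(tierStatistic,
    geometric_mean = sqrt(volSig[ok] * volInt[ok]),
    mean = (volSig[ok] + volInt[ok]) / 2,
    max = pmax(volSig[ok], volInt[ok]),
    stop("unknown tierStatistic", call. = FALSE))
  tier <- rep("Low", length(volSig))
  tier[ok & size >= tiers[1]] <- "Intermediate"
  tier[ok & size >= tiers[2]] <- "High"
  m <- rep(1, length(volSig))
  r <- volSig[ok] / volInt[ok]
  m[ok] <- pmax(r, 1 / r)
  sym <- rep("Symmetric", length(volSig))
  sym[m > symmetryBands[1]] <- "Mod asymmetric"
  sym[m > symmetryBands[2]] <- "Strong asymmetric"
  tier <- factor(tier, levels = .VOLUME_TIERS)
  sym <- factor(sym, levels = .SYMMETRY_CLASSES)
  data.frame(tier = tier, symmetry = sym,
             volumeClass = factor(paste(tier, sym, sep = "/"),
                                  levels = as.vector(outer(.VOLUME_TIERS,
                                                           .SYMMETRY_CLASSES,
                                                           paste, sep = "/"))))
}

#' Joint geometric phenotype
#'
#' Combines the distance regime with the volume class into the four
#' recurrent geometric phenotypes: concordant circuitries are those in the
#' high-concordance regime; the dimensionality arm is Low or High tier, with
#' the Intermediate tier mapped to the high-dimensional arm when asymmetric
#' and to the low-dimensional arm otherwise.
#'
#' @param regime factor/character of distance regimes.
#' @param tier factor/character of volume tiers.
#' @param symmetry factor/character of symmetry states.
#' @return factor over the four phenotypes.
#' @export
jointGeometricPhenotype <- function(regime, tier, symmetry) {
  regime <- as.character(regime)
  tier <- as.character(tier)
  symmetry <- as.character(symmetry)
  concordant <- regime == "high_concordance"
  highDim <- tier == "High" |
    (tier == "Intermediate" & symmetry != "Symmetric")
  lab <- ifelse(concordant,
                ifelse(highDim, "concordant_high_dim", "concordant_low_dim"),
                ifelse(highDim, "discordant_high_dim_asymmetric",
                       "discordant_low_dim"))
  factor(lab, levels = .JOINT_PHENOTYPES)
}

# signed comparison table of one circuitry's two sides over the annotated
# axis families used by the concordance summary
.concordanceSigns <- function(row, immuneMap) {
  sgn <- function(x) if (!is.finite(x) || x == 0) 0 else sign(x)
  survSigns <- function(side) {
    vapply(.SURV_ENDPOINTS, function(e) {
      if (!isTRUE(row[[paste0(side, "_", e, "_significant")]])) return(0)
      encodeDirection(row[[paste0(side, "_", e, "_direction")]])
    }, numeric(1))
  }
  rbind(
    sig = c(rho = sgn(row$sig_rho),
            tn = encodeDirection(row$sig_tn_direction),
            survSigns("sig"),
            micro = sgn(row$sig_micro_score),
            immune = encodeImmuneClass(row$sig_immune_class, immuneMap)),
    int = c(rho = sgn(row$int_rho),
            tn = encodeDirection(row$int_tn_direction),
            survSigns("int"),
            micro = sgn(row$int_micro_score),
            immune = encodeImmuneClass(row$int_immune_class, immuneMap)))
}

#' Concordance summary class of a circuitry
#'
#' Compares the signs of the two sides over the annotated axis families
#' (phenotype-correlation sign, tumor-normal direction, each survival
#' endpoint significant on both sides, microenvironment sign, immune
#' polarity). Axes where either side is zero/neutral are excluded. If every
#' comparable axis agrees the circuitry is Only Convergent, if every one
#' disagrees Only Divergent, otherwise Mixed; with no comparable axis the
#' explicit Indeterminate label is returned.
#'
#' @param table a [CircuitryTable-class].
#' @param ids circuitry identifiers (default: all).
#' @param immuneMap signed immune-class map.
#' @return factor over Only Convergent / Only Divergent / Mixed /
#'   Indeterminate.
#' @export
concordanceSummary <- function(table, ids = circuitryIds(table),
                               immuneMap = c(hot = 1, cold = -1,
                                             excluded = 0, intermediate = 0)) {
  stopifnot(methods::is(table, "CircuitryTable"))
  d <- table@data
  out <- vapply(ids, function(id) {
    row <- d[match(id, d$id), , drop = FALSE]
    s <- .concordanceSigns(row, immuneMap)
    comparable <- s[1, ] != 0 & s[2, ] != 0
    if (!any(comparable)) return("Indeterminate")
    agree <- s[1, comparable] == s[2, comparable]
    if (all(agree)) "Only Convergent"
    else if (!any(agree)) "Only Divergent"
    else "Mixed"
  }, character(1))
  factor(out, levels = .CONCORDANCE_CLASSES)
}
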