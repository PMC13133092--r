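#' @include AllClasses.R
NULL

#' Signed encoding of categorical directions
#'
#' Maps a three-state direction label onto a signed code: `up`/`risk` to +1,
#' `down`/`protective` to -1, `ns` (and common non-significant synonyms) to 0.
#'
#' @param label character vector of direction labels.
#' @return numeric vector in \{-1, 0, +1\}.
#' @examples
#' encodeDirection(c("risk", "protective", "ns", "up", "down"))
#' @export
encodeDirection <- function(label) {
  x <- tolower(trimws(as.character(label)))
  x[x %in% c("n.s.", "non-significant", "nonsignificant", "non_significant",
             "none")] <- "ns"
  out <- rep(NA_real_, length(x))
  out[x %in% c("up", "risk")] <- 1
  out[x %in% c("down", "protective")] <- -1
  out[x == "ns"] <- 0
  if (anyNA(out))
    stop("encoding error: unknown direction label '",
         label[which(is.na(out))[1]], "'", call. = FALSE)
  out
}

#' Strength encoding of p-values
#'
#' Transforms a p-value into a non-negative strength coordinate. The default
#' `neglog10` transform returns `-log10(p)` capped at `cap` so that
#' below-representable p-values (which underflow to 0 in double precision)
#' yield the cap rather than an infinity; `raw` returns p unchanged.
#'
#' @param p numeric vector of p-values in \code{[0, 1]} (0 is accepted as an
#'   underflowed value and maps to the cap under `neglog10`).
#' @param transform `"neglog10"` or `"raw"`.
#' @param cap ceiling for the transformed strength (default 300).
#' @return non-negative numeric vector.
#' @examples
#' encodeStrength(c(0.01, 1, 1e-400))
#' @export
encodeStrength <- function(p, transform = c("neglog10", "raw"), cap = 300) {
  transform <- match.arg(transform)
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("domain error: p-values must lie in [0, 1]", call. = FALSE)
  if (transform == "raw") return(p)
  pmin(-log10(pmax(p, 10^(-cap))), cap)
}

#' Encode one survival endpoint as (direction, strength, chi2)
#'
#' When the endpoint is flagged non-significant all three coordinates are set
#' exactly to zero, so non-informative axes do not deform the circuitry
#' geometry; otherwise the signed Cox direction, the transformed p-value and
#' the raw log-rank chi-squared statistic are returned.
#'
#' @param direction `"risk"`, `"protective"` or `"ns"`.
#' @param p endpoint p-value.
#' @param chi2 non-negative log-rank chi-squared statistic.
#' @param significant logical significance flag.
#' @param transform,cap passed to [encodeStrength()].
#' @return numeric(3): direction, strength, chi2.
#' @examples
#' encodeSurvivalBlock("risk", 0.001, 10.8, TRUE)
#' encodeSurvivalBlock("ns", 0.8, 0.06, FALSE)
#' @export
encodeSurvivalBlock <- function(direction, p, chi2, significant,
                                transform = "neglog10", cap = 300) {
  if (!isTRUE(significant) && !isFALSE(significant))
    stop("significance flag must be TRUE or FALSE", call. = FALSE)
  if (!significant) return(c(0, 0, 0))
  d <- encodeDirection(direction)
  if (d == 0)
    stop("consistency error: endpoint marked significant with direction 'ns'",
         call. = FALSE)
  if (!is.finite(chi2) || chi2 < 0)
    stop("domain error: chi2 must be non-negative", call. = FALSE)
  c(d, encodeStrength(p, transform, cap), chi2)
}

#' Signed encoding of the immune class
#'
#' The four immune classes map onto the signed codomain \{-1, 0, +1\}:
#' hot is +1, cold is -1, and the two non-polar states (excluded,
#' intermediate) are 0 under the default map. The map is configurable because
#' only the codomain, not the assignment of the non-polar states, is fixed by
#' the encoding contract.
#'
#' @param label character vector of immune classes (an optional `immune-`
#'   prefix is tolerated).
#' @param map named numeric mapping for the four classes.
#' @return numeric vector of signed codes.
#' @examples
#' encodeImmuneClass(c("hot", "cold", "excluded", "intermediate"))
#' @export
encodeImmuneClass <- function(label,
                              map = c(hot = 1, cold = -1,
                                      excluded = 0, intermediate = 0)) {
  x <- .normalizeImmune(label, "immune_class")
  unname(map[x])
}

# encode one side of one row of a canonical CircuitryTable
.encodeSideRow <- function(row, side, param) {
  g <- function(f) row[[paste0(side, "_", f)]]
  tr <- param@pvalueTransform
  cap <- param@strengthCap
  rho <- g("rho")
  if (!is.finite(rho)) stop("absent rho for side ", side, call. = FALSE)
  surv <- unlist(lapply(.SURV_ENDPOINTS, function(e) {
    encodeSurvivalBlock(g(paste0(e, "_direction")), g(paste0(e, "_p")),
                        g(paste0(e, "_chi2")), g(paste0(e, "_significant")),
                        transform = tr, cap = cap)
  }))
  v <- c(rho,
         encodeStrength(g("rho_adj_p"), tr, cap),
         encodeDirection(g("tn_direction")),
         encodeStrength(g("tn_wilcoxon_p"), tr, cap),
         surv,
         g("micro_score"),
         encodeImmuneClass(g("immune_class"), param@immuneMap))
  names(v) <- latentCoordinateNames()
  v
}

#' Build the 18-dimensional latent vector for one circuitry side
#'
#' @param table a [CircuitryTable-class].
#' @param id circuitry identifier.
#' @param side `"sig"` or `"int"`.
#' @param param a [SigPolytopeParam-class].
#' @return named numeric(18) in the fixed coordinate order of
#'   [latentCoordinateNames()].
#' @examples
#' tab <- simulateAtlas(simulationSpec(nCircuitries = 3, seed = 1))$table
#' buildLatentVector(tab, circuitryIds(tab)[1], "sig")
#' @export
buildLatentVector <- function(table, id, side = c("sig", "int"),
                              param = SigPolytopeParam()) {
  side <- match.arg(side)
  stopifnot(methods::is(table, "CircuitryTable"))
  i <- match(id, table@data$id)
  if (is.na(i)) stop("unknown circuitry id: ", id, call. = FALSE)
  .encodeSideRow(table@data[i, , drop = FALSE], side, param)
}

#' Build the joint 2N x 18 latent tensor
#'
#' Stacks the latent vectors of both sides of every circuitry. Rows are
#' ordered circuitry-major (all `sig` rows first, then all `int` rows, each in
#' table order) and carry a stable row index mapping row number to
#' (id, side).
#'
#' @param table a [CircuitryTable-class].
#' @param param a [SigPolytopeParam-class].
#' @return a numeric matrix with `2 * nCircuitries(table)` rows, 18 named
#'   columns, and attributes `index` (a data.frame with columns `id`, `side`,
#'   `row`) for the bijection between rows and (id, side) pairs.
#' @export
buildLatentTensor <- function(table, param = SigPolytopeParam()) {
  stopifnot(methods::is(table, "CircuitryTable"))
  d <- table@data
  n <- nrow(d)
  if (n == 0) stop("empty circuitry table", call. = FALSE)
  enc <- function(side) t(vapply(seq_len(n), function(i)
    .encodeSideRow(d[i, , drop = FALSE], side, param),
    numeric(18)))
  x <- rbind(enc("sig"), enc("int"))
  colnames(x) <- latentCoordinateNames()
  idx <- data.frame(id = rep(d$id, 2),
                    side = rep(c("sig", "int"), each = n),
                    row = seq_len(2 * n),
                    stringsAsFactors = FALSE)
  rownames(x) <- paste(idx$id, idx$side, sep = ":")
  attr(x, "index") <- idx
  x
}
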