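#' @include AllGenerics.R
NULL

#' Circuitry identifiers
#'
#' Accessors for [CircuitryTable-class] objects.
#'
#' @param x a `CircuitryTable`.
#' @return `circuitryIds` returns a character vector of unique circuitry
#'   identifiers; `nCircuitries` the number of circuitries; `circuitryData`
#'   the canonical annotation `data.frame` (one row per circuitry);
#'   `tableDialect` the input dialect the table was read with.
#' @aliases circuitryIds nCircuitries circuitryData tableDialect
#' @examples
#' tab <- simulateAtlas(simulationSpec(nCircuitries = 5, seed = 1))$table
#' circuitryIds(tab)
#' nCircuitries(tab)
#' @export
setGeneric("circuitryIds", function(x) standardGeneric("circuitryIds"))

#' @rdname circuitryIds
#' @export
setGeneric("nCircuitries", function(x) standardGeneric("nCircuitries"))

#' @rdname circuitryIds
#' @export
setGeneric("circuitryData", function(x) standardGeneric("circuitryData"))

#' @rdname circuitryIds
#' @export
setGeneric("tableDialect", function(x) standardGeneric("tableDialect"))
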