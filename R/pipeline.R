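#' @include AllClasses.R
NULL

#' Run the full geometric pipeline
#'
#' Executes encode, standardize, PCA, vertex generation, convex hulls,
#' descriptors and classification for every circuitry of the table. Fully
#' deterministic given the parameters; each stage logs a structured line
#' (stage, n, elapsed) unless `verbose = FALSE`.
#'
#' @param table a [CircuitryTable-class].
#' @param param a [SigPolytopeParam-class].
#' @param verbose emit per-stage log messages.
#' @return the geometry table: a `data.frame` with one row per circuitry
#'   (id, strata, dbary, side volumes, asymmetry, anisotropy, degeneracy
#'   flags, distance regime, volume class, joint phenotype, concordance
#'   class). Attributes: `embeddingModel` (the fitted
#'   [EmbeddingModel-class]), `tierThresholds`, `param`.
#' @examples
#' atlas <- simulateAtlas(simulationSpec(nCircuitries = 25, seed = 11))
#' geo <- runPipeline(atlas$table, verbose = FALSE)
#' table(geo$distance_regime)
#' @export
runPipeline <- function(table, param = SigPolytopeParam(), verbose = TRUE) {
  stopifnot(methods::is(table, "CircuitryTable"))
  if (nCircuitries(table) == 0) stop("empty circuitry table", call. = FALSE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
    if (verbose)
      message(sprintf("[sigpolytope] stage=%s n=%d elapsed=%.2fs",
                      name, nCircuitries(table),
                      proc.time()[["elapsed"]] - t0))
    out
  }
  x <- stage("encode", buildLatentTensor(table, param))
  n <- nrow(x) / 2
  xs <- stage("standardize", standardizeTensor(x, scale = param@scaleColumns))
  model <- stage("pca", fitEmbedding(xs, param@nComponents))

  d <- table@data
  geoms <- stage("geometry", lapply(seq_len(n), function(i)
    .dualGeometry(d$id[i],
                  x[i, ], x[n + i, ],
                  model, param)))
  g1 <- function(f) vapply(geoms, function(g) methods::slot(g, f), numeric(1))
  gl <- function(f) vapply(geoms, function(g) methods::slot(g, f), logical(1))
  volSig <- g1("volSig"); volInt <- g1("volInt")
  degen <- gl("degenerateSig") | gl("degenerateInt")
  dbary <- g1("dbary")

  cls <- stage("classify", {
    tiers <- volumeTierThresholds(c(volSig[!degen], volInt[!degen]),
                                  param@volumeQuantiles)
    vc <- classifyVolumeClass(volSig, volInt, tiers,
                              param@symmetryBands, param@tierStatistic)
    regime <- classifyDistanceRegime(dbary, param@distanceThresholds)
    list(tiers = tiers, vc = vc, regime = regime,
         joint = jointGeometricPhenotype(regime, vc$tier, vc$symmetry),
         conc = concordanceSummary(table, immuneMap = param@immuneMap))
  })

  asym <- ifelse(volSig > 0 & volInt > 0, volSig / volInt, NA_real_)
  out <- data.frame(
    id = d$id,
    cancer_type = d$cancer_type,
    superfamily = d$superfamily,
    pathway = d$pathway,
    phenotype_layer = d$phenotype_layer,
    dbary = dbary,
    vol_sig = volSig,
    vol_int = volInt,
    asym_ratio = asym,
    asym_symmetrized = ifelse(is.na(asym), NA_real_, pmax(asym, 1 / asym)),
    anisotropy_sig = g1("anisotropySig"),
    anisotropy_int = g1("anisotropyInt"),
    degenerate_sig = gl("degenerateSig"),
    degenerate_int = gl("degenerateInt"),
    distance_regime = as.character(cls$regime),
    volume_tier = as.character(cls$vc$tier),
    symmetry_class = as.character(cls$vc$symmetry),
    volume_class = as.character(cls$vc$volumeClass),
    joint_phenotype = as.character(cls$joint),
    concordance_class = as.character(cls$conc),
    stringsAsFactors = FALSE)
  attr(out, "embeddingModel") <- model
  attr(out, "tierThresholds") <- cls$tiers
  attr(out, "param") <- param
  out
}

.GEOMETRY_NUMERIC_COLS <- c("dbary", "vol_sig", "vol_int", "asym_ratio",
                            "asym_symmetrized", "anisotropy_sig",
                            "anisotropy_int")

#' Write / read a geometry table
#'
#' The geometry table is serialized as UTF-8 TSV with 17 significant digits,
#' so write-then-read round trips reproduce every descriptor exactly. A JSON
#' sidecar (`<path>.params.json`) records the fitted tier thresholds and all
#' classification parameters used.
#'
#' @param geometry a geometry `data.frame` from [runPipeline()].
#' @param path output TSV path.
#' @return `writeGeometryTable` invisibly returns `path`;
#'   `readGeometryTable` the restored `data.frame`.
#' @export
writeGeometryTable <- function(geometry, path) {
  if (!is.data.frame(geometry) || nrow(geometry) == 0)
    stop("geometry records must be a non-empty data.frame", call. = FALSE)
  .writeFullPrecisionTSV(geometry, path)
  tiers <- attr(geometry, "tierThresholds")
  param <- attr(geometry, "param")
  if (!is.null(param)) {
    side <- list(tierThresholds = tiers,
                 distanceThresholds = param@distanceThresholds,
                 volumeQuantiles = param@volumeQuantiles,
                 symmetryBands = param@symmetryBands,
                 alpha = param@alpha, epsilon = param@epsilon,
                 nComponents = param@nComponents,
                 tierStatistic = param@tierStatistic,
                 volumeSpace = param@volumeSpace)
    jsonlite::write_json(side, paste0(path, ".params.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname writeGeometryTable
#' @export
readGeometryTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "",
                           na.strings = "NA")
  for (cn in intersect(.GEOMETRY_NUMERIC_COLS, names(out)))
    out[[cn]] <- as.numeric(out[[cn]])
  out
}
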