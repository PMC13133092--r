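#' @include AllGenerics.R
NULL

#' Fixed order of the 18 latent coordinates
#'
#' Every circuitry side is encoded as an 18-dimensional latent vector whose
#' coordinates appear in this fixed, documented order: the phenotype Spearman
#' correlation and its strength, the tumor-versus-normal direction and
#' strength, then for each survival endpoint (OS, DSS, DFI, PFI) a signed Cox
#' direction, a strength and a log-rank chi-squared statistic, and finally the
#' continuous microenvironment score and the signed immune code.
#'
#' @return character vector of length 18.
#' @examples
#' latentCoordinateNames()
#' @export
latentCoordinateNames <- function() {
  c("rho", "rho_strength",
    "tn_dir", "tn_strength",
    "os_dir", "os_strength", "os_chi2",
    "dss_dir", "dss_strength", "dss_chi2",
    "dfi_dir", "dfi_strength", "dfi_chi2",
    "pfi_dir", "pfi_strength", "pfi_chi2",
    "micro_score", "immune_code")
}

.SURV_ENDPOINTS <- c("os", "dss", "dfi", "pfi")
.DIR_COORDS <- c("tn_dir", "os_dir", "dss_dir", "dfi_dir", "pfi_dir",
                 "immune_code")
.SURV_COORD_IDX <- 5:16    # the 4 x (dir, strength, chi2) block
.IMMUNE_COORD_IDX <- 18L

#' SigPolytopeParam: pipeline parameters
#'
#' Holds every tunable of the geometric pipeline: the vertex perturbation
#' constants (`alpha`, `epsilon`), the number of embedding components used for
#' distances, the distance-regime thresholds, the data-driven volume quantile
#' probabilities and symmetry bands, permutation settings, the p-value
#' strength transform and the entropy log base. Construct with
#' [SigPolytopeParam()].
#'
#' @slot alpha positive real; vertex perturbation proportionality constant.
#' @slot epsilon positive real; minimal perturbation safeguard.
#' @slot nComponents integer; embedding components used for barycenter
#'   distances (default 3).
#' @slot distanceThresholds three strictly increasing reals binning dbary.
#' @slot volumeQuantiles two probabilities defining volume tiers.
#' @slot symmetryBands two reals > 1 separating symmetric, moderately
#'   asymmetric and strongly asymmetric volume ratios.
#' @slot nPermutations integer; permutation replicates B.
#' @slot seed integer seed for all randomized operations.
#' @slot pvalueTransform `"neglog10"` or `"raw"`.
#' @slot strengthCap cap applied to -log10(p) strengths.
#' @slot entropyLogBase `"natural"` or `"base2"`.
#' @slot scaleColumns logical; divide by column standard deviations before
#'   PCA (`FALSE` reproduces the centering-only robustness variant).
#' @slot volumeSpace `"projected3d"` (hulls of projected vertices) or
#'   `"latent18"` (closed-form cross-polytope volume in the standardized
#'   18-dimensional space).
#' @slot tierStatistic scalar size summary used for volume tiers:
#'   `"geometric_mean"`, `"mean"` or `"max"` of the two side volumes.
#' @slot immuneMap named numeric mapping of the four immune classes onto
#'   signed codes.
#' @aliases SigPolytopeParam-class
#' @exportClass SigPolytopeParam
setClass("SigPolytopeParam",
  representation(
    alpha = "numeric",
    epsilon = "numeric",
    nComponents = "integer",
    distanceThresholds = "numeric",
    volumeQuantiles = "numeric",
    symmetryBands = "numeric",
    nPermutations = "integer",
    seed = "integer",
    pvalueTransform = "character",
    strengthCap = "numeric",
    entropyLogBase = "character",
    scaleColumns = "logical",
    volumeSpace = "character",
    tierStatistic = "character",
    immuneMap = "numeric"
  )
)

#' CircuitryTable: per-circuitry annotation table
#'
#' One row per regulatory circuitry with canonical column names. Each
#' circuitry carries two annotation blocks, one per side (`sig_*`, `int_*`):
#' a Spearman rho against a phenotypic attribute with its adjusted P, a
#' tumor-versus-normal direction with a Wilcoxon P, four survival endpoint
#' blocks (Cox direction, P, log-rank chi-squared, significance flag), a
#' continuous microenvironment score and a categorical immune class, plus
#' stratification metadata (cancer type is mandatory; it defines the
#' permutation strata).
#'
#' @slot data canonical annotation `data.frame`.
#' @slot dialect input dialect the table was parsed from
#'   (`"generic"` or `"dataset_s1"`).
#' @slot sourcePath path the table was read from (`""` for in-memory tables).
#' @aliases CircuitryTable-class
#' @seealso [readCircuitryTable()], [simulateAtlas()]
#' @exportClass CircuitryTable
setClass("CircuitryTable",
  representation(
    data = "data.frame",
    dialect = "character",
    sourcePath = "character"
  )
)

#' EmbeddingModel: the shared latent coordinate system
#'
#' Column means and scales of the global standardization plus the full
#' 18-component PCA loadings and eigenvalues fitted on the joint 2N x 18
#' latent tensor. Loadings columns are orthonormal, ordered by decreasing
#' eigenvalue, and carry a deterministic sign convention (the
#' largest-magnitude entry of each column is positive).
#'
#' @slot means,scales numeric(18) standardization parameters; zero-variance
#'   columns carry scale 1.
#' @slot loadings 18 x 18 orthonormal loading matrix.
#' @slot eigenvalues numeric(18), non-increasing, non-negative.
#' @slot nComponentsDefault integer, default projection dimension.
#' @slot scaled logical; whether variance scaling was applied.
#' @aliases EmbeddingModel-class
#' @seealso [fitEmbedding()], [projectLatent()]
#' @exportClass EmbeddingModel
setClass("EmbeddingModel",
  representation(
    means = "numeric",
    scales = "numeric",
    loadings = "matrix",
    eigenvalues = "numeric",
    nComponentsDefault = "integer",
    scaled = "logical"
  )
)

#' DualPolytope: per-circuitry geometry
#'
#' The two 36-vertex cross-polytopes of a circuitry (one per side), their
#' projections into the shared embedding, hull summaries and the derived
#' descriptors.
#'
#' @slot id circuitry identifier.
#' @slot verticesSig,verticesInt 36 x 18 latent-space vertex matrices.
#' @slot projSig,projInt 36 x k projected vertex matrices.
#' @slot barycenterSig,barycenterInt projected barycenters.
#' @slot dbary Euclidean distance between the two barycenters.
#' @slot volSig,volInt hull volumes (0 with a degeneracy flag when the
#'   projected cloud is rank-deficient).
#' @slot areaSig,areaInt hull surface areas.
#' @slot asymRatio volSig / volInt.
#' @slot anisotropySig,anisotropyInt principal semi-axis ratios of the
#'   projected vertex clouds.
#' @slot facetsSig,facetsInt integer facet matrices (rows are triangles,
#'   outward-oriented) for mesh export.
#' @slot degenerateSig,degenerateInt logical degeneracy flags.
#' @aliases DualPolytope-class
#' @seealso [buildDualPolytope()], [exportHullMesh()]
#' @exportClass DualPolytope
setClass("DualPolytope",
  representation(
    id = "character",
    verticesSig = "matrix", verticesInt = "matrix",
    projSig = "matrix", projInt = "matrix",
    barycenterSig = "numeric", barycenterInt = "numeric",
    dbary = "numeric",
    volSig = "numeric", volInt = "numeric",
    areaSig = "numeric", areaInt = "numeric",
    asymRatio = "numeric",
    anisotropySig = "numeric", anisotropyInt = "numeric",
    facetsSig = "matrix", facetsInt = "matrix",
    degenerateSig = "logical", degenerateInt = "logical"
  )
)

#' PermutationResult: stratified permutation null
#'
#' Result of the within-stratum permutation null model: observed global
#' statistics (mean dbary, proportion extreme discordance, proportion high
#' concordance), the B x 3 matrix of null draws and the bias-corrected
#' empirical p-values p = (k + 1) / (B + 1).
#'
#' @slot B integer number of permutation replicates.
#' @slot observed named numeric(3).
#' @slot nullDraws B x 3 matrix of null statistics.
#' @slot pValues named numeric(3) in [1/(B+1), 1].
#' @slot seed integer seed that drove the replicates.
#' @aliases PermutationResult-class
#' @seealso [permutationNull()]
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(
    B = "integer",
    observed = "numeric",
    nullDraws = "matrix",
    pValues = "numeric",
    seed = "integer"
  )
)

setValidity("EmbeddingModel", function(object) {
  p <- length(object@means)
  if (length(object@scales) != p) return("means/scales length mismatch")
  if (any(object@scales <= 0)) return("scales must be positive")
  if (!all(dim(object@loadings) == c(p, p))) return("loadings must be square p x p")
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(p))) > 1e-8) return("loadings columns not orthonormal")
  ev <- object@eigenvalues
  if (length(ev) != p) return("eigenvalues length mismatch")
  if (any(ev < -1e-10)) return("eigenvalues must be non-negative")
  if (any(diff(ev) > 1e-10)) return("eigenvalues must be non-increasing")
  TRUE
})

setValidity("PermutationResult", function(object) {
  if (object@B < 1L) return("B must be >= 1")
  if (!all(dim(object@nullDraws) == c(object@B, 3L)))
    return("nullDraws must be B x 3")
  pmin <- 1 / (object@B + 1)
  if (any(object@pValues < pmin - 1e-12 | object@pValues > 1 + 1e-12))
    return("p-values must lie in [1/(B+1), 1]")
  TRUE
})

setMethod("show", "EmbeddingModel", function(object) {
  ev <- object@eigenvalues
  cat("EmbeddingModel on", length(object@means), "latent coordinates\n")
  cat("  scaled:", object@scaled,
      " | default components:", object@nComponentsDefault, "\n")
  cat("  variance explained by PC1-3:",
      sprintf("%.1f%%", 100 * sum(ev[1:3]) / max(sum(ev), .Machine$double.eps)),
      "\n")
})

setMethod("show", "DualPolytope", function(object) {
  cat("DualPolytope", object@id, "\n")
  cat(sprintf("  dbary = %.4g | vol(sig) = %.4g | vol(int) = %.4g | asym = %.4g\n",
              object@dbary, object@volSig, object@volInt, object@asymRatio))
  if (object@degenerateSig || object@degenerateInt)
    cat("  degenerate hull(s):",
        paste(c("sig", "int")[c(object@degenerateSig, object@degenerateInt)],
              collapse = ", "), "\n")
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult (B =", object@B, ", seed =", object@seed, ")\n")
  out <- data.frame(observed = object@observed, p = object@pValues)
  print(out)
})
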