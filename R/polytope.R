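#' @include AllClasses.R
NULL

#' Generate the deterministic 36-vertex cross-polytope
#'
#' For each latent axis i the coordinate is perturbed symmetrically by
#' `delta_i = max(alpha * |x_i|, epsilon)`, yielding the 2 x 18 = 36 vertices
#' `x +/- delta_i e_i`. The perturbation is proportional to the coordinate
#' magnitude with a minimal epsilon safeguard, so strongly engaged axes
#' expand the polytope while silent axes contribute only the safeguard. The
#' vertex mean equals the input vector exactly.
#'
#' @param latent numeric latent vector (length d, typically 18).
#' @param alpha positive proportionality constant.
#' @param epsilon positive minimal perturbation.
#' @return a 2d x d matrix of vertices; attribute `deltas` carries the
#'   per-axis perturbation magnitudes.
#' @examples
#' v <- generateVertices(rep(0, 18))
#' nrow(v)            # 36
#' colMeans(v)        # the input vector
#' @export
generateVertices <- function(latent, alpha = 1, epsilon = 0.05) {
  if (!is.numeric(latent) || any(!is.finite(latent)))
    stop("latent vector must be finite numeric", call. = FALSE)
  if (alpha <= 0 || epsilon <= 0)
    stop("alpha and epsilon must be positive", call. = FALSE)
  d <- length(latent)
  delta <- pmax(alpha * abs(latent), epsilon)
  v <- matrix(rep(latent, each = 2 * d), nrow = 2 * d)
  idx <- rep(seq_len(d), each = 2)
  sgn <- rep(c(1, -1), d)
  v[cbind(seq_len(2 * d), idx)] <- latent[idx] + sgn * delta[idx]
  colnames(v) <- names(latent)
  attr(v, "deltas") <- delta
  v
}

#' Closed-form volume of an axis-aligned cross-polytope
#'
#' The convex hull of `x +/- delta_i e_i` in d dimensions has volume
#' `2^d / d! * prod(delta_i)`. Evaluated in log space for numerical safety at
#' d = 18.
#'
#' @param deltas positive per-axis semi-axis lengths.
#' @return the volume.
#' @examples
#' crossPolytopeVolume(c(1, 1, 1))   # 4/3
#' crossPolytopeVolume(c(1, 1))      # 2, the unit diamond
#' @export
crossPolytopeVolume <- function(deltas) {
  deltas <- as.numeric(deltas)
  if (any(!is.finite(deltas)) || any(deltas <= 0))
    stop("domain error: all deltas must be positive", call. = FALSE)
  d <- length(deltas)
  exp(d * log(2) - lfactorial(d) + sum(log(deltas)))
}

#' Barycenter of a point set
#'
#' The geometric center (arithmetic mean coordinate) of a polytope's
#' vertices, summarizing the net latent orientation of one circuitry side.
#'
#' @param points k x m numeric matrix, k >= 1.
#' @return numeric(m).
#' @export
polytopeBarycenter <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 1) stop("domain error: empty point set", call. = FALSE)
  colMeans(pts)
}

#' Barycenter distance between the two sides
#'
#' Euclidean distance between the sig and int barycenters in the shared
#' embedding; the geometric discordance metric.
#'
#' @param sig,int numeric vectors of equal dimension.
#' @return non-negative scalar.
#' @examples
#' barycenterDistance(c(0, 0, 0), c(3, 4, 0))   # 5
#' @export
barycenterDistance <- function(sig, int) {
  if (length(sig) != length(int))
    stop("shape error: barycenters of unequal dimension", call. = FALSE)
  sqrt(sum((sig - int)^2))
}

#' Volume asymmetry ratio
#'
#' @param volSig,volInt positive hull volumes.
#' @param symmetrized if `TRUE`, return `max(r, 1/r) >= 1` (the form used for
#'   symmetry classification); otherwise the raw `volSig / volInt`.
#' @return the ratio.
#' @examples
#' volumeAsymmetry(8, 2)                      # 4
#' volumeAsymmetry(2, 8, symmetrized = TRUE)  # 4
#' @export
volumeAsymmetry <- function(volSig, volInt, symmetrized = FALSE) {
  if (any(!is.finite(c(volSig, volInt))) || volSig <= 0 || volInt <= 0) {
    cond <- structure(
      class = c("degenerateGeometryError", "error", "condition"),
      list(message = "degenerate geometry: zero or non-finite hull volume",
           call = sys.call(-1)))
    stop(cond)
  }
  r <- volSig / volInt
  if (symmetrized) max(r, 1 / r) else r
}

#' Anisotropy of a projected vertex cloud
#'
#' Ratio of the largest to the smallest principal semi-axis length of the
#' cloud, i.e. the square root of the extreme eigenvalue ratio of its
#' covariance. A value of 1 indicates an isotropic cloud; large values
#' indicate directional dominance along one latent axis.
#'
#' @param points k x m numeric matrix, k > m, non-degenerate.
#' @return scalar >= 1.
#' @export
cloudAnisotropy <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < ncol(pts) + 1)
    stop("need at least m + 1 points", call. = FALSE)
  ev <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev, 1)) {
    cond <- structure(
      class = c("degenerateGeometryError", "error", "condition"),
      list(message = "degenerate geometry: rank-deficient cloud covariance",
           call = sys.call(-1)))
    stop(cond)
  }
  sqrt(max(ev) / min(ev))
}

# geometry of one circuitry given both latent vectors and a fitted model;
# the workhorse behind buildDualPolytope and runPipeline
.dualGeometry <- function(id, xsig, xint, model, param) {
  k <- param@nComponents
  vs <- generateVertices(xsig, param@alpha, param@epsilon)
  vi <- generateVertices(xint, param@alpha, param@epsilon)
  ps <- projectLatent(model, vs, k)
  pi_ <- projectLatent(model, vi, k)
  bs <- polytopeBarycenter(ps)
  bi <- polytopeBarycenter(pi_)

  hull_side <- function(proj, deltas) {
    if (param@volumeSpace == "latent18") {
      # closed form in the standardized full-dimensional latent space: the
      # orthonormal rotation preserves volume, so only the standardization
      # rescaling of the semi-axes enters
      vol <- crossPolytopeVolume(deltas / model@scales)
      h <- tryCatch(convexHull3d(proj), degenerateGeometryError = function(e) NULL)
      list(vol = vol, area = if (is.null(h)) NA_real_ else h$area,
           facets = if (is.null(h)) matrix(integer(0), 0, 3) else h$facets,
           degenerate = FALSE)
    } else {
      h <- tryCatch(convexHull3d(proj), degenerateGeometryError = function(e) NULL)
      if (is.null(h))
        list(vol = 0, area = 0, facets = matrix(integer(0), 0, 3),
             degenerate = TRUE)
      else
        list(vol = h$volume, area = h$area, facets = h$facets,
             degenerate = FALSE)
    }
  }
  hs <- hull_side(ps, attr(vs, "deltas"))
  hi <- hull_side(pi_, attr(vi, "deltas"))

  aniso <- function(proj) {
    tryCatch(cloudAnisotropy(proj),
             degenerateGeometryError = function(e) NA_real_,
             error = function(e) NA_real_)
  }
  methods::new("DualPolytope",
    id = as.character(id),
    verticesSig = `attributes<-`(vs, list(dim = dim(vs))),
    verticesInt = `attributes<-`(vi, list(dim = dim(vi))),
    projSig = ps, projInt = pi_,
    barycenterSig = as.numeric(bs), barycenterInt = as.numeric(bi),
    dbary = barycenterDistance(bs, bi),
    volSig = hs$vol, volInt = hi$vol,
    areaSig = hs$area, areaInt = hi$area,
    asymRatio = if (hs$vol > 0 && hi$vol > 0) hs$vol / hi$vol else NA_real_,
    anisotropySig = aniso(ps), anisotropyInt = aniso(pi_),
    facetsSig = hs$facets, facetsInt = hi$facets,
    degenerateSig = hs$degenerate, degenerateInt = hi$degenerate)
}

#' Build the dual polytope of one circuitry
#'
#' Composes vertex generation, projection into the fitted embedding, convex
#' hulls and all geometric descriptors for both sides of one circuitry.
#' Degenerate projected hulls (cloud rank < 3) are flagged and their volume
#' recorded as 0 rather than erroring the whole atlas.
#'
#' @param table a [CircuitryTable-class].
#' @param id circuitry identifier.
#' @param model a fitted [EmbeddingModel-class] (from the joint tensor of
#'   `table`).
#' @param param a [SigPolytopeParam-class].
#' @return a [DualPolytope-class].
#' @examples
#' tab <- simulateAtlas(simulationSpec(nCircuitries = 10, seed = 1))$table
#' x <- buildLatentTensor(tab)
#' model <- fitEmbedding(standardizeTensor(x))
#' buildDualPolytope(tab, circuitryIds(tab)[1], model)
#' @export
buildDualPolytope <- function(table, id, model, param = SigPolytopeParam()) {
  xsig <- buildLatentVector(table, id, "sig", param)
  xint <- buildLatentVector(table, id, "int", param)
  .dualGeometry(id, xsig, xint, model, param)
}
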