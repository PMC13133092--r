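#' @include AllClasses.R
NULL

# numeric rank of a centered point cloud, used in degeneracy diagnostics
.cloudRank <- function(pts, tol = 1e-9) {
  ctr <- sweep(as.matrix(pts), 2, colMeans(pts))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  sum(sv > tol * max(sv[1], 1))
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' 3-D convex hull of a point cloud
#'
#' Incremental convex hull in three dimensions. Points are inserted one at a
#' time; facets visible from the new point are removed and the horizon is
#' re-triangulated. Facets are returned with outward orientation (the
#' centroid of the input cloud is interior by convexity), suitable for OFF /
#' PLY export. Volume is accumulated from signed tetrahedra against the
#' interior point and surface area from the facet triangles.
#'
#' @param points numeric k x 3 matrix, k >= 4, not all coplanar.
#' @param tol visibility tolerance, scaled to the cloud extent by default.
#' @return list with `volume`, `area`, `nHullVertices`, `facets` (m x 3
#'   integer matrix of outward-oriented triangles indexing rows of `points`),
#'   and `hullVertexIndices`.
#' @examples
#' oct <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
#' convexHull3d(oct)$volume   # 4/3
#' @export
convexHull3d <- function(points, tol = NULL) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3) stop("shape error: points must be k x 3", call. = FALSE)
  n <- nrow(pts)
  if (n < 4 || .cloudRank(pts) < 3) {
    cond <- structure(
      class = c("degenerateGeometryError", "error", "condition"),
      list(message = sprintf(
             "degenerate geometry: point cloud has rank %d (< 3)",
             if (n == 0) 0L else .cloudRank(pts)),
           call = sys.call(-1), rank = if (n == 0) 0L else .cloudRank(pts)))
    stop(cond)
  }
  extent <- max(apply(pts, 2, function(v) diff(range(v))))
  if (is.null(tol)) tol <- 1e-10 * max(extent, 1)

  # initial tetrahedron from extreme points
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) { i1 <- which.min(pts[, 2]); i2 <- which.max(pts[, 2]) }
  d1 <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * d1[3] - rel[, 3] * d1[2],
              rel[, 3] * d1[1] - rel[, 1] * d1[3],
              rel[, 1] * d1[2] - rel[, 2] * d1[1])
  i3 <- which.max(rowSums(cr^2))
  nrm0 <- cr[i3, ]
  h <- abs(rel %*% nrm0) / sqrt(sum(nrm0^2))
  i4 <- which.max(h)
  interior <- colMeans(pts[c(i1, i2, i3, i4), , drop = FALSE])

  facetNormal <- function(f) {
    a <- pts[f[1], ]
    .cross3(pts[f[2], ] - a, pts[f[3], ] - a)
  }
  orientOut <- function(f) {
    if (sum(facetNormal(f) * (pts[f[1], ] - interior)) < 0) f[c(1, 3, 2)] else f
  }
  faces <- lapply(list(c(i1, i2, i3), c(i1, i2, i4),
                       c(i1, i3, i4), c(i2, i3, i4)), orientOut)
  normals <- lapply(faces, facetNormal)

  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    x <- pts[p, ]
    vis <- vapply(seq_along(faces), function(k) {
      nk <- normals[[k]]
      sum(nk * (x - pts[faces[[k]][1], ])) > tol * sqrt(sum(nk^2))
    }, logical(1))
    if (!any(vis)) next
    visfaces <- faces[vis]
    faces <- faces[!vis]
    normals <- normals[!vis]
    edges <- do.call(rbind, lapply(visfaces, function(f)
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    for (e in seq_len(nrow(horizon))) {
      f <- orientOut(c(horizon[e, 1], horizon[e, 2], p))
      faces[[length(faces) + 1L]] <- f
      normals[[length(normals) + 1L]] <- facetNormal(f)
    }
  }

  fm <- do.call(rbind, faces)
  a <- pts[fm[, 1], , drop = FALSE]
  b <- pts[fm[, 2], , drop = FALSE]
  cc <- pts[fm[, 3], , drop = FALSE]
  ao <- sweep(a, 2, interior); bo <- sweep(b, 2, interior)
  co <- sweep(cc, 2, interior)
  crx <- cbind(bo[, 2] * co[, 3] - bo[, 3] * co[, 2],
               bo[, 3] * co[, 1] - bo[, 1] * co[, 3],
               bo[, 1] * co[, 2] - bo[, 2] * co[, 1])
  vol <- sum(rowSums(ao * crx)) / 6
  ab <- b - a; ac <- cc - a
  crt <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
               ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
               ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  area <- sum(sqrt(rowSums(crt^2))) / 2
  verts <- sort(unique(as.vector(fm)))
  list(volume = vol, area = area,
       nHullVertices = length(verts),
       facets = fm, hullVertexIndices = verts)
}
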