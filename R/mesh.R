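#' @include AllClasses.R
NULL

.writeOFF <- function(pts, facets, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(pts), nrow(facets)), con)
  writeLines(sprintf("%.17g %.17g %.17g", pts[, 1], pts[, 2], pts[, 3]), con)
  writeLines(sprintf("3 %d %d %d", facets[, 1] - 1L, facets[, 2] - 1L,
                     facets[, 3] - 1L), con)
}

.writePLY <- function(pts, facets, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(pts)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(facets)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", pts[, 1], pts[, 2], pts[, 3]), con)
  writeLines(sprintf("3 %d %d %d", facets[, 1] - 1L, facets[, 2] - 1L,
                     facets[, 3] - 1L), con)
}

#' Export the dual hulls of a circuitry as meshes
#'
#' Writes the two convex hulls (sig and int) of a [DualPolytope-class] as
#' OFF or PLY meshes named `<basename>_sig.<ext>` and `<basename>_int.<ext>`.
#' Only the hull vertices are emitted; facet indices are remapped
#' accordingly and retain their outward orientation.
#'
#' @param polytope a [DualPolytope-class] with non-degenerate hulls.
#' @param path base output path; the side suffix and extension are appended.
#' @param format `"OFF"` or `"PLY"`.
#' @return invisibly, the two file paths written.
#' @export
exportHullMesh <- function(polytope, path, format = c("OFF", "PLY")) {
  format <- match.arg(format)
  stopifnot(methods::is(polytope, "DualPolytope"))
  if (polytope@degenerateSig || polytope@degenerateInt ||
      nrow(polytope@facetsSig) == 0 || nrow(polytope@facetsInt) == 0) {
    cond <- structure(
      class = c("degenerateGeometryError", "error", "condition"),
      list(message = "degenerate geometry: cannot export coplanar hull",
           call = sys.call()))
    stop(cond)
  }
  ext <- tolower(format)
  base <- sub("\\.(off|ply)$", "", path, ignore.case = TRUE)
  paths <- c(sig = paste0(base, "_sig.", ext),
             int = paste0(base, "_int.", ext))
  writer <- if (format == "OFF") .writeOFF else .writePLY
  for (side in c("sig", "int")) {
    proj <- methods::slot(polytope, paste0("proj",
                                           if (side == "sig") "Sig" else "Int"))
    facets <- methods::slot(polytope, paste0("facets",
                                             if (side == "sig") "Sig" else "Int"))
    verts <- sort(unique(as.vector(facets)))
    remap <- match(facets, verts)
    dim(remap) <- dim(facets)
    writer(proj[verts, , drop = FALSE], remap, paths[[side]])
  }
  invisible(paths)
}
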