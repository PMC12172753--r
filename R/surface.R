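#' Triangulated cortical surface
#'
#' Container for a triangulated surface mesh in RAS millimetre coordinates,
#' optionally carrying per-vertex signed curvature, atlas labels, and a
#' unit-sphere registration (per-vertex coordinates on the unit sphere, the
#' usual output of cortical inflation, enabling cross-subject vertex
#' correspondence through great-circle distances).
#'
#' Faces are stored 1-based (R convention); file readers and writers convert
#' from/to the 0-based on-disk convention.
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (mm, RAS).
#' @param faces integer M x 3 matrix of 1-based vertex indices.
#' @param curvature optional numeric vector of length N (signed,
#'   dimensionless; negative in gyri, positive in sulci under the FreeSurfer
#'   sign convention).
#' @param atlas_labels optional character vector of length N of anatomical
#'   parcellation labels (e.g. `"precentral L"`).
#' @param sphere optional numeric N x 3 matrix of unit-sphere registration
#'   coordinates; rows must have unit norm within 1e-6.
#' @return An object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, faces, curvature = NULL, atlas_labels = NULL,
                        sphere = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an M x 3 matrix")
  n <- nrow(vertices)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > n))
    stop("face indices out of range [1, ", n, "]")
  if (!is.null(curvature)) {
    curvature <- as.numeric(curvature)
    if (length(curvature) != n) stop("curvature must have one value per vertex")
  }
  if (!is.null(atlas_labels)) {
    atlas_labels <- as.character(atlas_labels)
    if (length(atlas_labels) != n)
      stop("atlas_labels must have one value per vertex")
  }
  if (!is.null(sphere)) {
    sphere <- as.matrix(sphere)
    storage.mode(sphere) <- "double"
    if (!all(dim(sphere) == c(n, 3L)))
      stop("sphere registration must be an N x 3 matrix")
    nrm <- sqrt(rowSums(sphere^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("sphere registration rows must have unit norm (tolerance 1e-6)")
  }
  ar <- triangle_areas(vertices, faces)
  if (any(ar <= 0))
    stop("mesh contains ", sum(ar <= 0), " degenerate (zero-area) triangle(s)")
  structure(
    list(vertices = vertices, faces = faces, curvature = curvature,
         atlas_labels = atlas_labels, sphere = sphere),
    class = "tri_surface"
  )
}

#' @export
print.tri_surface <- function(x, ...) {
  cat("tri_surface:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "triangles\n")
  cat("  curvature:", if (is.null(x$curvature)) "absent" else "present",
      " atlas labels:", if (is.null(x$atlas_labels)) "absent" else
        paste0(length(unique(x$atlas_labels)), " unique"),
      " sphere registration:", if (is.null(x$sphere)) "absent" else "present",
      "\n")
  invisible(x)
}

#' Geometric triangle areas
#'
#' Cross-product area of each triangle of a mesh, `0.5 * ||(v2-v1) x (v3-v1)||`.
#'
#' @param vertices N x 3 vertex matrix (or a `tri_surface`, in which case
#'   `faces` is ignored).
#' @param faces M x 3 1-based face index matrix.
#' @return Numeric vector of M triangle areas (mm^2).
#' @export
triangle_areas <- function(vertices, faces = NULL) {
  if (inherits(vertices, "tri_surface")) {
    faces <- vertices$faces
    vertices <- vertices$vertices
  }
  if (nrow(faces) == 0L) return(numeric(0))
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total geometric surface area
#'
#' @param surface a `tri_surface`.
#' @return Total cross-product triangle area (mm^2).
#' @export
surface_area <- function(surface) sum(triangle_areas(surface))

#' Undirected edge list of a mesh
#'
#' Unique undirected edges with their Euclidean lengths; the mesh graph used
#' for shortest-edge-path (Dijkstra) geodesic distances.
#'
#' @param surface a `tri_surface`.
#' @return data.frame with columns `from`, `to` (1-based vertex indices,
#'   `from < to`) and `length_mm`.
#' @export
mesh_edges <- function(surface) {
  f <- surface$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  d <- surface$vertices[e[, 1], , drop = FALSE] -
    surface$vertices[e[, 2], , drop = FALSE]
  data.frame(from = e[, 1], to = e[, 2], length_mm = sqrt(rowSums(d^2)))
}

# igraph over the mesh edges, weighted by Euclidean edge length
mesh_graph <- function(surface) {
  e <- mesh_edges(surface)
  igraph::graph_from_data_frame(
    e, directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(surface$vertices)))
  )
}

#' Geodesic (shortest edge-path) distances from source vertices
#'
#' Dijkstra shortest-path distances along mesh edges with Euclidean edge
#' weights; an approximation to exact polyhedral geodesics that is accurate at
#' the mesh resolutions used here.
#'
#' @param surface a `tri_surface`.
#' @param from integer vector of source vertex indices (1-based).
#' @return numeric matrix `length(from)` x N of distances (mm).
#' @export
geodesic_distances <- function(surface, from) {
  g <- mesh_graph(surface)
  d <- igraph::distances(g, v = as.character(from), weights = igraph::E(g)$length_mm)
  colnames(d) <- NULL
  rownames(d) <- NULL
  d
}

edge_manifold_ok <- function(surface) {
  f <- surface$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) <= 2L)
}
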