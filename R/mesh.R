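#' Triangulated surface mesh with optional per-vertex color
#'
#' The central data carrier of the package: a triangulated surface in
#' millimetres with optional per-vertex RGB colors in `[0, 1]`. Scans, the
#' registration atlas and synthetic fixtures are all `triangle_mesh` objects.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param colors optional numeric n x 3 matrix of per-vertex RGB in `[0, 1]`.
#'   Required by the landmarking pipeline, which reads appearance.
#'
#' @return An object of class `triangle_mesh`: a list with elements
#'   `vertices`, `triangles` and (possibly `NULL`) `colors`.
#' @export
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    rbind(c(1L, 2L, 3L)))
#' mesh_centroid(m)
triangle_mesh <- function(vertices, triangles, colors = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(triangles) > 0L && ncol(triangles) != 3L)
    stop("triangles must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(triangles) > 0L) {
    if (min(triangles) < 1L || max(triangles) > nrow(vertices))
      stop("triangle indices out of range [1, n_vertices]")
    degen <- triangles[, 1] == triangles[, 2] |
      triangles[, 2] == triangles[, 3] | triangles[, 1] == triangles[, 3]
    if (any(degen))
      stop("triangle(s) with a repeated vertex index: ",
           paste(utils::head(which(degen), 5), collapse = ", "))
  }
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    storage.mode(colors) <- "double"
    if (nrow(colors) != nrow(vertices) || ncol(colors) != 3L)
      stop("colors must be one RGB triple per vertex")
    if (!all(is.finite(colors)) || min(colors) < 0 || max(colors) > 1)
      stop("color channels must lie in [0, 1]")
  }
  structure(list(vertices = vertices, triangles = triangles, colors = colors),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d triangles, colors: %s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is.null(x$colors)) "none" else "per-vertex RGB"))
  invisible(x)
}

#' Number of vertices / triangles of a mesh
#' @param mesh a [triangle_mesh()].
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_triangles <- function(mesh) nrow(mesh$triangles)

#' Mesh centroid
#'
#' The unweighted mean of the vertex positions. This is the focal point of
#' every camera in the initial five-camera array.
#'
#' @param mesh a [triangle_mesh()] with at least one vertex.
#' @return numeric length-3 point (mm).
#' @export
mesh_centroid <- function(mesh) {
  if (n_vertices(mesh) < 1L) stop("mesh has no vertices")
  colMeans(mesh$vertices)
}

#' Per-vertex unit normals
#'
#' Area-weighted average of incident triangle normals. With counter-clockwise
#' winding (as produced by the fixture generator) normals point outward.
#'
#' @param mesh a [triangle_mesh()].
#' @return numeric n x 3 matrix of unit vectors (zero rows for isolated
#'   vertices).
#' @export
vertex_normals <- function(mesh) {
  cpp_vertex_normals(mesh$vertices, mesh$triangles)
}

# Undirected unique edge list, m x 2, each row i < j.
mesh_edges <- function(mesh) {
  f <- mesh$triangles
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Logical flag per vertex: lies on a boundary edge (edge used by exactly one
# triangle). Used for NICP correspondence rejection.
border_vertices <- function(mesh) {
  f <- mesh$triangles
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  border_keys <- names(cnt)[cnt == 1L]
  flag <- logical(n_vertices(mesh))
  if (length(border_keys)) {
    idx <- unique(as.integer(unlist(strsplit(border_keys, " "))))
    flag[idx] <- TRUE
  }
  flag
}

#' Apply a rigid (or any linear) transform to a point matrix
#'
#' Row-wise application of `p' = R p + t`.
#'
#' @param points n x 3 matrix.
#' @param rotation 3 x 3 matrix.
#' @param translation length-3 vector.
#' @return transformed n x 3 matrix.
#' @export
transform_points <- function(points, rotation, translation) {
  sweep(points %*% t(rotation), 2, translation, "+")
}
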