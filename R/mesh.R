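#' Triangulated cortical surface mesh
#'
#' A `surface_mesh` holds vertex coordinates in world millimetres and a
#' triangulation, and is the geometric substrate for the searchlight,
#' smoothing and cluster-enhancement stages. On construction the one-ring
#' adjacency is derived from the triangles and validated: every triangle
#' index must reference an existing vertex, every vertex must belong to at
#' least one triangle, and the adjacency is symmetric by construction.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param triangles integer matrix, one row per triangle, 1-based vertex
#'   indices.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `triangles`, `adjacency` (list of sorted neighbour indices, self
#'   excluded) and `vertex_count`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) abort("`vertices` must have 3 columns (x, y, z in mm).")
  if (ncol(triangles) != 3L) abort("`triangles` must have 3 columns of vertex indices.")
  n <- nrow(vertices)
  if (n < 4L) abort(sprintf("mesh has %d vertices; at least 4 are required.", n))
  if (!all(is.finite(vertices))) abort("vertex coordinates must be finite.")
  if (nrow(triangles) < 1L) abort("mesh has no triangles.")
  bad <- which(triangles < 1L | triangles > n)
  if (length(bad)) {
    abort(sprintf(
      "triangle index out of range: value %d at triangle row %d (vertex_count = %d).",
      triangles[bad[1L]], ((bad[1L] - 1L) %% nrow(triangles)) + 1L, n
    ))
  }
  degen <- triangles[, 1L] == triangles[, 2L] | triangles[, 2L] == triangles[, 3L] |
    triangles[, 1L] == triangles[, 3L]
  if (any(degen)) {
    abort(sprintf("degenerate triangle (repeated vertex index) at row %d.", which(degen)[1L]))
  }
  used <- tabulate(triangles, nbins = n)
  if (any(used == 0L)) {
    abort(sprintf("orphan vertex not referenced by any triangle: vertex %d.", which(used == 0L)[1L]))
  }
  adjacency <- .build_adjacency(triangles, n)
  structure(
    list(
      vertices = vertices,
      triangles = triangles,
      adjacency = adjacency,
      vertex_count = n
    ),
    class = "surface_mesh"
  )
}

.build_adjacency <- function(triangles, n) {
  e <- rbind(
    triangles[, c(1L, 2L), drop = FALSE],
    triangles[, c(2L, 3L), drop = FALSE],
    triangles[, c(1L, 3L), drop = FALSE]
  )
  e <- rbind(e, e[, 2:1, drop = FALSE])
  e <- unique(e)
  adj <- split(e[, 2L], factor(e[, 1L], levels = seq_len(n)))
  lapply(adj, function(v) sort(as.integer(v)))
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "<surface_mesh> %d vertices, %d triangles\n", x$vertex_count, nrow(x$triangles)
  ))
  invisible(x)
}

#' @rdname surface_mesh
#' @param x object to test.
#' @export
is_surface_mesh <- function(x) inherits(x, "surface_mesh")

#' One-ring neighbourhood of a vertex
#'
#' Returns the vertex itself plus all vertices sharing a triangle edge with
#' it. This set seeds the hybrid surface-to-volume searchlight.
#'
#' @param mesh a [surface_mesh()].
#' @param vertex 1-based vertex index.
#' @return Sorted integer vector of vertex indices, including `vertex`.
#' @export
one_ring <- function(mesh, vertex) {
  stopifnot(is_surface_mesh(mesh))
  vertex <- as.integer(vertex)
  if (length(vertex) != 1L || is.na(vertex) || vertex < 1L || vertex > mesh$vertex_count) {
    abort(sprintf("vertex index %s out of range [1, %d].", vertex, mesh$vertex_count))
  }
  sort(c(vertex, mesh$adjacency[[vertex]]))
}

#' Per-vertex surface area
#'
#' Each vertex is assigned one third of the area of every triangle incident
#' to it (barycentric area weighting), the extent measure used by the
#' surface TFCE integration.
#'
#' @param mesh a [surface_mesh()].
#' @return Numeric vector of vertex areas in mm^2.
#' @export
mesh_vertex_areas <- function(mesh) {
  stopifnot(is_surface_mesh(mesh))
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 2L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  b <- v[tr[, 3L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  tri_area <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  out <- numeric(mesh$vertex_count)
  for (k in 1:3) {
    s <- tapply(tri_area, tr[, k], sum)
    idx <- as.integer(names(s))
    out[idx] <- out[idx] + as.numeric(s)
  }
  out / 3
}

# Edge graph of the mesh in 0-based CSR form with Euclidean edge lengths,
# the input format of the compiled Dijkstra/TFCE kernels.
.mesh_csr <- function(mesh) {
  adj <- mesh$adjacency
  deg <- lengths(adj)
  ptr <- c(0L, cumsum(deg))
  idx <- unlist(adj, use.names = FALSE)
  src <- rep.int(seq_along(adj), deg)
  d <- sqrt(rowSums((mesh$vertices[src, , drop = FALSE] -
    mesh$vertices[idx, , drop = FALSE])^2))
  list(ptr = as.integer(ptr), idx = as.integer(idx - 1L), w = d)
}

#' Regular planar lattice mesh
#'
#' Builds a flat, regularly triangulated `nx` by `ny` grid with the given
#' spacing (mm) in the z = 0 plane. Used as a calibration surface for the
#' smoothing kernel, where geodesic distances along a lattice axis equal
#' Euclidean distances.
#'
#' @param nx,ny number of vertices along each axis.
#' @param spacing lattice spacing in mm.
#' @return A [surface_mesh()] with `nx * ny` vertices.
#' @export
make_lattice_mesh <- function(nx, ny, spacing = 1) {
  stopifnot(nx >= 2, ny >= 2, spacing > 0)
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  vertices <- cbind((g$i - 1) * spacing, (g$j - 1) * spacing, 0)
  vid <- function(i, j) (j - 1L) * nx + i
  tris <- vector("list", (nx - 1L) * (ny - 1L))
  k <- 0L
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      k <- k + 1L
      tris[[k]] <- rbind(
        c(vid(i, j), vid(i + 1L, j), vid(i, j + 1L)),
        c(vid(i + 1L, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
      )
    }
  }
  surface_mesh(vertices, do.call(rbind, tris))
}
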