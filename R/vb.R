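#' The 27-voxel cube around a centre voxel
#'
#' All candidate voxel positions of the hybrid searchlight: the 3x3x3 index
#' cube centred on the matched centre voxel (index-space offsets of at most
#' one along every axis).
#'
#' @param centre_voxel 0-based voxel index triple.
#' @return A 27 x 3 integer matrix of 0-based voxel indices.
#' @export
voxel_cube27 <- function(centre_voxel) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  out <- sweep(off, 2L, as.integer(centre_voxel), "+")
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Hybrid surface-to-volume searchlight neighbourhood
#'
#' Maps a vertex and its one-ring to their nearest voxels, then keeps only
#' masked voxels inside the 27-voxel cube centred on the vertex's own
#' matched voxel, deduplicated. The neighbourhood is unusable when the
#' centre voxel itself is outside the mask (or the grid).
#'
#' @param mesh a [surface_mesh()] sharing the world frame with `volume`.
#' @param vertex 1-based vertex index.
#' @param volume a [feature_volume()].
#' @return A list of class `vertex_neighbourhood`: `centre_vertex`,
#'   `centre_voxel` (0-based triple), `voxel_list` (m x 3, 0-based),
#'   `feature_vectors` (m x C) and `usable`.
#' @export
hybrid_neighbourhood <- function(mesh, vertex, volume) {
  stopifnot(is_surface_mesh(mesh), inherits(volume, "feature_volume"))
  ring <- one_ring(mesh, vertex)
  vox <- world_to_voxel(volume$affine, mesh$vertices[ring, , drop = FALSE])
  centre_voxel <- world_to_voxel(volume$affine, mesh$vertices[vertex, ])
  dims <- dim(volume$data)[1:3]
  in_grid <- function(m) {
    m[, 1L] >= 0L & m[, 1L] < dims[1L] &
      m[, 2L] >= 0L & m[, 2L] < dims[2L] &
      m[, 3L] >= 0L & m[, 3L] < dims[3L]
  }
  centre_ok <- in_grid(matrix(centre_voxel, nrow = 1L)) &&
    volume$mask[centre_voxel[1L] + 1L, centre_voxel[2L] + 1L, centre_voxel[3L] + 1L]
  if (!centre_ok) {
    return(structure(
      list(centre_vertex = vertex, centre_voxel = centre_voxel,
           voxel_list = matrix(integer(0), 0L, 3L), feature_vectors = NULL,
           usable = FALSE),
      class = "vertex_neighbourhood"
    ))
  }
  in_cube <- abs(vox[, 1L] - centre_voxel[1L]) <= 1L &
    abs(vox[, 2L] - centre_voxel[2L]) <= 1L &
    abs(vox[, 3L] - centre_voxel[3L]) <= 1L
  vox <- vox[in_cube & in_grid(vox), , drop = FALSE]
  masked <- volume$mask[vox + 1L]
  vox <- unique(vox[masked, , drop = FALSE])
  C <- dim(volume$data)[4L]
  plane <- prod(dims)
  lin <- vox[, 1L] + 1L + vox[, 2L] * dims[1L] + vox[, 3L] * dims[1L] * dims[2L]
  feats <- matrix(0, nrow(vox), C)
  for (k in seq_len(C)) feats[, k] <- volume$data[lin + (k - 1L) * plane]
  structure(
    list(centre_vertex = vertex, centre_voxel = centre_voxel,
         voxel_list = vox, feature_vectors = feats, usable = TRUE),
    class = "vertex_neighbourhood"
  )
}

#' Affinity between two feature vectors
#'
#' Pearson correlation across the feature dimension, with negative values
#' clipped to zero (only positive correlations are retained) and
#' zero-variance vectors assigned affinity 0.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Scalar weight in [0, 1].
#' @export
affinity <- function(x, y) {
  if (length(x) != length(y)) {
    abort(sprintf("feature vectors differ in length (%d vs %d).", length(x), length(y)))
  }
  if (length(x) < 2L) abort("feature vectors must have length >= 2.")
  if (sd(x) == 0 || sd(y) == 0) return(0)
  max(0, cor(x, y))
}

#' Affinity graph over a searchlight neighbourhood
#'
#' All-pairs affinities over the neighbourhood's voxel feature vectors:
#' a symmetric, non-negative weight matrix with zero diagonal. Graphs with
#' fewer than 3 nodes are flagged unusable (the VB index is undefined).
#'
#' @param neigh a [hybrid_neighbourhood()] result.
#' @return A list of class `affinity_graph` with `weights` (n x n) and
#'   `usable`.
#' @export
build_affinity_graph <- function(neigh) {
  stopifnot(inherits(neigh, "vertex_neighbourhood"))
  if (!isTRUE(neigh$usable) || is.null(neigh$feature_vectors) ||
    nrow(neigh$feature_vectors) < 3L) {
    return(structure(list(weights = NULL, usable = FALSE), class = "affinity_graph"))
  }
  w <- suppressWarnings(cor(t(neigh$feature_vectors)))
  w[!is.finite(w)] <- 0 # zero-variance vectors get affinity 0
  w[w < 0] <- 0
  diag(w) <- 0
  w <- (w + t(w)) / 2
  dimnames(w) <- NULL
  structure(list(weights = w, usable = TRUE), class = "affinity_graph")
}

#' Algebraic connectivity of a weighted graph
#'
#' Second-smallest eigenvalue of the unnormalised graph Laplacian
#' `L = D - W` (D the diagonal weighted-degree matrix). Zero iff the graph
#' is disconnected; equal to n for the complete unit-weight graph. Tiny
#' negative eigenvalues above `-1e-10` (numerical noise) are clipped to 0.
#'
#' @param graph an [build_affinity_graph()] result, or a symmetric
#'   non-negative weight matrix with zero diagonal.
#' @return Scalar `lambda_2 >= 0`.
#' @export
algebraic_connectivity <- function(graph) {
  w <- if (inherits(graph, "affinity_graph")) graph$weights else as.matrix(graph)
  if (is.null(w) || nrow(w) < 2L) abort("graph must have at least 2 nodes.")
  if (max(abs(w - t(w))) > 1e-10) abort("weight matrix is not symmetric.")
  lap <- diag(rowSums(w)) - w
  ev <- eigen(lap, symmetric = TRUE, only.values = TRUE)$values # descending
  l2 <- ev[length(ev) - 1L]
  if (l2 < -1e-10) abort(sprintf("Laplacian eigenvalue %g < 0: invalid weights.", l2))
  max(l2, 0)
}

#' VB index of an affinity graph
#'
#' The scaled algebraic connectivity `lambda_2 / n`, clipped to [0, 1]. The
#' scaling is chosen so the maximal-homogeneity graph — complete with unit
#' weights — scores exactly 1, and a disconnected neighbourhood (a sharp
#' feature boundary) scores 0.
#'
#' @param graph an [build_affinity_graph()] result.
#' @return Scalar in [0, 1], or `NA` for an unusable graph.
#' @export
vb_at_vertex <- function(graph) {
  stopifnot(inherits(graph, "affinity_graph"))
  if (!isTRUE(graph$usable)) return(NA_real_)
  n <- nrow(graph$weights)
  min(max(algebraic_connectivity(graph) / n, 0), 1)
}

#' Per-vertex VB map of a subject
#'
#' Runs the hybrid searchlight at every mesh vertex: one-ring to nearest
#' voxels, 27-voxel cube filter, affinity graph, scaled algebraic
#' connectivity. Unusable neighbourhoods (centre voxel unmasked, or fewer
#' than `min_neigh` voxels) yield missing values rather than aborting the
#' map. Fully deterministic.
#'
#' @param subject a `subject_record` (e.g. from [synth_subject()]) whose
#'   `features` are already z-scored, or pass `mesh` and `features`
#'   explicitly.
#' @param mesh a [surface_mesh()] (defaults to `subject$mesh`).
#' @param features a [feature_volume()] (defaults to `subject$features`).
#' @param min_neigh minimum usable neighbourhood size (voxels).
#' @return A tibble of class `vb_map` with columns `vertex`, `vb` and
#'   `n_voxels`, and attributes `subject_id` and `min_neigh`.
#' @export
vb_map <- function(subject = NULL, mesh = subject$mesh,
                   features = subject$features, min_neigh = 3L) {
  stopifnot(is_surface_mesh(mesh), inherits(features, "feature_volume"))
  if (min_neigh < 3L) abort("`min_neigh` must be >= 3 (VB is undefined below 3 nodes).")
  n <- mesh$vertex_count
  vb <- rep(NA_real_, n)
  sizes <- integer(n)
  for (vtx in seq_len(n)) {
    neigh <- hybrid_neighbourhood(mesh, vtx, features)
    sizes[vtx] <- nrow(neigh$voxel_list)
    if (!neigh$usable || sizes[vtx] < min_neigh) next
    vb[vtx] <- vb_at_vertex(build_affinity_graph(neigh))
  }
  out <- tibble::tibble(vertex = seq_len(n), vb = vb, n_voxels = sizes)
  class(out) <- c("vb_map", class(out))
  attr(out, "subject_id") <- if (!is.null(subject)) subject$subject_id else NA_character_
  attr(out, "min_neigh") <- as.integer(min_neigh)
  out
}

#' Z-score a subject's feature volume in place
#'
#' Convenience wrapper applying [zscore_channel()] to every channel of a
#' subject's raw feature volume over its mask, as required before [vb_map()].
#'
#' @param subject a `subject_record`.
#' @return The subject with standardised `features`.
#' @export
zscore_subject <- function(subject) {
  vol <- subject$features
  for (k in seq_along(vol$channels)) {
    vol$data[, , , k] <- zscore_channel(vol$data[, , , k], vol$mask)
  }
  subject$features <- feature_volume(vol$data, vol$affine, vol$mask, vol$channels)
  subject
}
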