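#' Simulation parameters for synthetic cohorts
#'
#' Bundles the generative settings for synthetic spherical-cortex cohorts:
#' an icosphere stands in for a hemisphere, geodesic-Voronoi patches stand
#' in for cortical areas with sharp between-area feature transitions, and a
#' group factor reduces the local feature noise SD (i.e. increases local
#' homogeneity) in designated patches of the preterm group.
#'
#' @param mesh_subdivisions icosphere subdivision level (vertex count
#'   `10 * 4^s + 2`).
#' @param sphere_radius sphere radius in mm.
#' @param voxel_size isotropic voxel size in mm.
#' @param patch_count number of geodesic-Voronoi patches (at most
#'   `channel_count`, so per-patch mean vectors can be mutually equidistant).
#' @param channel_count number of feature channels (six microstructural
#'   metrics).
#' @param patch_mean_separation Euclidean distance between per-patch mean
#'   feature vectors (feature units).
#' @param within_patch_sd voxel noise SD around the patch mean; `0` is the
#'   exactly noise-free limit.
#' @param homogeneity_boost multiplicative noise-SD factor (in (0, 1])
#'   applied to the preterm group inside `effect_patches`; 1 = null cohort.
#' @param effect_patches integer patch ids (1-based) carrying the group
#'   effect.
#' @param n_per_group subjects per group.
#' @param pma_range postmenstrual-age-at-scan range in weeks (uniform draw).
#' @param pma_slope per-channel linear PMA effect (feature units per week).
#' @param rng_seed integer seed; all child seeds derive from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(mesh_subdivisions = 3,
                       sphere_radius = 20,
                       voxel_size = 2,
                       patch_count = 6,
                       channel_count = 6,
                       patch_mean_separation = 3,
                       within_patch_sd = 1,
                       homogeneity_boost = 0.5,
                       effect_patches = c(1L, 2L),
                       n_per_group = 15,
                       pma_range = c(37, 43),
                       pma_slope = rep(0.05, 6),
                       rng_seed = 1L) {
  stopifnot(mesh_subdivisions >= 0, sphere_radius > 0, voxel_size > 0)
  if (within_patch_sd < 0) abort("`within_patch_sd` must be >= 0.")
  if (!(homogeneity_boost > 0 && homogeneity_boost <= 1)) {
    abort("`homogeneity_boost` must be in (0, 1].")
  }
  if (patch_count < 1) abort("`patch_count` must be >= 1.")
  if (patch_count > channel_count) {
    abort(sprintf(
      "patch_count (%d) exceeds channel_count (%d): mutually equidistant patch means need patch_count <= channel_count.",
      patch_count, channel_count
    ))
  }
  effect_patches <- as.integer(effect_patches)
  if (length(effect_patches) && any(effect_patches < 1L | effect_patches > patch_count)) {
    abort("`effect_patches` must be patch ids in [1, patch_count].")
  }
  if (length(pma_slope) == 1L) pma_slope <- rep(pma_slope, channel_count)
  if (length(pma_slope) != channel_count) {
    abort("`pma_slope` must have one entry per channel.")
  }
  structure(
    list(
      mesh_subdivisions = as.integer(mesh_subdivisions),
      sphere_radius = sphere_radius, voxel_size = voxel_size,
      patch_count = as.integer(patch_count), channel_count = as.integer(channel_count),
      patch_mean_separation = patch_mean_separation,
      within_patch_sd = within_patch_sd, homogeneity_boost = homogeneity_boost,
      effect_patches = effect_patches, n_per_group = as.integer(n_per_group),
      pma_range = pma_range, pma_slope = pma_slope, rng_seed = as.integer(rng_seed)
    ),
    class = "sim_params"
  )
}

#' Icosphere mesh
#'
#' Repeated 4-way triangle subdivision of a regular icosahedron with
#' vertices projected back to the sphere; vertex count is
#' `10 * 4^subdivisions + 2`.
#'
#' @param subdivisions non-negative subdivision count.
#' @param radius sphere radius in mm.
#' @return A [surface_mesh()].
#' @export
make_sphere_mesh <- function(subdivisions = 0, radius = 1) {
  stopifnot(subdivisions >= 0, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    midpoint <- new.env(hash = TRUE, parent = emptyenv())
    verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
    get_mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- midpoint[[key]]
      if (is.null(idx)) {
        verts[[length(verts) + 1L]] <<- (verts[[a]] + verts[[b]]) / 2
        idx <- length(verts)
        midpoint[[key]] <- idx
      }
      idx
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t_i in seq_len(nrow(f))) {
      a <- f[t_i, 1L]; b <- f[t_i, 2L]; c_ <- f[t_i, 3L]
      ab <- get_mid(a, b); bc <- get_mid(b, c_); ca <- get_mid(c_, a)
      newf[(t_i - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca)
      )
    }
    v <- do.call(rbind, verts)
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  surface_mesh(v, f)
}

#' Geodesic-Voronoi patch labelling of a mesh
#'
#' Seed vertices are chosen by farthest-point sampling under graph-geodesic
#' distance (edge weights = Euclidean edge lengths; the first seed is drawn
#' from `rng_seed`), then every vertex is labelled by nearest seed through a
#' multi-source Dijkstra flood, which guarantees each patch is connected.
#' Distance ties resolve to the lowest patch id.
#'
#' @param mesh a [surface_mesh()].
#' @param patch_count number of patches, in `[1, vertex_count]`.
#' @param rng_seed integer seed for the first farthest-point sample.
#' @return A list of class `patch_labeling` with `labels` (integer per
#'   vertex, 1-based), `patch_count` and `seed_vertices`.
#' @export
make_patch_labels <- function(mesh, patch_count, rng_seed = 1L) {
  stopifnot(is_surface_mesh(mesh))
  n <- mesh$vertex_count
  if (patch_count < 1L) abort("`patch_count` must be >= 1.")
  if (patch_count > n) {
    abort(sprintf("patch_count (%d) exceeds vertex_count (%d).", patch_count, n))
  }
  csr <- .mesh_csr(mesh)
  dist_from <- function(s) {
    res <- .cpp_geodesic_within(csr$ptr, csr$idx, csr$w, as.integer(s - 1L), Inf)
    d <- rep(Inf, n)
    d[res$dst + 1L] <- res$dist
    d
  }
  seeds <- integer(patch_count)
  seeds[1L] <- withr::with_seed(rng_seed, sample.int(n, 1L))
  dmin <- dist_from(seeds[1L])
  if (patch_count > 1L) {
    for (k in 2:patch_count) {
      seeds[k] <- which.max(dmin)
      dmin <- pmin(dmin, dist_from(seeds[k]))
    }
  }
  labels <- .voronoi_flood(mesh, seeds)
  structure(
    list(labels = labels, patch_count = as.integer(patch_count), seed_vertices = seeds),
    class = "patch_labeling"
  )
}

# Multi-source Dijkstra flood: each vertex inherits the label of the
# neighbour that finalised it, so every Voronoi cell is connected. Ties on
# distance keep the lower patch id.
.voronoi_flood <- function(mesh, seeds) {
  n <- mesh$vertex_count
  dist <- rep(Inf, n)
  labels <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[seeds] <- 0
  labels[seeds] <- seq_along(seeds)
  v <- mesh$vertices
  for (iter in seq_len(n)) {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    for (w in mesh$adjacency[[u]]) {
      if (done[w]) next
      nd <- dist[u] + sqrt(sum((v[u, ] - v[w, ])^2))
      if (nd < dist[w] - 1e-12 ||
        (abs(nd - dist[w]) <= 1e-12 && labels[u] < labels[w])) {
        dist[w] <- nd
        labels[w] <- labels[u]
      }
    }
  }
  labels
}

#' Vertices on a patch boundary
#'
#' A boundary vertex has at least one one-ring neighbour with a different
#' patch id; all other vertices are patch-interior.
#'
#' @param mesh a [surface_mesh()].
#' @param labeling a [make_patch_labels()] result (or an integer vector).
#' @return Logical vector, `TRUE` at boundary vertices.
#' @export
patch_boundary_vertices <- function(mesh, labeling) {
  labels <- if (inherits(labeling, "patch_labeling")) labeling$labels else as.integer(labeling)
  vapply(seq_len(mesh$vertex_count), function(vtx) {
    any(labels[mesh$adjacency[[vtx]]] != labels[vtx])
  }, logical(1))
}

# Per-patch mean feature vectors at exact mutual Euclidean distance `sep`:
# scaled standard-basis vectors (distance between any two is sep), rotated by
# a fixed orthogonal matrix so that every channel varies across patches (a
# constant channel would make z-scoring degenerate in the noise-free limit).
.patch_means <- function(patch_count, channel_count, sep) {
  mu <- matrix(0, patch_count, channel_count)
  for (k in seq_len(patch_count)) mu[k, k] <- sep / sqrt(2)
  q <- withr::with_seed(20240601L, qr.Q(qr(matrix(rnorm(channel_count^2), channel_count))))
  mu %*% t(q)
}

# Voxel grid enclosing the mesh plus nearest-vertex matching; independent of
# subject-level randomness, so cohorts compute it once and reuse it.
.voxel_scaffold <- function(mesh, params) {
  vox <- params$voxel_size
  lo <- apply(mesh$vertices, 2L, min)
  hi <- apply(mesh$vertices, 2L, max)
  margin <- 2L
  dims <- as.integer(floor((hi - lo) / vox)) + 2L * margin + 1L
  if (any(dims > 512L) || any(dims < 1L)) {
    abort(sprintf(
      "mesh extends outside the constructible grid (%s voxels at %g mm).",
      paste(dims, collapse = "x"), vox
    ))
  }
  affine <- diag(c(vox, vox, vox, 1))
  affine[1:3, 4L] <- lo - margin * vox
  centres <- as.matrix(expand.grid(
    x = seq_len(dims[1L]) - 1L, y = seq_len(dims[2L]) - 1L, z = seq_len(dims[3L]) - 1L
  ))
  world <- voxel_to_world(affine, centres)
  # nearest mesh vertex per voxel centre, chunked to bound memory
  nearest <- integer(nrow(world))
  ndist <- numeric(nrow(world))
  vtx <- mesh$vertices
  vtx_sq <- rowSums(vtx^2)
  chunk <- 4096L
  for (start in seq(1L, nrow(world), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(world))
    w <- world[rows, , drop = FALSE]
    d2 <- outer(rowSums(w^2), vtx_sq, "+") - 2 * (w %*% t(vtx))
    nearest[rows] <- max.col(-d2, ties.method = "first")
    ndist[rows] <- sqrt(pmax(d2[cbind(seq_along(rows), nearest[rows])], 0))
  }
  mask_vec <- ndist <= vox
  list(
    dims = dims, affine = affine,
    mask = array(mask_vec, dims),
    nearest_vertex = array(nearest, dims)
  )
}

#' Synthesise one subject
#'
#' Builds a voxel grid enclosing the mesh (margin 2 voxels), masks the
#' voxels within one voxel of the surface shell, assigns each masked voxel
#' the patch of its nearest vertex, and draws its feature vector as
#' patch mean + PMA trend + Gaussian noise. The noise SD is multiplied by
#' `homogeneity_boost` when the subject is preterm and the patch is an
#' effect patch, making preterm microstructure locally more homogeneous
#' there.
#'
#' @param mesh a [surface_mesh()].
#' @param labeling a [make_patch_labels()] result for `mesh`.
#' @param params a [sim_params()] object.
#' @param group `"preterm"` or `"term"`.
#' @param pma postmenstrual age at scan in weeks.
#' @param sex `"M"` or `"F"`.
#' @param rng_seed integer seed for this subject's noise.
#' @param subject_id subject identifier.
#' @param scaffold optional precomputed grid from the internal scaffold
#'   builder (used by [synth_cohort()] to share work across subjects).
#' @return A list of class `subject_record` with the raw (not yet z-scored)
#'   [feature_volume()], the mesh and the demographic fields.
#' @export
synth_subject <- function(mesh, labeling, params, group, pma, sex,
                          rng_seed = 1L, subject_id = "S01", scaffold = NULL) {
  stopifnot(inherits(params, "sim_params"), inherits(labeling, "patch_labeling"))
  group <- match.arg(group, c("preterm", "term"))
  sex <- match.arg(sex, c("M", "F"))
  if (length(labeling$labels) != mesh$vertex_count) {
    abort("patch labelling does not match the mesh.")
  }
  if (is.null(scaffold)) scaffold <- .voxel_scaffold(mesh, params)
  dims <- scaffold$dims
  mask_idx <- which(scaffold$mask)
  voxel_patch <- labeling$labels[scaffold$nearest_vertex[mask_idx]]
  mu <- .patch_means(params$patch_count, params$channel_count, params$patch_mean_separation)
  boosted <- group == "preterm" & voxel_patch %in% params$effect_patches
  sd_vox <- params$within_patch_sd * ifelse(boosted, params$homogeneity_boost, 1)
  nvox <- length(mask_idx)
  C <- params$channel_count
  feats <- withr::with_seed(rng_seed, {
    noise <- matrix(rnorm(nvox * C), nvox, C) * sd_vox
    mu[voxel_patch, , drop = FALSE] +
      matrix(pma * params$pma_slope, nvox, C, byrow = TRUE) + noise
  })
  data <- array(0, c(dims, C))
  plane <- prod(dims)
  for (k in seq_len(C)) data[mask_idx + (k - 1L) * plane] <- feats[, k]
  vol <- feature_volume(data, scaffold$affine, scaffold$mask,
                        channels = c("FA", "MD", "AD", "RD", "NDI_mod", "ODI_mod")[seq_len(C)])
  structure(
    list(
      subject_id = subject_id, group = group, pma_at_scan = pma, sex = sex,
      mesh = mesh, features = vol, nuisance_map = NULL,
      voxel_patch = voxel_patch
    ),
    class = "subject_record"
  )
}

#' Synthesise a two-group cohort
#'
#' Generates `2 * n_per_group` subjects on a shared icosphere with shared
#' patch labels: PMA uniform over `pma_range`, sex alternating, per-subject
#' child seeds derived deterministically from `rng_seed`. The ground-truth
#' effect mask (vertices inside the effect patches) is returned alongside.
#'
#' @param params a [sim_params()] object with `n_per_group >= 2`.
#' @return A list of class `synth_cohort`: `cohort` (tibble with a
#'   `subject` list-column), `mesh`, `labeling`, `effect_vertices` (logical
#'   per vertex) and `params`.
#' @export
synth_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_per_group < 2L) abort("`n_per_group` must be >= 2.")
  mesh <- make_sphere_mesh(params$mesh_subdivisions, params$sphere_radius)
  labeling <- make_patch_labels(mesh, params$patch_count, rng_seed = params$rng_seed)
  scaffold <- .voxel_scaffold(mesh, params)
  n <- 2L * params$n_per_group
  groups <- rep(c("preterm", "term"), each = params$n_per_group)
  sexes <- rep_len(c("M", "F"), n)
  pma <- withr::with_seed(params$rng_seed, runif(n, params$pma_range[1L], params$pma_range[2L]))
  child_seeds <- (as.numeric(params$rng_seed) + 104729 * seq_len(n)) %% 2147483647
  subjects <- vector("list", n)
  ids <- sprintf("S%03d", seq_len(n))
  for (i in seq_len(n)) {
    subjects[[i]] <- synth_subject(
      mesh, labeling, params, groups[i], pma[i], sexes[i],
      rng_seed = as.integer(child_seeds[i]), subject_id = ids[i], scaffold = scaffold
    )
  }
  cohort <- as_cohort_table(tibble::tibble(
    subject_id = ids, group = groups, pma_at_scan = pma, sex = sexes
  ))
  cohort$subject <- subjects
  structure(
    list(
      cohort = cohort, mesh = mesh, labeling = labeling,
      effect_vertices = labeling$labels %in% params$effect_patches,
      params = params
    ),
    class = "synth_cohort"
  )
}
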