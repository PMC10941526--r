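# Fixture builders shared across the suite. Everything is generated in code;
# no binary files are stored.

# regular tetrahedron: complete graph on 4 vertices
tetra_mesh <- function(scale = 1, centre = c(0, 0, 0)) {
  v <- rbind(
    c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)
  ) * scale
  v <- sweep(v, 2L, centre, "+")
  surface_mesh(v, rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
}

# star mesh: one centre vertex whose one-ring is the 26 remaining positions of
# the 3x3x3 voxel cube (world = index under the given isotropic affine)
cube27_fan_mesh <- function(centre_voxel = c(5, 5, 5)) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ] # 26 neighbours
  v <- rbind(centre_voxel, sweep(off, 2L, centre_voxel, "+"))
  k <- nrow(off)
  tri <- cbind(1L, 1L + seq_len(k), 1L + c(seq_len(k)[-1L], 1L))
  surface_mesh(v, tri)
}

# uniform feature volume over a full mask: every voxel carries `vec`
const_feature_volume <- function(dims = c(11, 11, 11), vec = c(1, 2, 3, 4, 5, 6),
                                 affine = diag(4)) {
  data <- array(rep(vec, each = prod(dims)), c(dims, length(vec)))
  feature_volume(data, affine, array(TRUE, dims))
}

# random feature volume (full mask, iid standard normal channels)
noise_feature_volume <- function(dims = c(11, 11, 11), channels = 6, seed = 1,
                                 affine = diag(4)) {
  data <- withr::with_seed(seed, array(rnorm(prod(dims) * channels), c(dims, channels)))
  feature_volume(data, affine, array(TRUE, dims))
}

# small noise-free synthetic subject on a patched sphere, z-scored
noise_free_subject <- function(subdivisions = 2, radius = 10, voxel = 2,
                               patches = 4, seed = 7) {
  p <- sim_params(
    mesh_subdivisions = subdivisions, sphere_radius = radius, voxel_size = voxel,
    patch_count = patches, within_patch_sd = 0, n_per_group = 2, rng_seed = seed
  )
  mesh <- make_sphere_mesh(subdivisions, radius)
  lab <- make_patch_labels(mesh, patches, rng_seed = seed)
  s <- zscore_subject(synth_subject(mesh, lab, p, "term", 40, "M", rng_seed = seed))
  list(subject = s, mesh = mesh, labeling = lab, params = p)
}

# independent Pearson correlation straight from the definition
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# symmetric random affinity-like weight matrix in [0,1], zero diagonal
random_weight_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    w <- matrix(runif(n * n), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    w
  })
}

# cohort -> smoothed VB matrix (subjects x vertices), the inference input
smoothed_vb_matrix <- function(sc, fwhm = 4) {
  M <- do.call(rbind, lapply(sc$cohort$subject, function(s) {
    vb_map(zscore_subject(s))$vb
  }))
  kern <- smoothing_kernel(sc$mesh, fwhm)
  Ms <- t(apply(M, 1L, function(v) smooth_map(sc$mesh, v, kernel = kern)))
  rownames(Ms) <- sc$cohort$subject_id
  Ms
}
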