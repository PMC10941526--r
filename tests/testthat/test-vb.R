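test_that("one-ring sizes match the mesh geometry", {
  expect_length(one_ring(tetra_mesh(), 2), 4L)
  ico <- make_sphere_mesh(0, 1)
  expect_length(one_ring(ico, 3), 6L) # degree 5 + centre
  sub <- make_sphere_mesh(1, 1)
  expect_length(one_ring(sub, 13), 7L) # subdivision vertices have degree 6
  expect_error(one_ring(ico, 13), "out of range")
})

test_that("hybrid neighbourhoods deduplicate and respect the 27-voxel cube", {
  # all one-ring vertices collapse onto a single voxel
  vol <- const_feature_volume(c(11, 11, 11))
  tiny <- tetra_mesh(scale = 0.05, centre = c(5, 5, 5))
  n <- hybrid_neighbourhood(tiny, 1, vol)
  expect_true(n$usable)
  expect_equal(nrow(n$voxel_list), 1L)
  expect_identical(n$voxel_list[1, ], c(5L, 5L, 5L))

  # a neighbour two voxels away on an axis is excluded by the cube rule
  v <- rbind(c(5, 5, 5), c(7.2, 5, 5), c(5.4, 5.6, 5), c(5.4, 5, 5.6))
  far <- surface_mesh(v, rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
  nf <- hybrid_neighbourhood(far, 1, vol)
  expect_true(all(abs(sweep(nf$voxel_list, 2L, c(5L, 5L, 5L))) <= 1L))
  expect_false(any(nf$voxel_list[, 1] == 7L))

  # centre voxel outside the mask flags the neighbourhood unusable
  masked <- vol
  masked$mask[6, 6, 6] <- FALSE
  n2 <- hybrid_neighbourhood(tiny, 1, masked)
  expect_false(n2$usable)
  expect_true(is.na(vb_at_vertex(build_affinity_graph(n2))))
})

test_that("a fully covered cube attains exactly 27 candidate positions", {
  cube <- voxel_cube27(c(5L, 5L, 5L))
  expect_equal(nrow(cube), 27L)
  expect_equal(nrow(unique(cube)), 27L)
  expect_true(all(abs(sweep(cube, 2L, c(5L, 5L, 5L))) <= 1L))

  fan <- cube27_fan_mesh(c(5, 5, 5))
  vol <- noise_feature_volume(c(11, 11, 11), seed = 2)
  n <- hybrid_neighbourhood(fan, 1, vol)
  expect_equal(nrow(n$voxel_list), 27L)
  expect_equal(nrow(unique(n$voxel_list)), 27L)
})

test_that("affinity is clipped Pearson correlation with zero-variance guard", {
  x <- c(0.3, -1, 2, 0.5, 1.1, -0.2)
  expect_equal(affinity(x, 2 * x + 1), 1)
  expect_equal(affinity(x, -x), 0)
  expect_equal(affinity(rep(1, 6), x), 0) # zero variance
  y <- c(1, 3, 2, 4, 6, 5)
  expect_equal(affinity(1:6, y), max(0, pearson_oracle(1:6, y)), tolerance = 1e-12)
  expect_equal(affinity(1:6, y), 0.885714285714286, tolerance = 1e-12)
  expect_error(affinity(1:6, 1:5), "length")
})

test_that("affinity graphs match entry-wise oracle recomputation", {
  feats <- withr::with_seed(8, matrix(rnorm(5 * 6), 5, 6))
  neigh <- structure(
    list(centre_vertex = 1L, centre_voxel = c(0L, 0L, 0L),
         voxel_list = matrix(0L, 5, 3), feature_vectors = feats, usable = TRUE),
    class = "vertex_neighbourhood"
  )
  g <- build_affinity_graph(neigh)
  for (i in 1:5) {
    for (j in 1:5) {
      expected <- if (i == j) 0 else max(0, pearson_oracle(feats[i, ], feats[j, ]))
      expect_equal(g$weights[i, j], expected, tolerance = 1e-12)
    }
  }

  # identical non-constant vectors: complete unit graph
  same <- neigh
  same$feature_vectors <- matrix(rep(c(1, 2, 3, 1, 0, 2), each = 3), 3, 6)
  gs <- build_affinity_graph(same)
  expect_equal(gs$weights, matrix(1, 3, 3) - diag(3))

  # two anticorrelated clusters: zero off-block
  anti <- neigh
  base <- c(1, -1, 2, -2, 0.5, -0.5)
  anti$feature_vectors <- rbind(base, base * 2, -base, -base * 3)
  ga <- build_affinity_graph(anti)
  expect_equal(ga$weights[1:2, 3:4], matrix(0, 2, 2))
  expect_equal(ga$weights[1, 2], 1)

  # fewer than 3 voxels: unusable
  small <- neigh
  small$feature_vectors <- feats[1:2, ]
  expect_false(build_affinity_graph(small)$usable)
})

test_that("algebraic connectivity reproduces closed-form spectra", {
  for (n in c(3, 5, 12)) {
    K <- matrix(1, n, n) - diag(n)
    expect_equal(algebraic_connectivity(K), n, tolerance = 1e-10)
  }
  P3 <- matrix(0, 3, 3)
  P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  expect_equal(algebraic_connectivity(P3), 1, tolerance = 1e-10)
  disc <- matrix(0, 4, 4)
  disc[1, 2] <- disc[2, 1] <- disc[3, 4] <- disc[4, 3] <- 1
  expect_equal(algebraic_connectivity(disc), 0)
  bad <- matrix(runif(9), 3, 3)
  expect_error(algebraic_connectivity(bad), "symmetric")
})

test_that("VB scaling, clipping and invariances hold", {
  for (n in c(3, 7, 27)) {
    K <- matrix(1, n, n) - diag(n)
    g <- structure(list(weights = K, usable = TRUE), class = "affinity_graph")
    expect_equal(vb_at_vertex(g), 1)
  }
  K4h <- 0.5 * (matrix(1, 4, 4) - diag(4))
  g <- structure(list(weights = K4h, usable = TRUE), class = "affinity_graph")
  expect_equal(vb_at_vertex(g), 0.5, tolerance = 1e-12)

  disc <- matrix(0, 4, 4)
  disc[1, 2] <- disc[2, 1] <- disc[3, 4] <- disc[4, 3] <- 1
  gd <- structure(list(weights = disc, usable = TRUE), class = "affinity_graph")
  expect_equal(vb_at_vertex(gd), 0)

  # uniform scaling of weights scales lambda_2 linearly
  w <- random_weight_matrix(9, seed = 10)
  l2 <- algebraic_connectivity(w)
  for (c_ in c(0.2, 0.7, 1)) {
    expect_equal(algebraic_connectivity(c_ * w), c_ * l2, tolerance = 1e-9)
  }

  # VB = 1 iff the graph is complete with unit weights
  eps <- w <- matrix(1, 5, 5) - diag(5)
  w[2, 3] <- w[3, 2] <- 1 - 1e-4
  g1 <- structure(list(weights = w, usable = TRUE), class = "affinity_graph")
  expect_lt(vb_at_vertex(g1), 1)

  # voxel-order permutation leaves VB unchanged
  feats <- withr::with_seed(11, matrix(rnorm(8 * 6), 8, 6))
  mk <- function(f) {
    structure(list(centre_vertex = 1L, centre_voxel = c(0L, 0L, 0L),
                   voxel_list = matrix(0L, nrow(f), 3), feature_vectors = f,
                   usable = TRUE), class = "vertex_neighbourhood")
  }
  v1 <- vb_at_vertex(build_affinity_graph(mk(feats)))
  perm <- withr::with_seed(12, sample(8))
  v2 <- vb_at_vertex(build_affinity_graph(mk(feats[perm, ])))
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("noise-free subjects give VB = 1 inside patches, < 1 at boundaries", {
  fx <- noise_free_subject(subdivisions = 2, radius = 10, voxel = 2, patches = 4)
  vm <- vb_map(fx$subject)
  expect_true(all(vm$n_voxels <= 27))
  boundary <- patch_boundary_vertices(fx$mesh, fx$labeling)
  interior_vb <- vm$vb[!boundary & !is.na(vm$vb)]
  expect_equal(interior_vb, rep(1, length(interior_vb)), tolerance = 1e-9)
  boundary_vb <- vm$vb[boundary & !is.na(vm$vb)]
  expect_true(all(boundary_vb < 1 - 1e-6))
  expect_true(all(vm$vb >= 0 & vm$vb <= 1, na.rm = TRUE))

  # determinism: running twice gives bit-identical maps
  vm2 <- vb_map(fx$subject)
  expect_identical(vm$vb, vm2$vb)
})
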