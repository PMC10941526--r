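test_that("icosphere subdivision gives the expected vertex and triangle counts", {
  m0 <- make_sphere_mesh(0, 1)
  expect_equal(m0$vertex_count, 12L)
  expect_equal(nrow(m0$triangles), 20L)
  m2 <- make_sphere_mesh(2, 3.5)
  expect_equal(m2$vertex_count, 162L) # 10 * 4^2 + 2
  expect_equal(nrow(m2$triangles), 20L * 16L)
  expect_lt(max(abs(sqrt(rowSums(m2$vertices^2)) - 3.5)), 1e-9)
})

test_that("patch labelling covers the mesh with connected patches", {
  mesh <- make_sphere_mesh(3, 10)

  lab1 <- make_patch_labels(mesh, 1)
  expect_true(all(lab1$labels == 1L))

  lab4 <- make_patch_labels(mesh, 4, rng_seed = 2)
  expect_setequal(unique(lab4$labels), 1:4)
  expect_length(lab4$labels, mesh$vertex_count)

  # flood-fill oracle: breadth-first search within each patch must reach
  # every member from the first member
  for (pid in 1:4) {
    members <- which(lab4$labels == pid)
    reached <- rep(FALSE, mesh$vertex_count)
    queue <- members[1L]
    reached[queue] <- TRUE
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- mesh$adjacency[[v]]
      nb <- nb[lab4$labels[nb] == pid & !reached[nb]]
      reached[nb] <- TRUE
      queue <- c(queue, nb)
    }
    expect_true(all(reached[members]), label = sprintf("patch %d connected", pid))
  }
})

test_that("degenerate patch counts behave as specified", {
  ico <- make_sphere_mesh(0, 1)
  labn <- make_patch_labels(ico, 12, rng_seed = 1)
  expect_setequal(labn$labels, 1:12) # every vertex its own patch
  expect_error(make_patch_labels(ico, 13), "exceeds")
})

test_that("subject synthesis is deterministic and honours the noise-free limit", {
  p <- sim_params(mesh_subdivisions = 1, sphere_radius = 5, voxel_size = 2,
                  patch_count = 3, within_patch_sd = 0.5, n_per_group = 2)
  mesh <- make_sphere_mesh(1, 5)
  lab <- make_patch_labels(mesh, 3, rng_seed = 1)
  s1 <- synth_subject(mesh, lab, p, "preterm", 40, "F", rng_seed = 42)
  s2 <- synth_subject(mesh, lab, p, "preterm", 40, "F", rng_seed = 42)
  expect_identical(s1$features$data, s2$features$data)

  # noise-free: every voxel of a patch carries one shared feature vector
  p0 <- sim_params(mesh_subdivisions = 1, sphere_radius = 5, voxel_size = 2,
                   patch_count = 3, within_patch_sd = 0, n_per_group = 2)
  s0 <- synth_subject(mesh, lab, p0, "term", 40, "M", rng_seed = 1)
  mask_idx <- which(s0$features$mask)
  plane <- prod(dim(s0$features$mask))
  feats <- sapply(1:6, function(k) s0$features$data[mask_idx + (k - 1L) * plane])
  for (pid in 1:3) {
    rows <- feats[s0$voxel_patch == pid, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2L, rows[1L, ]))), 1e-12)
  }

  # boost = 1: group does not enter the generative law (same seed, same data)
  pn <- sim_params(mesh_subdivisions = 1, sphere_radius = 5, voxel_size = 2,
                   patch_count = 3, within_patch_sd = 1, homogeneity_boost = 1,
                   n_per_group = 2)
  a <- synth_subject(mesh, lab, pn, "preterm", 40, "F", rng_seed = 9)
  b <- synth_subject(mesh, lab, pn, "term", 40, "F", rng_seed = 9)
  expect_identical(a$features$data, b$features$data)
})

test_that("cohort synthesis is balanced, reproducible and carries ground truth", {
  p <- sim_params(mesh_subdivisions = 1, sphere_radius = 5, voxel_size = 2,
                  patch_count = 4, n_per_group = 3, rng_seed = 5)
  sc1 <- synth_cohort(p)
  expect_equal(nrow(sc1$cohort), 6L)
  expect_equal(sum(sc1$cohort$group == "preterm"), 3L)
  expect_equal(sum(sc1$cohort$group == "term"), 3L)
  expect_true(all(sc1$cohort$pma_at_scan >= p$pma_range[1] &
    sc1$cohort$pma_at_scan <= p$pma_range[2]))
  expect_equal(sc1$effect_vertices, sc1$labeling$labels %in% p$effect_patches)

  sc2 <- synth_cohort(p)
  expect_identical(sc1$cohort$pma_at_scan, sc2$cohort$pma_at_scan)
  expect_identical(
    sc1$cohort$subject[[4]]$features$data,
    sc2$cohort$subject[[4]]$features$data
  )
  expect_error(synth_cohort(sim_params(n_per_group = 1)), ">= 2")
})

test_that("boosted preterm group has higher effect-region VB across cohorts", {
  # one-sided sign test over 20 tiny cohorts
  diffs <- vapply(1:20, function(i) {
    p <- sim_params(
      mesh_subdivisions = 1, sphere_radius = 5, voxel_size = 2, patch_count = 4,
      within_patch_sd = 1, homogeneity_boost = 0.4, effect_patches = 1:2,
      n_per_group = 2, rng_seed = 500 + i
    )
    sc <- synth_cohort(p)
    interior <- sc$effect_vertices & !patch_boundary_vertices(sc$mesh, sc$labeling)
    vb <- vapply(sc$cohort$subject, function(s) {
      mean(vb_map(zscore_subject(s))$vb[interior], na.rm = TRUE)
    }, numeric(1))
    mean(vb[sc$cohort$group == "preterm"]) - mean(vb[sc$cohort$group == "term"])
  }, numeric(1))
  st <- stats::binom.test(sum(diffs > 0), length(diffs), alternative = "greater")
  expect_lt(st$p.value, 0.05)
})

test_that("mean interior VB is non-increasing in the within-patch noise SD", {
  sds <- c(0.25, 1, 4)
  mesh <- make_sphere_mesh(1, 5)
  lab <- make_patch_labels(mesh, 3, rng_seed = 3)
  interior <- !patch_boundary_vertices(mesh, lab)
  mean_vb <- vapply(sds, function(s) {
    p <- sim_params(mesh_subdivisions = 1, sphere_radius = 5, voxel_size = 2,
                    patch_count = 3, within_patch_sd = s, n_per_group = 2)
    subj <- zscore_subject(synth_subject(mesh, lab, p, "term", 40, "M", rng_seed = 11))
    mean(vb_map(subj)$vb[interior], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_vb) <= 1e-12))
})
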