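toy_cohort <- function(n_per_group = 5, seed = 1) {
  n <- 2L * n_per_group
  as_cohort_table(tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = rep(c("preterm", "term"), each = n_per_group),
    pma_at_scan = withr::with_seed(seed, runif(n, 38, 42)),
    sex = rep_len(c("M", "F"), n)
  ))
}

test_that("Sidak correction gives the published two-hemisphere threshold", {
  expect_equal(sprintf("%.4f", sidak_threshold(0.05, 2)), "0.0253")
  expect_equal(sidak_threshold(0.05, 2), 0.025320566, tolerance = 1e-7)
  expect_equal(sidak_threshold(0.05, 1), 0.05)
  expect_equal(sidak_threshold(0.05, 4), 1 - 0.95^0.25, tolerance = 1e-15)
  expect_error(sidak_threshold(0, 2), "alpha")
  expect_error(sidak_threshold(0.05, 0), "m")
})

test_that("nuisance-map residualisation matches a least-squares oracle", {
  maps <- withr::with_seed(2, matrix(rnorm(4 * 3), 4, 3))
  # nuisance identical to the map: reduced to the vertex mean
  out <- residualize_nuisance_map(maps, maps)
  expect_equal(out, matrix(colMeans(maps), 4, 3, byrow = TRUE), tolerance = 1e-12)

  # orthogonal (after centring) nuisance leaves the map unchanged
  y <- c(1, 2, 3, 4)
  x <- c(1, -1, -1, 1) # centred, orthogonal to centred y
  expect_equal(
    residualize_nuisance_map(matrix(y), matrix(x)),
    matrix(y),
    tolerance = 1e-10
  )

  # worked 4-subject, 1-vertex case against lm()
  y <- c(2.1, -0.3, 1.4, 0.9)
  x <- c(10, 12, 9, 15)
  fit <- stats::lm(y ~ x)
  expect_equal(
    drop(residualize_nuisance_map(matrix(y), matrix(x))),
    unname(stats::residuals(fit)) + mean(y),
    tolerance = 1e-12
  )

  # constant nuisance: identity
  expect_equal(residualize_nuisance_map(matrix(y), matrix(rep(1, 4))), matrix(y))
})

test_that("vertex-wise GLM t equals the pooled two-sample t without covariates", {
  for (seed in 1:50) {
    fix <- withr::with_seed(seed, {
      n1 <- sample(3:8, 1)
      n0 <- sample(3:8, 1)
      list(y = rnorm(n1 + n0), g = rep(c(1, 0), c(n1, n0)))
    })
    X <- cbind(1, fix$g)
    t_glm <- glm_tstat(matrix(fix$y), X, c(0, 1))
    t_ref <- stats::t.test(fix$y[fix$g == 1], fix$y[fix$g == 0], var.equal = TRUE)$statistic
    expect_equal(t_glm, unname(t_ref), tolerance = 1e-10)
  }
})

test_that("GLM t-statistics match a normal-equations oracle with covariates", {
  cohort <- toy_cohort(3)
  des <- design_matrix(cohort)
  maps <- withr::with_seed(9, matrix(rnorm(6 * 4), 6, 4))
  tvals <- glm_tstat(maps, des)
  for (v in 1:4) {
    df <- data.frame(y = maps[, v], g = des$X[, 2], pma = des$X[, 3], sx = des$X[, 4])
    fit <- stats::lm(y ~ g + pma + sx, data = df)
    expect_equal(tvals[v], unname(summary(fit)$coefficients["g", "t value"]),
                 tolerance = 1e-10)
  }

  # zero contrast, missing propagation, rank deficiency
  expect_equal(glm_tstat(maps, des, c(0, 0, 0, 0)), rep(0, 4))
  maps[2, 3] <- NA
  expect_true(is.na(glm_tstat(maps, des)[3]))
  expect_false(anyNA(glm_tstat(maps, des)[c(1, 2, 4)]))
  bad <- cbind(des$X, des$X[, 2])
  expect_error(glm_tstat(maps, bad, rep(0, 5)), "rank-deficient")
})

test_that("TFCE matches a direct height-integration oracle", {
  mesh <- make_sphere_mesh(1, 5)
  areas <- mesh_vertex_areas(mesh)

  expect_equal(tfce(mesh, rep(0, mesh$vertex_count)), rep(0, mesh$vertex_count))

  # single suprathreshold vertex: isolated component of its own area
  stat <- rep(0, mesh$vertex_count)
  stat[11] <- 2
  params <- tfce_params(E = 1, H = 2, dh = 0.1)
  enh <- tfce(mesh, stat, params)
  hs <- seq(0.1, 2, by = 0.1)
  expect_equal(enh[11], sum(areas[11]^1 * hs^2 * 0.1), tolerance = 1e-10)
  expect_equal(enh[-11], rep(0, mesh$vertex_count - 1L))

  # two-vertex component: both members share the component extent
  stat2 <- rep(0, mesh$vertex_count)
  nb <- mesh$adjacency[[11]][1]
  stat2[c(11, nb)] <- 2
  enh2 <- tfce(mesh, stat2, params)
  ext <- areas[11] + areas[nb]
  expect_equal(enh2[11], sum(ext^1 * hs^2 * 0.1), tolerance = 1e-10)
  expect_equal(enh2[nb], enh2[11], tolerance = 1e-12)

  # monotonicity: raising one vertex never lowers any TFCE value
  base <- withr::with_seed(13, pmax(rnorm(mesh$vertex_count), 0))
  raised <- base
  raised[5] <- raised[5] + 1
  expect_true(all(tfce(mesh, raised, params) >= tfce(mesh, base, params) - 1e-12))

  # missing values never become suprathreshold
  stat3 <- stat
  stat3[12] <- NA
  enh3 <- tfce(mesh, stat3, params)
  expect_equal(enh3[12], 0)

  expect_error(tfce_params(E = 0), "> 0")
  expect_error(tfce_params(E = 1, H = -2), "> 0")
})

test_that("permutation p-values respect their formula bounds", {
  mesh <- make_sphere_mesh(0, 5)
  cohort <- toy_cohort(5)
  des <- design_matrix(cohort)
  # plant a strong term > preterm effect: observed preterm>term TFCE is zero
  maps <- withr::with_seed(14, {
    m <- matrix(rnorm(10 * 12, sd = 0.1), 10, 12)
    m[des$X[, 2] == 0, ] <- m[des$X[, 2] == 0, ] + 2
    m
  })
  rownames(maps) <- cohort$subject_id
  res <- permutation_fwe(maps, des, mesh, n_perm = 99, rng_seed = 3)
  p <- c(res$table$p_fwe_pos, res$table$p_fwe_neg)
  expect_true(all(p >= 1 / 100 & p <= 1))
  expect_equal(res$table$p_fwe_pos, rep(1, 12)) # obs TFCE 0 <= all null maxima
  expect_true(all(res$table$p_fwe_neg <= 0.05)) # planted effect detected
  expect_equal(min(res$table$p_fwe_neg), 1 / 100)
})

test_that("exhaustive enumeration matches a brute-force relabeling oracle", {
  mesh <- make_sphere_mesh(0, 5)
  g <- rep(c(1, 0), each = 3)
  ids <- sprintf("S%d", 1:6)
  X <- cbind(1, g)
  des <- structure(list(X = X, contrast = c(0, 1), subject_id = ids),
                   class = "design_matrix")
  maps <- withr::with_seed(15, matrix(rnorm(6 * 12), 6, 12,
                                      dimnames = list(ids, NULL)))
  expect_warning(
    res <- permutation_fwe(maps, des, mesh, n_perm = 1000, rng_seed = 1),
    "enumerating exhaustively"
  )
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, choose(6, 3))

  # oracle: direct Freedman-Lane enumeration over the 20 relabelings
  mu <- matrix(colMeans(maps), 6, 12, byrow = TRUE)
  R <- maps - mu
  g1 <- which(g == 1)
  g0 <- which(g == 0)
  subsets <- utils::combn(6, 3)
  null_max <- numeric(ncol(subsets))
  t_of <- function(Y) {
    apply(Y, 2L, function(y) {
      stats::t.test(y[g1], y[g0], var.equal = TRUE)$statistic
    })
  }
  obs_tfce <- tfce(mesh, t_of(maps))
  for (b in seq_len(ncol(subsets))) {
    Yb <- mu
    Yb[g1, ] <- mu[g1, ] + R[subsets[, b], ]
    Yb[g0, ] <- mu[g0, ] + R[setdiff(1:6, subsets[, b]), ]
    null_max[b] <- max(tfce(mesh, t_of(Yb)), 0)
  }
  p_oracle <- vapply(obs_tfce, function(o) mean(null_max >= o), numeric(1))
  expect_equal(res$table$p_fwe_pos, p_oracle, tolerance = 1e-12)
})

test_that("inference is invariant to subject row order", {
  mesh <- make_sphere_mesh(0, 5)
  cohort <- toy_cohort(4, seed = 6)
  des <- design_matrix(cohort)
  maps <- withr::with_seed(16, matrix(rnorm(8 * 12), 8, 12,
                                      dimnames = list(cohort$subject_id, NULL)))
  res1 <- permutation_fwe(maps, des, mesh, n_perm = 50, rng_seed = 2)

  perm <- withr::with_seed(17, sample(8))
  cohort2 <- as_cohort_table(cohort[perm, setdiff(names(cohort), "subject")])
  des2 <- design_matrix(cohort2)
  res2 <- permutation_fwe(maps[perm, ], des2, mesh, n_perm = 50, rng_seed = 2)
  expect_identical(res1$table, res2$table)
  expect_identical(res1$null_max, res2$null_max)
})

test_that("design construction validates groups and rank", {
  cohort <- toy_cohort(4)
  des <- design_matrix(cohort)
  expect_equal(dim(des$X), c(8, 4))
  expect_equal(qr(des$X)$rank, 4)
  expect_equal(des$contrast, c(0, 1, 0, 0))
  one_group <- dplyr::mutate(cohort, group = "preterm")
  expect_error(design_matrix(one_group), "both groups")
  const_cols <- dplyr::mutate(cohort, pma_at_scan = 40)
  expect_error(design_matrix(const_cols), "rank-deficient")
})

test_that("tidy and glance summarise inference results", {
  mesh <- make_sphere_mesh(0, 5)
  cohort <- toy_cohort(4)
  des <- design_matrix(cohort)
  maps <- withr::with_seed(18, matrix(rnorm(8 * 12), 8, 12,
                                      dimnames = list(cohort$subject_id, NULL)))
  res <- permutation_fwe(maps, des, mesh, n_perm = 20, rng_seed = 4)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("vertex", "t", "tfce_pos", "tfce_neg",
                     "p_fwe_pos", "p_fwe_neg", "sig_pos", "sig_neg"))
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_vertices, 12L)
  expect_equal(gl$threshold, sidak_threshold(0.05, 2))
})
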