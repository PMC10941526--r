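#' Sidak-corrected per-test alpha
#'
#' `1 - (1 - alpha)^(1/m)`: the per-test level controlling the familywise
#' level at `alpha` over `m` independent tests (here, the two hemispheres,
#' giving 0.0253 at alpha = 0.05).
#'
#' @param alpha familywise level in (0, 1).
#' @param m number of independent tests (>= 1).
#' @return Per-test alpha.
#' @export
sidak_threshold <- function(alpha, m) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    abort("`alpha` must be a single value in (0, 1).")
  }
  if (!(is.numeric(m) && length(m) == 1L && m >= 1)) abort("`m` must be >= 1.")
  1 - (1 - alpha)^(1 / m)
}

#' Group design matrix for vertex-wise GLMs
#'
#' Columns: intercept, group indicator (preterm = 1, term = 0), centred PMA
#' at scan, and centred sex indicator (M = 1, F = 0). The group contrast
#' tests preterm > term; its negation tests term > preterm.
#'
#' @param cohort a cohort table with `group`, `pma_at_scan` and `sex`.
#' @return A list of class `design_matrix` with `X`, `contrast` and
#'   `subject_id`.
#' @export
design_matrix <- function(cohort) {
  if (!all(c("group", "pma_at_scan", "sex") %in% names(cohort))) {
    abort("cohort needs `group`, `pma_at_scan` and `sex` columns.")
  }
  if (length(unique(cohort$group)) < 2L) {
    abort("both groups must be non-empty before inference.")
  }
  grp <- as.numeric(cohort$group == "preterm")
  sex <- as.numeric(cohort$sex == "M")
  X <- cbind(
    intercept = 1,
    group = grp,
    pma = cohort$pma_at_scan - mean(cohort$pma_at_scan),
    sex = sex - mean(sex)
  )
  if (qr(X)$rank < ncol(X)) abort("design matrix is rank-deficient.")
  structure(
    list(X = X, contrast = c(0, 1, 0, 0), subject_id = cohort$subject_id),
    class = "design_matrix"
  )
}

#' Regress a per-vertex nuisance map out of subject maps
#'
#' At each vertex, the across-subject map values are regressed on an
#' intercept plus the across-subject nuisance values (ordinary least
#' squares); the residuals are returned with the vertex grand mean added
#' back. Vertices where the nuisance is constant are left unchanged.
#'
#' @param maps subjects x vertices matrix.
#' @param nuisance subjects x vertices matrix (e.g. sulcal depth).
#' @return Matrix of the same shape.
#' @export
residualize_nuisance_map <- function(maps, nuisance) {
  maps <- as.matrix(maps)
  nuisance <- as.matrix(nuisance)
  if (!all(dim(maps) == dim(nuisance))) {
    abort("`maps` and `nuisance` must have identical subjects x vertices shape.")
  }
  out <- maps
  for (v in seq_len(ncol(maps))) {
    y <- maps[, v]
    x <- nuisance[, v]
    ok <- !is.na(y) & !is.na(x)
    if (sum(ok) < 3L || sd(x[ok]) == 0) next
    xc <- x[ok] - mean(x[ok])
    slope <- sum(xc * y[ok]) / sum(xc^2)
    # centred residual plus the vertex grand mean
    out[ok, v] <- (y[ok] - mean(y[ok]) - slope * xc) + mean(y[ok])
  }
  out
}

#' Vertex-wise GLM t-statistics
#'
#' Ordinary least squares at every vertex with a shared design matrix;
#' `t = c'beta / sqrt(c'(X'X)^{-1}c * sigma^2)` with residual degrees of
#' freedom `n - rank(X)`. Vertices with any missing subject value get a
#' missing t. With a two-column intercept+group design this reduces
#' algebraically to the classical pooled-variance two-sample t.
#'
#' @param maps subjects x vertices matrix.
#' @param design a [design_matrix()] or a plain numeric design matrix.
#' @param contrast numeric contrast vector (defaults to the design's group
#'   contrast).
#' @return Numeric vector of per-vertex t values.
#' @export
glm_tstat <- function(maps, design, contrast = NULL) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (is.null(contrast)) {
    if (!inherits(design, "design_matrix")) abort("`contrast` is required.")
    contrast <- design$contrast
  }
  maps <- as.matrix(maps)
  n <- nrow(X)
  p <- ncol(X)
  if (nrow(maps) != n) abort("`maps` rows must match design rows.")
  if (length(contrast) != p) abort("contrast length must match design columns.")
  if (qr(X)$rank < p) abort("design matrix is rank-deficient.")
  if (n < p + 2L) abort(sprintf("need at least %d subjects for %d design columns.", p + 2L, p))
  xtx_inv <- solve(crossprod(X))
  cpc <- drop(t(contrast) %*% xtx_inv %*% contrast)
  df <- n - p
  tvals <- rep(NA_real_, ncol(maps))
  complete <- colSums(is.na(maps)) == 0L
  if (any(complete)) {
    Y <- maps[, complete, drop = FALSE]
    beta <- xtx_inv %*% crossprod(X, Y)
    res <- Y - X %*% beta
    sigma2 <- colSums(res^2) / df
    num <- drop(t(contrast) %*% beta)
    tvals[complete] <- num / sqrt(pmax(sigma2 * cpc, .Machine$double.xmin))
  }
  tvals
}

#' TFCE parameters
#'
#' @param E extent exponent (> 0); surface default 1.
#' @param H height exponent (> 0); default 2.
#' @param dh integration step; `NULL` uses `max(stat)/100` per map.
#' @return A list of class `tfce_params`.
#' @export
tfce_params <- function(E = 1, H = 2, dh = NULL) {
  if (E <= 0 || H <= 0) abort("TFCE exponents E and H must be > 0.")
  if (!is.null(dh) && dh <= 0) abort("`dh` must be > 0.")
  structure(list(E = E, H = H, dh = dh), class = "tfce_params")
}

#' Threshold-free cluster enhancement on a surface
#'
#' `TFCE(v) = sum_h extent_v(h)^E * h^H * dh` over thresholds
#' `h = dh, 2dh, ... <= max(stat)`, where `extent_v(h)` is the surface area
#' (one third of incident triangle areas per member vertex) of the connected
#' suprathreshold component containing `v` under one-ring connectivity.
#' Missing stat values are treated as never suprathreshold.
#'
#' @param mesh a [surface_mesh()].
#' @param stat_map per-vertex statistic (NA allowed).
#' @param params a [tfce_params()] object.
#' @return Per-vertex enhanced map (zero where the stat is not positive).
#' @export
tfce <- function(mesh, stat_map, params = tfce_params()) {
  stopifnot(is_surface_mesh(mesh), inherits(params, "tfce_params"))
  if (length(stat_map) != mesh$vertex_count) {
    abort("stat map length does not match vertex count.")
  }
  stat <- as.double(stat_map)
  stat[is.na(stat)] <- -Inf
  mx <- max(stat[is.finite(stat)], -Inf)
  if (!is.finite(mx) || mx <= 0) return(numeric(mesh$vertex_count))
  dh <- if (is.null(params$dh)) mx / 100 else params$dh
  csr <- .mesh_csr(mesh)
  .cpp_tfce(stat, csr$ptr, csr$idx, mesh_vertex_areas(mesh), params$E, params$H, dh)
}

# all permutations of 1..n (n small), for exhaustive enumeration
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (k in seq_len(n)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], n, after = k - 1L)
    }
  }
  out
}

#' Permutation-based group inference with TFCE and FWE correction
#'
#' Freedman-Lane permutation scheme: the nuisance-only model (all design
#' columns with zero contrast weight) is fitted, its residuals are permuted
#' across subjects and added back to the nuisance fit, and the full-model t
#' and its TFCE enhancement are recomputed for every shuffle. The null
#' statistic is the maximum TFCE over vertices, giving familywise-error-
#' corrected p-values `(b + 1) / (n_perm + 1)`; both one-sided group
#' contrasts (preterm > term and term > preterm) are computed in one run.
#' When `n_perm` reaches the number of distinct permutations the test
#' switches, with a warning, to exhaustive enumeration with exact p-values
#' `b / m`. Permutations are drawn in canonical subject-id order, so results
#' are invariant to the row order of `maps`.
#'
#' @param maps subjects x vertices matrix of (smoothed) VB maps; rownames
#'   are subject ids when available.
#' @param design a [design_matrix()].
#' @param mesh the common [surface_mesh()].
#' @param n_perm number of random shuffles (>= 1).
#' @param rng_seed integer seed making the shuffle sequence reproducible.
#' @param params a [tfce_params()] object.
#' @param alpha familywise level before the across-hemisphere correction.
#' @param m_hemis number of hemispheres tested (Sidak correction factor).
#' @return A list of class `group_inference_result`; see [tidy()] and
#'   [glance()] methods.
#' @export
permutation_fwe <- function(maps, design, mesh, n_perm = 10000L, rng_seed = 1L,
                            params = tfce_params(), alpha = 0.05, m_hemis = 2L) {
  stopifnot(inherits(design, "design_matrix"), is_surface_mesh(mesh))
  maps <- as.matrix(maps)
  if (n_perm < 1L) abort("`n_perm` must be >= 1.")
  X <- design$X
  n <- nrow(X)
  if (nrow(maps) != n) abort("`maps` rows must match design rows.")
  grp <- X[, which(design$contrast != 0)]
  if (min(sum(grp == max(grp)), sum(grp == min(grp))) < 2L) {
    abort("both groups need at least 2 subjects.")
  }
  # canonical subject order so results do not depend on input row order
  ids <- rownames(maps)
  if (is.null(ids)) ids <- design$subject_id
  if (!is.null(ids)) {
    ord <- order(ids)
    maps <- maps[ord, , drop = FALSE]
    X <- X[ord, , drop = FALSE]
  }
  contrast <- design$contrast
  plain_design <- structure(list(X = X, contrast = contrast), class = "design_matrix")

  nuis_cols <- which(contrast == 0)
  Z <- X[, nuis_cols, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
  complete <- colSums(is.na(maps)) == 0L
  Yc <- maps[, complete, drop = FALSE]
  Yf <- Hz %*% Yc
  Yr <- Yc - Yf

  # distinct-permutation count; pure intercept nuisance collapses to group
  # relabelings
  intercept_only <- ncol(Z) == 1L && all(Z == Z[1L])
  n1 <- sum(grp == 1)
  n_distinct <- if (intercept_only && ncol(X) == 2L) choose(n, n1) else factorial(n)
  exhaustive <- is.finite(n_distinct) && n_perm >= n_distinct
  if (exhaustive) {
    warn(sprintf(
      "n_perm (%d) >= distinct permutations (%d); enumerating exhaustively.",
      n_perm, n_distinct
    ))
    if (n_distinct > 50000) abort("exhaustive enumeration too large (> 50000).")
    if (intercept_only && ncol(X) == 2L) {
      subsets <- utils::combn(n, n1)
      g1_rows <- which(grp == 1)
      g0_rows <- which(grp != 1)
      perms <- t(apply(subsets, 2L, function(s) {
        p <- integer(n)
        p[g1_rows] <- s
        p[g0_rows] <- setdiff(seq_len(n), s)
        p
      }))
    } else {
      perms <- .all_perms(n)
    }
  } else {
    perms <- withr::with_seed(rng_seed, {
      t(replicate(n_perm, sample.int(n)))
    })
  }

  tfce_of <- function(tvals) {
    full <- rep(NA_real_, ncol(maps))
    full[complete] <- tvals
    list(
      pos = tfce(mesh, full, params),
      neg = tfce(mesh, -full, params)
    )
  }
  t_obs_c <- glm_tstat(Yc, plain_design, contrast)
  obs <- tfce_of(t_obs_c)
  B <- nrow(perms)
  null_max <- matrix(NA_real_, B, 2L, dimnames = list(NULL, c("pos", "neg")))
  for (b in seq_len(B)) {
    Yb <- Yf + Yr[perms[b, ], , drop = FALSE]
    tb <- glm_tstat(Yb, plain_design, contrast)
    eb <- tfce_of(tb)
    null_max[b, 1L] <- max(eb$pos, 0)
    null_max[b, 2L] <- max(eb$neg, 0)
  }
  p_of <- function(obs_map, null_vec) {
    p <- rep(NA_real_, length(obs_map))
    idx <- which(!is.na(obs_map) & complete)
    for (v in idx) {
      b <- sum(null_vec >= obs_map[v])
      p[v] <- if (exhaustive) b / B else (b + 1) / (B + 1)
    }
    p
  }
  p_pos <- p_of(obs$pos, null_max[, 1L])
  p_neg <- p_of(obs$neg, null_max[, 2L])
  thr <- sidak_threshold(alpha, m_hemis)
  t_full <- rep(NA_real_, ncol(maps))
  t_full[complete] <- t_obs_c
  res <- tibble::tibble(
    vertex = seq_len(ncol(maps)),
    t = t_full,
    tfce_pos = obs$pos, tfce_neg = obs$neg,
    p_fwe_pos = p_pos, p_fwe_neg = p_neg,
    sig_pos = !is.na(p_pos) & p_pos < thr,
    sig_neg = !is.na(p_neg) & p_neg < thr
  )
  structure(
    list(
      table = res, null_max = null_max, n_perm = B, rng_seed = rng_seed,
      exhaustive = exhaustive, alpha = alpha, m_hemis = m_hemis,
      threshold = thr, tfce_params = params
    ),
    class = "group_inference_result"
  )
}

#' @export
print.group_inference_result <- function(x, ...) {
  cat(sprintf(
    "<group_inference_result> %d vertices, %d permutations%s, threshold p < %.4f\n",
    nrow(x$table), x$n_perm, if (x$exhaustive) " (exhaustive)" else "", x$threshold
  ))
  cat(sprintf(
    "  significant vertices: %d (preterm > term), %d (term > preterm)\n",
    sum(x$table$sig_pos), sum(x$table$sig_neg)
  ))
  invisible(x)
}

#' Tidy a group inference result
#'
#' @param x a `group_inference_result`.
#' @param ... unused.
#' @return The per-vertex tibble of t, TFCE and FWE-corrected p values.
#' @export
tidy.group_inference_result <- function(x, ...) x$table

#' One-row summary of a group inference result
#'
#' @param x a `group_inference_result`.
#' @param ... unused.
#' @return A one-row tibble.
#' @export
glance.group_inference_result <- function(x, ...) {
  tibble::tibble(
    n_vertices = nrow(x$table),
    n_perm = x$n_perm,
    exhaustive = x$exhaustive,
    threshold = x$threshold,
    n_sig_pos = sum(x$table$sig_pos),
    n_sig_neg = sum(x$table$sig_neg),
    min_p_pos = suppressWarnings(min(x$table$p_fwe_pos, na.rm = TRUE)),
    min_p_neg = suppressWarnings(min(x$table$p_fwe_neg, na.rm = TRUE))
  )
}
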