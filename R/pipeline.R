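#' Experiment configuration
#'
#' Bundles the full simulate -> features -> vb -> smooth -> stats run:
#' simulation parameters, VB minimum neighbourhood, smoothing FWHM (default
#' 4 mm), and the inference settings (permutations, alpha, number of
#' hemispheres in the Sidak correction, seed).
#'
#' @param sim a [sim_params()] object.
#' @param vb_min_neigh minimum usable searchlight size (voxels).
#' @param fwhm smoothing kernel FWHM in mm.
#' @param n_perm permutation count for the group inference.
#' @param alpha familywise level.
#' @param m_hemis hemispheres entering the Sidak correction.
#' @param seed integer seed for the inference shuffles.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_params(), vb_min_neigh = 3L, fwhm = 4,
                       n_perm = 10000L, alpha = 0.05, m_hemis = 2L, seed = 1L) {
  stopifnot(inherits(sim, "sim_params"))
  if (sim$n_per_group < 2L) abort("validation error: n_per_group must be >= 2.")
  if (fwhm <= 0) abort("validation error: fwhm must be > 0.")
  if (n_perm < 1L) abort("validation error: n_perm must be >= 1.")
  structure(
    list(sim = sim, vb_min_neigh = as.integer(vb_min_neigh), fwhm = fwhm,
         n_perm = as.integer(n_perm), alpha = alpha, m_hemis = as.integer(m_hemis),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read an experiment configuration from JSON
#'
#' @param path JSON file with fields matching [run_config()] (the `sim`
#'   entry holds [sim_params()] fields).
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- cfg$sim %||% list()
  sim <- do.call(sim_params, sim_args)
  do.call(run_config, c(list(sim = sim), cfg[setdiff(names(cfg), "sim")]))
}

.config_hash <- function(config) rlang::hash(unclass(config))

.stage_marker <- function(dir, stage) file.path(dir, sprintf(".stage_%s.json", stage))

.stage_done <- function(dir, stage, hash, outputs = character()) {
  marker <- .stage_marker(dir, stage)
  if (!file.exists(marker)) return(FALSE)
  m <- tryCatch(jsonlite::read_json(marker), error = function(e) NULL)
  identical(m$hash, hash) && isTRUE(m$status == "DONE") && all(file.exists(outputs))
}

.mark_stage <- function(dir, stage, hash, status = "DONE") {
  jsonlite::write_json(
    list(stage = stage, hash = hash, status = status, time = format(Sys.time())),
    .stage_marker(dir, stage), auto_unbox = TRUE
  )
}

.run_stage <- function(out_dir, stage, hash, force, fn, outputs = character()) {
  if (!force && .stage_done(out_dir, stage, hash, outputs)) {
    message(sprintf("[neovb] stage '%s': up to date, skipped", stage))
    return(invisible(FALSE))
  }
  ok <- FALSE
  tryCatch(
    {
      fn()
      ok <- TRUE
    },
    error = function(e) {
      .mark_stage(out_dir, stage, hash, "FAILED")
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    }
  )
  if (ok) .mark_stage(out_dir, stage, hash)
  message(sprintf("[neovb] stage '%s': done", stage))
  invisible(TRUE)
}

#' Run a full synthetic experiment
#'
#' Executes simulate -> features (z-scoring) -> vb -> smooth -> stats,
#' writing per-subject artifacts (GIFTI surface and maps, NIfTI feature
#' channels), a cohort CSV, a ground-truth JSON, the inference maps and a
#' final report (significant-vertex counts per direction and overlap with
#' the planted effect). Each stage records a marker keyed by the config
#' hash: re-running with the same config skips completed stages, so deleting
#' only the stats outputs recomputes only the stats stage. The run is
#' deterministic for a fixed config.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param force recompute all stages even if up to date.
#' @return The report, invisibly (a list; also written to
#'   `report.json`).
#' @export
run_experiment <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  hash <- .config_hash(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subj_root <- file.path(out_dir, "subjects")
  stats_dir <- file.path(out_dir, "stats")

  # kept in memory across stages of a single call; stages re-load from disk
  # when a later stage runs alone (resume)
  env <- new.env(parent = emptyenv())
  ids <- sprintf("S%03d", seq_len(2L * config$sim$n_per_group))

  .run_stage(out_dir, "simulate", hash, force, function() {
    sc <- synth_cohort(config$sim)
    env$sc <- sc
    dir.create(subj_root, showWarnings = FALSE, recursive = TRUE)
    write_mesh(sc$mesh, file.path(out_dir, "mesh.surf.gii"))
    rows <- lapply(sc$cohort$subject, function(s) {
      sdir <- file.path(subj_root, s$subject_id)
      dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      paths <- write_feature_volume(s$features, sdir, prefix = "raw")
      tibble::tibble(
        subject_id = s$subject_id, group = s$group,
        pma_at_scan = s$pma_at_scan, sex = s$sex,
        dir = sdir, mask_path = paths$mask
      )
    })
    write_cohort(dplyr::bind_rows(rows), file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(
      list(
        effect_vertices = which(sc$effect_vertices),
        patch_labels = sc$labeling$labels,
        seed_vertices = sc$labeling$seed_vertices,
        params = unclass(config$sim)
      ),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE
    )
  }, outputs = c(file.path(out_dir, c("mesh.surf.gii", "cohort.csv", "ground_truth.json")),
                 file.path(subj_root, ids, "raw_mask.nii.gz")))

  load_cohort <- function() {
    if (is.null(env$sc)) env$sc <- synth_cohort(config$sim)
    env$sc
  }

  .run_stage(out_dir, "features", hash, force, function() {
    sc <- load_cohort()
    env$z <- lapply(sc$cohort$subject, zscore_subject)
    for (s in env$z) {
      write_feature_volume(s$features, file.path(subj_root, s$subject_id), prefix = "features")
    }
  }, outputs = file.path(subj_root, ids, "features_mask.nii.gz"))

  .run_stage(out_dir, "vb", hash, force, function() {
    sc <- load_cohort()
    if (is.null(env$z)) env$z <- lapply(sc$cohort$subject, zscore_subject)
    env$vb <- lapply(env$z, function(s) vb_map(s, min_neigh = config$vb_min_neigh))
    for (i in seq_along(env$z)) {
      sdir <- file.path(subj_root, env$z[[i]]$subject_id)
      save_vertex_map(file.path(sdir, "vb.func.gii"), env$vb[[i]]$vb, sc$mesh)
      save_vertex_map(file.path(sdir, "vb_nsize.func.gii"),
                      as.double(env$vb[[i]]$n_voxels), sc$mesh)
    }
  }, outputs = file.path(subj_root, ids, "vb.func.gii"))

  .run_stage(out_dir, "smooth", hash, force, function() {
    sc <- load_cohort()
    kern <- smoothing_kernel(sc$mesh, config$fwhm)
    ids <- sc$cohort$subject_id
    for (id in ids) {
      sdir <- file.path(subj_root, id)
      v <- load_vertex_map(file.path(sdir, "vb.func.gii"))
      save_vertex_map(file.path(sdir, "vb_smoothed.func.gii"),
                      smooth_map(sc$mesh, v, kernel = kern), sc$mesh)
    }
  }, outputs = file.path(subj_root, ids, "vb_smoothed.func.gii"))

  .run_stage(out_dir, "stats", hash, force, function() {
    sc <- load_cohort()
    ids <- sc$cohort$subject_id
    maps <- t(vapply(ids, function(id) {
      load_vertex_map(file.path(subj_root, id, "vb_smoothed.func.gii"))
    }, numeric(sc$mesh$vertex_count)))
    rownames(maps) <- ids
    des <- design_matrix(sc$cohort)
    res <- permutation_fwe(
      maps, des, sc$mesh, n_perm = config$n_perm, rng_seed = config$seed,
      alpha = config$alpha, m_hemis = config$m_hemis
    )
    env$res <- res
    dir.create(stats_dir, showWarnings = FALSE, recursive = TRUE)
    tb <- res$table
    save_vertex_map(file.path(stats_dir, "tstat.func.gii"), tb$t, sc$mesh)
    save_vertex_map(file.path(stats_dir, "tfce_pos.func.gii"), tb$tfce_pos, sc$mesh)
    save_vertex_map(file.path(stats_dir, "tfce_neg.func.gii"), tb$tfce_neg, sc$mesh)
    save_vertex_map(file.path(stats_dir, "p_fwe_pos.func.gii"), tb$p_fwe_pos, sc$mesh)
    save_vertex_map(file.path(stats_dir, "p_fwe_neg.func.gii"), tb$p_fwe_neg, sc$mesh)
    jsonlite::write_json(
      list(
        seed = res$rng_seed, n_perm = res$n_perm, exhaustive = res$exhaustive,
        threshold = res$threshold,
        tfce = unclass(res$tfce_params),
        null_max_pos = as.numeric(stats::quantile(res$null_max[, "pos"], c(0, .5, .95, 1))),
        null_max_neg = as.numeric(stats::quantile(res$null_max[, "neg"], c(0, .5, .95, 1)))
      ),
      file.path(stats_dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA
    )
  }, outputs = file.path(stats_dir, c("tstat.func.gii", "p_fwe_pos.func.gii",
                                      "p_fwe_neg.func.gii", "run_manifest.json")))

  # report: always refreshed from stats outputs
  sc <- load_cohort()
  p_pos <- load_vertex_map(file.path(stats_dir, "p_fwe_pos.func.gii"))
  p_neg <- load_vertex_map(file.path(stats_dir, "p_fwe_neg.func.gii"))
  thr <- sidak_threshold(config$alpha, config$m_hemis)
  sig_pos <- !is.na(p_pos) & p_pos < thr
  sig_neg <- !is.na(p_neg) & p_neg < thr
  truth <- sc$effect_vertices
  vb_miss <- tryCatch(
    sum(vapply(sc$cohort$subject_id, function(id) {
      sum(is.na(load_vertex_map(file.path(subj_root, id, "vb.func.gii"))))
    }, numeric(1))),
    error = function(e) NA_real_
  )
  report <- list(
    config_hash = hash,
    package_version = as.character(utils::packageVersion("neovb")),
    threshold = thr,
    n_sig_preterm_gt_term = sum(sig_pos),
    n_sig_term_gt_preterm = sum(sig_neg),
    n_effect_vertices = sum(truth),
    sensitivity = if (sum(truth)) sum(sig_pos & truth) / sum(truth) else NA,
    false_discovery_proportion = if (sum(sig_pos)) sum(sig_pos & !truth) / sum(sig_pos) else 0,
    total_missing_vb_vertices = vb_miss,
    seeds = list(sim = config$sim$rng_seed, inference = config$seed)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
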