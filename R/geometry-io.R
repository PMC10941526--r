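#' Read a cortical surface mesh
#'
#' Reads either a GIFTI surface (`.gii`, `.surf.gii`) or the package's
#' plain-text mesh format (`.txt`/`.mesh`, see Details). Coordinates are
#' taken to be world millimetres.
#'
#' @details The plain-text format is line-oriented:
#' ```
#' neovb-mesh 1
#' <n_vertices> <n_triangles>
#' x y z            # one line per vertex, full double precision
#' i j k            # one line per triangle, 0-based vertex indices
#' ```
#'
#' @param path file path.
#' @return A [surface_mesh()].
#' @export
load_mesh <- function(path) {
  if (!file.exists(path)) abort(sprintf("mesh file not found: '%s'.", path))
  if (grepl("\\.gii$", path, ignore.case = TRUE)) {
    .read_gifti_surface(path)
  } else {
    .read_mesh_text(path)
  }
}

#' Write a cortical surface mesh
#'
#' Format is chosen from the extension: `.gii` writes GIFTI, anything else
#' the plain-text format documented in [load_mesh()].
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(is_surface_mesh(mesh))
  if (grepl("\\.gii$", path, ignore.case = TRUE)) {
    .write_gifti_surface(mesh, path)
  } else {
    .write_mesh_text(mesh, path)
  }
  invisible(path)
}

.write_mesh_text <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("neovb-mesh 1", con)
  writeLines(sprintf("%d %d", mesh$vertex_count, nrow(mesh$triangles)), con)
  writeLines(apply(mesh$vertices, 1L, function(v) paste(sprintf("%.17g", v), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1L, paste, collapse = " "), con)
}

.read_mesh_text <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !grepl("^neovb-mesh 1", lines[1L])) {
    abort(sprintf("parse error in '%s': missing 'neovb-mesh 1' header line.", path))
  }
  counts <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]]))
  if (length(counts) != 2L || anyNA(counts)) {
    abort(sprintf("parse error in '%s': count line must be '<n_vertices> <n_triangles>'.", path))
  }
  nv <- counts[1L]; nt <- counts[2L]
  if (length(lines) < 2L + nv + nt) {
    abort(sprintf("parse error in '%s': expected %d vertex + %d triangle lines.", path, nv, nt))
  }
  vtx <- matrix(scan(text = lines[3:(2 + nv)], what = double(), quiet = TRUE),
                ncol = 3L, byrow = TRUE)
  tri <- matrix(scan(text = lines[(3 + nv):(2 + nv + nt)], what = integer(), quiet = TRUE),
                ncol = 3L, byrow = TRUE) + 1L
  surface_mesh(vtx, tri)
}

#' Save / load a per-vertex scalar map
#'
#' `.gii` paths write a GIFTI metric array; other extensions use a one-value-
#' per-line text format with `NA` for missing vertices. Both round-trip
#' finite values bit-identically and preserve missingness.
#'
#' @param path file path.
#' @param values numeric vector, one value per mesh vertex (NA = missing).
#' @param mesh optional [surface_mesh()] used to validate the length.
#' @return `save_vertex_map()` the path invisibly; `load_vertex_map()` a
#'   numeric vector.
#' @export
save_vertex_map <- function(path, values, mesh = NULL) {
  values <- as.double(values)
  if (!is.null(mesh)) {
    stopifnot(is_surface_mesh(mesh))
    if (length(values) != mesh$vertex_count) {
      abort(sprintf(
        "map length %d does not match mesh vertex count %d.",
        length(values), mesh$vertex_count
      ))
    }
  }
  if (grepl("\\.gii$", path, ignore.case = TRUE)) {
    .write_gifti_metric(values, path)
  } else {
    out <- ifelse(is.na(values), "NA", sprintf("%.17g", values))
    writeLines(c("neovb-map 1", sprintf("%d", length(values)), out), path)
  }
  invisible(path)
}

#' @rdname save_vertex_map
#' @export
load_vertex_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("vertex map not found: '%s'.", path))
  if (grepl("\\.gii$", path, ignore.case = TRUE)) {
    return(.read_gifti_metric(path))
  }
  lines <- readLines(path)
  if (length(lines) < 2L || !grepl("^neovb-map 1", lines[1L])) {
    abort(sprintf("parse error in '%s': missing 'neovb-map 1' header line.", path))
  }
  n <- as.integer(lines[2L])
  vals <- suppressWarnings(as.double(lines[3:(2 + n)]))
  if (length(vals) != n) abort(sprintf("parse error in '%s': expected %d values.", path, n))
  vals
}

#' Read a cohort table
#'
#' Reads the cohort CSV (columns `subject_id`, `group`, `pma_at_scan`,
#' `sex`, plus per-subject file-path columns) and validates the invariants
#' required downstream: unique subject ids, `group` limited to
#' preterm/term, positive PMA, and a single hemisphere per table.
#'
#' @param path CSV path.
#' @param hemisphere hemisphere label, `"L"` or `"R"`.
#' @return A tibble with class `cohort_table` and attribute `hemisphere`.
#' @export
read_cohort <- function(path, hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_cohort_table(tbl, hemisphere = hemisphere)
}

#' Validate a data frame as a cohort table
#'
#' @param tbl data frame with at least `subject_id`, `group`, `pma_at_scan`
#'   and `sex` columns.
#' @param hemisphere hemisphere label, `"L"` or `"R"`.
#' @return A tibble with class `cohort_table`.
#' @export
as_cohort_table <- function(tbl, hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  tbl <- tibble::as_tibble(tbl)
  required <- c("subject_id", "group", "pma_at_scan", "sex")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    abort(sprintf("cohort table missing columns: %s.", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(tbl$subject_id)) {
    abort("cohort table has duplicated subject_id values.")
  }
  if (!all(tbl$group %in% c("preterm", "term"))) {
    abort("`group` must be 'preterm' or 'term'.")
  }
  if (!all(tbl$pma_at_scan > 0)) abort("`pma_at_scan` must be positive (weeks).")
  if (!all(tbl$sex %in% c("M", "F"))) abort("`sex` must be 'M' or 'F'.")
  structure(tbl, class = c("cohort_table", class(tbl)), hemisphere = hemisphere)
}

#' Write a cohort table to CSV
#'
#' @param tbl cohort table (data frame).
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(tbl, path) {
  readr::write_csv(tibble::as_tibble(tbl), path)
  invisible(path)
}
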