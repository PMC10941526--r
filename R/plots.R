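# ggplot2 views of per-vertex results. Spherical meshes are flattened to
# longitude/latitude; planar meshes are drawn in their own x/y plane.

.flat_coords <- function(mesh) {
  v <- mesh$vertices
  if (diff(range(v[, 3L])) < 1e-9) {
    tibble::tibble(x = v[, 1L], y = v[, 2L], proj = "plane")
  } else {
    r <- sqrt(rowSums(v^2))
    tibble::tibble(
      x = atan2(v[, 2L], v[, 1L]) * 180 / pi,
      y = asin(pmin(pmax(v[, 3L] / r, -1), 1)) * 180 / pi,
      proj = "lonlat"
    )
  }
}

#' Plot a VB map
#'
#' Flattens the mesh (longitude/latitude for closed surfaces, native x/y
#' for planar meshes) and draws per-vertex VB values; missing vertices are
#' shown hollow.
#'
#' @param object a [vb_map()] tibble.
#' @param mesh the [surface_mesh()] the map lives on.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.vb_map <- function(object, mesh, ...) {
  xy <- .flat_coords(mesh)
  df <- dplyr::bind_cols(tibble::as_tibble(object), xy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = df[is.na(df$vb), ], shape = 1, colour = "grey60") +
    ggplot2::geom_point(
      data = df[!is.na(df$vb), ],
      ggplot2::aes(colour = .data$vb)
    ) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1), name = "VB") +
    ggplot2::labs(
      x = if (xy$proj[1L] == "lonlat") "longitude (deg)" else "x (mm)",
      y = if (xy$proj[1L] == "lonlat") "latitude (deg)" else "y (mm)",
      title = "Vogt-Bailey index"
    ) +
    ggplot2::theme_minimal()
}

#' Plot group-inference significance maps
#'
#' Shows -log10 FWE-corrected p per vertex for both one-sided contrasts.
#'
#' @param object a `group_inference_result`.
#' @param mesh the common [surface_mesh()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.group_inference_result <- function(object, mesh, ...) {
  xy <- .flat_coords(mesh)
  tb <- object$table
  df <- dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_cols(tb, xy),
                  contrast = "preterm > term", p = .data$p_fwe_pos),
    dplyr::mutate(dplyr::bind_cols(tb, xy),
                  contrast = "term > preterm", p = .data$p_fwe_neg)
  )
  df$neglogp <- -log10(df$p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$neglogp)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::scale_colour_viridis_c(name = expression(-log[10] * p)) +
    ggplot2::geom_point(
      data = df[!is.na(df$p) & df$p < object$threshold, ],
      shape = 21, colour = "red", fill = NA, size = 3
    ) +
    ggplot2::labs(
      title = "Permutation TFCE inference",
      subtitle = sprintf("FWE-corrected, threshold p < %.4f", object$threshold),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}
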