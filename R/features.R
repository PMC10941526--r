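#' Single microstructural metric map
#'
#' Light container for one scalar 3D metric grid (FA, MD, AD, RD, NDI, ODI
#' or ISO) with its affine. Bounded metrics (FA, NDI, ODI, ISO) must lie in
#' [0, 1] inside the mask; diffusivities (MD, AD, RD, in mm^2/s) must be
#' non-negative.
#'
#' @param name metric name, one of FA, MD, AD, RD, NDI, ODI, ISO (a
#'   `_mod` suffix marks tissue-fraction-modulated maps).
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-index-to-world transform.
#' @param mask optional logical 3D array; when given, range invariants are
#'   checked inside it.
#' @return An object of class `metric_map`.
#' @export
metric_map <- function(name, data, affine, mask = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) abort("`data` must be a 3D array.")
  base <- sub("_mod$", "", name)
  if (!base %in% c("FA", "MD", "AD", "RD", "NDI", "ODI", "ISO", "TF")) {
    abort(sprintf("unknown metric name '%s'.", name))
  }
  if (!is.null(mask)) {
    v <- data[mask]
    if (base %in% c("FA", "NDI", "ODI", "ISO", "TF") && any(v < -1e-9 | v > 1 + 1e-9)) {
      bad <- which(array(mask, dim(data)) & (data < -1e-9 | data > 1 + 1e-9))
      abort(sprintf(
        "%s outside [0, 1] inside the mask at %d voxels (first linear index %d, value %g).",
        name, length(bad), bad[1L], data[bad[1L]]
      ))
    }
    if (base %in% c("MD", "AD", "RD") && any(v < 0)) {
      abort(sprintf("negative %s (diffusivity) inside the mask.", name))
    }
  }
  structure(list(name = name, data = data, affine = as.matrix(affine), mask = mask),
            class = "metric_map")
}

#' Tissue fraction from the isotropic water fraction
#'
#' Returns `1 - ISO` voxel-wise: the fraction of the voxel occupied by
#' tissue rather than free water, used to modulate the NODDI NDI and ODI
#' maps so that neurite properties are weighted by actual tissue content.
#'
#' @param iso a [metric_map()] named `ISO` with values in [0, 1] in its mask.
#' @return A [metric_map()] named `TF`.
#' @export
tissue_fraction <- function(iso) {
  stopifnot(inherits(iso, "metric_map"))
  if (iso$name != "ISO") abort("`iso` must be the ISO metric map.")
  if (!is.null(iso$mask)) {
    v <- iso$data[iso$mask]
    if (any(v < -1e-9 | v > 1 + 1e-9)) {
      bad <- which(iso$mask & (iso$data < -1e-9 | iso$data > 1 + 1e-9))
      abort(sprintf(
        "ISO outside [0, 1] inside the mask at %d voxels (first linear index %d, value %g).",
        length(bad), bad[1L], iso$data[bad[1L]]
      ))
    }
  }
  metric_map("TF", 1 - iso$data, iso$affine, iso$mask)
}

#' Modulate NDI/ODI by the tissue fraction
#'
#' Voxel-wise product of a NODDI map with the tissue fraction `1 - ISO`.
#'
#' @param map a [metric_map()] named `NDI` or `ODI`.
#' @param tf the tissue-fraction [metric_map()] from [tissue_fraction()].
#' @return A [metric_map()] with `_mod` appended to the name.
#' @export
modulate <- function(map, tf) {
  stopifnot(inherits(map, "metric_map"), inherits(tf, "metric_map"))
  if (!map$name %in% c("NDI", "ODI")) abort("only NDI and ODI maps are modulated.")
  if (!identical(dim(map$data), dim(tf$data))) {
    abort(sprintf(
      "grid mismatch: %s is %s, tissue fraction is %s.",
      map$name, paste(dim(map$data), collapse = "x"), paste(dim(tf$data), collapse = "x")
    ))
  }
  if (!isTRUE(all.equal(map$affine, tf$affine, tolerance = 1e-6))) {
    abort("affine mismatch between metric map and tissue fraction.")
  }
  metric_map(paste0(map$name, "_mod"), map$data * tf$data, map$affine, map$mask)
}

#' Z-score a channel over masked voxels
#'
#' Standardises one channel to mean 0 and population SD 1 (denominator n,
#' not n-1) over the masked voxels; voxels outside the mask are set to NA.
#'
#' @param data 3D numeric array.
#' @param mask logical 3D array with at least two masked voxels.
#' @return 3D array with masked voxels standardised and the rest NA.
#' @export
zscore_channel <- function(data, mask) {
  data <- as.array(data)
  mask <- array(as.logical(mask), dim(data))
  v <- data[mask]
  if (length(v) < 2L) abort("need at least 2 masked voxels to z-score.")
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0) abort("constant channel: zero variance inside the mask.")
  out <- array(NA_real_, dim(data))
  out[mask] <- (v - mu) / sigma
  out
}

#' Stack six metric maps into a z-scored feature volume
#'
#' Assembles the per-voxel feature vector used by the searchlight: channels
#' are re-sorted to the fixed order (FA, MD, AD, RD, NDI_mod, ODI_mod),
#' each z-scored over the mask, and stacked into a [feature_volume()].
#'
#' @param maps list of exactly six [metric_map()] objects named FA, MD, AD,
#'   RD, NDI_mod and ODI_mod (any order; re-sorted by name).
#' @param mask logical 3D array of brain-tissue voxels.
#' @return A [feature_volume()] with z-scored channels.
#' @export
stack_channels <- function(maps, mask) {
  wanted <- c("FA", "MD", "AD", "RD", "NDI_mod", "ODI_mod")
  if (length(maps) != 6L) {
    abort(sprintf("expected 6 metric maps, got %d.", length(maps)))
  }
  nms <- vapply(maps, function(m) m$name, character(1))
  if (anyDuplicated(nms)) abort("duplicate metric names in `maps`.")
  if (!setequal(nms, wanted)) {
    abort(sprintf(
      "metric maps must be exactly {%s}; got {%s}. Modulate NDI/ODI first.",
      paste(wanted, collapse = ", "), paste(sort(nms), collapse = ", ")
    ))
  }
  maps <- maps[match(wanted, nms)]
  dims <- dim(maps[[1L]]$data)
  aff <- maps[[1L]]$affine
  for (m in maps[-1L]) {
    if (!identical(dim(m$data), dims)) abort(sprintf("grid mismatch for channel %s.", m$name))
    if (!isTRUE(all.equal(m$affine, aff, tolerance = 1e-6))) {
      abort(sprintf("affine mismatch for channel %s.", m$name))
    }
  }
  mask <- array(as.logical(mask), dims)
  data <- array(NA_real_, c(dims, 6L))
  for (k in 1:6) data[, , , k] <- zscore_channel(maps[[k]]$data, mask)
  # outside-mask voxels are NA by construction; feature_volume only checks
  # finiteness inside the mask
  feature_volume(data, aff, mask, channels = wanted)
}
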