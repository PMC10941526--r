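#' Multi-channel feature volume
#'
#' A `feature_volume` is a 4D grid (three spatial axes by C channels) of
#' microstructural features together with the voxel-to-world affine and the
#' brain-tissue mask. The canonical channel order is FA, MD, AD, RD and the
#' tissue-fraction-modulated NDI and ODI. Values inside the mask must be
#' finite; the affine must be invertible.
#'
#' The affine maps 0-based voxel indices (the NIfTI sform convention) to
#' world millimetres, so that a voxel's world position is the image of its
#' index, and the 27-voxel searchlight cube is symmetric about a matched
#' voxel.
#'
#' @param data 4D numeric array (X, Y, Z, C).
#' @param affine 4x4 voxel-index-to-world-mm transform.
#' @param mask logical/0-1 3D array marking brain-tissue voxels.
#' @param channels character vector of channel names.
#' @return An object of class `feature_volume`.
#' @export
feature_volume <- function(data, affine, mask,
                           channels = c("FA", "MD", "AD", "RD", "NDI_mod", "ODI_mod")) {
  data <- as.array(data)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) abort("`data` must be a 4D array (X, Y, Z, channels).")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) abort("`affine` must be 4x4.")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12) abort("`affine` is singular.")
  mask <- array(as.logical(mask), dim = dim(data)[1:3])
  if (!any(mask)) abort("empty mask: no voxels inside the brain-tissue mask.")
  if (dim(data)[4L] != length(channels)) {
    abort(sprintf("%d channels in `data` but %d channel names.", dim(data)[4L], length(channels)))
  }
  for (c_i in seq_len(dim(data)[4L])) {
    ch <- data[, , , c_i, drop = FALSE]
    if (!all(is.finite(ch[mask]))) {
      abort(sprintf("non-finite values inside the mask in channel '%s'.", channels[c_i]))
    }
  }
  structure(
    list(data = data, affine = affine, mask = mask, channels = channels,
         voxel_size = sqrt(colSums(affine[1:3, 1:3]^2))),
    class = "feature_volume"
  )
}

#' @export
print.feature_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<feature_volume> %dx%dx%d voxels, %d channels (%s), %d masked voxels\n",
    d[1L], d[2L], d[3L], d[4L], paste(x$channels, collapse = ", "), sum(x$mask)
  ))
  invisible(x)
}

#' Map world coordinates to nearest voxel indices
#'
#' Applies the inverse affine and rounds each coordinate to the nearest
#' integer, matching each surface vertex to its closest corresponding voxel.
#' Ties (fractional part exactly 0.5) round half away from zero. Returned
#' indices are 0-based (NIfTI convention) and no bounds check is applied.
#'
#' @param affine 4x4 voxel-index-to-world transform.
#' @param point_mm numeric vector of length 3 or an n x 3 matrix of world
#'   coordinates in mm.
#' @return Integer vector of length 3, or an n x 3 integer matrix.
#' @export
world_to_voxel <- function(affine, point_mm) {
  affine <- as.matrix(affine)
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12) abort("`affine` is singular.")
  single <- is.null(dim(point_mm))
  pts <- if (single) matrix(point_mm, nrow = 1L) else as.matrix(point_mm)
  if (ncol(pts) != 3L) abort("`point_mm` must have 3 coordinates per point.")
  ijk <- solve(affine, rbind(t(pts), 1))[1:3, , drop = FALSE]
  out <- t(.round_half_away(ijk))
  storage.mode(out) <- "integer"
  if (single) out[1L, ] else out
}

# round half away from zero (R's round() rounds half to even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Map voxel indices to world coordinates
#'
#' @param affine 4x4 voxel-index-to-world transform.
#' @param ijk 0-based voxel index triple or an n x 3 matrix.
#' @return World coordinates in mm (vector or n x 3 matrix).
#' @export
voxel_to_world <- function(affine, ijk) {
  single <- is.null(dim(ijk))
  idx <- if (single) matrix(ijk, nrow = 1L) else as.matrix(ijk)
  w <- t((as.matrix(affine) %*% rbind(t(idx), 1))[1:3, , drop = FALSE])
  if (single) w[1L, ] else w
}

#' Load a six-channel feature volume from NIfTI files
#'
#' Reads six single-channel metric volumes plus a brain-tissue mask, checks
#' that all grids and affines agree, and stacks them in the canonical
#' channel order.
#'
#' @param paths character vector of six NIfTI paths, in the order FA, MD,
#'   AD, RD, NDI_mod, ODI_mod (names, if present, are kept).
#' @param mask_path NIfTI path of the binary tissue mask.
#' @return A [feature_volume()].
#' @export
load_feature_volume <- function(paths, mask_path) {
  if (length(paths) != 6L) {
    abort(sprintf("expected 6 channel volumes, got %d.", length(paths)))
  }
  imgs <- lapply(paths, RNifti::readNifti)
  mask_img <- RNifti::readNifti(mask_path)
  dims <- lapply(imgs, dim)
  affs <- lapply(imgs, function(i) unclass(RNifti::xform(i)))
  ref_dim <- dims[[1L]]
  ref_aff <- affs[[1L]]
  bad <- c(
    which(!vapply(dims, identical, logical(1), ref_dim)),
    which(!vapply(affs, function(a) isTRUE(all.equal(a, ref_aff, tolerance = 1e-6, check.attributes = FALSE)), logical(1)))
  )
  if (length(bad)) {
    abort(sprintf(
      "channel volumes do not share grid/affine with channel 1: %s",
      paste(unique(paths[sort(unique(bad))]), collapse = ", ")
    ))
  }
  if (!identical(dim(mask_img)[1:3], ref_dim[1:3])) {
    abort(sprintf("mask grid %s does not match channel grid.", paste(dim(mask_img), collapse = "x")))
  }
  data <- array(0, c(ref_dim[1:3], 6L))
  for (k in 1:6) data[, , , k] <- as.array(imgs[[k]])
  nm <- names(paths)
  channels <- if (!is.null(nm) && all(nzchar(nm))) nm else c("FA", "MD", "AD", "RD", "NDI_mod", "ODI_mod")
  feature_volume(data, ref_aff, as.array(mask_img) > 0, channels = channels)
}

#' Write a 3D/4D array as NIfTI with an explicit affine
#'
#' @param data 3D or 4D numeric array.
#' @param affine 4x4 voxel-index-to-world transform.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(data, affine, path) {
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(as.matrix(affine), code = 2L))
  img <- RNifti::`qform<-`(img, structure(as.matrix(affine), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a feature_volume to per-channel NIfTI files plus a mask
#'
#' @param vol a [feature_volume()].
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return Named list with `channels` (named paths) and `mask` path.
#' @export
write_feature_volume <- function(vol, dir, prefix = "features") {
  stopifnot(inherits(vol, "feature_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(vol$channels))
  for (k in seq_along(vol$channels)) {
    paths[k] <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, vol$channels[k]))
    write_volume(vol$data[, , , k], vol$affine, paths[k])
  }
  names(paths) <- vol$channels
  mask_path <- file.path(dir, sprintf("%s_mask.nii.gz", prefix))
  write_volume(array(as.numeric(vol$mask), dim(vol$mask)), vol$affine, mask_path)
  list(channels = paths, mask = mask_path)
}
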