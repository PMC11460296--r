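#' Read a volume from NIfTI
#'
#' Loads a `.nii`/`.nii.gz` file and decomposes its affine into spacing,
#' origin and direction. Only orthonormal direction matrices are supported
#' (oblique acquisitions are fine, shear is not).
#'
#' @param path NIfTI file path
#' @return a [volume_sample()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  if (is.null(aff)) stop("volume has no geometry metadata: ", path)
  A <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(A^2))
  if (any(spacing <= 0)) stop("volume has degenerate spacing: ", path)
  direction <- sweep(A, 2, spacing, "/")
  vals <- array(as.numeric(img), dim(img)[1:3])
  volume_sample(vals, spacing, origin = aff[1:3, 4],
                direction = direction[, 1:2])
}

#' Write a volume to NIfTI
#'
#' Values and geometry round-trip losslessly within format precision
#' (float32 affine, float64 voxel data).
#'
#' @param sample a [volume_sample()]
#' @param path output path (`.nii` or `.nii.gz`)
#' @export
write_volume <- function(sample, path) {
  geom <- geometry_of(sample)
  write_nifti_array(sample$values, geom, path, datatype = "double")
}

write_nifti_array <- function(values, geom, path, datatype = "double") {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- geom$spacing
  aff <- diag(4)
  aff[1:3, 1:3] <- full_direction(geom) %*% diag(geom$spacing)
  aff[1:3, 4] <- geom$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write structure masks to NIfTI
#'
#' Either a single label volume (0 background, 1 gland, 2 PZ-within-gland)
#' or two binary files with `_gland`/`_pz` suffixes.
#'
#' @param masks a [structure_mask_set()]
#' @param path output path; for `format = "channels"` the structure name is
#'   inserted before the extension
#' @param format `"labels"` or `"channels"`
#' @export
write_masks <- function(masks, path, format = c("labels", "channels")) {
  format <- match.arg(format)
  geom <- masks$geometry
  if (format == "labels") {
    lab <- masks$gland
    if (!is.null(masks$pz)) lab <- lab + masks$pz  # PZ sits inside the gland
    write_nifti_array(lab, geom, path, datatype = "uint8")
    return(invisible(path))
  }
  stem <- sub("(\\.nii(\\.gz)?)$", "", path)
  ext <- substring(path, nchar(stem) + 1)
  if (ext == "") ext <- ".nii.gz"
  write_nifti_array(masks$gland, geom, paste0(stem, "_gland", ext), "uint8")
  if (!is.null(masks$pz))
    write_nifti_array(masks$pz, geom, paste0(stem, "_pz", ext), "uint8")
  invisible(path)
}

#' Read structure masks from a label NIfTI
#' @param path label volume written by [write_masks()] (labels format)
#' @return a [structure_mask_set()]
#' @export
read_masks <- function(path) {
  vol <- read_volume(path)
  lab <- round(vol$values)
  structure_mask_set((lab >= 1) * 1L, if (any(lab == 2)) (lab == 2) * 1L,
                     geometry_of(vol))
}
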