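#' Image containers and patient-coordinate geometry
#'
#' A `volume_sample` is the unit of all image I/O and inference: a rank-3
#' intensity grid together with voxel spacing (mm), the patient-space
#' position of the centre of voxel (0,0,0), and two orthonormal direction
#' vectors (row and column direction). The slice direction is derived as
#' their vector cross product, so only two vectors are stored.
#'
#' @param values numeric 3D array indexed (row, col, slice)
#' @param spacing numeric length-3, voxel spacing in mm (row, col, slice);
#'   all components must be positive
#' @param origin numeric length-3, patient coordinates (mm) of the centre of
#'   voxel (0,0,0)
#' @param direction 3x2 matrix whose columns are the row- and
#'   column-direction unit vectors (orthonormal within 1e-6)
#' @return an object of class `volume_sample`
#' @export
volume_sample <- function(values, spacing, origin = c(0, 0, 0),
                          direction = cbind(c(1, 0, 0), c(0, 1, 0))) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("'values' must be a rank-3 array")
  if (!all(is.finite(values))) stop("'values' must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive components")
  direction <- as.matrix(direction)
  check_direction(direction)
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin), direction = direction),
            class = "volume_sample")
}

check_direction <- function(direction) {
  if (!all(dim(direction) == c(3L, 2L)))
    stop("'direction' must be a 3x2 matrix (row and column direction)")
  g <- crossprod(direction)
  if (max(abs(g - diag(2))) > 1e-6)
    stop("direction vectors must be orthonormal within 1e-6")
  invisible(direction)
}

#' @export
print.volume_sample <- function(x, ...) {
  cat("<volume_sample> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Co-registered binary structure masks
#'
#' Holds the gland and (optionally) peripheral-zone masks on the same grid
#' as a [volume_sample()]. The PZ mask may be `NULL`: some cohorts ship no
#' peripheral-zone reference.
#'
#' @param gland binary 3D array (0/1)
#' @param pz binary 3D array or `NULL`
#' @param geometry list with `spacing`, `origin`, `direction` and `dim`
#'   matching the parent volume (see [geometry_of()])
#' @return an object of class `structure_mask_set`
#' @export
structure_mask_set <- function(gland, pz = NULL, geometry) {
  gland <- as.array(gland)
  if (!all(gland %in% c(0, 1))) stop("gland mask must be binary")
  if (!all(dim(gland) == geometry$dim))
    stop("gland mask shape does not match geometry")
  if (!is.null(pz)) {
    pz <- as.array(pz)
    if (!all(pz %in% c(0, 1))) stop("pz mask must be binary")
    if (!all(dim(pz) == dim(gland))) stop("pz mask shape mismatch")
  }
  structure(list(gland = gland, pz = pz, geometry = geometry),
            class = "structure_mask_set")
}

#' Extract the geometry block of a volume
#' @param sample a [volume_sample()]
#' @return list with `spacing`, `origin`, `direction`, `dim`
#' @export
geometry_of <- function(sample) {
  list(spacing = sample$spacing, origin = sample$origin,
       direction = sample$direction, dim = dim(sample$values))
}

#' Slice direction of a geometry
#'
#' The through-plane direction is the vector cross product of the row and
#' column direction vectors.
#' @param geometry geometry list (see [geometry_of()])
#' @return unit length-3 vector
#' @export
slice_direction <- function(geometry) {
  d <- geometry$direction
  c(d[2, 1] * d[3, 2] - d[3, 1] * d[2, 2],
    d[3, 1] * d[1, 2] - d[1, 1] * d[3, 2],
    d[1, 1] * d[2, 2] - d[2, 1] * d[1, 2])
}

full_direction <- function(geometry) {
  cbind(geometry$direction, slice_direction(geometry))
}

#' Map 0-based voxel indices to patient coordinates (mm)
#'
#' @param index numeric matrix (n x 3) of continuous 0-based (row, col,
#'   slice) indices, or a length-3 vector
#' @param geometry geometry list
#' @return n x 3 matrix of patient coordinates in mm
#' @export
index_to_patient <- function(index, geometry) {
  index <- rbind_or_matrix(index)
  R <- full_direction(geometry)
  t(R %*% (t(index) * geometry$spacing) + geometry$origin)
}

#' Map patient coordinates (mm) to continuous 0-based voxel indices
#'
#' Affine inverse of [index_to_patient()]; the two maps round-trip to within
#' 1e-9 relative for orthonormal directions.
#'
#' @param point numeric matrix (n x 3) of patient coordinates, or a
#'   length-3 vector
#' @param geometry geometry list
#' @return n x 3 matrix of continuous (row, col, slice) indices
#' @export
patient_to_index <- function(point, geometry) {
  point <- rbind_or_matrix(point)
  R <- full_direction(geometry)
  if (abs(det(R)) < 1e-12) stop("singular direction matrix")
  t(solve(R, t(point) - geometry$origin) / geometry$spacing)
}

rbind_or_matrix <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
}
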