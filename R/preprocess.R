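#' Preprocessing configuration
#'
#' Defaults follow the standard pipeline for multi-cohort prostate T2W MR:
#' resample to 0.5 x 0.5 x 3 mm with cubic B-spline interpolation, resize to
#' a 256 x 256 x 23 reference grid by symmetric centre crop/pad, clip each
#' axial slice to mean +/- 3 sd and min-max rescale it to [0, 1]. The 3D
#' network input is a centred 128 x 128 x 23 crop.
#'
#' @param target_spacing_mm length-3 resampling target (mm)
#' @param target_shape length-3 reference grid (rows, cols, slices)
#' @param crop3d_shape length-3 centred crop for the 3D member; must not
#'   exceed `target_shape` in any dimension
#' @param clip_sd slice-wise clipping width in standard deviations
#' @return a `preprocess_config` list
#' @export
preprocess_config <- function(target_spacing_mm = c(0.5, 0.5, 3),
                              target_shape = c(256, 256, 23),
                              crop3d_shape = c(128, 128, 23),
                              clip_sd = 3) {
  if (any(target_spacing_mm <= 0) || any(target_shape <= 0) ||
      any(crop3d_shape <= 0) || clip_sd <= 0)
    stop("all preprocessing config entries must be positive")
  if (any(crop3d_shape > target_shape))
    stop("crop3d_shape must not exceed target_shape")
  structure(list(target_spacing_mm = as.numeric(target_spacing_mm),
                 target_shape = as.integer(target_shape),
                 crop3d_shape = as.integer(crop3d_shape),
                 clip_sd = clip_sd),
            class = "preprocess_config")
}

#' Resample a volume (and masks) to the target spacing
#'
#' The image is interpolated with a cubic B-spline (interpolating spline via
#' the standard recursive prefilter); masks use nearest-neighbour so they
#' stay binary. The physical extent is preserved within one voxel and the
#' origin (centre of voxel (0,0,0)) is kept fixed.
#'
#' @param sample a [volume_sample()]
#' @param masks optional [structure_mask_set()] on the same grid
#' @param cfg a [preprocess_config()]
#' @return list `(volume, masks)` at the target spacing
#' @export
resample <- function(sample, masks = NULL, cfg = preprocess_config()) {
  sp_in <- sample$spacing
  sp_out <- cfg$target_spacing_mm
  if (any(sp_in <= 0)) stop("non-positive input spacing")
  d_in <- dim(sample$values)
  d_out <- pmax(1L, as.integer(round(d_in * sp_in / sp_out)))
  pos <- lapply(1:3, function(a)
    (seq_len(d_out[a]) - 1) * sp_out[a] / sp_in[a])
  v <- sample$values
  for (a in 1:3) v <- .resample_axis_bspline(v, dim(v), a - 1L, pos[[a]])
  geom <- geometry_of(sample)
  geom$spacing <- sp_out
  geom$dim <- d_out
  out_vol <- volume_sample(v, sp_out, geom$origin, geom$direction)
  out_masks <- NULL
  if (!is.null(masks)) {
    g <- .resample_nearest(masks$gland + 0, dim(masks$gland),
                           pos[[1]], pos[[2]], pos[[3]])
    p <- if (is.null(masks$pz)) NULL else
      .resample_nearest(masks$pz + 0, dim(masks$pz),
                        pos[[1]], pos[[2]], pos[[3]])
    out_masks <- structure_mask_set(g, p, geom)
  }
  list(volume = out_vol, masks = out_masks)
}

#' Crop/pad to the standard reference shape
#'
#' Symmetric centre crop or pad at fixed spacing (images pad with their
#' minimum intensity, masks with 0). The applied offsets are recorded so
#' predictions can be mapped back to the original grid: `offsets[k]` is the
#' 0-based index in the *input* grid of the first output voxel along axis k
#' (negative when padding).
#'
#' @param sample a [volume_sample()] already at target spacing
#' @param masks optional [structure_mask_set()]
#' @param cfg a [preprocess_config()]
#' @return list `(volume, masks, offsets, input_dim)`
#' @export
standardize_shape <- function(sample, masks = NULL,
                              cfg = preprocess_config()) {
  d_in <- dim(sample$values)
  d_out <- cfg$target_shape
  offsets <- as.integer(floor((d_in - d_out) / 2))
  pad_val <- min(sample$values)
  v <- crop_pad(sample$values, offsets, d_out, pad_val)
  geom <- geometry_of(sample)
  geom$dim <- d_out
  geom$origin <- as.numeric(index_to_patient(as.numeric(offsets), geom))
  out_vol <- volume_sample(v, geom$spacing, geom$origin, geom$direction)
  out_masks <- NULL
  if (!is.null(masks)) {
    g <- crop_pad(masks$gland, offsets, d_out, 0L)
    p <- if (is.null(masks$pz)) NULL
         else crop_pad(masks$pz, offsets, d_out, 0L)
    out_masks <- structure_mask_set(g, p, geom)
  }
  list(volume = out_vol, masks = out_masks, offsets = offsets,
       input_dim = d_in)
}

crop_pad <- function(arr, offsets, d_out, pad_val) {
  d_in <- dim(arr)
  storage.mode(pad_val) <- storage.mode(arr)
  out <- array(pad_val, d_out)
  src <- lapply(1:3, function(a) {
    i <- (seq_len(d_out[a]) - 1) + offsets[a]
    i[i >= 0 & i <= d_in[a] - 1] + 1L
  })
  dst <- lapply(1:3, function(a) {
    i <- seq_len(d_out[a]) - 1
    which((i + offsets[a]) >= 0 & (i + offsets[a]) <= d_in[a] - 1)
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Undo [standardize_shape()] for a mask
#'
#' Places a mask predicted on the reference grid back onto the pre-crop grid
#' (regions cropped away come back as 0).
#'
#' @param mask binary array of shape `target_shape`
#' @param offsets,input_dim as returned by [standardize_shape()]
#' @return binary array of shape `input_dim`
#' @export
unstandardize_mask <- function(mask, offsets, input_dim) {
  crop_pad(mask, -as.integer(offsets), as.integer(input_dim), 0L)
}

#' Slice-wise intensity normalization
#'
#' Per axial slice independently: clip to mean +/- `clip_sd` standard
#' deviations of that slice, then min-max rescale to [0, 1]. Constant
#' slices map to all-zero.
#'
#' @param sample a [volume_sample()]
#' @param cfg a [preprocess_config()]
#' @return normalized [volume_sample()]
#' @export
normalize_intensity <- function(sample, cfg = preprocess_config()) {
  v <- sample$values
  for (s in seq_len(dim(v)[3])) {
    sl <- v[, , s]
    m <- mean(sl)
    sd_s <- stats::sd(as.numeric(sl))
    if (!is.finite(sd_s) || sd_s == 0) {
      v[, , s] <- 0
      next
    }
    sl <- pmin(pmax(sl, m - cfg$clip_sd * sd_s), m + cfg$clip_sd * sd_s)
    lo <- min(sl); hi <- max(sl)
    v[, , s] <- if (hi > lo) (sl - lo) / (hi - lo) else 0
  }
  volume_sample(v, sample$spacing, sample$origin, sample$direction)
}

#' Split a standardized volume into per-slice 2D training pairs
#'
#' @param sample standardized [volume_sample()]
#' @param masks [structure_mask_set()] on the same grid (optional)
#' @return list with one element per axial slice:
#'   `list(image, gland, pz)` 2D arrays (masks `NULL` when absent)
#' @export
extract_2d_slices <- function(sample, masks = NULL) {
  d <- dim(sample$values)
  lapply(seq_len(d[3]), function(s) {
    list(image = sample$values[, , s],
         gland = if (is.null(masks)) NULL else masks$gland[, , s],
         pz = if (is.null(masks) || is.null(masks$pz)) NULL
              else masks$pz[, , s])
  })
}

#' Centred 3D crop for the volumetric network
#'
#' @param sample standardized [volume_sample()]
#' @param masks optional [structure_mask_set()]
#' @param cfg a [preprocess_config()]
#' @return list `(volume, masks, offsets)`; offsets are 0-based input
#'   indices of the crop corner, for paste-back
#' @export
crop_3d <- function(sample, masks = NULL, cfg = preprocess_config()) {
  d_in <- dim(sample$values)
  d_out <- cfg$crop3d_shape
  if (any(d_out > d_in)) stop("3D crop larger than the volume")
  offsets <- as.integer((d_in - d_out) %/% 2)
  idx <- lapply(1:3, function(a) offsets[a] + seq_len(d_out[a]))
  geom <- geometry_of(sample)
  geom$dim <- d_out
  geom$origin <- as.numeric(index_to_patient(as.numeric(offsets), geom))
  v <- sample$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out_masks <- NULL
  if (!is.null(masks)) {
    g <- masks$gland[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    p <- if (is.null(masks$pz)) NULL
         else masks$pz[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    out_masks <- structure_mask_set(g, p, geom)
  }
  list(volume = volume_sample(v, geom$spacing, geom$origin, geom$direction),
       masks = out_masks, offsets = offsets)
}

#' Full preprocessing pipeline for one case
#'
#' resample -> standardize_shape -> normalize_intensity, returning
#' everything needed for inference and for mapping predictions back to the
#' original geometry.
#'
#' @param sample a [volume_sample()]
#' @param masks optional [structure_mask_set()]
#' @param cfg a [preprocess_config()]
#' @return list `(volume, masks, offsets, resampled_dim, original)` where
#'   `original` records the input spacing/dim/geometry
#' @export
preprocess_case <- function(sample, masks = NULL, cfg = preprocess_config()) {
  orig <- geometry_of(sample)
  rs <- resample(sample, masks, cfg)
  st <- standardize_shape(rs$volume, rs$masks, cfg)
  vol <- normalize_intensity(st$volume, cfg)
  list(volume = vol, masks = st$masks, offsets = st$offsets,
       resampled_dim = st$input_dim, original = orig)
}

#' Map a predicted mask on the reference grid back to original geometry
#'
#' Reverses the centre crop/pad and nearest-neighbour-resamples back to the
#' original voxel grid.
#'
#' @param mask binary array on the reference grid
#' @param pre result of [preprocess_case()] for the same case
#' @param cfg the [preprocess_config()] used
#' @return binary array with the original volume's dimensions
#' @export
restore_mask <- function(mask, pre, cfg = preprocess_config()) {
  m <- unstandardize_mask(mask, pre$offsets, pre$resampled_dim)
  sp_out <- pre$original$spacing
  sp_in <- cfg$target_spacing_mm
  d_orig <- pre$original$dim
  pos <- lapply(1:3, function(a)
    (seq_len(d_orig[a]) - 1) * sp_out[a] / sp_in[a])
  .resample_nearest(m + 0, dim(m), pos[[1]], pos[[2]], pos[[3]])
}
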