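#' Specification of a synthetic prostate phantom
#'
#' Describes one synthetic T2-like volume: an ellipsoid-like gland with a
#' smooth band-limited boundary deformation, a posterior-crescent peripheral
#' zone strictly inside the gland, a cohort intensity profile, and additive
#' Gaussian noise. Defaults emulate the ranges seen across public prostate
#' T2W cohorts: gland volumes of roughly 25-70 cm^3, PZ taking 20-35% of the
#' gland, in-plane spacing well below the 2-4.5 mm slice thickness.
#'
#' @param grid_shape integer length-3 voxel counts (row, col, slice); every
#'   dimension must be at least 8
#' @param spacing_mm positive length-3 voxel spacing in mm
#' @param gland_volume_cm3 target gland volume in cm^3
#' @param pz_fraction target PZ volume as a fraction of gland volume,
#'   strictly in (0, 1)
#' @param gland_axis_ratios positive length-3 ellipsoid anisotropy
#'   (row : col : slice semi-axes)
#' @param deformation_amplitude nonnegative strength of the smooth radial
#'   boundary perturbation (relative units; 0 = exact ellipsoid)
#' @param intensity_profile `"bimodal_heavy_tail"` (background peak plus a
#'   bright tissue mode with a log-normal right tail) or
#'   `"unimodal_low_contrast"` (all regions compressed near zero)
#' @param noise_sd nonnegative additive Gaussian noise sd
#' @param seed integer seed controlling geometry and intensities
#' @param noise_seed optional integer seed for the intensity/noise draw only
#'   (defaults to `seed`); cohort generation uses it to vary noise while
#'   keeping geometry fixed
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 20),
                         spacing_mm = c(0.5, 0.5, 3),
                         gland_volume_cm3 = 55,
                         pz_fraction = 0.28,
                         gland_axis_ratios = c(1.05, 1, 0.85),
                         deformation_amplitude = 0.08,
                         intensity_profile = "bimodal_heavy_tail",
                         noise_sd = 0.04,
                         seed = 1L,
                         noise_seed = NULL) {
  spec <- list(grid_shape = as.integer(grid_shape),
               spacing_mm = as.numeric(spacing_mm),
               gland_volume_cm3 = gland_volume_cm3,
               pz_fraction = pz_fraction,
               gland_axis_ratios = as.numeric(gland_axis_ratios),
               deformation_amplitude = deformation_amplitude,
               intensity_profile = intensity_profile,
               noise_sd = noise_sd,
               seed = as.integer(seed),
               noise_seed = if (is.null(noise_seed)) as.integer(seed)
                            else as.integer(noise_seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 8L))
    stop("grid_shape must have 3 dimensions, each >= 8")
  if (any(spec$spacing_mm <= 0)) stop("all spacing components must be > 0")
  if (!(spec$pz_fraction > 0 && spec$pz_fraction < 1))
    stop("pz_fraction must lie strictly between 0 and 1")
  if (spec$gland_volume_cm3 <= 0) stop("gland_volume_cm3 must be positive")
  if (any(spec$gland_axis_ratios <= 0)) stop("axis ratios must be positive")
  if (spec$deformation_amplitude < 0) stop("deformation_amplitude must be >= 0")
  if (!spec$intensity_profile %in%
      c("bimodal_heavy_tail", "unimodal_low_contrast"))
    stop("unknown intensity_profile '", spec$intensity_profile, "'")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  invisible(spec)
}

#' Largest gland volume realizable on a phantom grid
#'
#' The deformed ellipsoid must stay inside the voxel-centre bounding box;
#' this returns the corresponding volume ceiling in cm^3.
#' @param spec a [phantom_spec()]
#' @return volume in cm^3
#' @export
max_feasible_volume <- function(spec) {
  half_extent <- (spec$grid_shape - 1) / 2 * spec$spacing_mm
  margin <- 1 + spec$deformation_amplitude * 2.5   # worst-case perturbation
  s_max <- min(half_extent / (spec$gland_axis_ratios * margin))
  4 / 3 * pi * s_max^3 * prod(spec$gland_axis_ratios) / 1000
}

#' Generate one synthetic prostate phantom
#'
#' Builds the gland as a smoothly deformed ellipsoid (largest 6-connected
#' component kept), carves the peripheral zone as the posterior outer shell
#' of the gland sized to `pz_fraction`, and synthesizes intensities from the
#' chosen cohort profile plus Gaussian noise. Identical spec and seed give
#' bit-identical output.
#'
#' @param spec a [phantom_spec()]
#' @return list with elements `volume` ([volume_sample()]) and `masks`
#'   ([structure_mask_set()]); the spec is attached as attribute
#'   `"phantom_spec"` on the volume
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  target_mm3 <- spec$gland_volume_cm3 * 1000
  r <- spec$gland_axis_ratios
  s <- (3 * target_mm3 / (4 * pi * prod(r)))^(1 / 3)
  axes <- s * r
  half_extent <- (spec$grid_shape - 1) / 2 * spec$spacing_mm
  if (any(axes * (1 + spec$deformation_amplitude * 2.5) > half_extent)) {
    stop(sprintf(
      "requested gland volume %.1f cm^3 does not fit on the grid; maximum feasible volume is %.1f cm^3",
      spec$gland_volume_cm3, max_feasible_volume(spec)))
  }

  d <- spec$grid_shape
  sp <- spec$spacing_mm
  cr <- (seq_len(d[1]) - 1 - (d[1] - 1) / 2) * sp[1]
  cc <- (seq_len(d[2]) - 1 - (d[2] - 1) / 2) * sp[2]
  cz <- (seq_len(d[3]) - 1 - (d[3] - 1) / 2) * sp[3]
  X <- array(cr, d)
  Y <- array(rep(cc, each = d[1]), d)
  Z <- array(rep(cz, each = d[1] * d[2]), d)

  rho <- sqrt((X / axes[1])^2 + (Y / axes[2])^2 + (Z / axes[3])^2)
  g_env <- with_seed(spec$seed, {
    cf <- stats::rnorm(6)
    cf / sqrt(sum(cf^2))
  })
  theta <- atan2(Y, X)
  zn <- (Z / axes[3]) / pmax(rho, 1e-9)
  phi <- acos(pmin(pmax(zn, -1), 1))
  f <- g_env[1] * cos(theta) + g_env[2] * sin(theta) +
    g_env[3] * cos(2 * theta) + g_env[4] * sin(2 * theta) +
    g_env[5] * cos(phi) + g_env[6] * sin(phi)
  gland <- (rho <= 1 + spec$deformation_amplitude * f) * 1L

  lab <- .label_components(as.integer(gland), dim(gland))
  gland <- (lab == 1L) * 1L

  # posterior crescent: among posterior-half gland voxels, the outer shell
  # (largest normalized radius) sized to the requested fraction
  n_gland <- sum(gland)
  target_pz <- round(spec$pz_fraction * n_gland)
  eligible <- which(gland == 1L & X > 0)
  pz <- array(0L, d)
  if (length(eligible) > 0 && target_pz > 0) {
    take <- min(target_pz, length(eligible))
    ord <- order(rho[eligible], decreasing = TRUE)
    pz[eligible[ord[seq_len(take)]]] <- 1L
  }

  values <- phantom_intensities(gland, pz, spec$intensity_profile,
                                spec$noise_sd, spec$noise_seed)
  geom <- list(spacing = sp, origin = c(0, 0, 0),
               direction = cbind(c(1, 0, 0), c(0, 1, 0)),
               dim = d)
  vol <- volume_sample(values, sp, origin = geom$origin,
                       direction = geom$direction)
  attr(vol, "phantom_spec") <- spec
  masks <- structure_mask_set(gland, pz, geom)
  list(volume = vol, masks = masks)
}

# Region intensity model. Raw values live roughly in [0, 1.6]; the heavy
# right tail of the bimodal profile comes from a log-normal bright
# subpopulation inside the gland.
phantom_intensities <- function(gland, pz, profile, noise_sd, seed) {
  pars <- switch(profile,
    bimodal_heavy_tail = list(bg = c(0.06, 0.03), tz = c(0.40, 0.07),
                              pz = c(0.60, 0.07), tail_frac = 0.08,
                              tail_meanlog = log(0.85), tail_sdlog = 0.25),
    unimodal_low_contrast = list(bg = c(0.05, 0.02), tz = c(0.12, 0.03),
                                 pz = c(0.16, 0.03), tail_frac = 0),
    stop("unknown intensity_profile '", profile, "'"))
  with_seed(seed, {
    v <- array(0, dim(gland))
    regions <- list(bg = which(gland == 0L),
                    tz = which(gland == 1L & pz == 0L),
                    pz = which(pz == 1L))
    for (nm in names(regions)) {
      idx <- regions[[nm]]
      if (length(idx))
        v[idx] <- stats::rnorm(length(idx), pars[[nm]][1], pars[[nm]][2])
    }
    if (pars$tail_frac > 0) {
      gl <- which(gland == 1L)
      nb <- round(pars$tail_frac * length(gl))
      if (nb > 0) {
        bright <- gl[sample.int(length(gl), nb)]
        v[bright] <- stats::rlnorm(nb, pars$tail_meanlog, pars$tail_sdlog)
      }
    }
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    pmax(v, 0)
  })
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Sampler of phantom specs for cohort generation
#'
#' Returns a closure drawing gland volumes from a truncated normal and PZ
#' fractions uniformly from a range, on top of a fixed base spec. Specs come
#' back with `seed = NA`, signalling [generate_cohort()] to assign
#' deterministic per-case seeds.
#'
#' @param base_spec template [phantom_spec()]
#' @param mean_volume,sd_volume gland volume distribution (cm^3)
#' @param pz_fraction_range length-2 range of PZ fractions
#' @param min_volume lower truncation bound (cm^3)
#' @return function() returning a `phantom_spec`
#' @export
cohort_spec_sampler <- function(base_spec = phantom_spec(),
                                mean_volume = 50, sd_volume = 12,
                                pz_fraction_range = c(0.2, 0.35),
                                min_volume = 15) {
  max_vol <- 0.95 * max_feasible_volume(base_spec)
  function() {
    v <- stats::rnorm(1, mean_volume, sd_volume)
    v <- min(max(v, min_volume), max_vol)
    sp <- base_spec
    sp$gland_volume_cm3 <- v
    sp$pz_fraction <- stats::runif(1, pz_fraction_range[1],
                                   pz_fraction_range[2])
    sp$seed <- NA_integer_
    sp
  }
}

#' Generate a cohort of phantoms
#'
#' Draws `n` independent phantoms. Per-case seeds are derived
#' deterministically from the master seed; a spec returned by the sampler
#' with a concrete `seed` keeps its geometry seed and only the
#' intensity/noise seed is varied per case.
#'
#' @param n number of phantoms (>= 1)
#' @param spec_sampler function() returning a [phantom_spec()]; defaults to
#'   [cohort_spec_sampler()] defaults
#' @param seed master integer seed
#' @return list of `n` elements, each `list(volume, masks)`
#' @export
generate_cohort <- function(n, spec_sampler = cohort_spec_sampler(),
                            seed = 1L) {
  if (n < 1) stop("'n' must be >= 1")
  with_seed(seed, {
    case_seeds <- sample.int(2147483646L, 2 * n)
    specs <- lapply(seq_len(n), function(i) spec_sampler())
    lapply(seq_len(n), function(i) {
      sp <- specs[[i]]
      if (is.na(sp$seed)) sp$seed <- case_seeds[i]
      sp$noise_seed <- case_seeds[n + i]
      generate_phantom(sp)
    })
  })
}

#' Remap a cohort's intensities to a target profile
#'
#' Re-synthesizes voxel intensities from each case's masks under the target
#' cohort profile; geometry and masks are untouched. Used to manufacture
#' domain-shifted test cohorts.
#'
#' @param cohort list of `list(volume, masks)` as from [generate_cohort()]
#' @param profile target intensity profile name
#' @return cohort with remapped volumes
#' @export
shift_cohort_intensity <- function(cohort, profile) {
  if (length(cohort) == 0) stop("cohort must be nonempty")
  if (!profile %in% c("bimodal_heavy_tail", "unimodal_low_contrast"))
    stop("unknown intensity_profile '", profile, "'")
  lapply(cohort, function(case) {
    spec <- attr(case$volume, "phantom_spec")
    nseed <- if (is.null(spec)) 104729L else spec$noise_seed + 104729L
    noise_sd <- if (is.null(spec)) 0.04 else spec$noise_sd
    pz <- if (is.null(case$masks$pz)) array(0L, dim(case$masks$gland))
          else case$masks$pz
    vals <- phantom_intensities(case$masks$gland, pz, profile, noise_sd,
                                nseed)
    vol <- volume_sample(vals, case$volume$spacing, case$volume$origin,
                         case$volume$direction)
    if (!is.null(spec)) {
      spec$intensity_profile <- profile
      attr(vol, "phantom_spec") <- spec
    }
    list(volume = vol, masks = case$masks)
  })
}
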