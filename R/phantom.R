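#' Specification of a synthetic PET phantom
#'
#' Describes a digital phantom: hot ellipsoidal lesions on a low uniform
#' background, blurred by an isotropic Gaussian point-spread function (PSF)
#' emulating scanner resolution, with optional voxel noise. The noiseless,
#' pre-blur voxel values are exactly `background_suv` outside every lesion
#' and `background_suv * uptake_contrast` inside, so every downstream stage
#' has an analytic ground truth.
#'
#' @param grid_shape integer length-3, voxels per axis (all >= 8).
#' @param voxel_spacing numeric length-3, mm per axis (> 0).
#' @param lesions list of lesions, each a list with `center` (0-based voxel
#'   coordinates), `semi_axes` (mm, length 3 or scalar) and
#'   `uptake_contrast` (lesion:background SUV ratio, > 1).
#' @param background_suv background SUV (> 0).
#' @param psf_fwhm isotropic Gaussian PSF full width at half maximum, mm
#'   (>= 0; 0 disables blurring).
#' @param noise one of `"none"`, `"gaussian"` (additive, SD =
#'   `noise_scale`), or `"scaled_poisson"` (draw Poisson with mean
#'   `value / noise_scale`, multiply back by `noise_scale`; approximates
#'   count statistics and is monotone in the mean).
#' @param noise_scale scale parameter of the noise model.
#' @param injected_activity_MBq,body_weight_g nominal acquisition metadata
#'   attached to the phantom; only their ratio matters to SUV, so the
#'   defaults (10 MBq, 25 g — a typical mouse scan) are inert conventions.
#' @param tracer,timepoint metadata tags, see [acquisition_meta()].
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' sp <- phantom_spec(c(24, 24, 24), lesions = list(
#'   list(center = c(12, 12, 12), semi_axes = 4, uptake_contrast = 8)))
#' ph <- make_phantom(sp, seed = 1)
#' ph$volume
phantom_spec <- function(grid_shape = c(32, 32, 32),
                         voxel_spacing = c(1, 1, 1),
                         lesions = list(),
                         background_suv = 1,
                         psf_fwhm = 1,
                         noise = c("none", "gaussian", "scaled_poisson"),
                         noise_scale = 0,
                         injected_activity_MBq = 10,
                         body_weight_g = 25,
                         tracer = "FDG",
                         timepoint = "baseline") {
  noise <- match.arg(noise)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("'grid_shape' must be three integers, all >= 8")
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3)
  if (any(voxel_spacing <= 0)) stop("'voxel_spacing' must be positive")
  if (!is.numeric(background_suv) || background_suv <= 0)
    stop("'background_suv' must be positive")
  if (!is.numeric(psf_fwhm) || psf_fwhm < 0)
    stop("'psf_fwhm' must be >= 0")
  if (noise != "none" && (!is.numeric(noise_scale) || noise_scale <= 0))
    stop("'noise_scale' must be > 0 for noise model ", noise)
  extent <- (grid_shape - 1) * voxel_spacing
  for (i in seq_along(lesions)) {
    le <- lesions[[i]]
    if (is.null(le$center) || is.null(le$semi_axes) ||
        is.null(le$uptake_contrast))
      stop("lesion ", i, " must have center, semi_axes and uptake_contrast")
    sa <- as.numeric(le$semi_axes)
    if (length(sa) == 1L) sa <- rep(sa, 3)
    if (any(sa <= 0)) stop("lesion ", i, ": semi_axes must be positive")
    if (le$uptake_contrast <= 1)
      stop("lesion ", i, ": uptake_contrast must exceed 1")
    # lesion, dilated by 2*psf_fwhm, must fit inside the grid
    lo <- le$center * voxel_spacing - sa - 2 * psf_fwhm
    hi <- le$center * voxel_spacing + sa + 2 * psf_fwhm
    if (any(lo < 0) || any(hi > extent))
      stop("lesion ", i, " (dilated by 2*psf_fwhm) extends outside the grid")
    lesions[[i]]$semi_axes <- sa
  }
  structure(list(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
                 lesions = lesions, background_suv = background_suv,
                 psf_fwhm = psf_fwhm, noise = noise,
                 noise_scale = noise_scale,
                 injected_activity_MBq = injected_activity_MBq,
                 body_weight_g = body_weight_g,
                 tracer = tracer, timepoint = timepoint),
            class = "phantom_spec")
}

# separable 3D Gaussian blur; kernel truncated at 3.5 sigma, edges replicated
# so a uniform field stays uniform
.gauss_blur3d <- function(arr, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(arr)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    sv <- sigma / spacing[ax]
    r <- max(1L, as.integer(ceiling(3.5 * sv)))
    k <- exp(-((-r:r)^2) / (2 * sv^2))
    k <- k / sum(k)
    n <- dim(arr)[ax]
    out <- array(0, dim(arr))
    for (j in -r:r) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)   # replicate edges
      shifted <- switch(ax,
                        arr[idx, , , drop = FALSE],
                        arr[, idx, , drop = FALSE],
                        arr[, , idx, drop = FALSE])
      out <- out + k[j + r + 1] * shifted
    }
    arr <- out
  }
  arr
}

# binary ellipsoid rasterization: voxel is inside when its center satisfies
# sum(((x - c) / a)^2) <= 1 (boundary counted inside, matching the MTV
# voxel-counting convention)
.ellipsoid_mask <- function(grid_shape, spacing, center_vox, semi_axes_mm) {
  cx <- (seq_len(grid_shape[1]) - 1 - center_vox[1]) * spacing[1]
  cy <- (seq_len(grid_shape[2]) - 1 - center_vox[2]) * spacing[2]
  cz <- (seq_len(grid_shape[3]) - 1 - center_vox[3]) * spacing[3]
  qx <- (cx / semi_axes_mm[1])^2
  qy <- (cy / semi_axes_mm[2])^2
  qz <- (cz / semi_axes_mm[3])^2
  q <- outer(outer(qx, qy, `+`), qz, `+`)
  q <= 1
}

#' Generate a synthetic PET phantom with ground truth
#'
#' Rasterizes the lesions of a [phantom_spec()] onto the voxel grid
#' (a voxel belongs to a lesion when its center lies inside the ellipsoid),
#' applies the Gaussian PSF, then adds noise. Returns both the simulated
#' volume and the exact pre-blur binary truth mask.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed; generation is reproducible bit-for-bit.
#' @return A list of class `pet_phantom` with elements `volume`
#'   (an [image_volume()] in SUV units), `truth` (a [lesion_mask()]), and
#'   `spec`.
#' @export
make_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- array(FALSE, spec$grid_shape)
  vals <- array(spec$background_suv, spec$grid_shape)
  for (le in spec$lesions) {
    m <- .ellipsoid_mask(spec$grid_shape, spec$voxel_spacing,
                         le$center, le$semi_axes)
    truth <- truth | m
    vals[m] <- pmax(vals[m], spec$background_suv * le$uptake_contrast)
  }
  vals <- .gauss_blur3d(vals, spec$psf_fwhm, spec$voxel_spacing)
  if (spec$noise != "none") {
    set.seed(as.integer(seed %% .Machine$integer.max))
    vals <- switch(spec$noise,
      gaussian = vals + stats::rnorm(length(vals), 0, spec$noise_scale),
      scaled_poisson = spec$noise_scale *
        stats::rpois(length(vals), vals / spec$noise_scale))
    vals <- array(pmax(vals, 0), spec$grid_shape)
  }
  meta <- acquisition_meta(spec$injected_activity_MBq, spec$body_weight_g,
                           tracer = spec$tracer, timepoint = spec$timepoint)
  structure(list(
    volume = image_volume(vals, spacing = spec$voxel_spacing,
                          units = "suv", meta = meta),
    truth = lesion_mask(truth, spacing = spec$voxel_spacing),
    spec = spec), class = "pet_phantom")
}

#' @export
print.pet_phantom <- function(x, ...) {
  cat("Synthetic PET phantom (", length(x$spec$lesions), " lesion(s), ",
      "PSF ", x$spec$psf_fwhm, " mm FWHM, noise: ", x$spec$noise, ")\n",
      sep = "")
  print(x$volume)
  print(x$truth)
  invisible(x)
}

#' Write a phantom to disk (NIfTI volume + truth mask + JSON sidecar)
#'
#' @param ph a `pet_phantom` from [make_phantom()].
#' @param dir output directory (created if needed).
#' @param stem filename stem.
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(ph, dir, stem = "phantom") {
  stopifnot(inherits(ph, "pet_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pv <- file.path(dir, paste0(stem, ".nii.gz"))
  pm <- file.path(dir, paste0(stem, "_truth.nii.gz"))
  pj <- file.path(dir, paste0(stem, ".json"))
  write_volume(ph$volume, pv)
  write_volume(ph$truth, pm)
  write_meta_sidecar(ph$volume$meta, pj, units = "suv")
  invisible(c(volume = pv, truth = pm, meta = pj))
}
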