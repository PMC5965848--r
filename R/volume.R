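#' PET image volume
#'
#' Container for a 3D scalar voxel grid with physical spacing and optional
#' acquisition metadata. Values are either raw activity concentration
#' (kBq/mL) or already-normalized standardized uptake values (SUV); the
#' `units` tag records which, and conversion is performed lazily by
#' [to_suv()] rather than at construction or read time.
#'
#' The internal axis order is (x, y, z): `values[i, j, k]` is the voxel at
#' 0-based lattice coordinate (i-1, j-1, k-1), whose center sits at physical
#' position `(i - 1) * spacing[1]` mm along x, and so on. No axis
#' reordering or resampling ever happens behind the caller's back.
#'
#' @param values numeric 3D array of finite, non-negative voxel values.
#' @param spacing numeric length-3, voxel spacing in mm per axis, all > 0.
#' @param units `"suv"` or `"activity_concentration"`.
#' @param meta an [acquisition_meta()] object, or `NULL`. Required
#'   (eventually) when `units = "activity_concentration"`, since the SUV
#'   conversion needs injected activity and body weight.
#' @return An object of class `image_volume`.
#' @seealso [acquisition_meta()], [lesion_mask()], [read_volume()], [to_suv()]
#' @export
#' @examples
#' vol <- image_volume(array(1, c(8, 8, 8)), spacing = c(1, 1, 1))
#' vol
image_volume <- function(values, spacing = c(1, 1, 1),
                         units = c("suv", "activity_concentration"),
                         meta = NULL) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (!all(is.finite(values)))
    stop("voxel values must all be finite")
  if (any(values < 0))
    stop("voxel values must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive finite numbers (mm)")
  if (!is.null(meta) && !inherits(meta, "acquisition_meta"))
    stop("'meta' must be an acquisition_meta object or NULL")
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, units = units,
                 meta = meta),
            class = "image_volume")
}

#' PET acquisition metadata
#'
#' Injected activity and animal body weight, the two quantities the SUV
#' normalization needs, plus tracer and timepoint tags. Decay correction is
#' assumed to have been applied upstream by the scanner pipeline; none is
#' performed here.
#'
#' @param injected_activity_MBq injected radioactivity, MBq (> 0).
#' @param body_weight_g animal body weight, g (> 0).
#' @param tracer tracer label, `"FDG"`, `"FLT"` or `"other"`.
#' @param timepoint `"baseline"` or `"post"`.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(injected_activity_MBq, body_weight_g,
                             tracer = c("FDG", "FLT", "other"),
                             timepoint = c("baseline", "post")) {
  tracer <- match.arg(tracer)
  timepoint <- match.arg(timepoint)
  if (!is.numeric(injected_activity_MBq) || length(injected_activity_MBq) != 1L ||
      !is.finite(injected_activity_MBq) || injected_activity_MBq <= 0)
    stop("'injected_activity_MBq' must be a single positive number")
  if (!is.numeric(body_weight_g) || length(body_weight_g) != 1L ||
      !is.finite(body_weight_g) || body_weight_g <= 0)
    stop("'body_weight_g' must be a single positive number")
  structure(list(injected_activity_MBq = as.numeric(injected_activity_MBq),
                 body_weight_g = as.numeric(body_weight_g),
                 tracer = tracer, timepoint = timepoint),
            class = "acquisition_meta")
}

#' Binary lesion mask
#'
#' A binary voxel grid congruent with a parent [image_volume()]: same shape,
#' same spacing. The empty mask is valid.
#'
#' @param values logical (or 0/1) 3D array.
#' @param spacing numeric length-3 voxel spacing, mm.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(values, spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1)))
      stop("numeric mask values must be 0 or 1")
    values <- array(values != 0, dim(values))
  }
  if (!is.logical(values)) stop("'values' must be logical or 0/1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive finite numbers (mm)")
  structure(list(values = values, spacing = spacing), class = "lesion_mask")
}

# shared congruence check used by segmentation and quantification
check_congruent <- function(vol, mask) {
  if (!identical(dim(vol$values), dim(mask$values)))
    stop("volume and mask shapes differ: (",
         paste(dim(vol$values), collapse = "x"), ") vs (",
         paste(dim(mask$values), collapse = "x"), ")")
  if (max(abs(vol$spacing - mask$spacing)) > 1e-9)
    stop("volume and mask voxel spacings differ")
  invisible(TRUE)
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat("PET image volume: ", paste(d, collapse = " x "), " voxels, spacing ",
      paste(format(x$spacing), collapse = " x "), " mm\n", sep = "")
  cat("  units: ", x$units,
      if (x$units == "suv") "" else " (kBq/mL)", "\n", sep = "")
  cat("  value range: [", format(min(x$values)), ", ",
      format(max(x$values)), "]\n", sep = "")
  if (!is.null(x$meta))
    cat("  meta: ", x$meta$tracer, ", ", x$meta$timepoint, ", ",
        format(x$meta$injected_activity_MBq), " MBq injected, ",
        format(x$meta$body_weight_g), " g\n", sep = "")
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("Lesion mask: ", paste(dim(x$values), collapse = " x "),
      " voxels, ", sum(x$values), " in mask (",
      format(sum(x$values) * prod(x$spacing)), " mm^3)\n", sep = "")
  invisible(x)
}

# voxel volume in mm^3
voxel_volume <- function(x) prod(x$spacing)
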