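#' Convert activity concentration to standardized uptake value
#'
#' SUV normalizes tissue radioactivity by the injected activity per unit
#' body mass: `SUV = concentration / (injected activity / body weight)`,
#' with the conventional 1 g = 1 mL tissue-density assumption. Voxels in
#' kBq/mL, injected activity in MBq and weight in g are scaled so that a
#' tracer distributed uniformly over the whole body gives SUV = 1
#' everywhere. No decay correction is applied (assumed done upstream).
#' Already-converted volumes pass through unchanged.
#'
#' @param vol an [image_volume()]; `units = "activity_concentration"`
#'   requires `meta` with injected activity and body weight.
#' @return An [image_volume()] with `units = "suv"`.
#' @export
#' @examples
#' m <- acquisition_meta(10, 25)
#' conc <- array(10 * 1000 / 25, c(8, 8, 8))   # uniform whole-body kBq/mL
#' v <- image_volume(conc, units = "activity_concentration", meta = m)
#' range(to_suv(v)$values)                      # 1 1
to_suv <- function(vol) {
  stopifnot(inherits(vol, "image_volume"))
  if (vol$units == "suv") return(vol)
  if (is.null(vol$meta))
    stop("SUV conversion requires acquisition metadata ",
         "(injected_activity_MBq, body_weight_g)")
  act_kBq <- vol$meta$injected_activity_MBq * 1000
  suv <- vol$values * vol$meta$body_weight_g / act_kBq
  image_volume(suv, spacing = vol$spacing, units = "suv", meta = vol$meta)
}

#' Per-lesion uptake metrics
#'
#' Computes the uptake summary of one segmented lesion: SUVmax and SUVmean
#' over the mask, metabolic tumor volume (MTV, the physical volume of the
#' mask in mm^3), and total lesion glycolysis (TLG, for FDG) or total
#' lesion proliferation (TLP, for FLT), defined as `SUVmean * MTV`. An
#' empty mask yields MTV = 0 with the SUV fields flagged `NA` rather than
#' an error.
#'
#' @param vol an [image_volume()] in SUV units.
#' @param mask a [lesion_mask()] congruent with `vol`.
#' @param tracer `"FDG"` or `"FLT"`; only names the `SUVmean * MTV`
#'   product (TLG vs TLP). Defaults to the volume's metadata tracer.
#' @param timepoint timepoint tag carried along; defaults to metadata.
#' @return An object of class `lesion_metrics`: list with `suv_max`,
#'   `suv_mean`, `mtv`, `total_lesion`, `total_lesion_name`, `tracer`,
#'   `timepoint`, `n_voxels`.
#' @export
lesion_metrics <- function(vol, mask, tracer = NULL, timepoint = NULL) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "lesion_mask"))
  if (vol$units != "suv")
    stop("'vol' must be in SUV units; call to_suv() first")
  check_congruent(vol, mask)
  if (is.null(tracer))
    tracer <- if (!is.null(vol$meta)) vol$meta$tracer else "FDG"
  if (is.null(timepoint))
    timepoint <- if (!is.null(vol$meta)) vol$meta$timepoint else "baseline"
  n <- sum(mask$values)
  if (n == 0L) {
    suv_max <- NA_real_; suv_mean <- NA_real_; mtv <- 0
  } else {
    inside <- vol$values[mask$values]
    suv_max <- max(inside)
    suv_mean <- mean(inside)
    mtv <- n * voxel_volume(mask)
  }
  total <- if (n == 0L) 0 else suv_mean * mtv
  structure(list(suv_max = suv_max, suv_mean = suv_mean, mtv = mtv,
                 total_lesion = total,
                 total_lesion_name = if (identical(tracer, "FLT")) "TLP"
                                     else "TLG",
                 tracer = tracer, timepoint = timepoint,
                 n_voxels = as.integer(n)),
            class = "lesion_metrics")
}

#' @export
print.lesion_metrics <- function(x, ...) {
  cat("Lesion metrics (", x$tracer, ", ", x$timepoint, ")\n", sep = "")
  cat(sprintf("  SUVmax  %8.4g\n  SUVmean %8.4g\n  MTV     %8.4g mm^3\n",
              x$suv_max, x$suv_mean, x$mtv))
  cat(sprintf("  %s     %8.4g SUV*mm^3  (%d voxels)\n",
              x$total_lesion_name, x$total_lesion, x$n_voxels))
  invisible(x)
}

#' Longitudinal percentage change of lesion metrics
#'
#' For each metric, `100 * (post - pre) / pre`. A delta is defined only
#' when its baseline value is strictly positive; otherwise that delta is
#' `NA` and the others are still computed. Deltas are scale-free in the
#' underlying SUV calibration.
#'
#' @param pre,post [lesion_metrics()] at baseline and post-treatment; must
#'   share a tracer.
#' @return An object of class `delta_metrics`: list with `d_suv_max`,
#'   `d_suv_mean`, `d_mtv`, `d_total_lesion`, `tracer`.
#' @export
#' @examples
#' pre <- structure(list(suv_max = 10, suv_mean = 5, mtv = 50,
#'   total_lesion = 250, tracer = "FDG"), class = "lesion_metrics")
#' post <- structure(list(suv_max = 1.131, suv_mean = 2.5, mtv = 125,
#'   total_lesion = 312.5, tracer = "FDG"), class = "lesion_metrics")
#' pct_change(pre, post)$d_suv_max    # -88.69
pct_change <- function(pre, post) {
  stopifnot(inherits(pre, "lesion_metrics"),
            inherits(post, "lesion_metrics"))
  if (!identical(pre$tracer, post$tracer))
    stop("pre and post metrics are from different tracers (",
         pre$tracer, " vs ", post$tracer, ")")
  one <- function(a, b) {
    if (is.na(a) || a <= 0) NA_real_ else 100 * (b - a) / a
  }
  structure(list(d_suv_max = one(pre$suv_max, post$suv_max),
                 d_suv_mean = one(pre$suv_mean, post$suv_mean),
                 d_mtv = one(pre$mtv, post$mtv),
                 d_total_lesion = one(pre$total_lesion, post$total_lesion),
                 tracer = pre$tracer),
            class = "delta_metrics")
}

#' @export
print.delta_metrics <- function(x, ...) {
  cat("Percentage change, baseline -> post (", x$tracer, ")\n", sep = "")
  cat(sprintf("  dSUVmax %+8.2f %%\n  dSUVmean %+7.2f %%\n", x$d_suv_max,
              x$d_suv_mean))
  cat(sprintf("  dMTV    %+8.2f %%\n  dTL     %+8.2f %%\n", x$d_mtv,
              x$d_total_lesion))
  invisible(x)
}
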