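#' Read a PET volume from NIfTI or a DICOM series
#'
#' Reads a 3D volume with its voxel spacing from either a NIfTI-1 file
#' (`.nii` / `.nii.gz`) or a directory containing the slices of one DICOM
#' series. Acquisition metadata (injected activity, body weight, tracer,
#' timepoint) is not part of either format in any standardized way for
#' preclinical scans, so it travels in a JSON sidecar; see
#' [read_meta_sidecar()] for its schema.
#'
#' Axis handling is deliberately conservative: the voxel grid is returned in
#' the file's native (x, y, z) order, spacing is taken from the header, and
#' obliquely oriented volumes are rejected rather than silently resampled.
#' DICOM slices are sorted by their position along the slice normal, so a
#' shuffled directory listing yields the same volume as a sorted one.
#'
#' @param path NIfTI file, or directory of single-series DICOM slices.
#' @param meta_path optional JSON sidecar path. If absent, the volume is
#'   returned without metadata and with `units = "suv"` only when the
#'   sidecar explicitly declares it; otherwise units default to
#'   `"activity_concentration"` when metadata is present and `"suv"` when
#'   nothing is known (the value-passthrough convention for phantoms).
#' @param units override the units tag; one of `"suv"`,
#'   `"activity_concentration"` or `NULL` (infer as described above).
#' @return An [image_volume()].
#' @export
read_volume <- function(path, meta_path = NULL, units = NULL) {
  if (dir.exists(path)) {
    vd <- read_dicom_series(path)
    values <- vd$values
    spacing <- vd$spacing
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L)
      stop("expected a 3D volume, got ", length(dim(img)), " dimensions")
    values <- array(as.numeric(img), dim(img))
    spacing <- abs(RNifti::pixdim(img))[seq_len(3)]
  }
  meta <- NULL
  declared_units <- NULL
  if (!is.null(meta_path)) {
    sc <- read_meta_sidecar(meta_path)
    meta <- sc$meta
    declared_units <- sc$units
  }
  if (is.null(units)) {
    units <- if (!is.null(declared_units)) declared_units
             else if (!is.null(meta)) "activity_concentration" else "suv"
  }
  image_volume(values, spacing = spacing, units = units, meta = meta)
}

#' Write a PET volume (or mask) as NIfTI
#'
#' Volumes are written as float32, masks as uint8. Header spacing equals the
#' object's spacing to float32 precision.
#'
#' @param vol an [image_volume()] or [lesion_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "lesion_mask")) {
    arr <- array(as.integer(vol$values), dim(vol$values))
    dt <- "uint8"
  } else if (inherits(vol, "image_volume")) {
    arr <- vol$values
    dt <- "float"
  } else stop("'vol' must be an image_volume or lesion_mask")
  if (length(arr) == 0L) stop("refusing to write an empty volume")
  if (!dir.exists(dirname(path)))
    stop("output directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI file holding a 0/1 volume.
#' @return A [lesion_mask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  if (!all(vals %in% c(0, 1)))
    stop("mask file contains values other than 0/1")
  lesion_mask(array(vals != 0, dim(vals)),
              spacing = abs(RNifti::pixdim(img))[seq_len(3)])
}

#' Read / write the JSON metadata sidecar
#'
#' Schema: `{"injected_activity_MBq": , "body_weight_g": , "tracer": ,
#' "timepoint": , "units": }`, where `units` is optional and declares how
#' the voxel values of the companion volume are to be interpreted.
#'
#' @param path JSON file path.
#' @return For the reader, a list with elements `meta`
#'   ([acquisition_meta()] or `NULL`) and `units` (string or `NULL`).
#' @export
read_meta_sidecar <- function(path) {
  if (!file.exists(path)) stop("no such metadata file: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- NULL
  if (!is.null(j$injected_activity_MBq) && !is.null(j$body_weight_g)) {
    meta <- acquisition_meta(
      injected_activity_MBq = j$injected_activity_MBq,
      body_weight_g = j$body_weight_g,
      tracer = if (is.null(j$tracer)) "other" else j$tracer,
      timepoint = if (is.null(j$timepoint)) "baseline" else j$timepoint)
  }
  list(meta = meta, units = j$units)
}

#' @rdname read_meta_sidecar
#' @param meta an [acquisition_meta()].
#' @param units optional units declaration to embed.
#' @export
write_meta_sidecar <- function(meta, path, units = NULL) {
  x <- list(injected_activity_MBq = meta$injected_activity_MBq,
            body_weight_g = meta$body_weight_g,
            tracer = meta$tracer, timepoint = meta$timepoint)
  if (!is.null(units)) x$units <- units
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
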