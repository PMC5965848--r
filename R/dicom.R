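# Minimal single-series DICOM reader.
#
# Scope: axis-aligned, single-frame, uncompressed slices in implicit or
# explicit VR little endian (the form preclinical scanners export). Enough
# header is parsed to recover geometry and rescaled pixel values; everything
# else is skipped. Multi-series directories, oblique orientations and
# non-uniform slice spacing are rejected rather than guessed at.

# transfer syntaxes we accept
.ts_implicit <- "1.2.840.10008.1.2"
.ts_explicit <- "1.2.840.10008.1.2.1"

.u16 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
          endian = "little", signed = FALSE)
}
.u32 <- function(raw, off) {
  v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
               endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

# parse one element at byte offset `off` (0-based); returns list(group,
# element, value_offset, value_length, next_offset, vr)
.dcm_element <- function(raw, off, explicit) {
  group <- .u16(raw, off)
  elem <- .u16(raw, off + 2)
  if (explicit && group != 0xFFFE) {
    vr <- rawToChar(raw[(off + 5):(off + 6)])
    if (vr %in% c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")) {
      len <- .u32(raw, off + 8)
      voff <- off + 12
    } else {
      len <- .u16(raw, off + 6)
      voff <- off + 8
    }
  } else {
    vr <- NA_character_
    len <- .u32(raw, off + 4)
    voff <- off + 8
  }
  if (len == 4294967295) {                       # undefined length
    if (!is.na(vr) && vr != "SQ" && !(group == 0x7FE0 && elem == 0x0010))
      stop("undefined length on non-sequence element")
    # scan for the sequence delimitation item (FFFE,E0DD)
    pos <- voff
    repeat {
      if (pos + 8 > length(raw)) stop("unterminated undefined-length element")
      g <- .u16(raw, pos); e <- .u16(raw, pos + 2)
      if (g == 0xFFFE && e == 0xE0DD) { nxt <- pos + 8; break }
      il <- .u32(raw, pos + 4)
      if (il == 4294967295) stop("nested undefined-length items unsupported")
      pos <- pos + 8 + il
    }
    len <- NA_integer_
  } else nxt <- voff + len
  list(group = group, element = elem, vr = vr,
       value_offset = voff, length = len, next_offset = nxt)
}

.dcm_string <- function(raw, el) {
  if (is.na(el$length) || el$length == 0) return("")
  b <- raw[(el$value_offset + 1):(el$value_offset + el$length)]
  b <- b[b != as.raw(0)]                          # UI values are NUL-padded
  trimws(rawToChar(b))
}

.dcm_ds <- function(raw, el) {
  s <- .dcm_string(raw, el)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

# parse the tags this reader needs from one Part-10 file
.parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM Part-10 file: ", path)
  off <- 132
  # file meta group (0002) is always explicit VR little endian
  ts <- .ts_explicit
  repeat {
    if (off + 8 > length(raw)) stop("truncated DICOM meta header: ", path)
    if (.u16(raw, off) != 0x0002) break
    el <- .dcm_element(raw, off, explicit = TRUE)
    if (el$element == 0x0010) ts <- .dcm_string(raw, el)
    off <- el$next_offset
  }
  explicit <- switch(ts, `1.2.840.10008.1.2` = FALSE,
                     `1.2.840.10008.1.2.1` = TRUE,
                     stop("unsupported transfer syntax ", ts, " in ", path))
  out <- list(rescale_slope = 1, rescale_intercept = 0,
              pixel_representation = 0L)
  while (off + 8 <= length(raw)) {
    el <- .dcm_element(raw, off, explicit = explicit)
    key <- sprintf("%04X%04X", el$group, el$element)
    switch(key,
      "0020000E" = out$series_uid <- .dcm_string(raw, el),
      "00200032" = out$ipp <- .dcm_ds(raw, el),
      "00200037" = out$iop <- .dcm_ds(raw, el),
      "00280010" = out$rows <- .u16(raw, el$value_offset),
      "00280011" = out$cols <- .u16(raw, el$value_offset),
      "00280030" = out$pixel_spacing <- .dcm_ds(raw, el),
      "00280100" = out$bits_allocated <- .u16(raw, el$value_offset),
      "00280103" = out$pixel_representation <- .u16(raw, el$value_offset),
      "00281052" = out$rescale_intercept <- .dcm_ds(raw, el)[1],
      "00281053" = out$rescale_slope <- .dcm_ds(raw, el)[1],
      "7FE00010" = {
        out$pixel_data_offset <- el$value_offset
        out$pixel_data_length <- el$length
      },
      NULL)
    off <- el$next_offset
  }
  for (need in c("rows", "cols", "pixel_spacing", "bits_allocated",
                 "pixel_data_offset"))
    if (is.null(out[[need]])) stop("missing required DICOM tag (", need,
                                   ") in ", path)
  nb <- out$bits_allocated / 8
  if (!nb %in% c(1, 2)) stop("unsupported BitsAllocated ", out$bits_allocated)
  n <- out$rows * out$cols
  px <- readBin(raw[(out$pixel_data_offset + 1):
                    (out$pixel_data_offset + n * nb)],
                "integer", n = n, size = nb, endian = "little",
                signed = (out$pixel_representation == 1))
  out$pixels <- px * out$rescale_slope + out$rescale_intercept
  out
}

#' Read a directory of DICOM slices as one volume
#'
#' Slices are sorted by their position along the slice normal, so the file
#' naming order does not matter. All slices must belong to one series, share
#' in-plane geometry, and be uniformly spaced (1% tolerance on the
#' slice-to-slice gap).
#'
#' @param dir directory containing the `.dcm` files of one series.
#' @return list with `values` (3D array, x fastest) and `spacing` (mm).
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory ", dir)
  slices <- lapply(files, .parse_dicom_file)
  uids <- vapply(slices, function(s)
    if (is.null(s$series_uid)) "" else s$series_uid, "")
  if (length(unique(uids)) > 1L)
    stop("directory mixes ", length(unique(uids)),
         " DICOM series; expected exactly one")
  dims <- vapply(slices, function(s) c(s$cols, s$rows), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("slices disagree on in-plane dimensions")
  # orientation: require axis-aligned rows/cols (identity up to sign)
  for (s in slices) {
    if (!is.null(s$iop)) {
      if (max(abs(abs(s$iop) - c(1, 0, 0, 0, 1, 0))) > 1e-3)
        stop("oblique DICOM orientation not supported; resample upstream")
    }
  }
  # sort by position along z (slice normal for axis-aligned volumes)
  zpos <- vapply(seq_along(slices), function(i) {
    if (!is.null(slices[[i]]$ipp)) slices[[i]]$ipp[3] else as.numeric(i)
  }, 0)
  ord <- order(zpos)
  slices <- slices[ord]
  zpos <- zpos[ord]
  nz <- length(slices)
  if (nz > 1) {
    gaps <- diff(zpos)
    if (any(gaps <= 0)) stop("duplicate or non-increasing slice positions")
    med <- stats::median(gaps)
    bad <- which(abs(gaps - med) / med > 0.01)
    if (length(bad))
      stop(sprintf(paste0("non-uniform slice spacing: gap %.6g mm between ",
                          "slices %d and %d (expected %.6g mm)"),
                   gaps[bad[1]], bad[1], bad[1] + 1, med))
    dz <- med
  } else dz <- 1
  nx <- slices[[1]]$cols; ny <- slices[[1]]$rows
  vals <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz))
    vals[, , k] <- matrix(slices[[k]]$pixels, nrow = nx, ncol = ny)
  # PixelSpacing is (between-rows, between-columns) = (y, x)
  ps <- slices[[1]]$pixel_spacing
  list(values = vals, spacing = c(ps[2], ps[1], dz))
}
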