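# Generate a DICOM test series with pydicom (an independent writer, so the
# package's reader is never checked against its own output).

make_dicom_series <- function(dir, values, spacing = c(1, 1, 1),
                              series_uids = NULL, filenames = NULL,
                              z_positions = NULL) {
  d <- dim(values)
  if (is.null(z_positions)) z_positions <- (seq_len(d[3]) - 1) * spacing[3]
  if (is.null(series_uids)) series_uids <- rep("1.2.826.0.1.999999.1", d[3])
  if (is.null(filenames))
    filenames <- sprintf("slice%03d.dcm", seq_len(d[3]))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(dir = dir, nx = d[1], ny = d[2], nz = d[3],
                            spacing = spacing,
                            values = as.integer(values),
                            filenames = filenames,
                            series_uids = series_uids,
                            z_positions = z_positions),
                       cfg, auto_unbox = TRUE, digits = NA)
  out <- system2("python", c(testthat::test_path("make_dicom.py"), cfg),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("pydicom fixture generation failed: ", paste(out, collapse = "\n"))
  invisible(dir)
}
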