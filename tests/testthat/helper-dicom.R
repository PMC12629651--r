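# Writes a minimal explicit-VR little-endian DICOM Part-10 file in pure R,
# used as the independent fixture for the metadata reader.

dicom_element_raw <- function(group, elem, vr, value) {
  val <- if (is.raw(value)) value else charToRaw(as.character(value))
  if (length(val) %% 2L == 1L)
    val <- c(val, as.raw(if (vr == "UI") 0L else 0x20))
  c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
    writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
    charToRaw(vr),
    writeBin(length(val), raw(), size = 2, endian = "little"),
    val)
}

write_minimal_dicom <- function(path, study_uid = "1.2.3.4",
                                n_frames = 30, frame_rate = 50,
                                heart_rate = NULL, pixel_spacing = NULL,
                                include_frame_rate = TRUE) {
  body <- c(
    dicom_element_raw(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dicom_element_raw(0x0008, 0x0060, "CS", "US"),
    dicom_element_raw(0x0020, 0x000D, "UI", study_uid),
    dicom_element_raw(0x0028, 0x0008, "IS", as.character(n_frames))
  )
  if (include_frame_rate)
    body <- c(body, dicom_element_raw(0x0018, 0x0040, "IS",
                                      as.character(frame_rate)))
  if (!is.null(heart_rate))
    body <- c(body, dicom_element_raw(0x0018, 0x1088, "IS",
                                      as.character(heart_rate)))
  if (!is.null(pixel_spacing))
    body <- c(body, dicom_element_raw(0x0028, 0x0030, "DS",
                                      paste(pixel_spacing, pixel_spacing,
                                            sep = "\\")))
  writeBin(c(raw(128), charToRaw("DICM"), body), path)
  invisible(path)
}
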