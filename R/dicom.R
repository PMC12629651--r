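# Minimal DICOM Part-10 metadata reader.
#
# Only a handful of public header attributes are needed to seed a
# Recording (study UID, frame count, frame rate, heart rate); vendor
# private tags carrying raw image data are out of scope. Supporting just
# explicit-VR little-endian keeps the reader small and auditable.

dicom_short_vrs <- c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO",
                     "LT","PN","SH","SL","SS","ST","TM","UI","UL","US")

read_uint <- function(raw, n) {
  sum(as.numeric(raw[seq_len(n)]) * 256^(seq_len(n) - 1))
}

#' Extract recording metadata from a DICOM file
#'
#' Reads the public header of an explicit-VR little-endian DICOM Part-10
#' file and returns a metadata-only [echo_recording()] (no masks;
#' modality/view left `"unknown"` for downstream classification).
#' Recognized attributes: Study Instance UID (0020,000D), Number of Frames
#' (0028,0008), Cine Rate (0018,0040), Frame Time (0018,1063, ms),
#' Recommended Display Frame Rate (0008,2144), Heart Rate (0018,1088) and
#' Pixel Spacing (0028,0030). A missing frame-rate attribute flags the
#' recording (`frame_rate_missing` attribute) rather than failing.
#'
#' @param path DICOM file path.
#' @param recording_id identifier for the resulting recording; defaults to
#'   the file name.
#' @return an [echo_recording()] with attributes `study_uid` and
#'   `frame_rate_missing`.
#' @export
ingest_dicom_metadata <- function(path, recording_id = basename(path)) {
  if (!file.exists(path)) ep_stop(sprintf("file not found: %s", path), "path")
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    ep_stop(sprintf("not a DICOM Part-10 file: %s", path), "path",
            class = "echopipe_dicom_error")
  pos <- 133L
  tags <- list()
  repeat {
    if (pos > length(raw)) break
    if (pos + 7L > length(raw))
      ep_stop("truncated DICOM element header", "path", path,
              class = "echopipe_dicom_error")
    group <- read_uint(raw[pos:(pos + 1L)], 2); elem <- read_uint(raw[(pos + 2L):(pos + 3L)], 2)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% dicom_short_vrs) {
      len <- read_uint(raw[(pos + 6L):(pos + 7L)], 2)
      vstart <- pos + 8L
    } else {
      if (pos + 11L > length(raw))
        ep_stop("truncated DICOM element header", "path", path,
                class = "echopipe_dicom_error")
      len <- read_uint(raw[(pos + 8L):(pos + 11L)], 4)
      vstart <- pos + 12L
      if (len == 4294967295)  # undefined length (sequences): unsupported
        ep_stop("undefined-length DICOM sequences are not supported", "path",
                path, class = "echopipe_dicom_error")
    }
    if (vstart + len - 1L > length(raw))
      ep_stop("truncated DICOM value field", "path", path,
              class = "echopipe_dicom_error")
    key <- sprintf("%04x,%04x", group, elem)
    if (group == 0x7fe0 && elem == 0x0010) break  # pixel data: stop
    val <- raw[seq.int(vstart, length.out = len)]
    tags[[key]] <- switch(
      vr,
      UI = , CS = , LO = , SH = , IS = , DS =
        trimws(rawToChar(val[val != as.raw(0)]), which = "both"),
      US = read_uint(val, 2),
      UL = read_uint(val, 4),
      NULL
    )
    pos <- vstart + len
  }
  num <- function(key) {
    v <- tags[[key]]
    if (is.null(v)) return(NULL)
    v <- suppressWarnings(as.numeric(strsplit(as.character(v), "\\\\")[[1]][1]))
    if (is.na(v)) NULL else v
  }
  study_uid <- tags[["0020,000d"]] %||% ""
  n_frames <- num("0028,0008") %||% 1
  frame_rate <- num("0018,0040") %||% num("0008,2144")
  if (is.null(frame_rate)) {
    ft <- num("0018,1063")
    if (!is.null(ft) && ft > 0) frame_rate <- 1000 / ft
  }
  frame_rate_missing <- is.null(frame_rate)
  spacing <- num("0028,0030") %||% 1
  rec <- echo_recording(
    recording_id = recording_id, modality = "unknown", view = "unknown",
    frame_rate = frame_rate %||% 1, n_frames = n_frames,
    pixel_spacing = spacing, heart_rate = num("0018,1088")
  )
  attr(rec, "study_uid") <- study_uid
  attr(rec, "frame_rate_missing") <- frame_rate_missing
  rec
}
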