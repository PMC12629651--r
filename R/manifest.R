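# Manifest I/O.
#
# A manifest is a JSON file describing exams -> recordings -> frames.
# Frame indices are stored 0-based in the file (language-neutral) and
# converted to 1-based indices in the R API. Masks are stored either as
# 8-bit binary PNG files (0/255) referenced by relative path, or inline as
# row-major run-length encodings ("rle"). The schema is versioned via the
# top-level "schema_version" field.

MANIFEST_SCHEMA_VERSION <- "1.0"

#' Write an exam manifest
#'
#' Serializes a list of exams to a JSON manifest. With
#' `mask_encoding = "png"` the mask stacks are written as one PNG file per
#' frame under `<manifest stem>_masks/<study>/<recording>/`, referenced by
#' relative path; with `"rle"` they are inlined as run-length encodings.
#'
#' @param exams list of [exam_record()] objects.
#' @param path output JSON path.
#' @param mask_encoding `"png"` (default) or `"rle"`.
#' @return `path`, invisibly.
#' @seealso [read_manifest()]
#' @export
write_manifest <- function(exams, path, mask_encoding = c("png", "rle")) {
  mask_encoding <- match.arg(mask_encoding)
  if (!is.list(exams) || !all(vapply(exams, inherits, logical(1), "exam_record")))
    ep_stop("exams must be a list of exam_record objects", "exams")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  mask_root <- paste0(tools::file_path_sans_ext(basename(path)), "_masks")

  ser_rec <- function(ex, rec) {
    masks <- NULL
    for (nm in names(rec$masks)) {
      stack <- rec$masks[[nm]]
      if (is.null(stack)) next
      frames <- which(!vapply(stack, is.null, logical(1)))
      if (!length(frames)) next
      entry <- list(frames = as.list(frames - 1L))
      if (mask_encoding == "png") {
        reldir <- file.path(mask_root, ex$study_uid, rec$recording_id)
        dir.create(file.path(dirname(path), reldir), recursive = TRUE,
                   showWarnings = FALSE)
        files <- sprintf("%s/%s_f%05d.png", reldir, nm, frames - 1L)
        for (i in seq_along(frames)) {
          m <- stack[[frames[i]]]
          png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)),
                        file.path(dirname(path), files[i]))
        }
        entry$files <- as.list(files)
      } else {
        entry$rle <- lapply(frames, function(f) rle_encode_mask(stack[[f]]))
      }
      masks[[nm]] <- entry
    }
    truth <- rec$truth
    if (!is.null(truth)) {
      for (k in c("ed_frames", "es_frames"))
        if (!is.null(truth[[k]])) truth[[k]] <- as.list(as.integer(truth[[k]]) - 1L)
    }
    list(
      recording_id = rec$recording_id, modality = rec$modality, view = rec$view,
      view_confidence = if (is.na(rec$view_confidence)) NULL else rec$view_confidence,
      frame_rate = rec$frame_rate, heart_rate = rec$heart_rate,
      n_frames = rec$n_frames, pixel_spacing = rec$pixel_spacing,
      cycle_starts = as.list(rec$cycle_starts - 1L),
      regional_quality = if (is.null(rec$regional_quality)) NULL else as.list(rec$regional_quality),
      masks = masks, truth = truth
    )
  }

  doc <- list(
    schema_version = MANIFEST_SCHEMA_VERSION,
    mask_encoding = mask_encoding,
    exams = lapply(exams, function(ex) list(
      study_uid = ex$study_uid,
      patient = unclass(ex$patient),
      recordings = lapply(ex$recordings, function(r) ser_rec(ex, r))
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an exam manifest
#'
#' Parses and fully validates a JSON manifest written by
#' [write_manifest()] (or by hand following the same schema). Every type
#' invariant — enum membership, positive spacing, unique recording ids,
#' matching mask geometry — is checked; violations raise errors naming the
#' offending exam/recording and field.
#'
#' @param path manifest JSON path.
#' @return list of [exam_record()] objects.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) ep_stop(sprintf("manifest not found: %s", path), "path")
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version))
    ep_stop("manifest lacks schema_version", "schema_version", path)
  enc <- doc$mask_encoding %||% "png"
  base <- dirname(path)

  num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)
  ivec <- function(x) if (is.null(x)) integer() else
    vapply(x, function(e) as.integer(e), integer(1))

  parse_stack <- function(entry, n_frames, where) {
    frames <- ivec(entry$frames) + 1L
    stack <- vector("list", n_frames)
    if (!is.null(entry$files)) {
      for (i in seq_along(frames)) {
        fp <- file.path(base, entry$files[[i]])
        if (!file.exists(fp))
          ep_stop(sprintf("mask file not found: %s", fp), "masks", where)
        img <- png::readPNG(fp)
        if (length(dim(img)) == 3L) img <- img[, , 1]
        stack[[frames[i]]] <- img > 0.5
      }
    } else if (!is.null(entry$rle)) {
      for (i in seq_along(frames))
        stack[[frames[i]]] <- rle_decode_mask(entry$rle[[i]])
    } else {
      ep_stop("mask stack entry has neither 'files' nor 'rle'", "masks", where)
    }
    stack
  }

  parse_rec <- function(r, study_uid) {
    where <- paste(study_uid, r$recording_id %||% "?", sep = ":")
    n_frames <- as.integer(r$n_frames %||% ep_stop("n_frames missing", "n_frames", where))
    masks <- list()
    for (nm in names(r$masks %||% list()))
      masks[[nm]] <- parse_stack(r$masks[[nm]], n_frames, where)
    truth <- r$truth
    if (!is.null(truth)) {
      for (k in c("ed_frames", "es_frames"))
        if (!is.null(truth[[k]])) truth[[k]] <- ivec(truth[[k]]) + 1L
      for (k in c("modality", "view"))
        if (!is.null(truth[[k]])) truth[[k]] <- as.character(truth[[k]])
      if (!is.null(truth$timing_available))
        truth$timing_available <- isTRUE(truth$timing_available)
      if (!is.null(truth$timing_offset_frames))
        truth$timing_offset_frames <- as.integer(truth$timing_offset_frames)
    }
    echo_recording(
      recording_id = as.character(r$recording_id),
      modality = as.character(r$modality),
      view = as.character(r$view %||% "unknown"),
      view_confidence = if (is.null(r$view_confidence)) NA_real_ else as.numeric(r$view_confidence),
      frame_rate = as.numeric(r$frame_rate),
      heart_rate = num_or_null(r$heart_rate),
      n_frames = n_frames,
      pixel_spacing = as.numeric(r$pixel_spacing),
      cycle_starts = ivec(r$cycle_starts) + 1L,
      regional_quality = if (is.null(r$regional_quality)) NULL else
        vapply(r$regional_quality, as.numeric, numeric(1)),
      masks = masks, truth = truth
    )
  }

  lapply(doc$exams %||% list(), function(e) {
    p <- e$patient
    exam_record(
      study_uid = as.character(e$study_uid),
      patient = patient_info(as.character(p$patient_id), as.character(p$sex),
                            as.numeric(p$height), as.numeric(p$weight)),
      recordings = lapply(e$recordings %||% list(), parse_rec,
                          study_uid = as.character(e$study_uid))
    )
  })
}
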