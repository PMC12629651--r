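#' Patient attributes
#'
#' Height and weight feed the Mosteller body-surface-area formula and sex
#' selects the ECG-based end-systole regression. Plausibility bounds are
#' enforced at construction so downstream formulas never see physically
#' impossible inputs.
#'
#' @param patient_id opaque identifier string.
#' @param sex `"male"` or `"female"`.
#' @param height body height in cm; must lie in (30, 260).
#' @param weight body weight in kg; must lie in (1, 400).
#' @return an object of class `patient_info`.
#' @export
patient_info <- function(patient_id, sex, height, weight) {
  if (!is.character(patient_id) || length(patient_id) != 1L || !nzchar(patient_id))
    ep_stop("patient_id must be a non-empty string", "patient_id")
  check_enum(sex, c("male", "female"), "sex", patient_id)
  check_scalar_number(height, "height", patient_id, lower = 30, upper = 260)
  check_scalar_number(weight, "weight", patient_id, lower = 1, upper = 400)
  structure(list(patient_id = patient_id, sex = sex,
                 height = as.numeric(height), weight = as.numeric(weight)),
            class = "patient_info")
}

#' One echocardiographic recording (clip)
#'
#' A recording is one stored clip of an exam: its imaging modality, B-mode
#' view label with classifier confidence, frame geometry, heart rate from
#' the ECG trace, cycle annotations, optional regional image-quality
#' scores, and up to four per-frame binary mask stacks: a primary and a
#' secondary (independent second segmenter, used for Dice QC) stack for
#' each of the left ventricle and left atrium.
#'
#' Frame indices in the R API are 1-based; the on-disk manifest stores them
#' 0-based (see [read_manifest()]). Mask stacks are lists of length
#' `n_frames` whose entries are logical matrices (row-major image grids,
#' origin top-left) or `NULL` where no segmentation exists for that frame.
#'
#' @param recording_id identifier, unique within its exam.
#' @param modality one of [echo_modalities()].
#' @param view one of [echo_views()]; `"unknown"` until classified.
#' @param view_confidence classifier confidence in \[0, 1\] (`NA` if
#'   unclassified).
#' @param frame_rate acquisition frame rate, Hz.
#' @param heart_rate heart rate in bpm from the ECG trace, or `NULL` when
#'   no ECG was recorded (the regression timing fallback is then
#'   unavailable).
#' @param n_frames number of frames in the clip.
#' @param pixel_spacing isotropic pixel size, mm/px.
#' @param cycle_starts integer vector of end-diastolic anchor frames, one
#'   per annotated cardiac cycle (1-based).
#' @param regional_quality optional numeric vector of regional image
#'   quality scores, each in \[0, 5\].
#' @param masks named list with optional elements `lv_primary`,
#'   `lv_secondary`, `la_primary`, `la_secondary`, each a per-frame mask
#'   stack as described above.
#' @param truth optional ground-truth block (synthetic data only) read by
#'   the oracle classifier/timing backends.
#' @return an object of class `echo_recording`.
#' @export
echo_recording <- function(recording_id, modality, view = "unknown",
                           view_confidence = NA_real_, frame_rate, n_frames,
                           pixel_spacing, heart_rate = NULL,
                           cycle_starts = integer(), regional_quality = NULL,
                           masks = list(), truth = NULL) {
  if (!is.character(recording_id) || length(recording_id) != 1L || !nzchar(recording_id))
    ep_stop("recording_id must be a non-empty string", "recording_id")
  w <- recording_id
  # "unknown" is allowed on a recording before classification, though it is
  # not part of the 8-class modality taxonomy itself
  check_enum(modality, c(echo_modalities(), "unknown"), "modality", w)
  check_enum(view, echo_views(), "view", w)
  if (!is.na(view_confidence))
    check_scalar_number(view_confidence, "view_confidence", w,
                        lower = -1e-9, upper = 1 + 1e-9)
  check_scalar_number(frame_rate, "frame_rate", w, lower = 0)
  check_scalar_number(heart_rate, "heart_rate", w, lower = 0, allow_null = TRUE)
  check_scalar_number(n_frames, "n_frames", w, lower = 0)
  if (n_frames != as.integer(n_frames))
    ep_stop("n_frames must be an integer", "n_frames", w)
  check_scalar_number(pixel_spacing, "pixel_spacing", w, lower = 0)
  if (length(cycle_starts)) {
    if (any(cycle_starts < 1 | cycle_starts > n_frames | cycle_starts != floor(cycle_starts)))
      ep_stop("cycle_starts must be integer frame indices in [1, n_frames]",
              "cycle_starts", w)
  }
  if (!is.null(regional_quality)) {
    if (!is.numeric(regional_quality) || !length(regional_quality) ||
        any(!is.finite(regional_quality)) ||
        any(regional_quality < 0 | regional_quality > 5))
      ep_stop("regional_quality scores must be reals in [0, 5]",
              "regional_quality", w)
  }
  masks <- validate_mask_stacks(masks, n_frames = as.integer(n_frames), where = w)
  structure(list(
    recording_id = recording_id, modality = modality, view = view,
    view_confidence = as.numeric(view_confidence),
    frame_rate = as.numeric(frame_rate),
    heart_rate = if (is.null(heart_rate)) NULL else as.numeric(heart_rate),
    n_frames = as.integer(n_frames),
    pixel_spacing = as.numeric(pixel_spacing),
    cycle_starts = as.integer(cycle_starts),
    regional_quality = if (is.null(regional_quality)) NULL else as.numeric(regional_quality),
    masks = masks, truth = truth
  ), class = "echo_recording")
}

mask_stack_names <- function() c("lv_primary", "lv_secondary", "la_primary", "la_secondary")

validate_mask_stacks <- function(masks, n_frames, where) {
  if (!is.list(masks)) ep_stop("masks must be a named list", "masks", where)
  bad <- setdiff(names(masks), mask_stack_names())
  if (length(bad))
    ep_stop(sprintf("unknown mask stack(s): %s", paste(bad, collapse = ", ")),
            "masks", where)
  dims <- NULL
  for (nm in names(masks)) {
    stack <- masks[[nm]]
    if (is.null(stack)) next
    if (!is.list(stack) || length(stack) != n_frames)
      ep_stop(sprintf("mask stack '%s' must be a list of length n_frames (%d)",
                      nm, n_frames), "masks", where)
    for (f in seq_along(stack)) {
      m <- stack[[f]]
      if (is.null(m)) next
      if (!is.matrix(m) || !is.logical(m))
        ep_stop(sprintf("mask stack '%s' frame %d is not a logical matrix", nm, f),
                "masks", where)
      if (is.null(dims)) dims <- dim(m)
      else if (!identical(dim(m), dims))
        ep_stop(sprintf("mask stack '%s' frame %d has dimensions %s, expected %s",
                        nm, f, paste(dim(m), collapse = "x"),
                        paste(dims, collapse = "x")),
                "masks", where)
    }
  }
  # primary/secondary pairing: same frames populated
  for (st in c("lv", "la")) {
    p <- masks[[paste0(st, "_primary")]]; s <- masks[[paste0(st, "_secondary")]]
    if (!is.null(p) && !is.null(s)) {
      fp <- which(!vapply(p, is.null, logical(1)))
      fs <- which(!vapply(s, is.null, logical(1)))
      if (!identical(fp, fs))
        ep_stop(sprintf("primary and secondary '%s' stacks cover different frames", st),
                "masks", where)
    }
  }
  masks
}

#' One exam (study)
#'
#' An exam groups all recordings acquired in one echocardiographic study,
#' indexed by a unique study UID, together with the patient attributes
#' needed for indexing volumes to body surface area and for the
#' sex-specific timing regression.
#'
#' @param study_uid unique, non-empty exam identifier.
#' @param patient a [patient_info()] object.
#' @param recordings list of [echo_recording()] objects with unique
#'   `recording_id`s.
#' @return an object of class `exam_record`.
#' @export
exam_record <- function(study_uid, patient, recordings = list()) {
  if (!is.character(study_uid) || length(study_uid) != 1L || !nzchar(study_uid))
    ep_stop("study_uid must be a non-empty string", "study_uid")
  if (!inherits(patient, "patient_info"))
    ep_stop("patient must be a patient_info object", "patient", study_uid)
  if (!is.list(recordings) ||
      !all(vapply(recordings, inherits, logical(1), "echo_recording")))
    ep_stop("recordings must be a list of echo_recording objects",
            "recordings", study_uid)
  ids <- vapply(recordings, `[[`, character(1), "recording_id")
  if (anyDuplicated(ids))
    ep_stop(sprintf("duplicate recording_id(s): %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "recordings", study_uid)
  structure(list(study_uid = study_uid, patient = patient,
                 recordings = recordings),
            class = "exam_record")
}

#' @export
print.exam_record <- function(x, ...) {
  cat(sprintf("<exam %s> patient %s (%s, %.0f cm, %.0f kg), %d recording(s)\n",
              x$study_uid, x$patient$patient_id, x$patient$sex,
              x$patient$height, x$patient$weight, length(x$recordings)))
  for (r in x$recordings)
    cat(sprintf("  %s: %s / %s (conf %.2f), %d frames @ %g Hz, %g mm/px\n",
                r$recording_id, r$modality, r$view,
                if (is.na(r$view_confidence)) NA else r$view_confidence,
                r$n_frames, r$frame_rate, r$pixel_spacing))
  invisible(x)
}
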