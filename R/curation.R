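# Exam curation: modality/view identification, confidence gating, image
# quality aggregation, hierarchical view selection, and exam-level
# exclusion accounting.

#' Classify the imaging modality of a recording
#'
#' Runs the modality backend on a recording, validates the backend's
#' probability contract, and writes the winning label and its confidence
#' onto the returned recording. A backend exception marks the recording
#' `modality = "unknown"` (with the error as attribute) instead of
#' failing; a backend violating the probability contract raises an error.
#'
#' @param recording an [echo_recording()].
#' @param backend a modality [classifier_backend()].
#' @return the recording with `modality` and attribute
#'   `modality_confidence` updated.
#' @export
classify_modality <- function(recording, backend) {
  res <- tryCatch(backend$classify(recording), error = function(e) e)
  if (inherits(res, "echopipe_backend_contract_error")) stop(res)
  if (inherits(res, "error")) {
    recording$modality <- "unknown"
    attr(recording, "modality_confidence") <- NA_real_
    attr(recording, "classification_note") <- conditionMessage(res)
    return(recording)
  }
  validate_probs(res$probs, backend$taxonomy, recording$recording_id)
  recording$modality <- res$label
  attr(recording, "modality_confidence") <- max(res$probs)
  recording
}

#' Classify the B-mode view of a recording
#'
#' Applies the view backend to a 2D B-mode recording and records the view
#' label and confidence. Calling this on a non-B-mode recording is an
#' error (view classification is only defined for B2D clips).
#'
#' @param recording an [echo_recording()] with `modality == "B2D"`.
#' @param backend a view [classifier_backend()].
#' @return the recording with `view` and `view_confidence` updated.
#' @export
classify_view <- function(recording, backend) {
  if (recording$modality != "B2D")
    ep_stop(sprintf("view classification requires a B2D recording (got %s)",
                    recording$modality), "modality", recording$recording_id)
  res <- backend$classify(recording)
  validate_probs(res$probs, backend$taxonomy, recording$recording_id)
  recording$view <- res$label
  recording$view_confidence <- unname(max(res$probs))
  recording
}

#' View-confidence inclusion gate
#'
#' A clip is eligible for measurement only when its view-classification
#' confidence reaches the threshold (inclusive; default 0.85).
#'
#' @param confidence confidence in \[0, 1\] (vectorized).
#' @param threshold inclusion threshold.
#' @return logical vector: `confidence >= threshold`.
#' @export
gate_view_confidence <- function(confidence, threshold = 0.85) {
  !is.na(confidence) & confidence >= threshold
}

#' Aggregate regional image-quality scores
#'
#' Regional (per-segment) quality scores in \[0, 5\] are averaged to one
#' global score and rounded half-up to an integer class, 0 (structures
#' barely visible) to 5 (all structures clearly identified).
#'
#' @param regional_scores non-empty numeric vector, each value in \[0, 5\].
#' @return integer in 0..5.
#' @export
aggregate_image_quality <- function(regional_scores) {
  if (is.null(regional_scores) || !length(regional_scores))
    ep_stop("regional_scores must be non-empty", "regional_scores")
  if (!is.numeric(regional_scores) || any(!is.finite(regional_scores)) ||
      any(regional_scores < 0 | regional_scores > 5))
    ep_stop("regional_scores must be reals in [0, 5]", "regional_scores")
  as.integer(min(5, max(0, round_half_up(mean(regional_scores)))))
}

# Per-slot hierarchical selection. Returns list(slots=, reason=, detail=):
# slots is a named list (A4C/A2C) of character vectors of recording ids
# (all gated-in clips of the preferred available view variant), or NULL
# with the exclusion reason for the first unfillable slot.
select_slots <- function(exam, hierarchy, threshold, la_reason_a2c = FALSE) {
  b2d <- Filter(function(r) r$modality == "B2D" && r$view != "TEE",
                exam$recordings)
  slots <- list(); reason <- "none"; detail <- NULL
  for (slot in names(hierarchy)) {
    chosen <- character(); present_any <- FALSE
    for (v in hierarchy[[slot]]) {
      of_view <- Filter(function(r) identical(r$view, v), b2d)
      if (length(of_view)) present_any <- TRUE
      gated <- Filter(function(r) gate_view_confidence(r$view_confidence, threshold),
                      of_view)
      if (length(gated)) {
        conf <- vapply(gated, `[[`, numeric(1), "view_confidence")
        chosen <- vapply(gated[order(-conf)], `[[`, character(1), "recording_id")
        break
      }
    }
    if (!length(chosen)) {
      if (present_any) {
        reason <- "low_view_confidence"
        detail <- sprintf("%s present but below confidence gate", slot)
      } else {
        reason <- if (slot == "A2C" && la_reason_a2c) "missing_A2C_for_LA"
                  else paste0("missing_", slot)
        detail <- sprintf("no %s view available", slot)
      }
      return(list(slots = NULL, reason = reason, detail = detail))
    }
    slots[[slot]] <- chosen
  }
  list(slots = slots, reason = "none", detail = NULL)
}

#' Select views for LV volume / LVEF measurement
#'
#' Fills the A4C and A2C slots independently, preferring the LV-focused
#' variant (clearer ventricular visualization, less foreshortening risk)
#' and falling back to the standard view. Only recordings passing the
#' confidence gate are eligible; all gated-in clips of the winning variant
#' are kept (measurements are averaged downstream), ordered by descending
#' confidence. Exclusions are returned as data, not errors.
#'
#' @param exam an [exam_record()] whose recordings are already classified.
#' @param threshold view-confidence gate (default 0.85).
#' @return `list(slots = list(A4C =, A2C =), reason, detail)`; `slots` is
#'   `NULL` when a slot is unfillable, with `reason` one of
#'   `missing_A4C`, `missing_A2C`, `low_view_confidence`, `no_bmode`.
#' @export
select_views_for_lvef <- function(exam, threshold = 0.85) {
  if (!any(vapply(exam$recordings, function(r)
        r$modality == "B2D" && r$view != "TEE", logical(1))))
    return(list(slots = NULL, reason = "no_bmode",
                detail = "no transthoracic B-mode recordings"))
  select_slots(exam,
               hierarchy = list(A4C = c("A4C_LV_focused", "A4C"),
                                A2C = c("A2C_LV_focused", "A2C")),
               threshold = threshold)
}

#' Select views for LA volume / LAVI measurement
#'
#' The left atrium is measured on standard (non-LV-focused) A4C and A2C
#' views only; the LV-focused zoom typically crops the atrium.
#'
#' @inheritParams select_views_for_lvef
#' @return as [select_views_for_lvef()], with `missing_A2C_for_LA` for an
#'   absent A2C.
#' @export
select_views_for_lavi <- function(exam, threshold = 0.85) {
  if (!any(vapply(exam$recordings, function(r)
        r$modality == "B2D" && r$view != "TEE", logical(1))))
    return(list(slots = NULL, reason = "no_bmode",
                detail = "no transthoracic B-mode recordings"))
  select_slots(exam, hierarchy = list(A4C = "A4C", A2C = "A2C"),
               threshold = threshold, la_reason_a2c = TRUE)
}

#' Curate one exam
#'
#' Runs the full curation phase: modality classification, view
#' classification of B-mode clips, confidence gating, hierarchical view
#' selection for the LV and LA measurement paths, and image-quality
#' aggregation. Exams containing only transoesophageal (TEE) or non-B-mode
#' recordings are excluded. Every exclusion carries exactly one primary
#' machine-readable reason (precedence: `no_bmode` over `missing_A4C` over
#' `missing_A2C` over `low_view_confidence`).
#'
#' @param exam an [exam_record()].
#' @param config a [pipeline_config()] (supplies threshold and backends).
#' @return object of class `curation_outcome`: `study_uid`, `included`
#'   (LVEF path), `exclusion_reason`, `exclusion_detail`, `selected_lv`,
#'   `representative_lv`, `la_available`, `la_exclusion_reason`,
#'   `selected_la`, `quality_class`, and the classified `exam`.
#' @export
curate_exam <- function(exam, config = pipeline_config()) {
  mod_be <- config$modality_backend
  view_be <- config$view_backend
  recs <- lapply(exam$recordings, classify_modality, backend = mod_be)
  recs <- lapply(recs, function(r) {
    if (r$modality == "B2D") classify_view(r, view_be) else r
  })
  exam$recordings <- recs

  lv <- select_views_for_lvef(exam, config$confidence_threshold)
  la <- select_views_for_lavi(exam, config$confidence_threshold)

  tee_only <- length(recs) > 0 &&
    all(vapply(recs, function(r) r$modality != "B2D" || r$view == "TEE",
               logical(1))) &&
    any(vapply(recs, function(r) r$view == "TEE", logical(1)))
  if (tee_only) {
    lv <- list(slots = NULL, reason = "other",
               detail = "transoesophageal-only exam")
  }

  quality_class <- NA_integer_
  used_ids <- unique(unlist(c(lv$slots, la$slots)))
  scored <- Filter(function(r) r$recording_id %in% used_ids &&
                     !is.null(r$regional_quality), recs)
  if (length(scored)) {
    per_rec <- vapply(scored, function(r) mean(r$regional_quality), numeric(1))
    quality_class <- as.integer(min(5, max(0, round_half_up(mean(per_rec)))))
  }

  structure(list(
    study_uid = exam$study_uid,
    included = is.null(lv$slots) == FALSE,
    exclusion_reason = lv$reason,
    exclusion_detail = lv$detail,
    selected_lv = lv$slots,
    representative_lv = if (!is.null(lv$slots)) lapply(lv$slots, `[`, 1L) else NULL,
    la_available = !is.null(la$slots),
    la_exclusion_reason = la$reason,
    selected_la = la$slots,
    quality_class = quality_class,
    exam = exam
  ), class = "curation_outcome")
}
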