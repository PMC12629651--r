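# Cardiac event timing.
#
# End-diastole (ED, mitral valve closure) and end-systole (ES, aortic
# valve closure) frames are found per recording by a pluggable
# event-detection backend; when the backend fails, or deviates from the
# ECG-based regression prediction by more than a frame cutoff, the
# pipeline falls back to the regression timing derived from the ECG heart
# rate and the annotated cycle-start (ED) anchor.

#' ES offset from ED by sex-specific heart-rate regression
#'
#' Predicts the ED-to-ES interval in milliseconds from the ECG heart rate
#' using the sex-specific linear regressions
#' `498 - 1.6 * HR` (male) and `522 - 1.77 * HR` (female).
#'
#' @param sex `"male"` or `"female"`.
#' @param heart_rate heart rate in bpm (non-negative).
#' @return ED-to-ES interval, ms.
#' @examples
#' regression_es_offset("male", 60)    # 402 ms
#' regression_es_offset("female", 60)  # 415.8 ms
#' @export
regression_es_offset <- function(sex, heart_rate) {
  check_enum(sex, c("male", "female"), "sex")
  if (!is.numeric(heart_rate) || length(heart_rate) != 1L ||
      !is.finite(heart_rate) || heart_rate < 0)
    ep_stop("heart_rate must be a non-negative number", "heart_rate")
  off <- if (sex == "male") 498 - 1.6 * heart_rate else 522 - 1.77 * heart_rate
  if (off <= 0)
    ep_stop(sprintf("regression offset non-positive (%.1f ms at %g bpm)",
                    off, heart_rate), "heart_rate")
  off
}

#' Construct a cardiac-events record
#'
#' @param ed_frame,es_frame 1-based frame indices, `es_frame > ed_frame`.
#' @param source `"network"` or `"ecg_regression"`.
#' @param deviation_frames optional absolute network-vs-regression
#'   deviation (frames).
#' @return object of class `cardiac_events`.
#' @export
cardiac_events <- function(ed_frame, es_frame, source,
                           deviation_frames = NA_real_) {
  check_enum(source, c("network", "ecg_regression"), "source")
  ed_frame <- as.integer(ed_frame); es_frame <- as.integer(es_frame)
  if (is.na(ed_frame) || is.na(es_frame) || ed_frame < 1L || es_frame <= ed_frame)
    ep_stop("need 1 <= ed_frame < es_frame", "es_frame")
  structure(list(ed_frame = ed_frame, es_frame = es_frame, source = source,
                 deviation_frames = as.numeric(deviation_frames)),
            class = "cardiac_events")
}

#' ECG-regression timing for a recording
#'
#' For each annotated cycle-start anchor, ED is the anchor frame and ES is
#' placed `round(offset_ms * frame_rate / 1000)` frames later (half-up
#' rounding), with the offset from [regression_es_offset()]. Cycles whose
#' predicted ES falls beyond the clip are dropped.
#'
#' @param recording an [echo_recording()] with `heart_rate` and at least
#'   one `cycle_starts` anchor.
#' @param patient a [patient_info()] (supplies the sex selector).
#' @return list of [cardiac_events()], one per usable cycle, or an
#'   exclusion signal (`reason = "timing_unavailable"`) when the heart
#'   rate or anchor is missing.
#' @export
ecg_events <- function(recording, patient) {
  if (is.null(recording$heart_rate))
    return(ep_signal("timing_unavailable", "no heart rate on recording"))
  if (!length(recording$cycle_starts))
    return(ep_signal("timing_unavailable", "no cycle-start (ED) anchor"))
  off_ms <- tryCatch(regression_es_offset(patient$sex, recording$heart_rate),
                     error = function(e) NULL)
  if (is.null(off_ms))
    return(ep_signal("timing_unavailable", "regression offset non-positive"))
  off_frames <- round_half_up(off_ms * recording$frame_rate / 1000)
  out <- list()
  for (ed in recording$cycle_starts) {
    es <- ed + off_frames
    if (es <= recording$n_frames)
      out[[length(out) + 1L]] <- cardiac_events(ed, es, "ecg_regression")
  }
  if (!length(out))
    return(ep_signal("timing_unavailable", "predicted ES beyond clip end"))
  out
}

#' Backend-based event detection
#'
#' Calls the event-detection backend on a B-mode recording. A backend that
#' throws, or returns `NULL`, yields `NULL` ("no valid output"); results
#' are validated against the frame range.
#'
#' @param recording an [echo_recording()], modality `"B2D"`.
#' @param backend an event-detection backend (see [timing_backend()]).
#' @return list of [cardiac_events()] (source `"network"`) or `NULL`.
#' @export
detect_events <- function(recording, backend) {
  res <- tryCatch(backend$detect(recording), error = function(e) NULL)
  if (is.null(res) || !length(res)) return(NULL)
  ok <- vapply(res, function(ev) {
    inherits(ev, "cardiac_events") && ev$es_frame <= recording$n_frames
  }, logical(1))
  if (!any(ok)) return(NULL)
  res[ok]
}

#' Reconcile network and ECG-regression timing
#'
#' The network result is kept unless it deviates from the regression
#' prediction by more than `cutoff_frames` frames (deviation = maximum
#' over the ED and ES differences; deviations of exactly the cutoff are
#' kept). A missing network result falls back to the ECG result and vice
#' versa; both missing is a timing-unavailable exclusion.
#'
#' @param network [cardiac_events()] or `NULL`.
#' @param ecg [cardiac_events()] or `NULL`.
#' @param cutoff_frames maximum tolerated deviation, frames (default 5).
#' @return [cardiac_events()] (with `deviation_frames` recorded when both
#'   sources were present) or an exclusion signal.
#' @export
reconcile_timing <- function(network, ecg, cutoff_frames = 5) {
  if (is.null(network) && is.null(ecg))
    return(ep_signal("timing_unavailable", "no timing source available"))
  if (is.null(network)) return(ecg)
  if (is.null(ecg)) return(network)
  dev <- max(abs(network$ed_frame - ecg$ed_frame),
             abs(network$es_frame - ecg$es_frame))
  if (dev > cutoff_frames) {
    ecg$deviation_frames <- dev
    ecg
  } else {
    network$deviation_frames <- dev
    network
  }
}

#' Resolved per-cycle timing for a recording
#'
#' Convenience wrapper running [detect_events()] and [ecg_events()] and
#' reconciling them cycle by cycle (cycles are paired in order; unmatched
#' cycles use whichever source has them).
#'
#' @inheritParams detect_events
#' @inheritParams ecg_events
#' @inheritParams reconcile_timing
#' @return list of [cardiac_events()] or an exclusion signal.
#' @export
recording_events <- function(recording, patient, backend,
                             cutoff_frames = 5) {
  net <- detect_events(recording, backend)
  ecg <- ecg_events(recording, patient)
  if (is_exclusion(ecg)) ecg <- NULL
  n <- max(length(net), length(ecg))
  if (n == 0L)
    return(ep_signal("timing_unavailable", "no timing source available"))
  out <- list()
  for (i in seq_len(n)) {
    r <- reconcile_timing(if (i <= length(net)) net[[i]] else NULL,
                          if (i <= length(ecg)) ecg[[i]] else NULL,
                          cutoff_frames)
    if (!is_exclusion(r)) out[[length(out) + 1L]] <- r
  }
  if (!length(out)) return(ep_signal("timing_unavailable"))
  out
}
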