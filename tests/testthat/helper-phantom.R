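# Shared fixture builders (everything generated in code at test time).

default_config <- function(...) pipeline_config(...)

# Generate, curate, time and measure one phantom exam in one call.
measure_phantom <- function(spec = phantom_spec(), corruption = corruption_spec(),
                            config = default_config()) {
  g <- generate_exam(spec, corruption)
  cur <- curate_exam(g$exam, config)
  events <- list()
  for (r in cur$exam$recordings) {
    if (r$modality != "B2D") next
    events[[r$recording_id]] <-
      recording_events(r, cur$exam$patient, config$timing_backend,
                       config$timing_cutoff_frames)
  }
  list(result = measure_exam(cur$exam, cur, events, config),
       curation = cur, truth = g$truth, exam = cur$exam, events = events)
}

# Minimal metadata-only recording for curation/timing tests (no masks).
bare_recording <- function(id = "r1", modality = "B2D", view = "A4C",
                           conf = 0.98, frame_rate = 50, n_frames = 60,
                           heart_rate = 60, cycle_starts = 1L, ...) {
  echo_recording(recording_id = id, modality = modality, view = view,
                 view_confidence = conf, frame_rate = frame_rate,
                 n_frames = n_frames, pixel_spacing = 0.5,
                 heart_rate = heart_rate, cycle_starts = cycle_starts,
                 truth = list(modality = modality, view = view), ...)
}

bare_exam <- function(recordings, uid = "ex1", sex = "male") {
  exam_record(uid, patient_info("p1", sex, 175, 75), recordings)
}

# Two masks with an exact, hand-countable Dice score.
masks_with_dice <- function(n_a, n_b, overlap, dims = c(20, 40)) {
  a <- matrix(FALSE, dims[1], dims[2]); b <- a
  a[1, seq_len(n_a)] <- TRUE
  b[1, seq.int(n_a - overlap + 1, length.out = n_b)] <- TRUE
  list(a = a, b = b)
}
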