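# Exam-level measurement extraction: runs timing, segmentation validity
# and Dice QC per clip, computes biplane volumes per clip pair and cycle,
# and averages (cycles within pair, then pairs).

measurement_failure <- function(study_uid, reason, detail = NULL) {
  structure(list(study_uid = study_uid, included = FALSE,
                 exclusion_reason = reason, exclusion_detail = detail,
                 edv = NA_real_, esv = NA_real_, ef = NA_real_,
                 la_esv = NA_real_, bsa = NA_real_, lavi = NA_real_,
                 dice_ed = NA_real_, dice_es = NA_real_, qc_pass = FALSE,
                 n_clips_averaged = 0L, timing_source = NA_character_,
                 foreshortening_warning = FALSE),
            class = "measurement_result")
}

# Collect per-clip usable cycles for one structure ("lv"/"la"), applying
# timing, mask availability and Dice QC stage by stage. Returns
# list(clips = <per-clip list of cycles>, stage_counts = ...) where each
# cycle carries masks and dice values.
collect_clips <- function(exam, ids, events, structure_name, config,
                          es_only = identical(structure_name, "la")) {
  recs <- stats::setNames(exam$recordings,
                          vapply(exam$recordings, `[[`, character(1), "recording_id"))
  out <- list(timing_ok = character(), seg_ok = character(), qc_ok = character(),
              clips = list())
  pkey <- paste0(structure_name, "_primary")
  skey <- paste0(structure_name, "_secondary")
  for (id in ids) {
    ev <- events[[id]]
    if (is.null(ev) || is_exclusion(ev) || !length(ev)) next
    out$timing_ok <- c(out$timing_ok, id)
    rec <- recs[[id]]
    stack_p <- rec$masks[[pkey]]
    stack_s <- rec$masks[[skey]]
    if (is.null(stack_p)) next
    cycles <- list(); seg_valid <- FALSE; qc_valid <- FALSE
    for (e in ev) {
      m_ed <- stack_p[[e$ed_frame]]; m_es <- stack_p[[e$es_frame]]
      if (is.null(m_es) || (!es_only && is.null(m_ed))) next
      seg_valid <- TRUE
      d_ed <- d_es <- NA_real_; pass <- TRUE
      if (!is.null(stack_s)) {
        s_ed <- if (es_only) NULL else stack_s[[e$ed_frame]]
        s_es <- stack_s[[e$es_frame]]
        if (!is.null(s_ed) && !is.null(m_ed)) {
          q <- segmentation_qc(m_ed, s_ed, config$dice_threshold)
          d_ed <- q$dice; pass <- pass && q$pass
        }
        if (!is.null(s_es)) {
          q <- segmentation_qc(m_es, s_es, config$dice_threshold)
          d_es <- q$dice; pass <- pass && q$pass
        }
      }
      if (!pass) next
      qc_valid <- TRUE
      cycles[[length(cycles) + 1L]] <- list(
        ed = m_ed, es = m_es, dice_ed = d_ed, dice_es = d_es,
        source = e$source, spacing = rec$pixel_spacing)
    }
    if (seg_valid) out$seg_ok <- c(out$seg_ok, id)
    if (qc_valid) {
      out$qc_ok <- c(out$qc_ok, id)
      out$clips[[id]] <- cycles
    }
  }
  out
}

# First stage at which a slot ran out of clips, in funnel order.
slot_failure_reason <- function(col) {
  if (!length(col$timing_ok)) "timing_unavailable"
  else if (!length(col$seg_ok)) "invalid_segmentation"
  else if (!length(col$qc_ok)) "low_dice"
  else NA_character_
}

#' Measure one curated exam
#'
#' For every gated-in clip pair and annotated cycle: Dice-QC the ED/ES
#' mask pairs, compute EDV and ESV by biplane Simpson, then EF; LA volume
#' at ES from the standard views, indexed to BSA. Measurements are
#' averaged over cycles within a clip pair and then over pairs. Any stage
#' running out of clips yields an exclusion (`timing_unavailable`,
#' `invalid_segmentation` or `low_dice`) — exclusions are data, not
#' errors. LA-path failures leave `la_esv`/`lavi` absent without
#' excluding the exam.
#'
#' @param exam classified [exam_record()] (from the curation outcome).
#' @param curation a `curation_outcome` from [curate_exam()].
#' @param events named list `recording_id -> list of` [cardiac_events()]
#'   (or exclusion signals), e.g. from [recording_events()].
#' @param config a [pipeline_config()].
#' @return object of class `measurement_result`.
#' @export
measure_exam <- function(exam, curation, events, config = pipeline_config()) {
  uid <- exam$study_uid
  if (!curation$included)
    return(measurement_failure(uid, curation$exclusion_reason,
                               curation$exclusion_detail))

  col_a4c <- collect_clips(exam, curation$selected_lv$A4C, events, "lv", config)
  col_a2c <- collect_clips(exam, curation$selected_lv$A2C, events, "lv", config)
  for (col in list(col_a4c, col_a2c)) {
    r <- slot_failure_reason(col)
    if (!is.na(r)) return(measurement_failure(uid, r))
  }

  pair_stats <- list()
  for (ida in names(col_a4c$clips)) for (idb in names(col_a2c$clips)) {
    ca <- col_a4c$clips[[ida]]; cb <- col_a2c$clips[[idb]]
    ncyc <- min(length(ca), length(cb))
    edvs <- esvs <- numeric(); dices <- c()
    fswarn <- FALSE
    for (k in seq_len(ncyc)) {
      ved <- biplane_simpson(ca[[k]]$ed, cb[[k]]$ed, ca[[k]]$spacing,
                             cb[[k]]$spacing, config$n_discs)
      ves <- biplane_simpson(ca[[k]]$es, cb[[k]]$es, ca[[k]]$spacing,
                             cb[[k]]$spacing, config$n_discs)
      if (is_exclusion(ved) || is_exclusion(ves)) next
      edvs <- c(edvs, ved$volume); esvs <- c(esvs, ves$volume)
      fswarn <- fswarn || ved$foreshortening_warning || ves$foreshortening_warning
    }
    if (!length(edvs)) next
    pair_stats[[length(pair_stats) + 1L]] <- list(
      edv = mean(edvs), esv = mean(esvs), fswarn = fswarn,
      clips = c(ida, idb))
  }
  if (!length(pair_stats))
    return(measurement_failure(uid, "invalid_segmentation",
                               "no clip pair produced valid volumes"))

  edv <- mean(vapply(pair_stats, `[[`, numeric(1), "edv"))
  esv <- mean(vapply(pair_stats, `[[`, numeric(1), "esv"))
  ef <- ejection_fraction(edv, esv)
  fswarn <- any(vapply(pair_stats, `[[`, logical(1), "fswarn"))
  used_clips <- unique(unlist(lapply(pair_stats, `[[`, "clips")))

  all_cycles <- unlist(c(col_a4c$clips[intersect(names(col_a4c$clips), used_clips)],
                         col_a2c$clips[intersect(names(col_a2c$clips), used_clips)]),
                       recursive = FALSE)
  dvals_ed <- vapply(all_cycles, function(cy) cy$dice_ed, numeric(1))
  dvals_es <- vapply(all_cycles, function(cy) cy$dice_es, numeric(1))
  sources <- unique(vapply(all_cycles, function(cy) cy$source, character(1)))

  bsa <- body_surface_area(exam$patient$weight, exam$patient$height,
                           config$bsa_formula)

  # LA path: ES-frame biplane volume from standard views; optional.
  la_esv <- NA_real_
  if (curation$la_available) {
    la_a4c <- collect_clips(exam, curation$selected_la$A4C, events, "la", config)
    la_a2c <- collect_clips(exam, curation$selected_la$A2C, events, "la", config)
    if (length(la_a4c$clips) && length(la_a2c$clips)) {
      la_vols <- numeric()
      for (ida in names(la_a4c$clips)) for (idb in names(la_a2c$clips)) {
        ca <- la_a4c$clips[[ida]]; cb <- la_a2c$clips[[idb]]
        ncyc <- min(length(ca), length(cb))
        vs <- numeric()
        for (k in seq_len(ncyc)) {
          v <- biplane_simpson(ca[[k]]$es, cb[[k]]$es, ca[[k]]$spacing,
                               cb[[k]]$spacing, config$n_discs)
          if (!is_exclusion(v)) vs <- c(vs, v$volume)
        }
        if (length(vs)) la_vols <- c(la_vols, mean(vs))
      }
      if (length(la_vols)) la_esv <- mean(la_vols)
    }
  }

  structure(list(
    study_uid = uid, included = TRUE, exclusion_reason = "none",
    exclusion_detail = NULL,
    edv = edv, esv = esv, ef = ef,
    la_esv = la_esv, bsa = bsa,
    lavi = if (is.na(la_esv)) NA_real_ else lavi(la_esv, bsa),
    dice_ed = if (all(is.na(dvals_ed))) NA_real_ else min(dvals_ed, na.rm = TRUE),
    dice_es = if (all(is.na(dvals_es))) NA_real_ else min(dvals_es, na.rm = TRUE),
    qc_pass = TRUE,
    n_clips_averaged = length(used_clips),
    timing_source = if (length(sources) == 1L) sources else "mixed",
    foreshortening_warning = fswarn
  ), class = "measurement_result")
}
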