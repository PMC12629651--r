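# Synthetic exam generator.
#
# The left ventricle is modeled as a full prolate spheroid (semi-axes a >=
# b = c) whose semi-axes interpolate smoothly (cosine) between an ED and
# an ES state with exact analytic volumes; the A4C and A2C recordings are
# the two orthogonal long-axis planes, whose cross-sections are identical
# ellipses, rasterized at the requested pixel spacing. The LA is an
# analogous spheroid realized at end-systole. ES is placed at the
# sex-specific heart-rate regression offset from the cycle-start ED
# anchor, so the network and ECG timing sources agree by construction
# unless a corruption disables or offsets the network. Controlled
# corruptions exercise every curation and QC exclusion path with known
# ground truth.

#' Phantom specification
#'
#' @param edv,esv LV end-diastolic / end-systolic volume, mL (0 < esv <
#'   edv).
#' @param la_esv LA volume at ES, mL (> 0).
#' @param heart_rate bpm.
#' @param frame_rate Hz (>= 20).
#' @param n_cycles annotated cardiac cycles per recording.
#' @param pixel_spacing mm/px.
#' @param sex,height,weight patient attributes.
#' @param seed integer seed for the exam's randomness.
#' @param lv_aspect ED long/short semi-axis ratio of the LV spheroid.
#' @param es_length_ratio ES/ED long-axis ratio (longitudinal shortening).
#' @param la_aspect long/short semi-axis ratio of the LA spheroid.
#' @param mask_frames `"events"` (masks at the frames the measurement
#'   will request: ED/ES and their corrupted-timing counterparts) or
#'   `"all"` (every frame; used for convergence studies).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(edv = 130, esv = 52, la_esv = 60, heart_rate = 60,
                         frame_rate = 50, n_cycles = 1L, pixel_spacing = 0.5,
                         sex = "male", height = 175, weight = 75, seed = 1L,
                         lv_aspect = 1.8, es_length_ratio = 0.9,
                         la_aspect = 1.25, mask_frames = c("events", "all")) {
  mask_frames <- match.arg(mask_frames)
  if (!(esv > 0 && esv < edv)) ep_stop("need 0 < esv < edv", "esv")
  if (la_esv <= 0) ep_stop("la_esv must be positive", "la_esv")
  if (frame_rate < 20) ep_stop("frame_rate must be >= 20 Hz", "frame_rate")
  check_enum(sex, c("male", "female"), "sex")
  structure(as.list(environment()), class = "phantom_spec")
}

#' Corruption specification
#'
#' Controlled defects injected into a phantom exam, each exercising one
#' curation/QC exclusion path.
#'
#' @param drop_views views to omit from the exam entirely.
#' @param confidence_override named numeric vector `view -> confidence`
#'   in \[0, 1\] replacing the classifier confidence for those views.
#' @param dice_degradation fraction in \[0, 1\] of the secondary-mask
#'   boundary replaced by a shrunken arc (0 = secondary identical to
#'   primary); the achieved Dice is recorded in the ground truth.
#' @param disable_timing_network if `TRUE`, the event-detection backend
#'   returns no output for this exam's recordings (ECG fallback path).
#' @param network_timing_offset frames added to the network's event
#'   output (exercises the reconciliation cutoff).
#' @param quality_scores optional regional image-quality scores in
#'   \[0, 5\] applied to every apical recording.
#' @return object of class `corruption_spec`.
#' @export
corruption_spec <- function(drop_views = character(),
                            confidence_override = numeric(),
                            dice_degradation = 0,
                            disable_timing_network = FALSE,
                            network_timing_offset = 0L,
                            quality_scores = NULL) {
  if (length(drop_views) && !all(drop_views %in% echo_views()))
    ep_stop("drop_views contains unknown view labels", "drop_views")
  if (length(confidence_override)) {
    if (is.null(names(confidence_override)) ||
        !all(names(confidence_override) %in% echo_views()))
      ep_stop("confidence_override must be named by view", "confidence_override")
    if (any(confidence_override < 0 | confidence_override > 1))
      ep_stop("confidence_override values must be in [0, 1]", "confidence_override")
  }
  if (dice_degradation < 0 || dice_degradation > 1)
    ep_stop("dice_degradation must be in [0, 1]", "dice_degradation")
  if (!is.null(quality_scores) &&
      (any(quality_scores < 0) || any(quality_scores > 5)))
    ep_stop("quality_scores must be in [0, 5]", "quality_scores")
  structure(list(drop_views = drop_views,
                 confidence_override = confidence_override,
                 dice_degradation = dice_degradation,
                 disable_timing_network = isTRUE(disable_timing_network),
                 network_timing_offset = as.integer(network_timing_offset),
                 quality_scores = quality_scores),
            class = "corruption_spec")
}

# Semi-axes (a = long, b = perpendicular) of a spheroid of volume v_ml
# with aspect ratio k = a/b: v = 4/3 pi a b^2 = 4/3 pi a^3 / k^2.
spheroid_semi_axes <- function(v_ml, k) {
  a <- (3 * v_ml * 1000 * k^2 / (4 * pi))^(1 / 3)
  c(a = a, b = a / k)
}

#' Generate one synthetic exam with ground truth
#'
#' Produces an [exam_record()] with four apical recordings (LV-focused
#' and standard A4C/A2C; LV masks on all four, LA masks on the standard
#' pair) plus the requested corruptions, and the exact analytic ground
#' truth.
#'
#' @param spec a [phantom_spec()].
#' @param corruption a [corruption_spec()].
#' @return `list(exam =, truth =)`; `truth` carries exact `edv`, `esv`,
#'   `ef`, `la_esv`, `bsa`, `lavi`, event frames, the achieved secondary
#'   Dice, and the injected corruption summary with the expected
#'   exclusion reason.
#' @export
generate_exam <- function(spec, corruption = corruption_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  stopifnot(inherits(corruption, "corruption_spec"))
  views_all <- c("A4C_LV_focused", "A2C_LV_focused", "A4C", "A2C")
  unknown_req <- setdiff(c(corruption$drop_views,
                           names(corruption$confidence_override)), views_all)
  if (length(unknown_req))
    ep_stop(sprintf("corruption targets view(s) not generated: %s",
                    paste(unknown_req, collapse = ", ")), "corruption")

  lv_ed <- spheroid_semi_axes(spec$edv, spec$lv_aspect)
  a_es <- lv_ed["a"] * spec$es_length_ratio
  b_es <- sqrt(3 * spec$esv * 1000 / (4 * pi * a_es))
  lv_es <- c(a = unname(a_es), b = unname(b_es))
  la_ax <- spheroid_semi_axes(spec$la_esv, spec$la_aspect)

  sp <- spec$pixel_spacing
  nrow_px <- ceiling(2 * max(lv_ed["a"], la_ax["a"]) * 1.15 / sp)
  ncol_px <- ceiling(2 * max(lv_ed["b"], la_ax["b"]) * 1.3 / sp)
  ctr <- c((nrow_px + 1) / 2, (ncol_px + 1) / 2)

  period <- round_half_up(60 * spec$frame_rate / spec$heart_rate)
  off_ms <- regression_es_offset(spec$sex, spec$heart_rate)
  off_frames <- round_half_up(off_ms * spec$frame_rate / 1000)
  if (off_frames >= period)
    ep_stop("regression ES offset exceeds the cardiac cycle", "heart_rate")
  ed_frames <- 1L + (seq_len(spec$n_cycles) - 1L) * period
  es_frames <- ed_frames + off_frames
  n_frames <- spec$n_cycles * period + 1L

  # contraction weight in [0, 1] for a frame (0 = ED state, 1 = ES state)
  phase_w <- function(f) {
    cyc <- pmax(1L, pmin(spec$n_cycles, (f - 1L) %/% period + 1L))
    ed <- ed_frames[cyc]; es <- es_frames[cyc]
    ifelse(f <= es,
           (1 - cos(pi * pmax(0, f - ed) / off_frames)) / 2,
           (1 + cos(pi * pmin(1, (f - es) / (period - off_frames)))) / 2)
  }
  lv_axes_at <- function(f) {
    w <- phase_w(f)
    c(a = lv_ed[["a"]] + (lv_es[["a"]] - lv_ed[["a"]]) * w,
      b = lv_ed[["b"]] + (lv_es[["b"]] - lv_ed[["b"]]) * w)
  }

  off_k <- corruption$network_timing_offset
  frames_needed <- if (spec$mask_frames == "all") seq_len(n_frames) else {
    fn <- c(ed_frames, es_frames)
    if (off_k != 0L) fn <- c(fn, ed_frames + off_k, es_frames + off_k)
    sort(unique(fn[fn >= 1L & fn <= n_frames]))
  }

  deg <- corruption$dice_degradation
  with_local_seed(spec$seed, {
    deg_phase <- stats::runif(1, 0, 2 * pi)
    default_quality <- stats::runif(8, 2.5, 4.5)
    conf_default <- c(A4C_LV_focused = 0.97, A2C_LV_focused = 0.96,
                      A4C = 0.98, A2C = 0.95)

    make_stacks <- function(with_la) {
      lv_p <- vector("list", n_frames); lv_s <- vector("list", n_frames)
      la_p <- la_s <- NULL
      for (f in frames_needed) {
        ax <- lv_axes_at(f) / sp
        lv_p[[f]] <- rasterize_ellipse(nrow_px, ncol_px, ctr, ax)
        lv_s[[f]] <- if (deg > 0)
          rasterize_ellipse_degraded(nrow_px, ncol_px, ctr, ax,
                                     frac = deg, phase = deg_phase)
          else lv_p[[f]]
      }
      if (with_la) {
        la_p <- vector("list", n_frames); la_s <- vector("list", n_frames)
        for (f in intersect(es_frames, frames_needed)) {
          la_p[[f]] <- rasterize_ellipse(nrow_px, ncol_px, ctr, la_ax / sp)
          la_s[[f]] <- if (deg > 0)
            rasterize_ellipse_degraded(nrow_px, ncol_px, ctr, la_ax / sp,
                                       frac = deg, phase = deg_phase)
            else la_p[[f]]
        }
      }
      out <- list(lv_primary = lv_p, lv_secondary = lv_s)
      if (with_la) { out$la_primary <- la_p; out$la_secondary <- la_s }
      out
    }

    recs <- list()
    for (v in setdiff(views_all, corruption$drop_views)) {
      conf <- unname(corruption$confidence_override[v])
      if (is.na(conf %||% NA)) conf <- NULL
      truth <- list(
        modality = "B2D", view = v,
        ed_frames = ed_frames, es_frames = es_frames,
        timing_available = !corruption$disable_timing_network,
        timing_offset_frames = off_k
      )
      if (!is.null(conf)) truth$confidence_override <- conf
      recs[[length(recs) + 1L]] <- echo_recording(
        recording_id = paste0("rec_", v),
        modality = "B2D", view = v,
        view_confidence = conf %||% conf_default[[v]],
        frame_rate = spec$frame_rate, heart_rate = spec$heart_rate,
        n_frames = n_frames, pixel_spacing = sp,
        cycle_starts = ed_frames,
        regional_quality = corruption$quality_scores %||% default_quality,
        masks = make_stacks(with_la = v %in% c("A4C", "A2C")),
        truth = truth
      )
    }

    exam <- exam_record(
      study_uid = sprintf("study_%08d", spec$seed %% 1e8),
      patient = patient_info(sprintf("pat_%08d", spec$seed %% 1e8),
                             spec$sex, spec$height, spec$weight),
      recordings = recs
    )

    achieved_dice <- NA_real_
    if (length(recs)) {
      r1 <- recs[[1]]
      f1 <- ed_frames[1]
      if (!is.null(r1$masks$lv_primary[[f1]]))
        achieved_dice <- dice(r1$masks$lv_primary[[f1]],
                              r1$masks$lv_secondary[[f1]])
    }

    bsa <- body_surface_area(spec$weight, spec$height)
    truth <- list(
      edv = spec$edv, esv = spec$esv,
      ef = (spec$edv - spec$esv) / spec$edv * 100,
      la_esv = spec$la_esv, bsa = bsa, lavi = spec$la_esv / bsa,
      ed_frames = ed_frames, es_frames = es_frames,
      lv_length_ed = 2 * lv_ed[["a"]], lv_diameter_ed = 2 * lv_ed[["b"]],
      achieved_dice = achieved_dice,
      injected = unclass(corruption),
      expected_exclusion = expected_exclusion_reason(corruption, achieved_dice)
    )
    list(exam = exam, truth = truth)
  })
}

# Predict which curation/QC stage (if any) will exclude the exam, given
# the injected corruption; used by funnel-accounting tests.
expected_exclusion_reason <- function(corruption, achieved_dice,
                                      confidence_threshold = 0.85,
                                      dice_threshold = 0.8) {
  dropped <- corruption$drop_views
  ov <- corruption$confidence_override
  slot_state <- function(variants) {
    present <- setdiff(variants, dropped)
    if (!length(present)) return("missing")
    confs <- vapply(present, function(v) {
      if (v %in% names(ov)) unname(ov[[v]]) else 1
    }, numeric(1))
    if (all(confs < confidence_threshold)) "low_conf" else "ok"
  }
  s4 <- slot_state(c("A4C_LV_focused", "A4C"))
  s2 <- slot_state(c("A2C_LV_focused", "A2C"))
  if (s4 == "missing" && s2 == "missing") return("no_bmode")
  if (s4 == "missing") return("missing_A4C")
  if (s2 == "missing") return("missing_A2C")
  if (s4 == "low_conf" || s2 == "low_conf") return("low_view_confidence")
  if (!is.na(achieved_dice) && achieved_dice < dice_threshold) return("low_dice")
  "none"
}

#' Generate a reproducible synthetic cohort
#'
#' Draws phantom parameters uniformly from the given ranges and applies a
#' corruption mix; everything is driven by the single `seed`.
#'
#' @param n number of exams (>= 1).
#' @param seed integer seed.
#' @param param_ranges named list overriding any of: `edv`, `ef`,
#'   `la_esv`, `heart_rate`, `height`, `weight` (each `c(lo, hi)`),
#'   `frame_rate`, `pixel_spacing` (scalars), `p_female` (probability).
#'   ESV is derived from the drawn EDV and EF.
#' @param corruption_mix list of `list(corruption = corruption_spec(...),
#'   count = k)` (exact number of exams, assigned at random without
#'   overlap) or `list(corruption =, prob = p)` (independent Bernoulli
#'   draw per remaining exam).
#' @return list of `list(exam =, truth =)` pairs.
#' @export
generate_cohort <- function(n, seed = 1L, param_ranges = list(),
                            corruption_mix = list()) {
  if (n < 1) ep_stop("n must be >= 1", "n")
  pr <- utils::modifyList(list(
    edv = c(80, 200), ef = c(20, 70), la_esv = c(30, 90),
    heart_rate = c(55, 95), height = c(150, 195), weight = c(50, 110),
    frame_rate = 50, pixel_spacing = 0.5, p_female = 0.5
  ), param_ranges)
  for (k in c("edv", "ef", "la_esv", "heart_rate", "height", "weight"))
    if (length(pr[[k]]) != 2L || diff(range(pr[[k]])) < 0)
      ep_stop(sprintf("param range '%s' must be c(lo, hi)", k), "param_ranges")

  with_local_seed(seed, {
    runi <- function(r) stats::runif(n, r[1], r[2])
    edv <- runi(pr$edv); ef <- runi(pr$ef)
    la <- runi(pr$la_esv); hr <- runi(pr$heart_rate)
    ht <- runi(pr$height); wt <- runi(pr$weight)
    sexes <- ifelse(stats::runif(n) < pr$p_female, "female", "male")
    exam_seeds <- sample.int(.Machine$integer.max - 1L, n)

    corr <- rep(list(corruption_spec()), n)
    remaining <- seq_len(n)
    for (entry in corruption_mix) {
      stopifnot(inherits(entry$corruption, "corruption_spec"))
      if (!is.null(entry$count)) {
        k <- as.integer(entry$count)
        if (k > length(remaining))
          ep_stop("corruption_mix counts exceed cohort size", "corruption_mix")
        pick <- if (k > 0) sample(remaining, k) else integer()
      } else {
        pick <- remaining[stats::runif(length(remaining)) < (entry$prob %||% 0)]
      }
      for (i in pick) corr[[i]] <- entry$corruption
      remaining <- setdiff(remaining, pick)
    }

    lapply(seq_len(n), function(i) {
      sp <- phantom_spec(
        edv = edv[i], esv = edv[i] * (1 - ef[i] / 100), la_esv = la[i],
        heart_rate = hr[i], frame_rate = pr$frame_rate,
        pixel_spacing = pr$pixel_spacing, sex = sexes[i],
        height = ht[i], weight = wt[i], seed = exam_seeds[i]
      )
      out <- generate_exam(sp, corr[[i]])
      out$exam$study_uid <- sprintf("study_%04d", i)
      out$exam$patient$patient_id <- sprintf("pat_%04d", i)
      out
    })
  })
}
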