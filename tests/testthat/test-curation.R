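test_that("view-confidence gate is inclusive at the threshold", {
  expect_true(gate_view_confidence(0.85))
  expect_false(gate_view_confidence(0.849))
  expect_true(gate_view_confidence(1.0))
  expect_identical(gate_view_confidence(c(0.9, 0.2, NA)),
                   c(TRUE, FALSE, FALSE))
  expect_true(gate_view_confidence(0.849, threshold = 0.8))
})

test_that("image quality aggregation is mean + half-up rounding into 0..5", {
  expect_identical(aggregate_image_quality(c(3, 3, 3, 3)), 3L)
  expect_identical(aggregate_image_quality(c(2.4, 2.4)), 2L)
  expect_identical(aggregate_image_quality(c(2.5)), 3L)
  expect_identical(aggregate_image_quality(c(5, 5, 5)), 5L)
  expect_identical(aggregate_image_quality(c(0, 0)), 0L)
  expect_error(aggregate_image_quality(numeric()), "non-empty")
  expect_error(aggregate_image_quality(c(2, 6)), "\\[0, 5\\]")
})

test_that("oracle backends reproduce the recording's true labels", {
  r <- bare_recording(view = "A4C_LV_focused")
  r2 <- classify_modality(r, classifier_backend("modality", "oracle"))
  expect_identical(r2$modality, "B2D")
  expect_equal(attr(r2, "modality_confidence"), 1)
  r3 <- classify_view(r2, classifier_backend("view", "oracle"))
  expect_identical(r3$view, "A4C_LV_focused")
  expect_equal(r3$view_confidence, 1)
})

test_that("view classification refuses non-B-mode recordings", {
  r <- bare_recording(modality = "cw_doppler", view = "unknown")
  expect_error(classify_view(r, classifier_backend("view", "oracle")),
               "B2D")
})

test_that("a backend violating the probability contract is an error, a crashing backend is not", {
  bad <- structure(list(kind = "modality", taxonomy = echo_modalities(),
                        classify = function(rec)
                          list(label = "B2D",
                               probs = rep(0.9 / 8, 8))),
                   class = "classifier_backend")
  expect_error(classify_modality(bare_recording(), bad), "probabilities")
  crashing <- structure(list(kind = "modality", taxonomy = echo_modalities(),
                             classify = function(rec) stop("GPU on fire")),
                        class = "classifier_backend")
  r <- classify_modality(bare_recording(), crashing)
  expect_identical(r$modality, "unknown")
  expect_match(attr(r, "classification_note"), "GPU")
})

test_that("noisy backend accuracy matches its flip rate within binomial bounds", {
  be <- classifier_backend("view", "noisy", flip_prob = 0.05, seed = 31)
  n <- 200
  hits <- vapply(seq_len(n), function(i) {
    r <- bare_recording(id = paste0("r", i), view = "A2C")
    be$classify(r)$label == "A2C"
  }, logical(1))
  bounds <- qbinom(c(0.001, 0.999), n, 0.95)
  expect_gte(sum(hits), bounds[1])
  expect_lte(sum(hits), bounds[2])
})

test_that("LV view selection prefers focused variants and falls back to standard", {
  ex <- bare_exam(list(
    bare_recording("f4", view = "A4C_LV_focused", conf = 0.90),
    bare_recording("s4", view = "A4C", conf = 0.99),
    bare_recording("s2", view = "A2C", conf = 0.95)))
  sel <- select_views_for_lvef(ex)
  expect_identical(sel$reason, "none")
  expect_identical(sel$slots$A4C, "f4")   # focused wins despite lower conf
  expect_identical(sel$slots$A2C, "s2")
})

test_that("low-confidence views exclude via the confidence gate, absent views via missing_*", {
  ex <- bare_exam(list(
    bare_recording("a4", view = "A4C", conf = 0.95),
    bare_recording("a2", view = "A2C", conf = 0.5)))
  expect_identical(select_views_for_lvef(ex)$reason, "low_view_confidence")
  ex2 <- bare_exam(list(bare_recording("a4", view = "A4C", conf = 0.95)))
  expect_identical(select_views_for_lvef(ex2)$reason, "missing_A2C")
  ex3 <- bare_exam(list(
    bare_recording("d1", modality = "cw_doppler", view = "unknown")))
  expect_identical(select_views_for_lvef(ex3)$reason, "no_bmode")
})

test_that("LA selection uses standard views only", {
  ex <- bare_exam(list(
    bare_recording("f4", view = "A4C_LV_focused"),
    bare_recording("f2", view = "A2C_LV_focused")))
  expect_false(is.null(select_views_for_lvef(ex)$slots))
  la <- select_views_for_lavi(ex)
  expect_null(la$slots)
  ex2 <- bare_exam(list(
    bare_recording("s4", view = "A4C"),
    bare_recording("s2", view = "A2C")))
  la2 <- select_views_for_lavi(ex2)
  expect_identical(la2$slots$A4C, "s4")
  expect_identical(la2$slots$A2C, "s2")
  ex3 <- bare_exam(list(bare_recording("s4", view = "A4C")))
  expect_identical(select_views_for_lavi(ex3)$reason, "missing_A2C_for_LA")
})

test_that("curation includes pristine phantoms and excludes TEE-only exams", {
  g <- generate_exam(phantom_spec(seed = 41))
  out <- curate_exam(g$exam, default_config())
  expect_true(out$included)
  expect_identical(out$exclusion_reason, "none")
  expect_length(out$selected_lv, 2L)
  expect_true(out$la_available)
  expect_true(out$quality_class %in% 0:5)

  tee <- bare_exam(list(bare_recording("t1", view = "TEE")))
  out2 <- curate_exam(tee, default_config())
  expect_false(out2$included)
  expect_identical(out2$exclusion_reason, "other")
  expect_match(out2$exclusion_detail, "transoesophageal")
})

test_that("raising the confidence threshold never includes more exams", {
  cohort <- generate_cohort(
    12, seed = 51,
    corruption_mix = list(list(
      corruption = corruption_spec(
        confidence_override = c(A4C_LV_focused = 0.9, A4C = 0.9)),
      prob = 0.5)))
  n_included <- function(th) {
    cfg <- pipeline_config(confidence_threshold = th)
    sum(vapply(cohort, function(x) curate_exam(x$exam, cfg)$included,
               logical(1)))
  }
  counts <- vapply(c(0.5, 0.85, 0.95, 0.99), n_included, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("every excluded exam carries exactly one primary reason and counts partition the cohort", {
  cohort <- generate_cohort(
    20, seed = 52,
    corruption_mix = list(
      list(corruption = corruption_spec(drop_views = c("A2C", "A2C_LV_focused")),
           count = 3),
      list(corruption = corruption_spec(
        confidence_override = c(A2C = 0.2, A2C_LV_focused = 0.2)), count = 4)))
  outs <- lapply(cohort, function(x) curate_exam(x$exam, default_config()))
  reasons <- vapply(outs, `[[`, character(1), "exclusion_reason")
  included <- vapply(outs, `[[`, logical(1), "included")
  expect_true(all(reasons %in% exclusion_reasons()))
  expect_identical(included, reasons == "none")
  expect_equal(sum(included) + sum(reasons != "none"), 20L)
  expect_equal(sum(reasons == "missing_A2C"), 3L)
  expect_equal(sum(reasons == "low_view_confidence"), 4L)
})
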