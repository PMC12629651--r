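test_that("ground-truth EF is forced by the volume definition", {
  g <- generate_exam(phantom_spec(edv = 150, esv = 75))
  expect_equal(g$truth$ef, 50)
  g2 <- generate_exam(phantom_spec(edv = 120, esv = 40))
  expect_equal(g2$truth$ef, (120 - 40) / 120 * 100)
})

test_that("the two orthogonal views share the long axis at every masked frame", {
  g <- generate_exam(phantom_spec(seed = 21))
  recs <- g$exam$recordings
  ids <- vapply(recs, `[[`, character(1), "recording_id")
  a4c <- recs[[which(ids == "rec_A4C_LV_focused")]]
  a2c <- recs[[which(ids == "rec_A2C_LV_focused")]]
  for (f in c(g$truth$ed_frames[1], g$truth$es_frames[1])) {
    ax1 <- extract_long_axis(a4c$masks$lv_primary[[f]], a4c$pixel_spacing)
    ax2 <- extract_long_axis(a2c$masks$lv_primary[[f]], a2c$pixel_spacing)
    expect_equal(ax1$length, ax2$length, tolerance = 1e-12)
  }
})

test_that("rasterized mask area converges to the analytic section area", {
  area_err <- function(sp, edv) {
    g <- generate_exam(phantom_spec(pixel_spacing = sp, edv = edv,
                                    esv = 0.4 * edv))
    r <- g$exam$recordings[[1]]
    ed <- g$truth$ed_frames[1]
    truth <- pi * g$truth$lv_length_ed / 2 * g$truth$lv_diameter_ed / 2
    abs(mask_area(r$masks$lv_primary[[ed]], sp) - truth) / truth
  }
  edvs <- c(100, 130, 160, 190)
  coarse <- mean(vapply(edvs, function(e) area_err(1.0, e), numeric(1)))
  fine <- mean(vapply(edvs, function(e) area_err(0.5, e), numeric(1)))
  expect_lt(fine, coarse)
  expect_lt(fine, 0.01)
})

test_that("measured biplane volume error decreases as spacing is halved", {
  edv_err <- function(sp, edv) {
    g <- generate_exam(phantom_spec(pixel_spacing = sp, edv = edv,
                                    esv = 0.4 * edv))
    recs <- g$exam$recordings
    ids <- vapply(recs, `[[`, character(1), "recording_id")
    ed <- g$truth$ed_frames[1]
    v <- biplane_simpson(
      recs[[which(ids == "rec_A4C_LV_focused")]]$masks$lv_primary[[ed]],
      recs[[which(ids == "rec_A2C_LV_focused")]]$masks$lv_primary[[ed]],
      sp, sp)
    abs(v$volume - g$truth$edv) / g$truth$edv
  }
  edvs <- c(100, 130, 160, 190)
  coarse <- mean(vapply(edvs, function(e) edv_err(1.0, e), numeric(1)))
  fine <- mean(vapply(edvs, function(e) edv_err(0.5, e), numeric(1)))
  expect_lt(fine, coarse)
})

test_that("ES frames sit at the sex-specific regression offset from ED", {
  for (sex in c("male", "female")) {
    sp <- phantom_spec(sex = sex, heart_rate = 72, frame_rate = 50)
    g <- generate_exam(sp)
    off <- round_half_up(regression_es_offset(sex, 72) * 50 / 1000)
    expect_equal(g$truth$es_frames, g$truth$ed_frames + off)
  }
})

test_that("corruption targeting an absent view is rejected", {
  expect_error(
    generate_exam(phantom_spec(),
                  corruption_spec(drop_views = "PLAX")),
    "not generated")
  expect_error(corruption_spec(confidence_override = c(0.5)),
               "named by view")
  expect_error(corruption_spec(dice_degradation = 1.5), "dice_degradation")
})

test_that("dice degradation measurably lowers the secondary-mask agreement", {
  g <- generate_exam(phantom_spec(seed = 22),
                     corruption_spec(dice_degradation = 1))
  expect_lt(g$truth$achieved_dice, 0.8)
  expect_gt(g$truth$achieved_dice, 0.4)
  g0 <- generate_exam(phantom_spec(seed = 22))
  expect_equal(g0$truth$achieved_dice, 1)
})

test_that("cohorts are reproducible and respect parameter ranges", {
  c1 <- generate_cohort(6, seed = 42)
  c2 <- generate_cohort(6, seed = 42)
  expect_identical(c1, c2)
  c3 <- generate_cohort(6, seed = 43)
  expect_false(identical(c1, c3))
  co <- generate_cohort(20, seed = 7, param_ranges = list(ef = c(20, 70)))
  efs <- vapply(co, function(x) x$truth$ef, numeric(1))
  expect_true(all(efs > 20 & efs < 70))
})

test_that("probabilistic corruption mix hits its rate within binomial bounds", {
  n <- 60
  co <- generate_cohort(
    n, seed = 99,
    corruption_mix = list(list(
      corruption = corruption_spec(
        confidence_override = c(A2C = 0.5, A2C_LV_focused = 0.5)),
      prob = 0.2)))
  k <- sum(vapply(co, function(x)
    x$truth$expected_exclusion == "low_view_confidence", logical(1)))
  bounds <- qbinom(c(0.001, 0.999), n, 0.2)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("count-based corruption mix injects exactly the requested numbers", {
  co <- generate_cohort(
    25, seed = 5,
    corruption_mix = list(
      list(corruption = corruption_spec(drop_views = c("A2C", "A2C_LV_focused")),
           count = 4),
      list(corruption = corruption_spec(dice_degradation = 1), count = 6)))
  exp <- vapply(co, function(x) x$truth$expected_exclusion, character(1))
  expect_equal(sum(exp == "missing_A2C"), 4L)
  expect_equal(sum(exp == "low_dice"), 6L)
  expect_equal(sum(exp == "none"), 15L)
})
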