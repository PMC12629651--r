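test_that("Dice matches hand-counted overlaps", {
  m <- matrix(FALSE, 5, 5)
  a <- m; a[2:3, 2:3] <- TRUE            # 2x2 block
  b <- m; b[2:3, 3:4] <- TRUE            # shifted one column: overlap 2 px
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 2 * 2 / (4 + 4))
  disj <- m; disj[5, 5] <- TRUE
  expect_equal(dice(a, disj), 0)
  expect_equal(dice(m, m), 1)            # empty vs empty agrees
  expect_error(dice(a, matrix(FALSE, 4, 4)), "dimensions")
})

test_that("segmentation QC is inclusive at Dice 0.8", {
  at <- masks_with_dice(10, 10, 8)       # dice = 16/20 = 0.8
  q <- segmentation_qc(at$a, at$b)
  expect_equal(q$dice, 0.8)
  expect_true(q$pass)
  below <- masks_with_dice(100, 100, 79, dims = c(4, 200))  # 158/200 = 0.79
  q2 <- segmentation_qc(below$a, below$b)
  expect_equal(q2$dice, 0.79)
  expect_false(q2$pass)
  expect_true(segmentation_qc(at$a, at$a)$pass)
})

test_that("long-axis extraction recovers ellipse length, rotated or not", {
  m <- rasterize_ellipse(120, 80, c(60.5, 40.5), c(40, 20))
  ax <- extract_long_axis(m, 0.5)
  expect_s3_class(ax, "long_axis")
  expect_lt(abs(ax$length - 40), 0.5)    # within 1 px of 2*40px*0.5mm
  mr <- rasterize_ellipse(140, 140, c(70.5, 70.5), c(40, 20), angle_deg = 30)
  axr <- extract_long_axis(mr, 0.5)
  expect_lt(abs(axr$length - ax$length), 0.5)
})

test_that("degenerate masks yield invalid-segmentation signals", {
  tiny <- matrix(FALSE, 10, 10); tiny[5, 5:6] <- TRUE
  expect_s3_class(extract_long_axis(tiny, 0.5), "echopipe_exclusion")
  split2 <- matrix(FALSE, 40, 40)
  split2[2:12, 2:12] <- TRUE; split2[25:35, 25:35] <- TRUE
  sig <- extract_long_axis(split2, 0.5)
  expect_s3_class(sig, "echopipe_exclusion")
  expect_identical(sig$reason, "invalid_segmentation")
})

test_that("disc diameters follow the analytic chord profile", {
  m <- rasterize_ellipse(200, 120, c(100.5, 60.5), c(80, 40))  # px semi-axes
  ax <- extract_long_axis(m, 0.5)
  d <- disc_diameters(m, ax, 0.5, 20)
  tc <- (seq_len(20) - 0.5) * ax$length_px / 20 - ax$length_px / 2
  analytic <- 2 * 40 * sqrt(pmax(0, 1 - (tc / 80)^2)) * 0.5
  expect_true(all(abs(d - analytic) <= 1 * 0.5))  # within 1 px everywhere

  s <- rasterize_ellipse(150, 150, c(75.5, 75.5), c(60, 60))   # circle r=30mm
  axs <- extract_long_axis(s, 0.5)
  ds <- disc_diameters(s, axs, 0.5, 20)
  expect_lt(abs(ds[10] - 2 * 30), 0.5)
  # slabs beyond the mask get zero diameter: shrink the mask, keep the axis
  small <- rasterize_ellipse(200, 120, c(100.5, 60.5), c(30, 20))
  d2 <- disc_diameters(small, ax, 0.5, 20)
  expect_equal(d2[1], 0)
  expect_equal(d2[20], 0)
})

test_that("biplane Simpson reproduces closed-form ellipsoid and sphere volumes", {
  m <- rasterize_ellipse(200, 120, c(100.5, 60.5), c(80, 40))
  v <- biplane_simpson(m, m, 0.5, 0.5, 20)
  truth <- pi / 6 * 80 * 40 * 40 / 1000   # 67.0 mL
  expect_lt(abs(v$volume - truth) / truth, 0.02)
  expect_length(v$diameters_a, 20L)
  expect_false(v$foreshortening_warning)

  s <- rasterize_ellipse(150, 150, c(75.5, 75.5), c(60, 60))
  vs <- biplane_simpson(s, s, 0.5, 0.5, 20)
  sphere <- 4 / 3 * pi * 30^3 / 1000      # 113.1 mL
  expect_lt(abs(vs$volume - sphere) / sphere, 0.02)

  empty <- matrix(FALSE, 50, 50)
  expect_s3_class(biplane_simpson(empty, m, 0.5, 0.5), "echopipe_exclusion")
})

test_that("volumes are rotation invariant and scale equivariant", {
  truth <- pi / 6 * 80 * 40 * 40 / 1000
  m0 <- rasterize_ellipse(200, 120, c(100.5, 60.5), c(80, 40))
  v0 <- biplane_simpson(m0, m0, 0.5, 0.5, 20)$volume
  mr <- rasterize_ellipse(260, 260, c(130.5, 130.5), c(80, 40), angle_deg = 30)
  vr <- biplane_simpson(mr, mr, 0.5, 0.5, 20)$volume
  expect_lt(abs(vr - v0) / v0, 0.02)
  # same physical object, twice the grid at half the spacing
  m2 <- rasterize_ellipse(400, 240, c(200.5, 120.5), c(160, 80))
  v2 <- biplane_simpson(m2, m2, 0.25, 0.25, 20)$volume
  expect_lt(abs(v2 - v0) / v0, 0.02)
  expect_lt(abs(v2 - truth) / truth, 0.02)
})

test_that("view-length discrepancy above 20% raises the foreshortening flag", {
  long <- rasterize_ellipse(200, 120, c(100.5, 60.5), c(80, 40))
  short <- rasterize_ellipse(200, 120, c(100.5, 60.5), c(55, 40))
  v <- biplane_simpson(long, short, 0.5, 0.5, 20)
  expect_true(v$foreshortening_warning)
  expect_equal(v$length, extract_long_axis(long, 0.5)$length)
})

test_that("EF, BSA and LAVI arithmetic", {
  expect_equal(ejection_fraction(100, 50), 50)
  expect_equal(ejection_fraction(150, 150), 0)
  expect_equal(ejection_fraction(120, 40), 200 / 3)
  expect_error(ejection_fraction(0, 10), "positive")

  expect_equal(body_surface_area(100, 36), 1)
  expect_equal(body_surface_area(72, 180), sqrt(72 * 180) / 60)
  expect_error(body_surface_area(0, 180), "positive")
  # DuBois alternative agrees with Mosteller to ~5% for average adults
  expect_equal(body_surface_area(72, 180, "dubois"),
               body_surface_area(72, 180), tolerance = 0.05)

  expect_equal(lavi(68, 2), 34)
  expect_equal(lavi(0, 1.5), 0)
  expect_equal(lavi(60, sqrt(72 * 180) / 60), 60 / 1.8974, tolerance = 1e-3)
  expect_error(lavi(60, 0), "positive")
})

test_that("EF is bounded and monotone decreasing in ESV at fixed EDV", {
  esvs <- seq(10, 140, by = 10)
  efs <- vapply(esvs, function(s) ejection_fraction(150, s), numeric(1))
  expect_true(all(efs > 0 & efs < 100))
  expect_true(all(diff(efs) < 0))
})

test_that("a pristine phantom is measured within discretization tolerance", {
  m <- measure_phantom(phantom_spec(edv = 150, esv = 75))
  expect_true(m$result$included)
  expect_lt(abs(m$result$ef - 50), 2)
  expect_lt(abs(m$result$edv - 150) / 150, 0.02)
  expect_lt(abs(m$result$lavi - m$truth$lavi), 2)
  expect_equal(m$result$dice_ed, 1)
  expect_identical(m$result$timing_source, "network")
  expect_equal(m$result$n_clips_averaged, 2L)
})

test_that("strong secondary-mask disagreement excludes the exam at the Dice gate", {
  m <- measure_phantom(phantom_spec(seed = 71),
                       corruption_spec(dice_degradation = 1))
  expect_false(m$result$included)
  expect_identical(m$result$exclusion_reason, "low_dice")
})

test_that("duplicated clips are averaged without changing the measurement", {
  base <- measure_phantom(phantom_spec(seed = 72))
  g <- generate_exam(phantom_spec(seed = 72))
  dup <- g$exam$recordings[[1]]
  dup$recording_id <- "rec_A4C_LV_focused_copy"
  g$exam$recordings <- c(g$exam$recordings, list(dup))
  cfg <- default_config()
  cur <- curate_exam(g$exam, cfg)
  ev <- list()
  for (r in cur$exam$recordings)
    ev[[r$recording_id]] <- recording_events(r, cur$exam$patient,
                                             cfg$timing_backend)
  res <- measure_exam(cur$exam, cur, ev, cfg)
  expect_equal(res$n_clips_averaged, 3L)
  expect_equal(res$ef, base$result$ef, tolerance = 1e-12)
  expect_equal(res$edv, base$result$edv, tolerance = 1e-12)
})

test_that("missing timing on all clips excludes with the timing reason", {
  m <- measure_phantom(phantom_spec(seed = 73),
                       corruption_spec(disable_timing_network = TRUE),
                       config = default_config())
  # ECG fallback still works: exam measured, source recorded
  expect_true(m$result$included)
  expect_identical(m$result$timing_source, "ecg_regression")

  # remove heart rate too: no timing source at all
  g <- generate_exam(phantom_spec(seed = 73),
                     corruption_spec(disable_timing_network = TRUE))
  g$exam$recordings <- lapply(g$exam$recordings, function(r) {
    r$heart_rate <- NULL; r
  })
  cfg <- default_config()
  cur <- curate_exam(g$exam, cfg)
  ev <- list()
  for (r in cur$exam$recordings)
    ev[[r$recording_id]] <- recording_events(r, cur$exam$patient,
                                             cfg$timing_backend)
  res <- measure_exam(cur$exam, cur, ev, cfg)
  expect_false(res$included)
  expect_identical(res$exclusion_reason, "timing_unavailable")
})
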