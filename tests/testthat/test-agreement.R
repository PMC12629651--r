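test_that("Bland-Altman handles the degenerate and hand-computed cases", {
  st <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(st$bias, 0)
  expect_equal(st$sd, 0)
  st2 <- bland_altman(c(2, 0), c(1, 1))   # differences +1, -1
  expect_equal(st2$bias, 0)
  expect_equal(st2$sd, sqrt(2))
  expect_equal(st2$loa_high, 1.96 * sqrt(2))
  expect_equal(st2$loa_low, -1.96 * sqrt(2))
  expect_error(bland_altman(1:3, 1:4), "equal length")
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Bland-Altman equals a brute-force recomputation to 1e-12 relative", {
  withr::with_seed(81, {
    for (i in 1:20) {
      n <- sample(5:200, 1)
      auto <- rnorm(n, 50, 10); ref <- auto + rnorm(n, -2, 5)
      st <- bland_altman(auto, ref)
      d <- numeric(n)
      for (j in seq_len(n)) d[j] <- auto[j] - ref[j]   # explicit loop oracle
      mu <- sum(d) / n
      ss <- 0
      for (j in seq_len(n)) ss <- ss + (d[j] - mu)^2
      sdv <- sqrt(ss / (n - 1))
      expect_equal(st$bias, mu, tolerance = 1e-12)
      expect_equal(st$sd, sdv, tolerance = 1e-12)
      expect_equal(st$loa_low, mu - 1.96 * sdv, tolerance = 1e-12)
      expect_equal(st$loa_high, mu + 1.96 * sdv, tolerance = 1e-12)
    }
  })
})

test_that("injected Gaussian error is recovered at Monte-Carlo scale", {
  withr::with_seed(82, {
    n <- 5000
    ref <- runif(n, 20, 70)
    auto <- ref + rnorm(n, mean = -1.8, sd = 7.6)
    st <- bland_altman(auto, ref)
    expect_lt(abs(st$bias - (-1.8)), 0.3)
    expect_lt(abs(st$sd - 7.6), 0.2)
  })
})

test_that("stratified agreement recovers per-group biases and reduces to the pooled case", {
  withr::with_seed(83, {
    n <- 2000
    grp <- sample(c("low", "high"), n, replace = TRUE)
    ref <- runif(n, 30, 60)
    auto <- ref + ifelse(grp == "low", rnorm(n, -3, 2), rnorm(n, 2, 2))
    res <- stratified_agreement(auto, ref, data.frame(quality = grp))
    lo <- res[res$value == "low", ]; hi <- res[res$value == "high", ]
    expect_lt(abs(lo$bias - (-3)), 0.3)
    expect_lt(abs(hi$bias - 2), 0.3)
    # n-weighted subgroup biases reproduce the pooled bias exactly
    pooled <- bland_altman(auto, ref)
    expect_equal((lo$n * lo$bias + hi$n * hi$bias) / n, pooled$bias,
                 tolerance = 1e-12)

    # overlapping logical flags: each pair counted in every matching group
    flags <- data.frame(hf = runif(n) < 0.4, ischaemic = runif(n) < 0.5)
    res2 <- stratified_agreement(auto, ref, flags)
    expect_equal(sum(res2$n[res2$value == "with"]) +
                 sum(res2$n[res2$value == "without"]), 2L * n)

    # a single all-encompassing group is just bland_altman
    res3 <- stratified_agreement(auto, ref, data.frame(all = rep("a", n)))
    expect_equal(res3$bias, pooled$bias)
    expect_equal(res3$sd, pooled$sd)
  })
})

test_that("tiny subgroups are reported without statistics", {
  res <- stratified_agreement(c(1, 2, 3), c(1, 1, 1),
                              data.frame(g = c("a", "a", "b")))
  b <- res[res$value == "b", ]
  expect_equal(b$n, 1L)
  expect_true(is.na(b$sd))
})

test_that("the feasibility funnel conserves counts stage by stage", {
  reasons <- c(rep("none", 85), rep("missing_A2C", 5), rep("low_dice", 10))
  f <- feasibility_funnel(reasons)
  st <- f$stages
  expect_equal(st$surviving[st$stage == "views_present"], 95)
  expect_equal(st$surviving[st$stage == "dice_qc"], 85)
  expect_equal(f$feasibility, 85)
  expect_true(all(st$entering - st$excluded == st$surviving))
  expect_equal(st$entering[-1], st$surviving[-nrow(st)])
  expect_error(feasibility_funnel(c("none", "bad_reason")), "unknown")
})

test_that("funnel edge cases: no corruption and all-TEE cohorts", {
  f <- feasibility_funnel(rep("none", 40))
  expect_equal(f$feasibility, 100)
  expect_true(all(f$stages$excluded == 0))
  f2 <- feasibility_funnel(rep("other", 10))   # TEE-only exams
  expect_equal(f2$feasibility, 0)
  expect_equal(f2$stages$excluded[1], 10)
  expect_true(all(f2$stages$excluded[-1] == 0))
})

test_that("distribution summaries behave on degenerate and Gaussian samples", {
  s <- distribution_summary(rep(3.5, 10))
  expect_equal(sum(s$counts > 0), 1L)
  expect_null(s$density)
  x <- withr::with_seed(84, rnorm(2000, 10, 1))
  s1 <- distribution_summary(x, bins = 12); s2 <- distribution_summary(x, bins = 12)
  expect_identical(s1$counts, s2$counts)
  mode_at <- s1$density$x[which.max(s1$density$y)]
  expect_lt(abs(mode_at - 10), diff(s1$breaks[1:2]))
})
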