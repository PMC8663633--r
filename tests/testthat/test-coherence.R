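test_that("the multi-trial confidence limit follows its closed form", {
  expect_identical(confidence_limit(2), 1 - 0.05)
  expect_equal(confidence_limit(20), 1 - 0.05^(1 / 19), tolerance = 1e-15)
  expect_equal(confidence_limit(100), 1 - 0.05^(1 / 99), tolerance = 1e-15)
  cls <- confidence_limit(2:200)
  expect_true(all(diff(cls) < 0))
  expect_error(confidence_limit(1), class = "emgait_domain_error")
})

test_that("identical epochs give coherence 1 at every bin", {
  set.seed(15)
  x <- matrix(rnorm(10 * 200), 10)
  res <- coherence_spectrum(coherence_input(x, x, fs = 1000))
  expect_true(all(abs(res$coherence - 1) < 1e-9))
  expect_equal(res$frequencies[2] - res$frequencies[1], 5)
  expect_equal(res$L, 10)
})

test_that("coherence is bounded and invariant to channel rescaling", {
  set.seed(16)
  x <- matrix(rnorm(8 * 200), 8)
  y <- 0.4 * x + matrix(rnorm(8 * 200), 8)
  r1 <- coherence_spectrum(coherence_input(x, y, fs = 1000))
  expect_true(all(r1$coherence >= 0 & r1$coherence <= 1))
  r2 <- coherence_spectrum(coherence_input(5 * x, 0.01 * y, fs = 1000))
  expect_equal(r1$coherence, r2$coherence, tolerance = 1e-9)
})

test_that("band areas integrate the coherence curve", {
  res <- structure(list(frequencies = seq(0, 500, 5),
                        coherence = rep(0.5, 101),
                        confidence_limit = 0.2,
                        bands = coherence_bands()),
                   class = "coherence_result")
  expect_equal(band_area(res, c(15, 30)), 0.5 * 15)
  res$coherence <- rep(0, 101)
  expect_equal(band_area(res, c(30, 45)), 0)
  # linear ramp 0 -> 1 across a 15 Hz band integrates to 7.5
  res$coherence <- rep(0, 101)
  sel <- res$frequencies >= 15 & res$frequencies <= 30
  res$coherence[sel] <- seq(0, 1, length.out = sum(sel))
  expect_equal(band_area(res, c(15, 30)), 7.5)
  expect_error(band_area(res, c(600, 700)), class = "emgait_empty_band")
})

test_that("band significance tests unambiguous bins against the limit", {
  res <- structure(list(frequencies = seq(0, 500, 5),
                        coherence = rep(0, 101),
                        confidence_limit = 0.146,
                        bands = coherence_bands()),
                   class = "coherence_result")
  expect_false(band_significant(res, "gamma"))
  res$coherence[res$frequencies == 40] <- 1
  expect_true(band_significant(res, "gamma"))
  expect_false(band_significant(res, "beta"))
  expect_false(band_significant(res, "alpha"))
  # the 30 Hz bin is shared by beta and gamma: excluded from both tests
  # by default, counted by both with boundary = "include"
  res$coherence <- rep(0, 101)
  res$coherence[res$frequencies == 30] <- 1
  expect_false(band_significant(res, "beta"))
  expect_false(band_significant(res, "gamma"))
  expect_true(band_significant(res, "beta", boundary = "include"))
  expect_true(band_significant(res, "gamma", boundary = "include"))
})

test_that("epochs are extracted from each step's co-activation slot", {
  fx <- fixture_cohort()
  rec <- fx$sims[[3]]$recording
  seg <- segment_recording(rec)
  profs <- recording_profiles(rec, seg)
  inp <- extract_epochs(rec, seg, profs, c("RF", "ST"), side = "R")
  expect_equal(ncol(inp$x), round(0.2 * rec$sampling_rate))
  expect_equal(ncol(inp$x), 200)
  expect_equal(inp$L, nrow(seg$steps))
  expect_true(all(inp$x >= 0))  # rectified input
})

test_that("muscles that never co-activate have no common slot", {
  tpl <- list(SOL = default_templates()$SOL,
              RF = muscle_template("RF", list(c(0, 30))),
              ST = muscle_template("ST", list(c(50, 80))))
  sim <- simulate_recording(tpl, n_steps = 10, seed = 44, sides = "R")
  seg <- segment_recording(sim$recording)
  profs <- recording_profiles(sim$recording, seg)
  expect_error(extract_epochs(sim$recording, seg, profs, c("RF", "ST"),
                              side = "R", phase_range = c(0, 100)),
               class = "emgait_no_common_slot")
})

test_that("step counts are matched before comparing timepoints", {
  set.seed(18)
  a <- coherence_input(matrix(rnorm(18 * 200), 18),
                       matrix(rnorm(18 * 200), 18), fs = 1000)
  b <- coherence_input(matrix(rnorm(24 * 200), 24),
                       matrix(rnorm(24 * 200), 24), fs = 1000)
  m <- match_step_counts(a, b)
  expect_equal(m$t0$L, 18)
  expect_equal(m$t1$L, 18)
  expect_identical(m$t1$x, b$x[1:18, ])
  r0 <- coherence_spectrum(m$t0)
  r1 <- coherence_spectrum(m$t1)
  expect_identical(r0$confidence_limit, r1$confidence_limit)
  # equal counts are left unchanged
  m2 <- match_step_counts(a, a)
  expect_identical(m2$t0$x, a$x)
})

test_that("improvement classification follows the band-specific rules", {
  combos <- expand.grid(t0 = c(FALSE, TRUE), t1 = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    t0 <- combos$t0[i]
    t1 <- combos$t1[i]
    expect_identical(classify_improvement(t0, t1, "alpha"), !t0 && t1)
    expect_identical(classify_improvement(t0, t1, "beta"), t0 && !t1)
    expect_identical(classify_improvement(t0, t1, "gamma"), t0 && !t1)
  }
})

test_that("too few epochs are refused", {
  expect_error(coherence_input(matrix(rnorm(200), 1),
                               matrix(rnorm(200), 1), fs = 1000),
               class = "emgait_too_few_epochs")
})
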