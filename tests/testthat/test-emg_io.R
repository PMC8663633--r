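test_that("recordings round-trip through the TSV dialect bit-exactly", {
  rec <- make_toy_recording()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$samples, rec$samples)
  expect_identical(back$footswitch, rec$footswitch)
  expect_identical(back$sampling_rate, rec$sampling_rate)
  expect_identical(back$subject_id, rec$subject_id)
  expect_identical(back$timepoint, rec$timepoint)
  expect_identical(back$group, rec$group)
  expect_identical(vapply(back$channels, format, ""),
                   vapply(rec$channels, format, ""))
})

test_that("round-trip preserves randomly generated recordings", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(10:80, 1)
    k <- sample(1:4, 1)
    muscles <- sample(c("TA", "SOL", "RF", "ST"), k)
    sides <- sample(c("L", "R"), k, replace = TRUE)
    chans <- mapply(channel_label, sides, muscles, SIMPLIFY = FALSE)
    rec <- emg_recording(matrix(rnorm(n * k) * 10^sample(-3:3, 1),
                                ncol = k),
                         chans, sampling_rate = sample(c(500, 1000, 2000), 1),
                         footswitch = if (i %% 2) rbinom(n, 1, 0.5),
                         subject_id = paste0("S", i),
                         timepoint = sample(c("T0", "T1"), 1),
                         group = sample(c("CG", "EG"), 1))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_recording(rec, path)
    back <- read_recording(path)
    expect_identical(back$samples, rec$samples)
    expect_identical(back$footswitch, rec$footswitch)
  }
})

test_that("duration follows from length and rate", {
  rec <- emg_recording(matrix(rnorm(10000), ncol = 1),
                       list(channel_label("R", "SOL")),
                       sampling_rate = 1000)
  expect_equal(duration(rec), 10)
  expect_equal(n_samples(rec), 10000)
})

test_that("an empty recording writes a header-only file that reads back", {
  rec <- emg_recording(matrix(0, nrow = 0, ncol = 1),
                       list(channel_label("L", "RF")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(n_samples(back), 0)
  expect_identical(format(back$channels[[1]]), "L_RF")
})

test_that("the footswitch column is written and declared", {
  rec <- make_toy_recording(n = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  lines <- readLines(path)
  cols <- strsplit(lines[!startsWith(lines, "#")][1], "\t")[[1]]
  expect_identical(cols[length(cols)], "footswitch")
})

test_that("constructor rejects invariant violations, never coerces", {
  ch <- list(channel_label("L", "TA"))
  expect_error(emg_recording(list(a = 1:3, b = 1:4),
                             list(channel_label("L", "TA"),
                                  channel_label("R", "TA"))),
               class = "emgait_ragged_channels")
  # non-binary footswitch is a value error, not a length error
  err <- tryCatch(emg_recording(matrix(rnorm(3)), ch, footswitch = c(0, 2, 1)),
                  condition = identity)
  expect_s3_class(err, "emgait_bad_footswitch")
  expect_false(inherits(err, "emgait_ragged_channels"))
  expect_error(emg_recording(matrix(rnorm(3)), ch, footswitch = c(0, 1)),
               class = "emgait_ragged_channels")
  expect_error(channel_label("L", "GAS"), class = "emgait_unknown_muscle")
  expect_error(emg_recording(matrix(rnorm(3)), ch, sampling_rate = 0),
               class = "emgait_bad_rate")
  expect_error(emg_recording(matrix(rnorm(6), ncol = 2),
                             list(channel_label("L", "TA"),
                                  channel_label("L", "TA"))),
               class = "emgait_duplicate_channel")
  expect_error(emg_recording(matrix(rnorm(3)),
                             list(channel_label("L", "TA", "PARETIC")),
                             group = "HEALTHY"),
               class = "emgait_bad_role")
})

test_that("reader rejects malformed files", {
  rec <- make_toy_recording(n = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  lines <- readLines(path)

  # missing rate header
  p2 <- withr::local_tempfile()
  writeLines(lines[-1], p2)
  expect_error(read_recording(p2), class = "emgait_malformed_header")

  # unknown muscle in channel list
  p3 <- withr::local_tempfile()
  writeLines(sub("L_TA", "L_XX", lines), p3)
  expect_error(read_recording(p3), class = "emgait_unknown_muscle")

  # ragged data row
  p4 <- withr::local_tempfile()
  bad <- lines
  bad[length(bad)] <- "0.5"
  writeLines(bad, p4)
  expect_error(read_recording(p4), class = "emgait_error")

  # footswitch value outside {0,1}
  p5 <- withr::local_tempfile()
  bad <- lines
  last <- strsplit(bad[length(bad)], "\t")[[1]]
  last[length(last)] <- "2"
  bad[length(bad)] <- paste(last, collapse = "\t")
  writeLines(bad, p5)
  expect_error(read_recording(p5), class = "emgait_bad_footswitch")

  expect_error(read_recording(file.path(tempdir(), "nope.tsv")),
               class = "emgait_io_failure")
})
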