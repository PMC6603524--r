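test_that("TSV recording round-trips exactly and declares its rate", {
  set.seed(1)
  rec <- recording(rnorm(250), 125, "LFP", startTime = 0)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRecording(rec, f)
  back <- readRecording(f, "LFP")
  expect_identical(samples(back), samples(rec))
  expect_equal(rate(back), 125)
  expect_equal(length(samples(back)), 250)
})

test_that("two-column text input infers the rate and rejects gapped time", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tt <- (0:99) / 125
  writeLines(sprintf("%.10f\t%.6f", tt, sin(tt)), f)
  rec <- readRecording(f, "LFP")
  expect_equal(rate(rec), 125, tolerance = 1e-6)
  # insert a gap > 2 sample intervals
  tt2 <- tt
  tt2[51:100] <- tt2[51:100] + 3 / 125
  writeLines(sprintf("%.10f\t%.6f", tt2, sin(tt)), f)
  expect_error(readRecording(f, "LFP"), "non-uniform")
})

test_that("EDF write/read round-trips within 16-bit quantization", {
  set.seed(7)
  lfp <- recording(cumsum(rnorm(2500)), 250, "LFP")
  emg <- recording(rnorm(2500, sd = 40), 250, "EMG")
  f <- withr::local_tempfile(fileext = ".edf")
  writeEDF(list(lfp, emg), f)
  edf <- readEDF(f)
  expect_equal(length(edf$signals), 2L)
  expect_equal(edf$rates, c(250, 250))
  lsb <- diff(range(samples(lfp))) / 65535
  expect_lt(max(abs(edf$signals[[1]] - samples(lfp))), 1.5 * lsb)
  # odd length (padding in the last record must be trimmed on read)
  odd <- recording(rnorm(777), 111, "LFP")
  writeEDF(odd, f)
  expect_equal(length(readEDF(f)$signals[[1]]), 777L)
  back <- readRecording(f, "LFP")
  expect_equal(rate(back), 111)
})

test_that("label tracks round-trip, reject overlap, allow empty files", {
  lt <- labelTrack(c(0, 10, 12), c(10, 12, 40), c("NT", "TO", "T"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLabels(lt, f)
  back <- readLabels(f)
  expect_equal(segments(back), segments(lt))
  expect_error(labelTrack(c(0, 5), c(10, 12), c("NT", "TO")), "overlap")
  writeLines("# start\tend\tstate", f)
  expect_equal(nrow(segments(readLabels(f))), 0L)
  # half-open intervals: boundary time belongs to the later segment
  expect_equal(stateAt(lt, c(0, 10, 12, 39.9, 40)),
               c("NT", "TO", "T", "T", NA))
})

test_that("measure series round-trip preserves values, params and bands", {
  ms <- tremorRN:::.measureSeries(
    midTimes = seq(1, 3, by = 0.2), C = seq(0.1, 1.1, by = 0.1),
    T = seq(0.2, 1.2, by = 0.1), A = c(NA, seq(0.1, 1, by = 0.1)),
    degenerate = rep(FALSE, 11), params = embeddingParams(6, 4), rr = 0.03)
  bands <- lapply(c(C = "C", T = "T", A = "A"), function(m)
    significanceBands(ms, m, medianWindowN = 3, baseline = "all"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMeasures(ms, f, bands)
  back <- readMeasures(f)
  expect_equal(measureValues(back$series, "C"), measureValues(ms, "C"))
  expect_equal(measureValues(back$series, "A"), measureValues(ms, "A"))
  expect_equal(back$series@params@tau, 6L)
  expect_equal(back$series@params@m, 4L)
  expect_equal(back$bands$T@sigma, bands$T@sigma)
})

test_that("config files round-trip through the INI dialect", {
  cfg <- analysisConfig(targetRate = 100, band = c(3, 40), rr = 0.05,
                        medianWindowN = 15)
  f <- withr::local_tempfile(fileext = ".ini")
  writeConfig(cfg, f)
  back <- readConfig(f)
  expect_equal(back@targetRate, 100)
  expect_equal(back@band, c(3, 40))
  expect_equal(back@rr, 0.05)
  expect_equal(back@medianWindowN, 15)
  expect_equal(back@sigmaTrigger, 2)   # unset key keeps its default
})

test_that("malformed inputs fail loudly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1.0", "2.0"), f)
  expect_error(readRecording(f, "LFP"), "rate")
  writeLines(c("0\t1\tx"), f)
  expect_error(readRecording(f, "LFP"), "columns|malformed")
  expect_error(readRecording(tempfile(), "LFP"), "not found")
})
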