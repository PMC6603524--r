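test_that("measure time course has one value per window at its mid-time", {
  rec <- recording(generateBenchmarkSignals("lorenz", 500), 125)
  ws <- segmentWindows(rec, 2, 0.5)
  ms <- measureTimecourse(ws, embeddingParams(6, 3), 0.03)
  expect_equal(midTimes(ms), midTimes(ws))
  expect_true(all(measureValues(ms, "C") >= 0 &
                  measureValues(ms, "C") <= 1, na.rm = TRUE))
  one <- segmentWindows(recording(rnorm(250), 125), 2, 0.9)
  expect_length(midTimes(measureTimecourse(one, embeddingParams(2, 3))), 1L)
})

test_that("degenerate windows are flagged and carried as missing", {
  flat <- recording(c(rep(1, 500), rnorm(500)), 125)
  ws <- segmentWindows(flat, 2, 0)
  ms <- measureTimecourse(ws, embeddingParams(2, 3))
  expect_true(ms@degenerate[1])
  expect_true(is.na(measureValues(ms, "C")[1]))
  expect_false(ms@degenerate[4])
})

test_that("significance bands: median track is robust, sigma well-defined", {
  x <- rep(5, 50)
  b <- significanceBands(x, medianWindowN = 5)
  expect_equal(b@medianTrack, rep(5, 50))
  expect_equal(b@sigma, 0)
  bl <- bandLimits(b, 2)
  expect_equal(bl$lower, bl$upper)    # bands collapse at sigma 0
  # a single outlier does not move the median track
  y <- rep(1, 51); y[26] <- 100
  by <- significanceBands(y, medianWindowN = 7)
  expect_equal(by@medianTrack[26], 1)
  # moving median of a monotone series is monotone
  z <- cumsum(runif(80))
  bz <- significanceBands(z, medianWindowN = 9)
  expect_true(all(diff(bz@medianTrack) >= 0))
})

test_that("bands translate with an additive shift of the series", {
  set.seed(12)
  x <- rnorm(120)
  b0 <- significanceBands(x, medianWindowN = 11)
  b1 <- significanceBands(x + 7, medianWindowN = 11)
  expect_equal(b1@medianTrack, b0@medianTrack + 7)
  expect_equal(b1@sigma, b0@sigma)
})

test_that("band3 lies strictly outside band2 wherever sigma > 0", {
  set.seed(13)
  b <- significanceBands(rnorm(60), medianWindowN = 9)
  expect_gt(b@sigma, 0)
  l2 <- bandLimits(b, 2); l3 <- bandLimits(b, 3)
  expect_true(all(l3$upper > l2$upper))
  expect_true(all(l3$lower < l2$lower))
})

test_that("sigma estimate tracks the residual scale of an AR(1) series", {
  # oracle: long-run residual sd of the same AR process around the same
  # moving median, estimated by direct simulation
  phi <- 0.6
  set.seed(99)
  long <- as.numeric(arima.sim(list(ar = phi), 20000))
  medL <- tremorRN:::.movingMedian(long, 21)
  sdTrue <- stats::sd(long - medL)
  set.seed(100)
  x <- as.numeric(arima.sim(list(ar = phi), 400))
  b <- significanceBands(x, medianWindowN = 21, baseline = "all")
  expect_lt(abs(b@sigma - sdTrue) / sdTrue, 0.15)
})

test_that("peak detection: flat series none, sustained step exactly one", {
  flat <- rep(1, 60)
  bf <- significanceBands(flat, medianWindowN = 5)
  expect_equal(nrow(detectPeaks(flat, bf)), 0L)
  set.seed(14)
  x <- c(rnorm(50, sd = 1), rnorm(10, mean = 30, sd = 1), rnorm(40, sd = 1))
  b <- significanceBands(x, medianWindowN = 21, baseline = "baseline",
                         midTimes = seq(0.2, by = 0.2, length.out = 100))
  pk <- detectPeaks(x, b, memoryWindows = 4)
  expect_equal(sum(pk$level == 3), 1L)     # one onset event for the step
  on3 <- pk$time[pk$level == 3]
  on2 <- pk$time[pk$level == 2]
  expect_true(any(on2 <= on3))             # 3-sigma implies 2-sigma
})

test_that("peak detection is invariant under affine rescaling", {
  set.seed(15)
  x <- c(rnorm(60), rnorm(5, mean = 8), rnorm(35))
  tt <- seq(0.2, by = 0.2, length.out = 100)
  b0 <- significanceBands(x, medianWindowN = 11, midTimes = tt)
  p0 <- detectPeaks(x, b0)
  y <- 3 * x - 40
  b1 <- significanceBands(y, medianWindowN = 11, midTimes = tt)
  p1 <- detectPeaks(y, b1)
  expect_equal(p0$time, p1$time)
  expect_equal(p0$level, p1$level)
})

test_that("peaks are summarised against labels with TO lead times", {
  lt <- labelTrack(c(0, 10, 12), c(10, 12, 40), c("NT", "TO", "T"))
  pk <- data.frame(time = 11, measure = "C", level = 2, value = 1)
  s <- stateOfPeaks(pk, lt)
  expect_equal(s$peaks$state, "TO")
  expect_equal(s$peaks$leadTime, 1)   # one second before the T boundary
  empty <- stateOfPeaks(pk[0, ], lt)
  expect_equal(nrow(empty$peaks), 0L)
})

test_that("stationary noise stays within its bands most of the time", {
  # measure series under the null: no 3-sigma clustering peak in the
  # large majority of short runs
  set.seed(1234)
  bad <- 0
  for (i in 1:12) {
    rec <- generateRecording(scenarioSpec(ntS = 24, toS = 0, tS = 0,
                                          postNtS = 0, seed = 5000 + i))
    res <- suppressWarnings(analyzeRecording(rec$lfp))
    cv <- stats::sd(res$measures@C, na.rm = TRUE) /
      mean(res$measures@C, na.rm = TRUE)
    expect_lt(cv, 0.5)
    if (any(res$peaks$level == 3)) bad <- bad + 1
  }
  expect_lte(bad, 2)
})
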