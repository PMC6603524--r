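test_that("downsampling reaches the target rate and preserves amplitude", {
  n <- 4000
  rec <- recording(sin(2 * pi * 10 * (0:(n - 1)) / 1000), 1000)
  out <- resampleLFP(rec, 125)
  expect_equal(rate(out), 125)
  expect_equal(length(samples(out)), 500)
  ref <- sin(2 * pi * 10 * (0:499) / 125)
  mid <- 40:460
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(samples(out)[mid]) / rms(ref[mid]) - 1), 0.01)
  # identity at target rate; upsampling refused
  at125 <- recording(rnorm(500), 125)
  expect_identical(resampleLFP(at125, 125), at125)
  expect_error(resampleLFP(at125, 250), "upsampling")
})

test_that("non-integer resampling ratios are handled", {
  rec <- recording(sin(2 * pi * 10 * (0:1999) / 300), 300)
  out <- resampleLFP(rec, 125)
  expect_equal(rate(out), 125)
  ref <- sin(2 * pi * 10 * (0:(length(samples(out)) - 1)) / 125)
  mid <- 40:(length(ref) - 40)
  expect_lt(max(abs(samples(out)[mid] - ref[mid])), 0.02)
})

test_that("LFP band-pass keeps the pass band and kills both stop bands", {
  fs <- 125
  n <- 4000
  tt <- (0:(n - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  outRMS <- function(f) {
    rec <- recording(sin(2 * pi * f * tt), fs)
    rms(samples(bandpassLFP(rec))[200:(n - 200)])
  }
  inRMS <- rms(sin(2 * pi * 10 * tt))
  expect_lt(outRMS(1) / inRMS, 0.05)      # movement-artefact band
  expect_lt(abs(outRMS(10) / inRMS - 1), 0.05)
  expect_lt(outRMS(50) / inRMS, 0.05)     # European line noise
  expect_equal(length(samples(bandpassLFP(recording(rnorm(n), fs)))), n)
  expect_error(bandpassLFP(recording(rnorm(900), fs)), "shorter")
})

test_that("filtering is linear", {
  set.seed(3)
  fs <- 125
  x <- recording(rnorm(2000), fs)
  y <- recording(rnorm(2000), fs)
  lhs <- bandpassLFP(recording(2 * samples(x) + 3 * samples(y), fs))
  rhs <- 2 * samples(bandpassLFP(x)) + 3 * samples(bandpassLFP(y))
  expect_equal(samples(lhs), rhs, tolerance = 1e-10)
})

test_that("EMG conditioning extracts the burst modulation", {
  fs <- 1000
  tt <- (0:19999) / fs
  # 40 Hz carrier amplitude-modulated at 5 Hz
  am <- recording((1 + 0.8 * sin(2 * pi * 5 * tt)) * sin(2 * pi * 40 * tt),
                  fs, "EMG")
  env <- preprocessEMG(am)
  sp <- stats::spec.pgram(stats::ts(samples(env)[500:19500], frequency = fs),
                          taper = 0, plot = FALSE, span = 5)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 5), 0.5)
  # content below the 30-Hz high-pass vanishes
  lo <- preprocessEMG(recording(sin(2 * pi * 5 * tt), fs, "EMG"))
  expect_lt(sqrt(mean(samples(lo)^2)), 0.02)
  zero <- preprocessEMG(recording(rep(0, 20000), fs, "EMG"))
  expect_equal(max(abs(samples(zero))), 0)
})

test_that("tremor-onset detection follows the confirmed-threshold rule", {
  fs <- 125
  env <- recording(c(rep(1, 10 * fs), rep(5, 10 * fs)), fs, "EMG")
  expect_equal(detectTremorOnset(env), 10)
  # a single spike is not confirmed by the following 5 s
  spiky <- rep(1, 20 * fs)
  spiky[7 * fs] <- 10
  expect_null(detectTremorOnset(recording(spiky, fs, "EMG")))
  expect_null(detectTremorOnset(recording(rep(1, 20 * fs), fs, "EMG")))
  expect_error(detectTremorOnset(recording(rep(0, 20 * fs), fs, "EMG")),
               "zero")
  # crossing too near the end cannot be confirmed
  tailOnly <- c(rep(1, 18 * fs), rep(5, 2 * fs))
  expect_null(detectTremorOnset(recording(tailOnly, fs, "EMG")))
})

test_that("onset detection is translation-covariant", {
  fs <- 125
  base <- c(rep(1, 10 * fs), rep(5, 10 * fs))
  t0 <- detectTremorOnset(recording(base, fs, "EMG"))
  shifted <- c(rep(1, 2 * fs), base)   # 2 s more of baseline-level data
  t1 <- detectTremorOnset(recording(shifted, fs, "EMG"))
  expect_equal(t1, t0 + 2)
})

test_that("window segmentation obeys the count/hop/mid-time contract", {
  rec <- recording(seq_len(5000), 125)
  ws <- segmentWindows(rec, 2, 0.90)
  expect_equal(nrow(ws@windows), 191L)
  expect_equal(ws@hop, 25L)
  expect_equal(ncol(ws@windows), 250L)
  expect_equal(midTimes(ws)[1], 1.0)
  expect_equal(diff(midTimes(ws))[1], 0.2)
  # windows reconstruct the source samples exactly
  for (i in c(1, 50, 191)) {
    start <- (i - 1) * 25
    expect_identical(ws@windows[i, ], as.numeric(seq_len(5000))[(start + 1):(start + 250)])
  }
  one <- segmentWindows(recording(seq_len(250), 125), 2, 0.9)
  expect_equal(nrow(one@windows), 1L)
  expect_equal(midTimes(one), 1.0)
  tiling <- segmentWindows(recording(seq_len(1000), 125), 2, 0)
  expect_equal(nrow(tiling@windows), 4L)
  expect_equal(tiling@hop, 250L)
  expect_error(segmentWindows(rec, 2, 0.999), "hop")
})
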