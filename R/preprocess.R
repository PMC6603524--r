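# Signal conditioning: downsampling, FIR band-pass of the LFP, EMG envelope
# extraction, EMG-threshold tremor-onset labelling, window segmentation.

# Single-pass FIR with reflection padding of the signal's own edges and
# group-delay compensation; length-preserving. `padN` samples are mirrored
# at each end (filter warm-up), the convolution output is shifted back by
# the group delay and trimmed to the input support.
.firApply <- function(x, b) {
  n <- length(x)
  L <- length(b) - 1L              # filter order (even by construction)
  gd <- L %/% 2L
  pad <- gd
  if (n < pad + 2L)
    stop("signal too short for FIR padding (need > ", pad + 1L, " samples)")
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  y <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
  y[(1L + 2L * gd):(2L * gd + n)]
}

# Zero-phase (forward-backward) FIR; length-preserving, no net delay.
.firTwoPass <- function(x, b) {
  y <- .firApply(x, b)
  rev(.firApply(rev(y), b))
}

#' Downsample an LFP recording
#'
#' Anti-alias FIR low-pass (Hamming design, cut-off at the target Nyquist
#' frequency) followed by sampling on the exact target time grid; for
#' non-integer rate ratios the filtered signal is interpolated with a cubic
#' spline at the target instants. Upsampling is refused: the analysis chain
#' only ever reduces the rate.
#'
#' @param rec an LFP [Recording-class] with `rate >= targetRate`.
#' @param targetRate desired sampling rate (Hz), default 125.
#' @return A [Recording-class] at `targetRate`. If the input is already at
#'   the target rate it is returned unchanged.
#' @examples
#' rec <- recording(sin(2 * pi * 10 * (0:3999) / 1000), 1000)
#' resampleLFP(rec, 125)
#' @export
resampleLFP <- function(rec, targetRate = 125) {
  stopifnot(is(rec, "Recording"))
  if (rec@rate < targetRate)
    stop("upsampling requested (rate ", rec@rate, " < target ", targetRate,
         "); the pipeline only downsamples")
  if (rec@rate == targetRate) return(rec)
  x <- rec@samples
  fs <- rec@rate
  ratio <- fs / targetRate
  L <- max(64L, 2L * as.integer(ceiling(16.5 * ratio / 2)) * 2L)
  b <- signal::fir1(L, (targetRate / 2) / (fs / 2))
  yal <- .firApply(x, b)
  n <- length(x)
  tout <- seq(0, (n - 1) / fs, by = 1 / targetRate)
  yi <- stats::spline(x = (0:(n - 1)) / fs, y = yal, xout = tout)$y
  recording(yi, targetRate, rec@role, rec@startTime)
}

#' Band-pass filter an LFP recording
#'
#' Single-pass FIR band-pass (default 500th order, 2-45 Hz, Hamming
#' window). Two seconds of the recording's own edge data are used as
#' filter padding and trimmed afterwards, and the group delay (order/2
#' samples) is compensated, so the output is aligned with and has the same
#' length as the input. The 45-Hz upper edge removes European 50-Hz line
#' noise; the 2-Hz lower edge removes movement artefacts.
#'
#' @param rec a [Recording-class], normally at 125 Hz.
#' @param band numeric length-2 pass band (Hz).
#' @param order FIR filter order.
#' @return A filtered [Recording-class] of identical length.
#' @examples
#' rec <- recording(sin(2 * pi * 10 * (0:1999) / 125), 125)
#' bandpassLFP(rec)
#' @export
bandpassLFP <- function(rec, band = c(2, 45), order = 500) {
  stopifnot(is(rec, "Recording"))
  n <- length(rec@samples)
  padN <- as.integer(2 * rec@rate)       # two seconds of real data
  if (n < order + 2L * padN)
    stop("recording shorter than filter order + 2 x 2-s padding (",
         order + 2L * padN, " samples needed)")
  b <- signal::fir1(as.integer(order), band / (rec@rate / 2), type = "pass")
  y <- .firPadded(rec@samples, b, padN)
  recording(y, rec@rate, rec@role, rec@startTime)
}

# FIR with an explicit padding length (>= group delay) of mirrored edge
# data; single pass, group-delay compensated, length preserving.
.firPadded <- function(x, b, padN) {
  n <- length(x)
  L <- length(b) - 1L
  gd <- L %/% 2L
  if (padN < gd) padN <- gd
  if (n < padN + 2L)
    stop("signal too short for requested padding")
  xp <- c(rev(x[2:(padN + 1L)]), x, rev(x[(n - padN):(n - 1L)]))
  y <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
  y[(padN + gd + 1L):(padN + gd + n)]
}

#' Condition an EMG recording into a low-frequency burst envelope
#'
#' Pipeline, in order: (1) zero-phase (two-pass) FIR high-pass above 30 Hz
#' of the stated order; (2) rectification by the magnitude of the analytic
#' signal (Hilbert envelope), which is non-negative; (3) single-pass FIR
#' 2-45 Hz band-pass, yielding the tremor-band modulation of the muscle
#' activity.
#'
#' @param rec an EMG [Recording-class]; its rate must exceed twice the 30-Hz
#'   high-pass edge.
#' @param hpFreq high-pass edge (Hz).
#' @param band final band-pass (Hz).
#' @param order FIR order for both filters.
#' @return A [Recording-class] with the processed envelope.
#' @export
preprocessEMG <- function(rec, hpFreq = 30, band = c(2, 45), order = 500) {
  stopifnot(is(rec, "Recording"))
  if (rec@rate <= 2 * hpFreq)
    stop("EMG rate too low for a ", hpFreq, " Hz high-pass")
  bh <- signal::fir1(as.integer(order), hpFreq / (rec@rate / 2),
                     type = "high")
  hp <- .firTwoPass(rec@samples, bh)
  env <- Mod(.analyticSignal(hp))
  bb <- signal::fir1(as.integer(order), band / (rec@rate / 2), type = "pass")
  padN <- max(as.integer(2 * rec@rate), as.integer(order) %/% 2L)
  out <- .firPadded(env, bb, padN)
  recording(out, rec@rate, rec@role, rec@startTime)
}

# Analytic signal via FFT (one-sided spectrum doubling).
.analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Detect the tremor onset from a processed EMG envelope
#'
#' Scans the amplitude (absolute value) of the processed EMG for the
#' earliest time `t` at which it strictly exceeds three times the mean
#' amplitude of the first `baselineS` seconds (assumed atremorous), and
#' confirms the detection by requiring the mean amplitude over the
#' half-open window `(t, t + confirmS]` to exceed the same threshold.
#' The confirmation step rejects isolated small-magnitude spikes that a
#' bare threshold would mistake for tremor. Crossings too close to the end
#' of the recording to fit a full confirmation window are not eligible.
#'
#' @param emgEnv the processed EMG (output of [preprocessEMG()]).
#' @param baselineS baseline length (s), default 5.
#' @param confirmS confirmation-window length (s), default 5.
#' @param factor threshold factor over the baseline mean, default 3.
#' @return Onset time in seconds (relative to `startTime`), or `NULL` when
#'   no confirmed crossing exists.
#' @examples
#' env <- recording(c(rep(1, 1250), rep(5, 1250)), 125, "EMG")
#' detectTremorOnset(env)   # 10 s
#' @export
detectTremorOnset <- function(emgEnv, baselineS = 5, confirmS = 5,
                              factor = 3) {
  stopifnot(is(emgEnv, "Recording"))
  fs <- emgEnv@rate
  a <- abs(emgEnv@samples)
  n <- length(a)
  if (n <= (baselineS + confirmS) * fs)
    stop("recording must be longer than baseline + confirmation window")
  nb <- as.integer(baselineS * fs)
  thr <- factor * mean(a[seq_len(nb)])
  if (thr == 0) stop("baseline EMG amplitude is zero; threshold undefined")
  nc <- as.integer(confirmS * fs)
  cross <- which(a > thr)
  cross <- cross[cross + nc <= n]
  for (i in cross) {
    if (mean(a[(i + 1L):(i + nc)]) > thr)
      return(emgEnv@startTime + (i - 1L) / fs)
  }
  NULL
}

#' Segment a recording into overlapping analysis windows
#'
#' Window length is `windowS * rate` samples; the hop between window starts
#' is `round(length * (1 - overlapFrac))` samples (25 samples, i.e. 0.2 s,
#' at the defaults of 2-s windows with 90% overlap at 125 Hz). Window `i`
#' (0-based) covers samples `[i * hop, i * hop + length)`; each window's
#' measure is later assigned to its mid-point time.
#'
#' @param rec a [Recording-class] at the analysis rate.
#' @param windowS window length (s).
#' @param overlapFrac fractional overlap in `[0, 1)`.
#' @return A [WindowSet-class].
#' @examples
#' rec <- recording(rnorm(5000), 125)
#' segmentWindows(rec)       # 191 windows of 250 samples, hop 25
#' @export
segmentWindows <- function(rec, windowS = 2, overlapFrac = 0.90) {
  stopifnot(is(rec, "Recording"))
  len <- as.integer(round(windowS * rec@rate))
  if (length(rec@samples) < len)
    stop("recording shorter than one window")
  hop <- as.integer(round(len * (1 - overlapFrac)))
  if (hop < 1L)
    stop("overlap too high: hop computes to 0 samples")
  n <- length(rec@samples)
  count <- (n - len) %/% hop + 1L
  starts <- (seq_len(count) - 1L) * hop
  W <- matrix(0, nrow = count, ncol = len)
  for (i in seq_len(count))
    W[i, ] <- rec@samples[(starts[i] + 1L):(starts[i] + len)]
  mid <- rec@startTime + (starts + len / 2) / rec@rate
  new("WindowSet", windows = W, midTimes = mid, hop = hop, rate = rec@rate)
}

#' Preprocess an LFP/EMG pair and label the tremor onset
#'
#' Convenience wrapper over the conditioning chain: downsample and band-pass
#' the LFP, condition the EMG, and (when the EMG is given) derive an
#' NT/TO/T label track by combining the EMG onset time with the point, if
#' any, at which labels are supplied externally. Without external labels the
#' track is `NT` up to the detected onset and `T` afterwards (`TO` cannot be
#' recovered from EMG alone, which is precisely why the LFP trigger is
#' useful).
#'
#' @param lfp LFP [Recording-class].
#' @param emg optional EMG [Recording-class].
#' @param config an [AnalysisConfig-class].
#' @return A list with `lfp` (filtered, at the target rate), `emg`
#'   (processed envelope or NULL), `onset` (seconds or NULL) and `labels`
#'   (a [LabelTrack-class] or NULL).
#' @export
preprocessRecording <- function(lfp, emg = NULL, config = analysisConfig()) {
  lfp2 <- resampleLFP(lfp, config@targetRate)
  lfp2 <- bandpassLFP(lfp2, config@band, config@filterOrder)
  emg2 <- NULL
  onset <- NULL
  labels <- NULL
  if (!is.null(emg)) {
    emg2 <- preprocessEMG(emg, band = config@band,
                          order = config@filterOrder)
    onset <- tryCatch(detectTremorOnset(emg2, baselineS = config@baselineS),
                      error = function(e) NULL)
    if (!is.null(onset)) {
      labels <- labelTrack(c(0, onset), c(onset, duration(lfp2)),
                           c("NT", "T"))
    }
  }
  list(lfp = lfp2, emg = emg2, onset = onset, labels = labels)
}
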