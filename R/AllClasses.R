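#' Recording: a uniformly sampled biosignal
#'
#' Container for a single-channel, uniformly sampled biosignal (microvolts),
#' either a subthalamic local field potential (`"LFP"`) or a surface
#' electromyogram (`"EMG"`).
#'
#' @slot samples numeric vector of sample values (uV).
#' @slot rate sampling rate in samples/second.
#' @slot role channel role, `"LFP"` or `"EMG"`.
#' @slot startTime time of the first sample in seconds (default 0).
#'
#' @seealso [recording()], [readRecording()], [resampleLFP()]
#' @exportClass Recording
setClass("Recording",
  representation(samples = "numeric", rate = "numeric",
                 role = "character", startTime = "numeric"),
  prototype(startTime = 0))

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (length(object@samples) < 1L)
    msg <- c(msg, "samples must have length >= 1")
  if (any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(object@role) != 1L || !object@role %in% c("LFP", "EMG"))
    msg <- c(msg, "role must be 'LFP' or 'EMG'")
  if (length(object@startTime) != 1L || !is.finite(object@startTime))
    msg <- c(msg, "startTime must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param samples numeric vector of sample values (uV).
#' @param rate sampling rate (Hz).
#' @param role `"LFP"` or `"EMG"`.
#' @param startTime time of the first sample (s).
#' @return A [Recording-class] object.
#' @examples
#' rec <- recording(sin(2 * pi * 5 * (0:999) / 125), rate = 125)
#' duration(rec)
#' @export
recording <- function(samples, rate, role = c("LFP", "EMG"), startTime = 0) {
  role <- match.arg(role)
  new("Recording", samples = as.numeric(samples), rate = as.numeric(rate),
      role = role, startTime = as.numeric(startTime))
}

#' LabelTrack: movement-state annotation of a recording
#'
#' Ordered, non-overlapping intervals labelling a recording with the clinical
#' movement states: non-tremorous rest (`NT`), tremor onset (`TO`) and overt
#' resting tremor (`T`). Intervals are half-open `[start, end)` in seconds,
#' so adjacent segments may share a boundary.
#'
#' @slot segments data.frame with columns `start`, `end` (seconds) and
#'   `state` (character, one of `NT`, `TO`, `T`).
#' @seealso [labelTrack()], [stateAt()], [readLabels()]
#' @exportClass LabelTrack
setClass("LabelTrack", representation(segments = "data.frame"))

setValidity("LabelTrack", function(object) {
  s <- object@segments
  msg <- character()
  if (!all(c("start", "end", "state") %in% names(s)))
    return("segments needs columns start, end, state")
  if (nrow(s)) {
    if (!all(s$state %in% c("NT", "TO", "T")))
      msg <- c(msg, "states must be NT, TO or T")
    if (any(s$start >= s$end))
      msg <- c(msg, "each segment needs start < end")
    if (is.unsorted(s$start, strictly = TRUE) && nrow(s) > 1)
      msg <- c(msg, "segments must be sorted by start")
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)] - 1e-12))
      msg <- c(msg, "segments must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LabelTrack
#'
#' @param start,end numeric vectors of segment bounds in seconds
#'   (half-open `[start, end)`).
#' @param state character vector of states in `NT`, `TO`, `T`.
#' @return A [LabelTrack-class] object.
#' @examples
#' labelTrack(c(0, 10, 12), c(10, 12, 40), c("NT", "TO", "T"))
#' @export
labelTrack <- function(start = numeric(), end = numeric(),
                       state = character()) {
  seg <- data.frame(start = as.numeric(start), end = as.numeric(end),
                    state = as.character(state),
                    stringsAsFactors = FALSE)
  seg <- seg[order(seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  new("LabelTrack", segments = seg)
}

#' AnalysisConfig: tunable parameters of the analysis pipeline
#'
#' All rates in Hz, durations in seconds. Defaults follow the published
#' processing chain: downsampling to 125 Hz, a 500th-order 2-45 Hz FIR
#' band-pass, 2-s windows with 90% overlap, recurrence rate 0.03, a 2-sigma
#' start trigger averaged over the current and four previous windows.
#'
#' @slot targetRate analysis sampling rate after downsampling (Hz).
#' @slot band band-pass edges for the LFP (Hz).
#' @slot filterOrder FIR filter order.
#' @slot windowS analysis window length (s).
#' @slot overlapFrac fractional overlap of consecutive windows, in `[0, 1)`.
#' @slot rr target recurrence rate of each window's network, in `(0, 1)`.
#' @slot medianWindowN length (windows, odd) of the moving-median filter.
#' @slot baselineS length of the atremorous baseline used for the residual
#'   scale estimate (s).
#' @slot sigmaTrigger start-trigger threshold in units of the baseline
#'   residual standard deviation.
#' @slot memoryWindows number of previous windows averaged with the current
#'   one by the controller (and peak detector).
#' @seealso [analysisConfig()]
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  representation(targetRate = "numeric", band = "numeric",
                 filterOrder = "numeric", windowS = "numeric",
                 overlapFrac = "numeric", rr = "numeric",
                 medianWindowN = "numeric", baselineS = "numeric",
                 sigmaTrigger = "numeric", memoryWindows = "numeric"))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@overlapFrac < 0 || object@overlapFrac >= 1)
    msg <- c(msg, "overlapFrac must be in [0, 1)")
  if (object@rr <= 0 || object@rr >= 1)
    msg <- c(msg, "rr must be in (0, 1)")
  if (any(c(object@targetRate, object@windowS, object@baselineS) <= 0))
    msg <- c(msg, "rates and durations must be positive")
  if (length(object@band) != 2L || object@band[1] >= object@band[2] ||
      object@band[1] <= 0)
    msg <- c(msg, "band must be increasing positive (low, high)")
  if (object@medianWindowN < 1 || object@medianWindowN %% 2 != 1)
    msg <- c(msg, "medianWindowN must be odd and >= 1")
  if (object@memoryWindows < 0)
    msg <- c(msg, "memoryWindows must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an AnalysisConfig
#'
#' @param targetRate,band,filterOrder,windowS,overlapFrac,rr,medianWindowN,baselineS,sigmaTrigger,memoryWindows
#'   see [AnalysisConfig-class] for meanings and units.
#' @return An [AnalysisConfig-class] object.
#' @examples
#' cfg <- analysisConfig()
#' cfg
#' @export
analysisConfig <- function(targetRate = 125, band = c(2, 45),
                           filterOrder = 500, windowS = 2,
                           overlapFrac = 0.90, rr = 0.03,
                           medianWindowN = 21, baselineS = 5,
                           sigmaTrigger = 2, memoryWindows = 4) {
  new("AnalysisConfig", targetRate = targetRate, band = band,
      filterOrder = filterOrder, windowS = windowS,
      overlapFrac = overlapFrac, rr = rr, medianWindowN = medianWindowN,
      baselineS = baselineS, sigmaTrigger = sigmaTrigger,
      memoryWindows = memoryWindows)
}

#' WindowSet: overlapping analysis windows of a recording
#'
#' @slot windows numeric matrix, one window per row.
#' @slot midTimes window mid-point times (s).
#' @slot hop hop between consecutive window starts (samples).
#' @slot rate sampling rate of the source recording (Hz).
#' @seealso [segmentWindows()]
#' @exportClass WindowSet
setClass("WindowSet",
  representation(windows = "matrix", midTimes = "numeric",
                 hop = "integer", rate = "numeric"))

setValidity("WindowSet", function(object) {
  msg <- character()
  if (nrow(object@windows) != length(object@midTimes))
    msg <- c(msg, "one midTime per window required")
  if (length(object@midTimes) > 1) {
    d <- diff(object@midTimes)
    if (any(d <= 0)) msg <- c(msg, "midTimes must be strictly increasing")
    if (max(abs(d - d[1])) > 1e-9)
      msg <- c(msg, "midTimes must advance with a constant step")
  }
  if (object@hop < 1) msg <- c(msg, "hop must be >= 1 sample")
  if (length(msg)) msg else TRUE
})

#' EmbeddingParams: delay-embedding parameters
#'
#' @slot tau embedding delay (samples, >= 1).
#' @slot m embedding dimension (>= 1).
#' @seealso [selectEmbedding()], [embedSeries()]
#' @exportClass EmbeddingParams
setClass("EmbeddingParams", representation(tau = "integer", m = "integer"),
         prototype(tau = 1L, m = 1L))

setValidity("EmbeddingParams", function(object) {
  if (object@tau < 1L || object@m < 1L)
    "tau and m must be positive integers" else TRUE
})

#' Construct EmbeddingParams
#'
#' @param tau embedding delay in samples.
#' @param m embedding dimension.
#' @return An [EmbeddingParams-class] object.
#' @examples
#' embeddingParams(6, 4)
#' @export
embeddingParams <- function(tau, m) {
  new("EmbeddingParams", tau = as.integer(tau), m = as.integer(m))
}

#' RecurrenceNetwork: epsilon-recurrence network of an embedded window
#'
#' The adjacency matrix is the recurrence matrix of the embedded state
#' vectors (maximum-norm distance at most epsilon, boundary inclusive) with
#' the diagonal removed: a binary, symmetric, undirected graph.
#'
#' @slot adjacency binary symmetric integer matrix with zero diagonal.
#' @slot epsilon phase-space distance threshold used.
#' @slot achievedRR achieved fraction of recurrent off-diagonal pairs.
#' @slot tieFlag TRUE when heavy distance ties pushed the achieved rate
#'   beyond the usual tolerance of the requested rate.
#' @seealso [buildNetwork()], [epsilonForRR()], [networkMeasures()]
#' @exportClass RecurrenceNetwork
setClass("RecurrenceNetwork",
  representation(adjacency = "matrix", epsilon = "numeric",
                 achievedRR = "numeric", tieFlag = "logical"),
  prototype(tieFlag = FALSE))

setValidity("RecurrenceNetwork", function(object) {
  A <- object@adjacency
  msg <- character()
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  else {
    if (!all(A %in% c(0L, 1L))) msg <- c(msg, "adjacency must be binary")
    if (any(diag(A) != 0L)) msg <- c(msg, "diagonal must be zero")
    if (!identical(A, t(A))) msg <- c(msg, "adjacency must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' MeasureSeries: per-window network measures over a recording
#'
#' @slot midTimes window mid-point times (s).
#' @slot C global clustering coefficient per window.
#' @slot T transitivity per window.
#' @slot A degree assortativity per window (NA where undefined).
#' @slot degenerate TRUE for windows whose measures are missing because the
#'   window was degenerate (constant signal or all states identical).
#' @slot params the [EmbeddingParams-class] used for every window.
#' @slot rr requested recurrence rate.
#' @seealso [measureTimecourse()]
#' @exportClass MeasureSeries
setClass("MeasureSeries",
  representation(midTimes = "numeric", C = "numeric", T = "numeric",
                 A = "numeric", degenerate = "logical",
                 params = "EmbeddingParams", rr = "numeric"))

setValidity("MeasureSeries", function(object) {
  n <- length(object@midTimes)
  if (length(object@C) != n || length(object@T) != n ||
      length(object@A) != n || length(object@degenerate) != n)
    "midTimes, C, T, A and degenerate must have equal lengths" else TRUE
})

# internal constructor: the single-letter slot names C/T/A would partially
# match new()'s Class argument, so slots are assigned explicitly
.measureSeries <- function(midTimes, C, T, A, degenerate, params, rr) {
  obj <- new("MeasureSeries")
  obj@midTimes <- midTimes
  obj@C <- C
  obj@T <- T
  obj@A <- A
  obj@degenerate <- degenerate
  obj@params <- params
  obj@rr <- rr
  validObject(obj)
  obj
}

#' SignificanceBands: moving-median track with sigma bands
#'
#' A centred moving median smooths a measure series; the residual standard
#' deviation over an atremorous baseline region sets the scale sigma of the
#' +/-2 sigma and +/-3 sigma significance bands around the median track.
#'
#' @slot midTimes window mid-point times (s).
#' @slot medianTrack centred moving median of the raw series.
#' @slot sigma residual scale estimate.
#' @slot baselineIdx indices of the windows used for the sigma estimate.
#' @seealso [significanceBands()], [bandLimits()]
#' @exportClass SignificanceBands
setClass("SignificanceBands",
  representation(midTimes = "numeric", medianTrack = "numeric",
                 sigma = "numeric", baselineIdx = "integer"))

setValidity("SignificanceBands", function(object) {
  msg <- character()
  if (length(object@midTimes) != length(object@medianTrack))
    msg <- c(msg, "one medianTrack value per midTime required")
  if (length(object@sigma) != 1L || is.na(object@sigma) || object@sigma < 0)
    msg <- c(msg, "sigma must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' ValidityReport: classification validity of a stop/start decision module
#'
#' Percentages aggregated from a pooled cross-validated confusion matrix.
#' By construction `FPR = 100 - specificity` and `FNR = 100 - sensitivity`.
#'
#' @slot acc accuracy (%).
#' @slot sensitivity proportion of positive-class samples classified
#'   correctly (%).
#' @slot specificity proportion of negative-class samples classified
#'   correctly (%).
#' @slot fpr false-positive rate (%), `100 - specificity`.
#' @slot fnr false-negative rate (%), `100 - sensitivity`.
#' @slot counts named integer vector (TP, FN, TN, FP).
#' @slot positiveClass label of the positive class.
#' @seealso [trainStopClassifier()], [trainOnsetClassifier()]
#' @exportClass ValidityReport
setClass("ValidityReport",
  representation(acc = "numeric", sensitivity = "numeric",
                 specificity = "numeric", fpr = "numeric", fnr = "numeric",
                 counts = "integer", positiveClass = "character"))

#' ScenarioSpec: parameters of a synthetic labelled recording
#'
#' Describes a recording with an atremorous segment (band-limited linear
#' stochastic activity), a tremor-onset transition (gradual admixture of a
#' nonlinear oscillatory source) and a tremor segment, optionally followed by
#' a return to rest; with an EMG channel whose tremor-locked bursts begin
#' midway through the transition.
#'
#' @slot ntS,toS,tS,postNtS segment durations (s); `ntS` must be positive,
#'   the others may be zero.
#' @slot rate synthesis sampling rate before downsampling (Hz).
#' @slot tremorFreq dominant tremor frequency (Hz), in (2, 45).
#' @slot ramp nonlinearity mixing schedule over the transition:
#'   `"overshoot"` (default; abrupt early surge that partially recedes,
#'   then a second rise into tremor), `"sigmoid"` or `"linear"`.
#' @slot snrDb additive white measurement noise level (dB, signal/noise).
#' @slot seed integer seed driving every stochastic draw.
#' @seealso [scenarioSpec()], [generateRecording()]
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
  representation(ntS = "numeric", toS = "numeric", tS = "numeric",
                 postNtS = "numeric", rate = "numeric",
                 tremorFreq = "numeric", ramp = "character",
                 snrDb = "numeric", seed = "integer"))

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  if (object@ntS <= 0) msg <- c(msg, "ntS must be positive")
  if (min(object@toS, object@tS, object@postNtS) < 0)
    msg <- c(msg, "segment durations must be non-negative")
  if (object@tremorFreq <= 2 || object@tremorFreq >= 45)
    msg <- c(msg, "tremorFreq must lie in (2, 45) Hz")
  if (object@rate <= 4 * 45) msg <- c(msg, "rate too low for the EMG band")
  if (!object@ramp %in% c("overshoot", "sigmoid", "linear"))
    msg <- c(msg, "ramp must be 'overshoot', 'sigmoid' or 'linear'")
  if (length(msg)) msg else TRUE
})

#' Construct a ScenarioSpec
#'
#' @param ntS,toS,tS,postNtS segment durations in seconds (rest, onset
#'   transition, tremor, trailing rest).
#' @param rate synthesis sampling rate (Hz).
#' @param tremorFreq tremor frequency (Hz).
#' @param ramp nonlinearity schedule: `"overshoot"` (default),
#'   `"sigmoid"` or `"linear"`.
#' @param snrDb measurement signal-to-noise ratio (dB).
#' @param seed integer seed.
#' @return A [ScenarioSpec-class] object.
#' @examples
#' scenarioSpec(seed = 1)
#' @export
scenarioSpec <- function(ntS = 20, toS = 10, tS = 15, postNtS = 10,
                         rate = 1000, tremorFreq = 5, ramp = "overshoot",
                         snrDb = 10, seed = 1L) {
  new("ScenarioSpec", ntS = ntS, toS = toS, tS = tS, postNtS = postNtS,
      rate = rate, tremorFreq = tremorFreq, ramp = ramp, snrDb = snrDb,
      seed = as.integer(seed))
}
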