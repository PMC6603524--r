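#' @name accessors
#' @title Accessors for tremorRN classes
#' @description Small accessor generics: `samples()`, `rate()`, `role()`,
#'   `startTime()`, `duration()` for [Recording-class]; `segments()` for
#'   [LabelTrack-class]; `midTimes()` where windows carry time stamps;
#'   `adjacency()`, `epsilon()`, `achievedRR()` for
#'   [RecurrenceNetwork-class]; `measureValues()` for [MeasureSeries-class];
#'   `bandLimits()` for [SignificanceBands-class]; `validityTable()` for
#'   [ValidityReport-class].
#' @param object an object of the documented class.
#' @param measure one of `"C"`, `"T"`, `"A"`.
#' @param level band level multiplier (2 or 3).
#' @return The corresponding slot value (see Description).
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("rate", function(object) standardGeneric("rate"))
#' @rdname accessors
#' @export
setGeneric("role", function(object) standardGeneric("role"))
#' @rdname accessors
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))
#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("midTimes", function(object) standardGeneric("midTimes"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("epsilon", function(object) standardGeneric("epsilon"))
#' @rdname accessors
#' @export
setGeneric("achievedRR", function(object) standardGeneric("achievedRR"))
#' @rdname accessors
#' @export
setGeneric("measureValues",
           function(object, measure = c("C", "T", "A"))
             standardGeneric("measureValues"))
#' @rdname accessors
#' @export
setGeneric("bandLimits",
           function(object, level = 2) standardGeneric("bandLimits"))
#' @rdname accessors
#' @export
setGeneric("validityTable", function(object) standardGeneric("validityTable"))

#' @rdname accessors
setMethod("samples", "Recording", function(object) object@samples)
#' @rdname accessors
setMethod("rate", "Recording", function(object) object@rate)
#' @rdname accessors
setMethod("role", "Recording", function(object) object@role)
#' @rdname accessors
setMethod("startTime", "Recording", function(object) object@startTime)
#' @rdname accessors
setMethod("duration", "Recording",
          function(object) length(object@samples) / object@rate)
#' @rdname accessors
setMethod("segments", "LabelTrack", function(object) object@segments)
#' @rdname accessors
setMethod("midTimes", "WindowSet", function(object) object@midTimes)
#' @rdname accessors
setMethod("midTimes", "MeasureSeries", function(object) object@midTimes)
#' @rdname accessors
setMethod("midTimes", "SignificanceBands", function(object) object@midTimes)
#' @rdname accessors
setMethod("adjacency", "RecurrenceNetwork", function(object) object@adjacency)
#' @rdname accessors
setMethod("epsilon", "RecurrenceNetwork", function(object) object@epsilon)
#' @rdname accessors
setMethod("achievedRR", "RecurrenceNetwork",
          function(object) object@achievedRR)

#' @rdname accessors
setMethod("measureValues", "MeasureSeries",
  function(object, measure = c("C", "T", "A")) {
    measure <- match.arg(measure)
    slot(object, measure)
  })

#' @rdname accessors
setMethod("bandLimits", "SignificanceBands", function(object, level = 2) {
  data.frame(midTime = object@midTimes,
             lower = object@medianTrack - level * object@sigma,
             upper = object@medianTrack + level * object@sigma)
})

#' @rdname accessors
setMethod("validityTable", "ValidityReport", function(object) {
  data.frame(ACC = object@acc, Sensitivity = object@sensitivity,
             Specificity = object@specificity, FPR = object@fpr,
             FNR = object@fnr)
})

#' State of a LabelTrack at given times
#'
#' Looks up the movement state of half-open labelled intervals
#' `[start, end)` at each time point.
#'
#' @param object a [LabelTrack-class].
#' @param time numeric vector of times (s).
#' @return Character vector of states (`NA` outside all segments).
#' @examples
#' lt <- labelTrack(c(0, 10), c(10, 20), c("NT", "T"))
#' stateAt(lt, c(5, 10, 25))
#' @export
setGeneric("stateAt", function(object, time) standardGeneric("stateAt"))

#' @rdname stateAt
setMethod("stateAt", "LabelTrack", function(object, time) {
  s <- object@segments
  vapply(time, function(t) {
    i <- which(s$start <= t & t < s$end)
    if (length(i)) s$state[i[1]] else NA_character_
  }, character(1))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording (%s): %d samples @ %g Hz, %.2f s, start %g s\n",
              object@role, length(object@samples), object@rate,
              duration(object), object@startTime))
})

setMethod("show", "LabelTrack", function(object) {
  s <- object@segments
  cat(sprintf("LabelTrack: %d segment(s)\n", nrow(s)))
  if (nrow(s)) print(s, row.names = FALSE)
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig:\n")
  cat(sprintf("  targetRate %g Hz | band [%g, %g] Hz | filterOrder %d\n",
              object@targetRate, object@band[1], object@band[2],
              as.integer(object@filterOrder)))
  cat(sprintf("  windowS %g s | overlapFrac %.2f | rr %.3f\n",
              object@windowS, object@overlapFrac, object@rr))
  cat(sprintf("  medianWindowN %d | baselineS %g s | sigmaTrigger %g | memoryWindows %d\n",
              as.integer(object@medianWindowN), object@baselineS,
              object@sigmaTrigger, as.integer(object@memoryWindows)))
})

setMethod("show", "WindowSet", function(object) {
  cat(sprintf("WindowSet: %d windows of %d samples, hop %d samples @ %g Hz\n",
              nrow(object@windows), ncol(object@windows), object@hop,
              object@rate))
})

setMethod("show", "EmbeddingParams", function(object) {
  cat(sprintf("EmbeddingParams: tau = %d samples, m = %d\n",
              object@tau, object@m))
})

setMethod("show", "RecurrenceNetwork", function(object) {
  n <- nrow(object@adjacency)
  cat(sprintf(
    "RecurrenceNetwork: %d vertices, %d edges, epsilon %.4g, RR %.4f%s\n",
    n, sum(object@adjacency) / 2, object@epsilon, object@achievedRR,
    if (object@tieFlag) " (distance ties)" else ""))
})

setMethod("show", "MeasureSeries", function(object) {
  cat(sprintf(
    "MeasureSeries: %d windows (tau %d, m %d, rr %.3f), %d degenerate\n",
    length(object@midTimes), object@params@tau, object@params@m, object@rr,
    sum(object@degenerate)))
})

setMethod("show", "SignificanceBands", function(object) {
  cat(sprintf(
    "SignificanceBands: %d windows, sigma %.4g (baseline %d windows)\n",
    length(object@midTimes), object@sigma, length(object@baselineIdx)))
})

setMethod("show", "ValidityReport", function(object) {
  cat(sprintf("ValidityReport (positive class %s):\n", object@positiveClass))
  print(round(validityTable(object), 2), row.names = FALSE)
})

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf(
    "ScenarioSpec: NT %g s | TO %g s | T %g s | NT %g s @ %g Hz\n",
    object@ntS, object@toS, object@tS, object@postNtS, object@rate))
  cat(sprintf("  tremorFreq %g Hz, %s ramp, snr %g dB, seed %d\n",
              object@tremorFreq, object@ramp, object@snrDb, object@seed))
})
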