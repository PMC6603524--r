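# Closed-loop stimulation controller: nonlinearity-peak START trigger,
# classifier-based STOP, per-recording SVM training with ten-fold
# cross-validation and validity reporting.

#' One controller step
#'
#' With stimulation OFF, the controller averages the current measure value
#' with the buffered previous ones (up to `memoryWindows`) and issues
#' `START` when that average strictly exceeds
#' `baselineMedian + sigmaTrigger * sigma`. With stimulation ON, the
#' supplied classifier label decides: `NT` issues `STOP`, anything else
#' keeps stimulating. The buffer is updated first-in-first-out either way;
#' besides it the controller keeps only an arming flag: after a `STOP`,
#' the start trigger stays disarmed until the averaged measure has once
#' returned to or below the threshold (hysteresis), so the elevated
#' measures of windows straddling the tremor offset cannot immediately
#' re-start stimulation.
#'
#' @param state list with `dbsOn` (logical), `buffer` (numeric, most
#'   recent last) and `armed` (logical) as produced by
#'   [controllerState()].
#' @param value the current window's trigger-measure value (may be NA).
#' @param threshold trigger threshold `median + sigmaTrigger * sigma` for
#'   this window.
#' @param classifierLabel classification of the current window (`"NT"` or
#'   `"T"`); required while stimulation is ON.
#' @param memoryWindows buffer capacity.
#' @param rearmThreshold level at or below which a disarmed trigger
#'   re-arms (default the median track itself, i.e. the band centre:
#'   a Schmitt-trigger hysteresis width of `sigmaTrigger` sigmas).
#' @return List with `state` (updated) and `command` (`"START"`, `"STOP"`
#'   or `"NONE"`).
#' @seealso [runLoop()]
#' @export
controllerStep <- function(state, value, threshold, classifierLabel = NULL,
                           memoryWindows = 4, rearmThreshold = threshold) {
  command <- "NONE"
  if (!state$dbsOn) {
    avg <- mean(c(state$buffer, value), na.rm = TRUE)
    if (is.finite(avg) && is.finite(threshold)) {
      if (state$armed && avg > threshold) {
        command <- "START"
        state$dbsOn <- TRUE
      } else if (!state$armed && avg <= rearmThreshold) {
        state$armed <- TRUE
      }
    }
  } else {
    if (is.null(classifierLabel))
      stop("stimulation is ON but no classifier label was provided")
    if (identical(classifierLabel, "NT")) {
      command <- "STOP"
      state$dbsOn <- FALSE
      state$armed <- FALSE
    }
  }
  state$buffer <- utils::tail(c(state$buffer, value), memoryWindows)
  list(state = state, command = command)
}

#' Fresh controller state
#'
#' @param dbsOn initial stimulation state.
#' @return List understood by [controllerStep()].
#' @export
controllerState <- function(dbsOn = FALSE) {
  list(dbsOn = dbsOn, buffer = numeric(0), armed = TRUE)
}

#' Simulate the closed loop over a measure series
#'
#' Deterministically folds [controllerStep()] over the windows in time
#' order. The trigger measure (clustering by default, the measure with the
#' most abrupt nonlinearity peaks) is compared against its significance
#' band; the classifier is consulted only while stimulation is ON.
#' Evaluation starts after the band's baseline region, where the
#' subject-specific reference is established.
#'
#' @param series a [MeasureSeries-class].
#' @param bands the trigger measure's [SignificanceBands-class].
#' @param classifier a function `(features, time) -> "NT"/"T"` as returned
#'   by [trainStopClassifier()]'s `$predictFn` or [oracleClassifier()].
#' @param config an [AnalysisConfig-class] (`sigmaTrigger`,
#'   `memoryWindows`).
#' @param measure trigger measure name.
#' @return A data.frame trace with one row per evaluated window:
#'   `time`, `dbsOn` (state after the command), `command`.
#' @export
runLoop <- function(series, bands, classifier,
                    config = analysisConfig(), measure = "C") {
  stopifnot(is(series, "MeasureSeries"), is(bands, "SignificanceBands"))
  x <- measureValues(series, measure)
  tt <- series@midTimes
  thr <- bands@medianTrack + config@sigmaTrigger * bands@sigma
  feats <- windowFeatures(series, config@memoryWindows)
  st <- controllerState()
  # warm-up: the controller starts evaluating once the subject-specific
  # reference (baselineS seconds of windows) has been established
  hopS <- if (length(tt) > 1) tt[2] - tt[1] else 1
  startIdx <- min(length(tt),
                  max(2L, as.integer(round(config@baselineS / hopS)) + 1L))
  n <- length(x)
  time <- numeric(0); dbs <- logical(0); cmd <- character(0)
  for (i in seq_len(n)) {
    if (i < startIdx) {      # baseline: only warm the buffer
      st$buffer <- utils::tail(c(st$buffer, x[i]), config@memoryWindows)
      next
    }
    lab <- if (st$dbsOn) classifier(feats[i, , drop = FALSE], tt[i])
           else NULL
    step <- controllerStep(st, x[i], thr[i], lab, config@memoryWindows,
                           rearmThreshold = bands@medianTrack[i])
    st <- step$state
    time <- c(time, tt[i]); dbs <- c(dbs, st$dbsOn)
    cmd <- c(cmd, step$command)
  }
  data.frame(time = time, dbsOn = dbs, command = cmd,
             stringsAsFactors = FALSE)
}

#' Label-reading oracle classifier
#'
#' Classifies each window from the ground-truth labels instead of a trained
#' model: `NT` where the label is `NT`, `T` elsewhere (`TO` counts as
#' tremorous so the oracle never stops stimulation early). Used to exercise
#' the loop logic independently of classifier quality.
#'
#' @param labels a [LabelTrack-class].
#' @return A function `(features, time) -> "NT"/"T"`.
#' @export
oracleClassifier <- function(labels) {
  stopifnot(is(labels, "LabelTrack"))
  function(features, time) {
    s <- stateAt(labels, time)
    if (is.na(s) || s == "NT") "NT" else "T"
  }
}

#' Per-window classifier features
#'
#' The feature vector of each window is the measure triple (C, T, A) plus
#' its trailing mean over the current and `memoryWindows` previous windows
#' (the same memory the controller keeps). Missing assortativity values
#' are carried as 0 after standardisation upstream.
#'
#' @param series a [MeasureSeries-class].
#' @param memoryWindows trailing-mean length.
#' @return Numeric matrix, one row per window, columns
#'   `C, T, A, Cmem, Tmem, Amem`.
#' @export
windowFeatures <- function(series, memoryWindows = 4) {
  stopifnot(is(series, "MeasureSeries"))
  f <- cbind(C = series@C, T = series@T, A = series@A,
             Cmem = .memoryMean(series@C, memoryWindows),
             Tmem = .memoryMean(series@T, memoryWindows),
             Amem = .memoryMean(series@A, memoryWindows))
  f
}

.validity <- function(tp, fn, tn, fp, positiveClass) {
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  new("ValidityReport",
      acc = 100 * (tp + tn) / (tp + fn + tn + fp),
      sensitivity = sens, specificity = spec,
      fpr = 100 - spec, fnr = 100 - sens,
      counts = c(TP = as.integer(tp), FN = as.integer(fn),
                 TN = as.integer(tn), FP = as.integer(fp)),
      positiveClass = positiveClass)
}

#' Validity report from confusion counts
#'
#' @param tp,fn,tn,fp confusion-matrix counts.
#' @param positiveClass label of the positive class.
#' @return A [ValidityReport-class]; by construction
#'   `FPR = 100 - specificity` and `FNR = 100 - sensitivity`.
#' @examples
#' validityFromCounts(9, 1, 8, 2)   # sens 90, spec 80, ACC 85
#' @export
validityFromCounts <- function(tp, fn, tn, fp, positiveClass = "T") {
  .validity(tp, fn, tn, fp, positiveClass)
}

# Shared SVM trainer: radial-basis kernel, class-balanced weights,
# stratified (or contiguous-block) ten-fold CV, pooled confusion matrix.
.trainClassifier <- function(features, labels, positiveClass, folds, seed,
                             blockCV, scale) {
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2)
    stop("need exactly two classes, got: ",
         paste(levels(labels), collapse = ", "))
  if (any(table(labels) < 10))
    stop("need at least 10 samples per class")
  features <- as.matrix(features)
  keep <- stats::complete.cases(features)
  features[is.na(features)] <- 0
  if (scale) {
    mu <- colMeans(features)
    sdv <- apply(features, 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    features <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  } else {
    mu <- rep(0, ncol(features)); sdv <- rep(1, ncol(features))
  }
  n <- length(labels)
  set.seed(seed)
  if (blockCV) {
    fold <- cut(seq_len(n), breaks = folds, labels = FALSE)
  } else {
    fold <- integer(n)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  }
  wts <- rev(as.numeric(table(labels))) / n * 2
  names(wts) <- levels(labels)
  pred <- factor(rep(levels(labels)[1], n), levels = levels(labels))
  for (k in seq_len(folds)) {
    tr <- fold != k
    if (length(unique(labels[tr])) < 2) next
    fit <- e1071::svm(features[tr, , drop = FALSE], labels[tr],
                      kernel = "radial", class.weights = wts,
                      scale = FALSE)
    pred[!tr] <- stats::predict(fit, features[!tr, , drop = FALSE])
  }
  pos <- positiveClass
  neg <- setdiff(levels(labels), pos)
  tp <- sum(pred == pos & labels == pos)
  fn <- sum(pred == neg & labels == pos)
  tn <- sum(pred == neg & labels == neg)
  fp <- sum(pred == pos & labels == neg)
  report <- .validity(tp, fn, tn, fp, pos)
  final <- e1071::svm(features, labels, kernel = "radial",
                      class.weights = wts, scale = FALSE)
  predictFn <- function(newFeatures, time = NULL) {
    nf <- as.matrix(newFeatures)
    nf[is.na(nf)] <- 0
    nf <- sweep(sweep(nf, 2, mu), 2, sdv, "/")
    as.character(stats::predict(final, nf))
  }
  list(model = final, report = report, predictFn = predictFn,
       center = mu, scale = sdv, cvFold = fold, cvPred = pred,
       usedRows = keep)
}

#' Train the stop-stimulation classifier (NT vs T)
#'
#' Support-vector classifier (radial-basis kernel, class-balanced weights)
#' on per-window network-measure features, evaluated by ten-fold
#' cross-validation with the held-out predictions pooled into a single
#' confusion matrix. In the stop scenario the tremor class `T` is
#' positive: sensitivity is the ability to recognise `T`, specificity the
#' ability to recognise `NT`, and a false positive is an `NT` window
#' called `T`. Folds are stratified by default; `blockCV = TRUE` uses
#' contiguous blocks instead, which avoids leakage between overlapping
#' neighbouring windows and is the recommended setting for honest error
#' estimates on a single recording.
#'
#' @param features matrix or data.frame of per-window features, e.g.
#'   [windowFeatures()].
#' @param labels factor/character of `NT`/`T` per window (>= 10 each).
#' @param folds number of CV folds.
#' @param seed RNG seed for fold assignment.
#' @param blockCV use contiguous-block folds instead of stratified random
#'   folds.
#' @param scale standardise features (recommended).
#' @return List with `model` (the fitted svm), `report`
#'   ([ValidityReport-class]), `predictFn` (a `(features, time)` function
#'   for [runLoop()]), and CV bookkeeping.
#' @export
trainStopClassifier <- function(features, labels, folds = 10, seed = 1,
                                blockCV = FALSE, scale = TRUE) {
  labels <- factor(as.character(labels), levels = c("NT", "T"))
  if (any(is.na(labels))) stop("labels must be NT or T")
  .trainClassifier(features, labels, positiveClass = "T", folds, seed,
                   blockCV, scale)
}

#' Train the start-scenario classifier (NT vs TO)
#'
#' As [trainStopClassifier()] but for distinguishing rest from the onset
#' transition, with the class roles swapped: here `NT` is the positive
#' class: sensitivity is the ability to recognise `NT`, specificity the
#' ability to recognise `TO`, and the false-positive rate
#' (`100 - specificity`) counts `TO` windows mistaken for rest. The
#' transition class resembles rest by construction, so this classifier is
#' expected to perform worse than the stop classifier; the peak trigger,
#' not this model, drives the start decision.
#'
#' @inheritParams trainStopClassifier
#' @param labels factor/character of `NT`/`TO` per window.
#' @return As [trainStopClassifier()].
#' @export
trainOnsetClassifier <- function(features, labels, folds = 10, seed = 1,
                                 blockCV = FALSE, scale = TRUE) {
  labels <- factor(as.character(labels), levels = c("NT", "TO"))
  if (any(is.na(labels))) stop("labels must be NT or TO")
  .trainClassifier(features, labels, positiveClass = "NT", folds, seed,
                   blockCV, scale)
}
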