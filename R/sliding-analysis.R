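# Moving-window recurrence-network analysis: per-window measure time
# courses, moving-median significance bands, peak detection and peak/state
# bookkeeping.

#' Per-window network-measure time course
#'
#' For every analysis window: delay-embed at the (fixed) parameters, set
#' the distance threshold for the requested recurrence rate, build the
#' recurrence network and record clustering, transitivity and
#' assortativity at the window's mid-point time. Degenerate windows
#' (constant signal, or all state vectors identical) yield missing values
#' and are flagged rather than dropped; undefined assortativity is
#' recorded as missing.
#'
#' @param windows a [WindowSet-class] from [segmentWindows()].
#' @param params an [EmbeddingParams-class], normally from
#'   [selectEmbedding()] on the recording's initial atremorous stretch and
#'   held fixed across windows.
#' @param rr target recurrence rate.
#' @param theiler optional Theiler window for [buildNetwork()].
#' @return A [MeasureSeries-class].
#' @export
measureTimecourse <- function(windows, params, rr = 0.03, theiler = 0L) {
  stopifnot(is(windows, "WindowSet"), is(params, "EmbeddingParams"))
  nw <- nrow(windows@windows)
  C <- Tv <- A <- rep(NA_real_, nw)
  degen <- logical(nw)
  for (i in seq_len(nw)) {
    x <- windows@windows[i, ]
    if (stats::sd(x) == 0) { degen[i] <- TRUE; next }
    pts <- embedSeries(x, params)
    net <- tryCatch(buildNetwork(pts, rr = rr, theiler = theiler),
                    error = function(e) NULL)
    if (is.null(net)) { degen[i] <- TRUE; next }
    mm <- networkMeasures(net)
    C[i] <- mm$C
    Tv[i] <- mm$T
    A[i] <- mm$A
  }
  .measureSeries(windows@midTimes, C, Tv, A, degen, params, rr)
}

# Centred moving median of odd nominal length; near the ends the
# half-window shrinks symmetrically instead of padding, so no values are
# fabricated. Missing values are ignored within each window.
.movingMedian <- function(x, n) {
  stopifnot(n %% 2 == 1)
  h <- (n - 1L) %/% 2L
  N <- length(x)
  out <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    hh <- min(h, i - 1L, N - i)
    w <- x[(i - hh):(i + hh)]
    if (all(is.na(w))) next
    out[i] <- stats::median(w, na.rm = TRUE)
  }
  out
}

#' Moving-median significance bands for a measure series
#'
#' Smooths one measure with a centred moving median (odd length,
#' default 21 windows, about 4.2 s of signal at the default hop) and
#' estimates the residual scale `sigma` from `raw - medianTrack` with the
#' Gaussian-consistent median absolute deviation — robust, because the
#' residual pool contains the very transients the bands are meant to
#' flag. The pool is the whole recording by default, or only the first
#' `baselineS` seconds' worth of windows with `baseline = "baseline"`.
#' The `+/-2 sigma` and `+/-3 sigma` bands around the
#' median track mark transients nominally significant at p < 0.05 and
#' p < 0.01 (a Gaussian labelling convention, not a formal test).
#' Missing values (degenerate windows, undefined assortativity) are
#' excluded from both the median and the sigma estimate, never
#' interpolated.
#'
#' @param series a [MeasureSeries-class] (or numeric vector of one
#'   measure's values, with `midTimes` supplied).
#' @param measure which measure to band when `series` is a MeasureSeries.
#' @param medianWindowN moving-median length in windows (odd).
#' @param baseline `"all"` (default: whole recording) or `"baseline"`
#'   (first `baselineS` seconds of windows). The moving median absorbs
#'   level shifts, so whole-recording residuals give a stable scale even
#'   when the recording contains tremor; a 5-s baseline leaves so few
#'   effectively independent windows (overlapping windows are strongly
#'   correlated) that the nominal 2/3-sigma calibration breaks down.
#' @param baselineS baseline length in seconds.
#' @param midTimes window times when `series` is a bare numeric vector.
#' @return A [SignificanceBands-class].
#' @export
significanceBands <- function(series, measure = c("C", "T", "A"),
                              medianWindowN = 21,
                              baseline = c("all", "baseline"),
                              baselineS = 5, midTimes = NULL) {
  baseline <- match.arg(baseline)
  if (is(series, "MeasureSeries")) {
    measure <- match.arg(measure)
    x <- measureValues(series, measure)
    tt <- series@midTimes
  } else {
    x <- as.numeric(series)
    tt <- if (is.null(midTimes)) seq_along(x) else midTimes
  }
  if (length(x) < medianWindowN)
    stop("series shorter than the median window (", medianWindowN,
         " windows)")
  med <- .movingMedian(x, medianWindowN)
  resid <- x - med
  h <- (medianWindowN - 1L) %/% 2L
  if (baseline == "all") {
    bi <- seq_along(x)
  } else {
    hopS <- if (length(tt) > 1) tt[2] - tt[1] else 1
    nb <- max(2L, as.integer(round(baselineS / hopS)))
    bi <- seq_len(min(nb, length(x)))
    # windows whose centred median had to shrink towards the series start
    # have structurally small residuals; they would deflate the scale
    full <- bi[bi > h]
    if (length(full) >= 2) bi <- full
  }
  r <- resid[bi]
  # robust, Gaussian-consistent scale: the residual pool may contain the
  # very transients the bands are meant to flag, which would inflate a
  # plain standard deviation and mask them; Qn keeps near-normal
  # efficiency so the null calibration does not suffer
  sig <- if (sum(!is.na(r)) >= 2) .qnScale(r[!is.na(r)]) else 0
  if (is.na(sig)) sig <- 0
  new("SignificanceBands", midTimes = tt, medianTrack = med, sigma = sig,
      baselineIdx = as.integer(bi))
}

#' Detect significant peaks in a measure series
#'
#' Mirrors the controller's memory: window `i`'s test statistic is the
#' mean of the raw measure over windows `i - memoryWindows .. i` (fewer at
#' the start). A level-`L` peak event is recorded at each upward crossing,
#' i.e. the first window where the statistic strictly exceeds
#' `medianTrack + L * sigma` after having been at or below it. A 3-sigma
#' exceedance implies the 2-sigma one by construction; the two levels are
#' reported as separate event streams labelled with nominal significance
#' (2 sigma ~ p < 0.05, 3 sigma ~ p < 0.01).
#'
#' @param series a [MeasureSeries-class] or numeric vector.
#' @param bands the matching [SignificanceBands-class].
#' @param measure measure name used for the events (and extraction when
#'   `series` is a MeasureSeries).
#' @param memoryWindows number of previous windows averaged in.
#' @param levels band levels to scan (default 2 and 3).
#' @return data.frame with columns `time`, `measure`, `level`, `value`
#'   (the exceeding mean), one row per peak event; zero rows when the
#'   series never leaves the bands.
#' @export
detectPeaks <- function(series, bands, measure = c("C", "T", "A"),
                        memoryWindows = 4, levels = c(2, 3)) {
  measure <- match.arg(measure)
  x <- if (is(series, "MeasureSeries")) measureValues(series, measure)
       else as.numeric(series)
  stopifnot(is(bands, "SignificanceBands"),
            length(x) == length(bands@medianTrack))
  sm <- .memoryMean(x, memoryWindows)
  out <- data.frame(time = numeric(0), measure = character(0),
                    level = numeric(0), value = numeric(0))
  for (L in levels) {
    thr <- bands@medianTrack + L * bands@sigma
    above <- !is.na(sm) & !is.na(thr) & sm > thr
    onset <- above & !c(FALSE, above[-length(above)])
    idx <- which(onset)
    if (length(idx))
      out <- rbind(out, data.frame(time = bands@midTimes[idx],
                                   measure = measure, level = L,
                                   value = sm[idx]))
  }
  out <- out[order(out$time, out$level), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Rousseeuw-Croux Qn scale estimator, Gaussian-consistent: the k-th order
# statistic of all pairwise absolute differences, k = choose(h, 2) with
# h = floor(n/2) + 1. ~82% efficiency at the normal with 50% breakdown,
# so a minority of large (tremor-transient) residuals cannot inflate it.
# Naive O(n^2) enumeration; residual pools here are a few hundred values.
.qnScale <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  d <- abs(outer(x, x, "-"))
  d <- sort(d[upper.tri(d)])
  h <- n %/% 2L + 1L
  k <- h * (h - 1L) %/% 2L
  # finite-sample consistency correction (Rousseeuw & Croux 1993)
  cn <- if (n <= 9) c(NA, 0.399, 0.994, 0.512, 0.844, 0.611, 0.857,
                      0.669, 0.872)[n]
        else if (n %% 2 == 1) n / (n + 1.4) else n / (n + 3.8)
  2.2219 * cn * d[k]
}

# Trailing mean over the current and up to `mem` previous values,
# ignoring missing entries.
.memoryMean <- function(x, mem) {
  N <- length(x)
  out <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    w <- x[max(1L, i - mem):i]
    if (any(!is.na(w))) out[i] <- mean(w, na.rm = TRUE)
  }
  out
}

#' Summarise peaks against movement-state labels
#'
#' Attaches to each peak the movement state at its time and, where the
#' labels contain a tremor (`T`) segment, the lead time to the first `T`
#' boundary (positive = peak before overt tremor). Also tabulates peak
#' counts per state and level.
#'
#' @param peaks data.frame from [detectPeaks()].
#' @param labels a [LabelTrack-class].
#' @return List with `peaks` (the input plus `state` and `leadTime`
#'   columns) and `counts` (per state x level table); both empty when no
#'   peaks were supplied.
#' @export
stateOfPeaks <- function(peaks, labels) {
  stopifnot(is(labels, "LabelTrack"))
  if (nrow(peaks) == 0)
    return(list(peaks = peaks, counts = table(state = character(0),
                                              level = numeric(0))))
  st <- stateAt(labels, peaks$time)
  seg <- labels@segments
  tT <- seg$start[seg$state == "T"]
  lead <- if (length(tT)) tT[1] - peaks$time else rep(NA_real_, nrow(peaks))
  out <- cbind(peaks, state = st, leadTime = lead)
  list(peaks = out, counts = table(state = st, level = peaks$level))
}

#' End-to-end moving-window analysis of one recording
#'
#' Runs the full chain: downsample + band-pass the LFP (and condition the
#' EMG when given), select the embedding on the initial stretch, segment
#' into overlapping windows, compute the measure time courses, band each
#' measure, and detect peaks. Labels, when supplied, annotate the peaks.
#'
#' @param lfp LFP [Recording-class] (raw).
#' @param emg optional EMG [Recording-class] (raw).
#' @param labels optional [LabelTrack-class].
#' @param config an [AnalysisConfig-class].
#' @param params optional [EmbeddingParams-class] to skip selection (used
#'   by robustness sweeps).
#' @param baseline band sigma mode, `"all"` (default) or `"baseline"`.
#' @return List with `measures` ([MeasureSeries-class]), `bands` (named
#'   list over C/T/A), `peaks` (clustering peaks with state annotation if
#'   labels given), `params`, `onset` (EMG onset or NULL) and `lfp`
#'   (the conditioned recording).
#' @export
analyzeRecording <- function(lfp, emg = NULL, labels = NULL,
                             config = analysisConfig(), params = NULL,
                             baseline = c("all", "baseline")) {
  baseline <- match.arg(baseline)
  pre <- preprocessRecording(lfp, emg, config)
  if (is.null(labels)) labels <- pre$labels
  if (is.null(params))
    params <- selectEmbedding(pre$lfp,
                              selectS = max(10, config@baselineS))
  ws <- segmentWindows(pre$lfp, config@windowS, config@overlapFrac)
  ms <- measureTimecourse(ws, params, config@rr)
  bands <- lapply(c(C = "C", T = "T", A = "A"), function(mm)
    significanceBands(ms, mm, config@medianWindowN, baseline,
                      config@baselineS))
  peaks <- detectPeaks(ms, bands$C, "C", config@memoryWindows)
  if (!is.null(labels) && nrow(peaks))
    peaks <- stateOfPeaks(peaks, labels)$peaks
  list(measures = ms, bands = bands, peaks = peaks, params = params,
       onset = pre$onset, lfp = pre$lfp, labels = labels)
}

#' Robustness sweep over the embedding dimension
#'
#' Recomputes the transitivity time course of one recording at several
#' embedding dimensions (delay fixed) and reports the pairwise Spearman
#' correlations of the resulting trajectories — the check that the
#' measure's temporal profile, and hence tremor detection, is insensitive
#' to the exact dimension.
#'
#' @param lfp LFP [Recording-class] (raw).
#' @param mList dimensions to sweep.
#' @param config an [AnalysisConfig-class].
#' @param tau embedding delay; selected from the recording when NULL.
#' @param measure which measure to track.
#' @return List with `series` (named list of [MeasureSeries-class]) and
#'   `spearman` (correlation matrix across dimensions).
#' @export
robustnessSweep <- function(lfp, mList = c(4, 6, 8, 10),
                            config = analysisConfig(), tau = NULL,
                            measure = c("T", "C", "A")) {
  measure <- match.arg(measure)
  pre <- preprocessRecording(lfp, NULL, config)
  if (is.null(tau)) {
    p0 <- selectEmbedding(pre$lfp, selectS = max(10, config@baselineS))
    tau <- p0@tau
  }
  ws <- segmentWindows(pre$lfp, config@windowS, config@overlapFrac)
  series <- lapply(mList, function(m)
    measureTimecourse(ws, embeddingParams(tau, m), config@rr))
  names(series) <- paste0("m", mList)
  vals <- vapply(series, measureValues, numeric(length(ws@midTimes)),
                 measure = measure)
  rho <- stats::cor(vals, method = "spearman",
                    use = "pairwise.complete.obs")
  list(series = series, spearman = rho, tau = tau)
}
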