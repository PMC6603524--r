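# File I/O: recordings (EDF or delimited text), label tracks, measure
# series and configuration files.
#
# Delimited-text dialect used throughout: tab-separated values, header lines
# prefixed with "#". EDF support is a minimal self-contained implementation
# of the continuous 16-bit EDF layout (256-byte global header + one
# 256-byte block per signal + little-endian 2-byte data records).

.trim <- function(x) sub("[ \t]+$", "", sub("^[ \t]+", "", x))

#' Read a biosignal recording
#'
#' Reads either an EDF file (detected by the `.edf` extension or the EDF
#' header magic) or a `#`-commented tab-separated text file. Text files may
#' carry one value per line with the rate declared in a `# rate=...` header
#' line, or two columns (time, value) from which the rate is inferred; a
#' uniformity check rejects time columns with gaps larger than twice the
#' sample interval. Values are taken as stored (uV); reading never rescales.
#'
#' @param path path to the file.
#' @param role channel role to assign, `"LFP"` or `"EMG"`.
#' @param channel for EDF files with several signals: index or label of the
#'   channel to read (default first).
#' @return A [Recording-class].
#' @seealso [writeRecording()], [readEDF()]
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeRecording(recording(rnorm(250), 125), f)
#' readRecording(f, "LFP")
#' @export
readRecording <- function(path, role = c("LFP", "EMG"), channel = 1L) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  isEDF <- grepl("\\.edf$", path, ignore.case = TRUE)
  if (!isEDF) {
    hdr <- readBin(path, "raw", n = 8L)
    isEDF <- length(hdr) == 8L && rawToChar(hdr[1]) == "0" &&
      all(hdr[-1] == charToRaw(" "))
  }
  if (isEDF) {
    edf <- readEDF(path)
    ch <- if (is.character(channel)) match(channel, edf$labels) else channel
    if (is.na(ch) || ch < 1 || ch > length(edf$signals))
      stop("channel not present in EDF file")
    return(recording(edf$signals[[ch]], edf$rates[ch], role,
                     startTime = 0))
  }
  lines <- readLines(path, warn = FALSE)
  hdrLines <- grep("^#", lines, value = TRUE)
  dataLines <- lines[!grepl("^#", lines) & nzchar(.trim(lines))]
  if (!length(dataLines)) stop("no data in ", path)
  fields <- strsplit(dataLines, "[\t ]+")
  ncol <- length(fields[[1]])
  vals <- suppressWarnings(lapply(fields, as.numeric))
  if (any(vapply(vals, function(v) any(is.na(v)) || length(v) != ncol,
                 logical(1))))
    stop("malformed numeric data in ", path)
  getHdr <- function(key) {
    m <- regmatches(hdrLines,
                    regexpr(paste0(key, "[ \t]*=[ \t]*[-0-9.eE+]+"), hdrLines))
    if (length(m)) as.numeric(sub(".*=", "", m[[1]])) else NA_real_
  }
  if (ncol == 1L) {
    fs <- getHdr("rate")
    if (is.na(fs)) stop("single-column file needs a '# rate=' header line")
    st <- getHdr("start_time")
    recording(vapply(vals, `[`, numeric(1), 1L), fs, role,
              startTime = if (is.na(st)) 0 else st)
  } else if (ncol == 2L) {
    tt <- vapply(vals, `[`, numeric(1), 1L)
    xx <- vapply(vals, `[`, numeric(1), 2L)
    dt <- diff(tt)
    if (any(dt <= 0)) stop("time column must be strictly increasing")
    fs <- 1 / median(dt)
    if (any(dt > 2 / fs + 1e-9))
      stop("non-uniform time column: gap exceeds 2 sample intervals")
    recording(xx, fs, role, startTime = tt[1])
  } else stop("expected 1 or 2 columns, got ", ncol)
}

#' Write a recording as tab-separated text
#'
#' One sample per line with `# rate=`, `# role=` and `# start_time=` header
#' lines; full floating-point precision, so
#' `readRecording(writeRecording(x))` round-trips exactly.
#'
#' @param rec a [Recording-class].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate=%.10g", rec@rate),
               sprintf("# role=%s", rec@role),
               sprintf("# start_time=%.10g", rec@startTime),
               sprintf("%.17g", rec@samples)), con)
  invisible(path)
}

#' Read a minimal continuous EDF file
#'
#' Parses the 256-byte EDF header, the per-signal header blocks and the
#' 16-bit little-endian data records, applying each signal's
#' digital-to-physical calibration. A `NSAMP=<n>` token in the reserved
#' header field (written by [writeEDF()]) trims record padding to the true
#' sample count; files without it are read record-complete.
#'
#' @param path path to the EDF file.
#' @return A list with `labels`, `rates`, `signals` (list of numeric
#'   vectors) and `recordDuration`.
#' @seealso [writeEDF()], [readRecording()]
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) .trim(readChar(con, n, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file (bad version field): ", path)
  rd(80); rd(80); rd(8); rd(8)                 # patient, recording, date, time
  nbytes <- as.integer(rd(8))
  reserved <- rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("EDF header corrupt: ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)                # transducer
  for (i in seq_len(ns)) rd(8)                 # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)                # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)                # reserved
  if (nbytes != 256L * (ns + 1L))
    stop("EDF header length field inconsistent: ", path)
  sig <- lapply(spr, function(k) numeric(0))
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2L,
                     signed = TRUE, endian = "little")
      if (length(raw) < spr[i]) stop("EDF data truncated: ", path)
      sig[[i]] <- c(sig[[i]], raw)
    }
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  signals <- lapply(seq_len(ns), function(i)
    pmin[i] + (sig[[i]] - dmin[i]) * gain[i])
  m <- regmatches(reserved, regexpr("NSAMP=[0-9]+", reserved))
  if (length(m) && nchar(m)) {
    nsamp <- as.integer(sub("NSAMP=", "", m))
    signals <- lapply(signals, function(s) s[seq_len(min(nsamp, length(s)))])
  }
  list(labels = labels, rates = spr / recDur, signals = signals,
       recordDuration = recDur)
}

#' Write recordings to a minimal continuous EDF file
#'
#' Writes one or more [Recording-class] objects as 16-bit EDF with 1-second
#' data records. All channels must share an integer sampling rate. The last
#' record is zero-padded; the true sample count is stored as `NSAMP=<n>` in
#' the reserved header field so [readEDF()] restores the exact length.
#' Amplitudes are quantized to 16 bits over each channel's range.
#'
#' @param recs a [Recording-class] or list of them.
#' @param path destination path.
#' @param labels channel labels (default from the roles).
#' @return `path`, invisibly.
#' @export
writeEDF <- function(recs, path, labels = NULL) {
  if (is(recs, "Recording")) recs <- list(recs)
  stopifnot(length(recs) >= 1, all(vapply(recs, is, logical(1), "Recording")))
  rates <- vapply(recs, function(r) r@rate, numeric(1))
  if (any(rates != round(rates)))
    stop("EDF writer requires integer sampling rates")
  if (is.null(labels))
    labels <- vapply(seq_along(recs), function(i)
      sprintf("%s %d", recs[[i]]@role, i), character(1))
  ns <- length(recs)
  nsamp <- vapply(recs, function(r) length(r@samples), integer(1))
  nrec <- max(ceiling(nsamp / rates))
  pad <- function(x, w) formatC(substr(x, 1, w), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad(x, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (ns + 1L)), 8)
  wr(sprintf("NSAMP=%d", max(nsamp)), 44)
  wr(as.character(nrec), 8); wr("1", 8); wr(as.character(ns), 4)
  physMin <- physMax <- numeric(ns)
  for (i in seq_len(ns)) {
    rg <- range(recs[[i]]@samples)
    if (diff(rg) == 0) rg <- rg + c(-1, 1)
    physMin[i] <- rg[1]; physMax[i] <- rg[2]
  }
  for (i in seq_len(ns)) wr(labels[i], 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", physMin[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", physMax[i]), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(as.integer(rates[i])), 8)
  for (i in seq_len(ns)) wr("", 32)
  # EDF stores the physical min/max only to 8 ascii chars; quantize against
  # the written (rounded) bounds so read-back error stays within one LSB.
  pminW <- as.numeric(sprintf("%.8g", physMin))
  pmaxW <- as.numeric(sprintf("%.8g", physMax))
  dig <- lapply(seq_len(ns), function(i) {
    x <- recs[[i]]@samples
    d <- round(-32768 + (x - pminW[i]) / (pmaxW[i] - pminW[i]) * 65535)
    as.integer(pmin(32767, pmax(-32768, d)))
  })
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * rates[i] + 1L):(r * rates[i])
      chunk <- rep(0L, length(idx))
      ok <- idx <= nsamp[i]
      chunk[ok] <- dig[[i]][idx[ok]]
      writeBin(chunk, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read / write movement-state label tracks
#'
#' Tab-separated files with `#`-prefixed header lines and columns
#' `start`, `end`, `state` (seconds; states `NT`, `TO`, `T`). Intervals are
#' half-open `[start, end)`. `readLabels(writeLabels(x)) == x` at full
#' precision. An empty file yields an empty track; overlapping segments are
#' a validation error.
#'
#' @param path file path.
#' @return `readLabels`: a [LabelTrack-class]. `writeLabels`: `path`,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLabels(labelTrack(c(0, 10), c(10, 40), c("NT", "T")), f)
#' readLabels(f)
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(.trim(lines))]
  if (!length(lines)) return(labelTrack())
  f <- strsplit(lines, "\t")
  if (any(lengths(f) != 3L)) stop("label rows need 3 tab-separated fields")
  labelTrack(as.numeric(vapply(f, `[`, character(1), 1L)),
             as.numeric(vapply(f, `[`, character(1), 2L)),
             .trim(vapply(f, `[`, character(1), 3L)))
}

#' @param labels a [LabelTrack-class].
#' @rdname readLabels
#' @export
writeLabels <- function(labels, path) {
  stopifnot(is(labels, "LabelTrack"))
  s <- labels@segments
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# start\tend\tstate", con)
  if (nrow(s))
    writeLines(sprintf("%.17g\t%.17g\t%s", s$start, s$end, s$state), con)
  invisible(path)
}

#' Read / write a measure series (with optional significance bands)
#'
#' Tab-separated columns: `time`, `C`, `T`, `A`; when bands are given, also
#' per-measure `<measure>_median` and a `# sigma_<measure>=` header line per
#' measure. Missing values are written as `NA`. Embedding parameters and the
#' recurrence rate travel in `#` header lines so the round trip restores a
#' complete [MeasureSeries-class].
#'
#' @param path file path.
#' @return `readMeasures`: a list with `series` ([MeasureSeries-class]) and
#'   `bands` (list of [SignificanceBands-class] or NULL).
#'   `writeMeasures`: `path`, invisibly.
#' @export
readMeasures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  getH <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[-0-9.eE+]+"), hdr))
    if (length(m)) as.numeric(sub(".*=", "", m[[1]])) else NA_real_
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  cols <- strsplit(body[1], "\t")[[1]]
  dat <- read.table(text = paste(body[-1], collapse = "\n"), sep = "\t",
                    col.names = cols, na.strings = "NA")
  ms <- .measureSeries(dat$time, dat$C, dat$T, dat$A,
                       is.na(dat$C) & is.na(dat$T),
                       embeddingParams(getH("tau"), getH("m")),
                       getH("rr"))
  bands <- NULL
  if ("C_median" %in% cols) {
    bands <- lapply(c("C", "T", "A"), function(mm) {
      new("SignificanceBands", midTimes = dat$time,
          medianTrack = dat[[paste0(mm, "_median")]],
          sigma = getH(paste0("sigma_", mm)),
          baselineIdx = integer(0))
    })
    names(bands) <- c("C", "T", "A")
  }
  list(series = ms, bands = bands)
}

#' @param series a [MeasureSeries-class].
#' @param bands optional named list of [SignificanceBands-class]
#'   (names `C`, `T`, `A`).
#' @rdname readMeasures
#' @export
writeMeasures <- function(series, path, bands = NULL) {
  stopifnot(is(series, "MeasureSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tau=%d", series@params@tau), con)
  writeLines(sprintf("# m=%d", series@params@m), con)
  writeLines(sprintf("# rr=%.10g", series@rr), con)
  dat <- data.frame(time = series@midTimes, C = series@C, T = series@T,
                    A = series@A)
  if (!is.null(bands)) {
    for (mm in names(bands)) {
      dat[[paste0(mm, "_median")]] <- bands[[mm]]@medianTrack
      writeLines(sprintf("# sigma_%s=%.17g", mm, bands[[mm]]@sigma), con)
    }
  }
  writeLines(paste(names(dat), collapse = "\t"), con)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  writeLines(do.call(paste, c(lapply(dat, fmt), sep = "\t")), con)
  invisible(path)
}

#' Read / write an analysis configuration
#'
#' INI/TOML-style `key = value` lines (comments with `#`). Keys mirror the
#' [AnalysisConfig-class] fields in snake_case: `target_rate`, `band`
#' (two comma-separated numbers), `filter_order`, `window_s`,
#' `overlap_frac`, `recurrence_rate`, `median_window_n`, `baseline_s`,
#' `sigma_trigger`, `memory_windows`. Missing keys keep their defaults.
#'
#' @param path file path.
#' @return `readConfig`: an [AnalysisConfig-class]. `writeConfig`: `path`,
#'   invisibly.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- strsplit(lines, "=")
  keys <- .trim(vapply(kv, `[`, character(1), 1L))
  vals <- .trim(vapply(kv, function(p) paste(p[-1], collapse = "="),
                       character(1)))
  vals <- gsub("[][]", "", vals)
  get <- function(key, default) {
    i <- match(key, keys)
    if (is.na(i)) default else as.numeric(strsplit(vals[i], ",")[[1]])
  }
  analysisConfig(
    targetRate = get("target_rate", 125),
    band = get("band", c(2, 45)),
    filterOrder = get("filter_order", 500),
    windowS = get("window_s", 2),
    overlapFrac = get("overlap_frac", 0.90),
    rr = get("recurrence_rate", 0.03),
    medianWindowN = get("median_window_n", 21),
    baselineS = get("baseline_s", 5),
    sigmaTrigger = get("sigma_trigger", 2),
    memoryWindows = get("memory_windows", 4))
}

#' @param config an [AnalysisConfig-class].
#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  stopifnot(is(config, "AnalysisConfig"))
  writeLines(c(
    sprintf("target_rate = %.10g", config@targetRate),
    sprintf("band = %.10g,%.10g", config@band[1], config@band[2]),
    sprintf("filter_order = %.10g", config@filterOrder),
    sprintf("window_s = %.10g", config@windowS),
    sprintf("overlap_frac = %.10g", config@overlapFrac),
    sprintf("recurrence_rate = %.10g", config@rr),
    sprintf("median_window_n = %.10g", config@medianWindowN),
    sprintf("baseline_s = %.10g", config@baselineS),
    sprintf("sigma_trigger = %.10g", config@sigmaTrigger),
    sprintf("memory_windows = %.10g", config@memoryWindows)), path)
  invisible(path)
}
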