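# Synthetic labelled LFP+EMG recordings with the statistical structure the
# analysis assumes: linear-stochastic rest activity, a transition with
# gradually rising nonlinearity, and a nonlinear oscillatory tremor segment
# with burst-modulated EMG. Also canonical benchmark signals for validating
# the embedding and network stages.

# Mean rotation frequency of the Rossler system (a = b = 0.2, c = 5.7) in
# cycles per model time unit, measured by direct long-run integration;
# fixes the integration step that maps the attractor's dominant frequency
# onto the requested tremor frequency.
.ROSSLER_CPU <- 0.170

.rk4 <- function(f, s, h, n, keep = 1L) {
  out <- matrix(0, nrow = n, ncol = length(s))
  for (i in seq_len(n)) {
    k1 <- f(s)
    k2 <- f(s + h / 2 * k1)
    k3 <- f(s + h / 2 * k2)
    k4 <- f(s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i, ] <- s
  }
  out[, keep]
}

.rosslerF <- function(a = 0.2, b = 0.2, c = 5.7) {
  function(s) c(-s[2] - s[3], s[1] + a * s[2], b + s[3] * (s[1] - c))
}

.lorenzF <- function(sigma = 10, rho = 28, beta = 8 / 3) {
  function(s) c(sigma * (s[2] - s[1]), s[1] * (rho - s[3]) - s[2],
                s[1] * s[2] - beta * s[3])
}

# Resonant AR(2): poles at radius r and frequency f0, unit-variance output.
.ar2 <- function(n, fs, f0 = 20, r = 0.94) {
  phi1 <- 2 * r * cos(2 * pi * f0 / fs)
  phi2 <- -r^2
  e <- stats::rnorm(n + 200)
  x <- as.numeric(stats::filter(e, c(phi1, phi2), method = "recursive"))
  x <- x[-(1:200)]
  x / stats::sd(x)
}

#' Canonical benchmark signals
#'
#' Deterministic (under `seed`) scalar series used to validate the
#' embedding and recurrence-network stages: a unit-amplitude sine, white
#' Gaussian noise, the x-components of the Lorenz (sigma = 10, rho = 28,
#' beta = 8/3, step 0.01) and Rossler (a = b = 0.2, c = 5.7, step 0.05)
#' systems integrated with a fixed-step 4th-order Runge-Kutta scheme with
#' transients discarded, and a resonant second-order autoregression.
#'
#' @param kind one of `"sine"`, `"white_noise"`, `"lorenz"`, `"rossler"`,
#'   `"ar2"`.
#' @param n number of samples.
#' @param seed RNG seed (stochastic kinds).
#' @param period sine period in samples.
#' @param dt integration step for the flows.
#' @return Numeric series of length `n`.
#' @examples
#' x <- generateBenchmarkSignals("lorenz", 1000)
#' max(abs(x)) < 25
#' @export
generateBenchmarkSignals <- function(kind = c("sine", "white_noise",
                                              "lorenz", "rossler", "ar2"),
                                     n, seed = 1, period = 25,
                                     dt = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    sine = sin(2 * pi * (0:(n - 1)) / period),
    white_noise = { set.seed(seed); stats::rnorm(n) },
    lorenz = {
      h <- if (is.null(dt)) 0.01 else dt
      tr <- .rk4(.lorenzF(), c(1, 1, 1), h, 2000L + n, keep = 1L)
      tr[(2000L + 1L):(2000L + n)]
    },
    rossler = {
      h <- if (is.null(dt)) 0.05 else dt
      f <- .rosslerF()
      ntr <- as.integer(ceiling(100 / h))
      tr <- .rk4(f, c(1, 1, 1), h, ntr + n, keep = 1L)
      tr[(ntr + 1L):(ntr + n)]
    },
    ar2 = { set.seed(seed); .ar2(n, fs = 125) })
}

# Mixing schedule across the transition segment, in units of the tremor
# mixing level (1 = the tremor segment's level). "overshoot" (default)
# emulates the observed phenomenology: an abrupt nonlinearity surge early
# in the transition that partially recedes to an intermediate level, then
# a second rise into overt tremor. "sigmoid" is a plain steep cross-fade,
# "linear" a straight one.
.ramp <- function(n, shape) {
  if (n == 0) return(numeric(0))
  u <- seq(0, 1, length.out = n)
  switch(shape,
    linear = u,
    sigmoid = 1 / (1 + exp(-20 * (u - 0.5))),
    overshoot = pmin(1.2,
      0.55 / (1 + exp(-25 * (u - 0.08))) +
      0.65 * exp(-((u - 0.2) / 0.12)^2) +
      0.45 / (1 + exp(-20 * (u - 0.85)))))
}

#' Generate a labelled synthetic LFP + EMG recording
#'
#' The LFP is a mixture `(1 - w(t)) * AR + w(t) * Rossler` of a
#' unit-variance resonant AR(2) process (poles near 20 Hz: band-limited
#' linear stochastic rest activity) and the unit-variance x-component of a
#' Rossler oscillator integrated so its dominant frequency equals
#' `tremorFreq`: a nonlinear, weakly chaotic limit-cycle source standing
#' in for the tremor-locked subthalamic oscillation. The mixing weight
#' `w(t)` is 0 at rest, follows the configured ramp from 0 to its tremor
#' level of 0.8 across the transition segment, holds during tremor, and
#' fades back over 1 s when a trailing rest segment is present. White
#' measurement noise is added at `snrDb`. The EMG is a band-limited
#' (40-120 Hz) carrier whose amplitude is multiplied by
#' `1 + 6 * max(0, sin(2 pi tremorFreq t))^2` bursts that begin midway
#' through the transition (muscle symptoms lag the neural change, which
#' is exactly the window a demand-driven trigger exploits) and stop at the
#' end of the tremor segment. Labels follow the construction exactly and a
#' fixed seed reproduces the recording bit for bit.
#'
#' @param spec a [ScenarioSpec-class].
#' @return List with `lfp` and `emg` ([Recording-class], at `spec@rate`),
#'   `labels` ([LabelTrack-class]) and `burstOnset` (the constructed EMG
#'   burst onset time in seconds, NA when there is no transition).
#' @examples
#' rec <- generateRecording(scenarioSpec(ntS = 12, toS = 0, tS = 0,
#'                                       postNtS = 0, seed = 7))
#' rec$labels
#' @export
generateRecording <- function(spec) {
  stopifnot(is(spec, "ScenarioSpec"))
  set.seed(spec@seed)
  fs <- spec@rate
  nNT <- as.integer(round(spec@ntS * fs))
  nTO <- as.integer(round(spec@toS * fs))
  nT <- as.integer(round(spec@tS * fs))
  nPost <- as.integer(round(spec@postNtS * fs))
  n <- nNT + nTO + nT + nPost
  tt <- (0:(n - 1)) / fs

  ar <- .ar2(n, fs)
  # Rossler source scaled so the attractor's dominant frequency lands on
  # tremorFreq: h model-time units per sample.
  h <- spec@tremorFreq / .ROSSLER_CPU / fs
  f <- .rosslerF()
  ntr <- as.integer(ceiling(50 / h))
  ross <- .rk4(f, c(1 + stats::runif(1), 1, 1), h, ntr + n, keep = 1L)
  ross <- ross[(ntr + 1L):(ntr + n)]
  ross <- (ross - mean(ross)) / stats::sd(ross)

  w <- c(rep(0, nNT), pmin(0.95, 0.8 * .ramp(nTO, spec@ramp)),
         rep(0.8, nT), rep(0, nPost))
  if (nPost > 0 && nT > 0) {           # 1-s fade back to rest
    nf <- min(nPost, as.integer(fs))
    w[(nNT + nTO + nT + 1L):(nNT + nTO + nT + nf)] <-
      0.8 * rev(seq_len(nf)) / nf
  }
  clean <- (1 - w) * ar + w * ross
  noise <- stats::rnorm(n, sd = stats::sd(clean) * 10^(-spec@snrDb / 20))
  lfp <- recording(50 * (clean + noise), fs, "LFP")

  carrier <- stats::rnorm(n)
  bc <- signal::fir1(300, c(40, 120) / (fs / 2), type = "pass")
  carrier <- .firApply(carrier, bc)
  carrier <- carrier / stats::sd(carrier)
  burst <- pmax(0, sin(2 * pi * spec@tremorFreq * tt))^2
  gate <- numeric(n)
  burstOnset <- NA_real_
  if (nTO + nT > 0) {
    onsetIdx <- nNT + as.integer(floor(nTO / 2)) + 1L   # midway through TO
    offIdx <- nNT + nTO + nT
    if (onsetIdx <= offIdx) {
      gate[onsetIdx:offIdx] <- 1
      nr <- min(as.integer(fs), offIdx - onsetIdx + 1L)  # 1-s ramp-in
      gate[onsetIdx:(onsetIdx + nr - 1L)] <- seq_len(nr) / nr
      burstOnset <- (onsetIdx - 1L) / fs
    }
  }
  emg <- recording(20 * (1 + 6 * gate * burst) * carrier, fs, "EMG")

  segs <- data.frame(start = numeric(0), end = numeric(0),
                     state = character(0))
  bounds <- cumsum(c(0, spec@ntS, spec@toS, spec@tS, spec@postNtS))
  states <- c("NT", "TO", "T", "NT")
  for (i in 1:4) {
    if (bounds[i + 1] > bounds[i])
      segs <- rbind(segs, data.frame(start = bounds[i], end = bounds[i + 1],
                                     state = states[i]))
  }
  labels <- labelTrack(segs$start, segs$end, segs$state)
  list(lfp = lfp, emg = emg, labels = labels, burstOnset = burstOnset)
}
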