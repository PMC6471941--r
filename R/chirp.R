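#' Chirp waveform specification
#'
#' Describes a windowed frequency-sweep pulse: start/end frequency, duration,
#' sample rate, amplitude window and sweep law. Narrowband ultrasonic
#' transducers (e.g. 40 kHz piezo elements with ~2 kHz of usable bandwidth)
#' are driven with such pulses so that matched filtering compresses the long
#' pulse into a narrow correlation peak.
#'
#' @param f_start,f_end Sweep start and end frequency in Hz. Both must lie in
#'   (0, sample_rate/2) and differ (bandwidth B = |f_end - f_start| > 0).
#' @param duration Pulse duration T in seconds.
#' @param sample_rate Sampling rate in samples/s.
#' @param window Amplitude window: "rectangular", "hann" or "hamming".
#' @param sweep Instantaneous-frequency law: "linear" (f = fs + (fe-fs) t/T),
#'   "logarithmic" (f = fs (fe/fs)^(t/T)) or "quadratic"
#'   (f = fs + (fe-fs)(t/T)^2).
#' @param initial_phase Initial phase in radians.
#' @return An object of class `chirp_spec`.
#' @examples
#' chirp_spec(39e3, 41e3, 7e-3, 125e3)
#' @export
chirp_spec <- function(f_start, f_end, duration, sample_rate,
                       window = c("rectangular", "hann", "hamming"),
                       sweep = c("linear", "logarithmic", "quadratic"),
                       initial_phase = 0) {
  window <- match.arg(window)
  sweep <- match.arg(sweep)
  stopifnot(is.numeric(f_start), is.numeric(f_end), is.numeric(duration),
            is.numeric(sample_rate), length(duration) == 1L)
  if (duration <= 0) stop("duration must be > 0")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  nyq <- sample_rate / 2
  for (f in c(f_start = f_start, f_end = f_end)) {
    if (f <= 0 || f >= nyq) {
      stop(sprintf("frequencies must lie in (0, Nyquist = %g Hz); got %g Hz",
                   nyq, f))
    }
  }
  if (f_start == f_end) stop("bandwidth |f_end - f_start| must be > 0")
  structure(
    list(f_start = f_start, f_end = f_end, duration = duration,
         sample_rate = sample_rate, window = window, sweep = sweep,
         initial_phase = initial_phase),
    class = "chirp_spec"
  )
}

#' @export
print.chirp_spec <- function(x, ...) {
  cat(sprintf("<chirp_spec> %s %s sweep %g -> %g kHz, T = %g ms @ %g kS/s (%s window)\n",
              if (x$f_end >= x$f_start) "up" else "down", x$sweep,
              x$f_start / 1e3, x$f_end / 1e3, x$duration * 1e3,
              x$sample_rate / 1e3, x$window))
  invisible(x)
}

#' Bandwidth, centre frequency and chirp rate of a spec
#' @param spec A `chirp_spec`.
#' @return Bandwidth B = |f_end - f_start| in Hz.
#' @export
chirp_bandwidth <- function(spec) abs(spec$f_end - spec$f_start)

#' @rdname chirp_bandwidth
#' @return `chirp_centre()`: centre frequency (f_start + f_end)/2 in Hz.
#' @export
chirp_centre <- function(spec) (spec$f_start + spec$f_end) / 2

#' Sampled waveform container
#'
#' A real sampled signal with its sample rate and the time of its first
#' sample. Used for transmitted chirps and simulated received signals.
#'
#' @param samples Numeric vector of amplitudes; all finite, length >= 1.
#' @param sample_rate Samples per second.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate, t0 = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 1L,
            is.numeric(sample_rate), sample_rate > 0)
  if (!all(is.finite(samples))) stop("all samples must be finite")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 t0 = t0),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g kS/s (%.3f ms), t0 = %g s\n",
              length(x$samples), x$sample_rate / 1e3,
              1e3 * length(x$samples) / x$sample_rate, x$t0))
  invisible(x)
}

#' Sample times of a waveform
#' @param wf A `waveform`.
#' @return Numeric vector of sample times in seconds.
#' @export
waveform_times <- function(wf) {
  wf$t0 + (seq_along(wf$samples) - 1L) / wf$sample_rate
}

# Phase law (radians, without initial phase) for a sweep at times t in [0, T].
chirp_phase <- function(spec, t) {
  fs <- spec$f_start; fe <- spec$f_end; T <- spec$duration
  switch(spec$sweep,
    linear = 2 * pi * (fs * t + (fe - fs) * t^2 / (2 * T)),
    logarithmic = {
      r <- fe / fs
      2 * pi * fs * T / log(r) * (r^(t / T) - 1)
    },
    quadratic = 2 * pi * (fs * t + (fe - fs) * t^3 / (3 * T^2))
  )
}

chirp_window <- function(kind, n) {
  switch(kind,
    rectangular = rep(1, n),
    hann = as.numeric(signal::hanning(n)),
    hamming = as.numeric(signal::hamming(n))
  )
}

#' Generate a windowed chirp waveform
#'
#' Produces the real (cosine) chirp `W(t) cos(phi(t) + phi0)` sampled at the
#' spec's rate, with the instantaneous frequency following the spec's sweep
#' law from `f_start` to `f_end` over the pulse duration.
#'
#' @param spec A [chirp_spec()].
#' @return A [waveform()] of length `round(duration * sample_rate)`, carrying
#'   the generating spec in attribute `"spec"`.
#' @examples
#' tx <- make_chirp(chirp_spec(39e3, 41e3, 7e-3, 125e3))
#' length(tx$samples)  # 875
#' @export
make_chirp <- function(spec) {
  stopifnot(inherits(spec, "chirp_spec"))
  n <- round(spec$duration * spec$sample_rate)
  if (n < 2) stop("duration too short for the sample rate")
  t <- (seq_len(n) - 1L) / spec$sample_rate
  w <- chirp_window(spec$window, n)
  wf <- waveform(w * cos(chirp_phase(spec, t) + spec$initial_phase),
                 spec$sample_rate)
  attr(wf, "spec") <- spec
  wf
}

# Analytic signal (FFT construction): zero the negative frequencies, double
# the positive ones; returns a complex vector whose modulus is the envelope.
analytic_signal <- function(x) {
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

#' Matched-filter pulse compression
#'
#' Full cross-correlation of a received waveform against the transmitted
#' template (time-reversed conjugate convolution), with the envelope taken as
#' the magnitude of the analytic signal of the correlation. The lag axis is in
#' seconds relative to the start of the received record, so for a template
#' transmitted at time zero the envelope peak lag estimates the time of
#' flight.
#'
#' When the template carries a chirp spec (as produced by [make_chirp()]) the
#' raw correlation sum is scaled by `2 B / sample_rate`, which recovers the
#' idealized continuous-time compression peak value T*B for a unit-amplitude
#' rectangular chirp; otherwise the scale is `1 / sample_rate`. All detectors
#' in this package are amplitude-scale invariant, so the choice only affects
#' reported envelope units.
#'
#' @param received,template [waveform()] objects at the same sample rate.
#' @return A `correlation_trace`: list with `lags` (seconds), `values`
#'   (correlation) and `envelope` (non-negative analytic magnitude).
#' @export
matched_filter <- function(received, template) {
  stopifnot(inherits(received, "waveform"), inherits(template, "waveform"))
  if (received$sample_rate != template$sample_rate) {
    stop("received and template sample rates differ")
  }
  fr <- received$sample_rate
  r <- received$samples
  s <- template$samples
  nr <- length(r); ns <- length(s)
  nfull <- nr + ns - 1L
  nfft <- stats::nextn(nfull, c(2, 3, 5))
  C <- stats::fft(stats::fft(c(r, numeric(nfft - nr))) *
                  Conj(stats::fft(c(s, numeric(nfft - ns)))),
                  inverse = TRUE) / nfft
  # lags 0..nr-1 live at the front, lags -(ns-1)..-1 wrap to the tail
  vals <- Re(c(C[(nfft - ns + 2L):nfft], C[1:nr]))
  spec <- attr(template, "spec")
  scale <- if (!is.null(spec)) 2 * chirp_bandwidth(spec) / fr else 1 / fr
  vals <- vals * scale
  lags <- received$t0 + (-(ns - 1L):(nr - 1L)) / fr
  structure(list(lags = lags, values = vals,
                 envelope = Mod(analytic_signal(vals)),
                 sample_rate = fr),
            class = "correlation_trace")
}

#' @export
print.correlation_trace <- function(x, ...) {
  i <- which.max(x$envelope)
  cat(sprintf("<correlation_trace> %d lags [%.3f, %.3f] ms; envelope peak %.4g at %.4f ms\n",
              length(x$lags), 1e3 * x$lags[1], 1e3 * x$lags[length(x$lags)],
              x$envelope[i], 1e3 * x$lags[i]))
  invisible(x)
}

#' Ideal chirp range resolution
#'
#' Minimum path-length separation at which two echoes of the same chirp give
#' distinguishable compressed peaks: v / B for a rectangular-windowed chirp.
#'
#' @param speed_of_sound Speed of sound in m/s.
#' @param bandwidth Chirp bandwidth in Hz.
#' @return Range resolution in metres.
#' @examples
#' range_resolution(345.3, 2000)  # ~0.1727 m, i.e. 172 mm
#' @export
range_resolution <- function(speed_of_sound, bandwidth) {
  stopifnot(speed_of_sound > 0, bandwidth > 0)
  speed_of_sound / bandwidth
}
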