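#' Time-of-arrival detector configuration
#'
#' Parameters shared by the envelope-based detectors: the fractional-peak
#' denominator m (threshold P0/m), the noise margin a candidate peak (and the
#' fractional threshold) must clear, and how the noise level is estimated.
#'
#' @param m Fraction denominator (>= 1): the fractional-peak detector times
#'   the upward crossing of 1/m of the earliest peak's height. m = 1
#'   degenerates to the earliest-peak time; m = 2 is half-peak detection.
#' @param noise_floor_factor Multiple of the estimated noise level that a
#'   peak (and the P0/m threshold) must exceed (> 1).
#' @param noise_window Leading portion of the correlation trace, in seconds,
#'   used to estimate the noise level (RMS of the envelope there).
#' @param min_rel_height Minimum height of a candidate peak relative to the
#'   global envelope maximum. Rejects pulse-compression sidelobes (first
#'   sidelobe of a rectangular-window chirp is ~0.22 of the main peak) that
#'   would otherwise masquerade as an earlier arrival.
#' @return An object of class `toa_config`.
#' @export
toa_config <- function(m = 2, noise_floor_factor = 4, noise_window = 3e-3,
                       min_rel_height = 0.5) {
  if (m < 1) stop("m must be >= 1")
  if (noise_floor_factor <= 1) stop("noise_floor_factor must be > 1")
  structure(list(m = m, noise_floor_factor = noise_floor_factor,
                 noise_window = noise_window,
                 min_rel_height = min_rel_height),
            class = "toa_config")
}

new_toa_estimate <- function(toa, method, peak_value, peak_time, threshold,
                             m = NA_real_, m_eff = NA_real_,
                             detected = TRUE) {
  structure(list(toa = toa, method = method, peak_value = peak_value,
                 peak_time = peak_time, threshold = threshold, m = m,
                 m_eff = m_eff, detected = detected),
            class = "toa_estimate")
}

#' @export
print.toa_estimate <- function(x, ...) {
  if (!x$detected) {
    cat(sprintf("<toa_estimate> no detection (%s)\n", x$method))
  } else {
    cat(sprintf("<toa_estimate> %s: toa %.5f ms (peak %.4g at %.5f ms, threshold %.4g)\n",
                x$method, 1e3 * x$toa, x$peak_value, 1e3 * x$peak_time,
                x$threshold))
  }
  invisible(x)
}

#' Did a detector produce a time of arrival?
#' @param est A `toa_estimate`.
#' @return Logical.
#' @export
is_detected <- function(est) isTRUE(est$detected)

# RMS of the envelope over the leading noise window.
trace_noise_level <- function(trace, noise_window) {
  idx <- which(trace$lags <= trace$lags[1] + noise_window)
  if (length(idx) < 2L) return(0)
  sqrt(mean(trace$envelope[idx]^2))
}

# Indices of strict-left local maxima (earliest index of any plateau).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  which(y[i] > y[i - 1L] & y[i] >= y[i + 1L]) + 1L
}

#' Classical peak time-of-arrival detection
#'
#' The lag of the global maximum of the correlation, the traditional
#' correlation receiver's estimate. By default the detector works on the
#' absolute value of the raw correlation waveform — the classical receiver
#' picks the tallest carrier peak at sample resolution. With
#' `on = "envelope"` it works on the analytic-magnitude envelope instead and
#' refines the peak position to sub-sample precision by 3-point parabolic
#' interpolation (meaningless on the oscillating raw correlation). Ties
#' break to the earliest lag.
#'
#' @param trace A `correlation_trace` from [matched_filter()].
#' @param on `"correlation"` (absolute raw correlation, the classical
#'   receiver) or `"envelope"`.
#' @return A `toa_estimate` with `method = "peak"`.
#' @export
detect_peak <- function(trace, on = c("correlation", "envelope")) {
  on <- match.arg(on)
  sig <- if (on == "correlation") abs(trace$values) else trace$envelope
  if (length(sig) == 0L || all(sig == 0)) {
    stop("all-zero correlation: nothing to detect")
  }
  i <- which.max(sig)
  dt <- 1 / trace$sample_rate
  toa <- trace$lags[i] +
    if (on == "envelope") parabolic_offset(sig, i) * dt else 0
  new_toa_estimate(toa, "peak", sig[i], toa, sig[i])
}

# Shared candidate-peak search; returns index of the earliest qualifying
# local maximum, or NA. Level is the estimated noise level.
earliest_candidate <- function(trace, cfg, level) {
  env <- trace$envelope
  floor_abs <- max(cfg$noise_floor_factor * level,
                   cfg$min_rel_height * max(env))
  cand <- local_maxima(env)
  cand <- cand[env[cand] > floor_abs]
  if (length(cand) == 0L) NA_integer_ else cand[1L]
}

#' Earliest-peak time-of-arrival detection
#'
#' The first local envelope maximum that clears the noise floor (and the
#' relative-height sidelobe gate), which under resolvable multipath may be an
#' earlier, lower peak than the global one.
#'
#' @param trace A `correlation_trace`.
#' @param cfg A [toa_config()].
#' @return A `toa_estimate` with `method = "earliest_peak"`; when no peak
#'   clears the floor, an estimate with `detected = FALSE` and `toa = NA`.
#' @export
detect_earliest_peak <- function(trace, cfg = toa_config()) {
  env <- trace$envelope
  level <- trace_noise_level(trace, cfg$noise_window)
  i <- earliest_candidate(trace, cfg, level)
  if (is.na(i)) {
    return(new_toa_estimate(NA_real_, "earliest_peak", NA_real_, NA_real_,
                            NA_real_, detected = FALSE))
  }
  dt <- 1 / trace$sample_rate
  toa <- trace$lags[i] + parabolic_offset(env, i) * dt
  new_toa_estimate(toa, "earliest_peak", env[i], toa, env[i])
}

# Fractional crossing for one m given the earliest-peak index and noise
# level; returns list(toa, threshold, m_eff, detected).
fractional_crossing <- function(trace, ip, peak_toa, level, m, nff) {
  env <- trace$envelope
  p0 <- env[ip]
  floor_abs <- nff * level
  m_max <- if (floor_abs > 0) p0 / floor_abs else Inf
  m_eff <- min(m, m_max)
  if (m_eff < 1) {
    return(list(toa = NA_real_, threshold = NA_real_, m_eff = m_eff,
                detected = FALSE))
  }
  threshold <- p0 / m_eff
  if (m_eff == 1) {
    return(list(toa = peak_toa, threshold = threshold, m_eff = 1,
                detected = TRUE))
  }
  below <- which(env[seq_len(ip - 1L)] < threshold)
  dt <- 1 / trace$sample_rate
  if (length(below) == 0L) {
    # envelope never dips under the threshold left of the peak
    return(list(toa = trace$lags[1L], threshold = threshold, m_eff = m_eff,
                detected = TRUE))
  }
  j <- below[length(below)]
  frac <- (threshold - env[j]) / (env[j + 1L] - env[j])
  list(toa = trace$lags[j] + frac * dt, threshold = threshold, m_eff = m_eff,
       detected = TRUE)
}

#' Earliest 1/m fractional-peak time-of-arrival detection
#'
#' Locates the earliest qualifying envelope peak (height P0 at time Tp), then
#' takes the time at which the envelope last rises through P0/m to the left
#' of that peak, with sub-sample linear interpolation of the crossing. The
#' crossing on the rising edge is less perturbed by close multipath than the
#' peak itself, because echoes always arrive later than the direct path and
#' corrupt mostly the falling side of the merged lobe.
#'
#' The threshold P0/m must stay above `noise_floor_factor` times the noise
#' level; when it does not, the detector falls back to the largest usable
#' m' < m (recorded in `m_eff`), and reports no detection if even m' = 1
#' cannot clear the margin.
#'
#' @param trace A `correlation_trace`.
#' @param cfg A [toa_config()]; `cfg$m` is the fraction denominator.
#' @return A `toa_estimate` with `method = "fractional_peak"`, `peak_value` =
#'   P0, `peak_time` = Tp, `threshold` = P0/m_eff.
#' @export
detect_fractional_peak <- function(trace, cfg = toa_config()) {
  env <- trace$envelope
  level <- trace_noise_level(trace, cfg$noise_window)
  ip <- earliest_candidate(trace, cfg, level)
  if (is.na(ip)) {
    return(new_toa_estimate(NA_real_, "fractional_peak", NA_real_, NA_real_,
                            NA_real_, m = cfg$m, detected = FALSE))
  }
  dt <- 1 / trace$sample_rate
  peak_toa <- trace$lags[ip] + parabolic_offset(env, ip) * dt
  cr <- fractional_crossing(trace, ip, peak_toa, level, cfg$m,
                            cfg$noise_floor_factor)
  new_toa_estimate(cr$toa, "fractional_peak", env[ip], peak_toa,
                   cr$threshold, m = cfg$m, m_eff = cr$m_eff,
                   detected = cr$detected)
}
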