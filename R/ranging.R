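#' Up/down-chirp ranging cycle timing
#'
#' One ranging cycle interrogates the channel twice: an up-chirp in the first
#' slot and a down-chirp in the second, with a guard interval after each pulse
#' so echoes die out before the next transmission. The defaults (7 ms pulse +
#' 13 ms guard per 20 ms slot, 40 ms cycle) give a 25 Hz range update rate.
#'
#' @param cycle_period Full cycle duration in seconds.
#' @param slot Per-chirp slot duration in seconds.
#' @param chirp_duration Pulse duration in seconds.
#' @param guard Quiet interval after each pulse in seconds.
#' @return An object of class `cycle_timing`.
#' @export
cycle_timing <- function(cycle_period = 0.040, slot = 0.020,
                         chirp_duration = 0.007, guard = 0.013) {
  if (abs(slot - (chirp_duration + guard)) > 1e-12) {
    stop("slot must equal chirp_duration + guard")
  }
  if (abs(cycle_period - 2 * slot) > 1e-12) {
    stop("cycle_period must equal 2 * slot")
  }
  structure(list(cycle_period = cycle_period, slot = slot,
                 chirp_duration = chirp_duration, guard = guard),
            class = "cycle_timing")
}

#' Range update rate of a cycle timing
#' @param timing A [cycle_timing()].
#' @return Updates per second (Hz).
#' @export
update_rate <- function(timing) 1 / timing$cycle_period

#' Convert a time of arrival to a range
#'
#' @param toa Time of arrival in seconds.
#' @param v Speed of sound in m/s.
#' @param offset Calibration offset in metres subtracted from the raw range
#'   (e.g. the constant early bias of fractional-peak detection, measured by
#'   [calibrate_offset()]).
#' @return Range in metres: `toa * v - offset`.
#' @export
toa_to_range <- function(toa, v = 345.3, offset = 0) {
  if (any(toa < 0, na.rm = TRUE)) stop("toa must be >= 0")
  toa * v - offset
}

#' Doppler compensation by up/down-chirp averaging
#'
#' Range-Doppler coupling biases a linear up-chirp's range estimate by
#' +Rdot * f0 * T / B and the down-chirp's by the same amount with opposite
#' sign, so their mean recovers the true range:
#' R0 = (R1 + R2) / 2. Inverting the bias terms also yields a Doppler
#' velocity estimate Rdot = (R1 - R2) * B / (2 * f0 * T).
#'
#' @param r_up Range from the up-chirp (R1), metres.
#' @param r_down Range from the down-chirp (R2), metres.
#' @param bandwidth Chirp bandwidth B in Hz.
#' @param centre Chirp centre frequency f0 in Hz.
#' @param duration Chirp duration T in seconds.
#' @return An object of class `ranging_cycle` with fields `r_up`, `r_down`,
#'   `r_compensated` and `doppler_estimate`.
#' @examples
#' doppler_compensate(1.14, 0.86)$r_compensated  # 1
#' @export
doppler_compensate <- function(r_up, r_down, bandwidth = 2000,
                               centre = 40e3, duration = 7e-3) {
  structure(list(r_up = r_up, r_down = r_down,
                 r_compensated = (r_up + r_down) / 2,
                 doppler_estimate = (r_up - r_down) * bandwidth /
                   (2 * centre * duration),
                 detected = !is.na(r_up) && !is.na(r_down)),
            class = "ranging_cycle")
}

#' @export
print.ranging_cycle <- function(x, ...) {
  if (!x$detected) {
    cat("<ranging_cycle> no detection\n")
  } else {
    cat(sprintf("<ranging_cycle> R1 %.4f m, R2 %.4f m -> R0 %.4f m (Rdot %.3f m/s)\n",
                x$r_up, x$r_down, x$r_compensated, x$doppler_estimate))
  }
  invisible(x)
}

#' Default up/down chirp pair
#'
#' @param f_low,f_high Sweep band edges in Hz.
#' @param duration Pulse duration in seconds.
#' @param sample_rate Samples per second.
#' @param window,sweep Passed to [chirp_spec()].
#' @return List with elements `up` and `down` ([chirp_spec()]s).
#' @export
chirp_pair <- function(f_low = 39e3, f_high = 41e3, duration = 7e-3,
                       sample_rate = 125e3, window = "rectangular",
                       sweep = "linear") {
  list(up = chirp_spec(f_low, f_high, duration, sample_rate, window, sweep),
       down = chirp_spec(f_high, f_low, duration, sample_rate, window, sweep))
}

# Dispatch a detector by name.
detect_toa <- function(trace, method, cfg) {
  switch(method,
    peak = detect_peak(trace),
    earliest = detect_earliest_peak(trace, cfg),
    fractional = detect_fractional_peak(trace, cfg),
    stop("unknown detection method: ", method)
  )
}

#' Run one up/down-chirp ranging cycle through a simulated channel
#'
#' Propagates the up- and then the down-chirp through the channel (with
#' independent noise realizations), estimates both times of arrival with the
#' configured detector, converts them to ranges and applies the up/down
#' Doppler compensation.
#'
#' @param channel A [channel_spec()].
#' @param chirps A [chirp_pair()].
#' @param toa_cfg A [toa_config()].
#' @param method Detector: "peak", "earliest" or "fractional".
#' @param timing A [cycle_timing()] (retained for record keeping; the two
#'   slots are simulated back to back).
#' @param seed Optional integer; the two noise realizations derive from it.
#' @param offset Calibration offset in metres passed to [toa_to_range()].
#' @return A `ranging_cycle`; `detected = FALSE` if either slot's detector
#'   reported no detection.
#' @export
run_cycle <- function(channel, chirps = chirp_pair(),
                      toa_cfg = toa_config(), method = "fractional",
                      timing = cycle_timing(), seed = NULL, offset = 0) {
  v <- channel$speed_of_sound
  b <- chirp_bandwidth(chirps$up)
  f0 <- chirp_centre(chirps$up)
  ranges <- vapply(c(up = 1L, down = 2L), function(k) {
    spec <- if (k == 1L) chirps$up else chirps$down
    s <- if (is.null(seed)) NULL else derive_seed(seed, c("up", "down")[k])
    rx <- propagate(make_chirp(spec), channel, noise_seed = s)
    est <- detect_toa(matched_filter(rx, make_chirp(spec)), method, toa_cfg)
    if (is_detected(est)) toa_to_range(est$toa, v, offset) else NA_real_
  }, numeric(1))
  doppler_compensate(ranges[["up"]], ranges[["down"]], b, f0,
                     chirps$up$duration)
}

#' Measure a detector's constant range offset on a reference channel
#'
#' Fractional-peak detection fires on the rising edge of the compressed
#' pulse, a constant interval before the peak (the envelope's left width at
#' height P0/m), so raw ranges carry a constant early bias. This measures the
#' bias once on a noiseless single-path channel so absolute ranges can be
#' reported; differential ranges cancel it regardless.
#'
#' @param chirps A [chirp_pair()].
#' @param toa_cfg A [toa_config()].
#' @param method Detector name as in [run_cycle()].
#' @param reference_distance Known distance of the calibration channel, m.
#' @param speed_of_sound Speed of sound in m/s.
#' @return Offset in metres (estimated minus true range) to pass as `offset`.
#' @export
calibrate_offset <- function(chirps = chirp_pair(), toa_cfg = toa_config(),
                             method = "fractional", reference_distance = 1,
                             speed_of_sound = 345.3) {
  ch <- channel_spec(reference_distance, speed_of_sound = speed_of_sound,
                     attenuation_const = 0, snr_db = Inf)
  cyc <- run_cycle(ch, chirps, toa_cfg, method)
  cyc$r_compensated - reference_distance
}
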