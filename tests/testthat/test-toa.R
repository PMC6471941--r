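test_that("classical peak detection finds the direct-path delay", {
  tr <- matched_filter(propagate(std_chirp(),
                                 channel_spec(1, attenuation_const = 0,
                                              snr_db = Inf)),
                       std_chirp())
  one_sample <- 345.3 / 125e3
  for (on in c("correlation", "envelope")) {
    est <- detect_peak(tr, on)
    expect_equal(est$toa * 345.3, 1, tolerance = one_sample)
    expect_lte(est$threshold, est$peak_value)
  }
  expect_error(detect_peak(structure(list(values = numeric(0),
                                          envelope = numeric(0)),
                                     class = "correlation_trace")),
               "nothing to detect")
})

test_that("equal maxima break ties to the earliest lag", {
  tr <- structure(list(lags = (0:9) / 1e3,
                       values = c(0, 1, 5, 1, 0, 1, 5, 1, 0, 0),
                       envelope = c(0, 1, 5, 1, 0, 1, 5, 1, 0, 0),
                       sample_rate = 1e3),
                  class = "correlation_trace")
  expect_equal(detect_peak(tr, "correlation")$toa, 2e-3)
  expect_equal(detect_peak(tr, "envelope")$toa, 2e-3)
})

test_that("a weak resolvable echo does not displace the global peak", {
  # extra 300 mm > range resolution, echo at half amplitude
  tr <- two_path_trace(1, 0.5, 0.3)
  expect_equal(detect_peak(tr)$toa * 345.3, 1, tolerance = 0.01)
})

test_that("earliest-peak detection finds a weak direct path before a
           stronger echo", {
  tr <- two_path_trace(0.55, 1.0, 0.4)
  pk <- detect_peak(tr, "envelope")
  ep <- detect_earliest_peak(tr, toa_config())
  expect_equal(pk$toa * 345.3, 1.4, tolerance = 0.01)   # global = echo
  expect_equal(ep$toa * 345.3, 1.0, tolerance = 0.015)  # earliest = LOS

  # single path: earliest peak coincides with the envelope global peak
  tr1 <- matched_filter(propagate(std_chirp(), channel_spec(1, snr_db = Inf)),
                        std_chirp())
  expect_equal(detect_earliest_peak(tr1, toa_config())$toa,
               detect_peak(tr1, "envelope")$toa)
})

test_that("a pure-noise trace yields an explicit no-detection", {
  set.seed(2)
  tr <- matched_filter(waveform(stats::rnorm(2000, sd = 0.1), 125e3),
                       std_chirp())
  est <- detect_earliest_peak(tr, toa_config())
  expect_false(is_detected(est))
  expect_true(is.na(est$toa))
  expect_false(is_detected(detect_fractional_peak(tr, toa_config(2))))
})

test_that("fractional-peak detection degenerates and interpolates correctly", {
  tr <- matched_filter(propagate(std_chirp(),
                                 channel_spec(1, attenuation_const = 0,
                                              snr_db = Inf)),
                       std_chirp())
  # m = 1: the crossing of P0 is the earliest peak itself
  est1 <- detect_fractional_peak(tr, toa_config(m = 1))
  expect_equal(est1$toa, detect_earliest_peak(tr, toa_config())$toa)

  # m = 2 on a symmetric noiseless envelope: peak_time - toa equals the
  # envelope's left half-height width, measured independently
  est2 <- detect_fractional_peak(tr, toa_config(m = 2))
  ip <- which.max(tr$envelope)
  p0 <- tr$envelope[ip]
  left <- tr$envelope[1:ip]
  j <- max(which(left < p0 / 2))
  frac <- (p0 / 2 - left[j]) / (left[j + 1] - left[j])
  half_width <- (tr$lags[ip] +
                 chirpgait:::parabolic_offset(tr$envelope, ip) / 125e3) -
                (tr$lags[j] + frac / 125e3)
  expect_equal(est2$peak_time - est2$toa, half_width, tolerance = 1e-9)
  expect_lte(est2$threshold, est2$peak_value)
  expect_lte(est2$toa, est2$peak_time)
})

test_that("the detection threshold falls back when too close to the noise
           floor", {
  set.seed(4)
  ch <- channel_spec(1, snr_db = -3)
  tr <- matched_filter(propagate(std_chirp(), ch, noise_seed = 8),
                       std_chirp())
  est <- detect_fractional_peak(tr, toa_config(m = 50))
  if (is_detected(est)) {
    expect_lt(est$m_eff, 50)
    level <- chirpgait:::trace_noise_level(tr, 3e-3)
    expect_gte(est$peak_value / est$m_eff, 4 * level - 1e-9)
  } else {
    succeed("threshold under the floor even after fallback")
  }
})

test_that("larger m crosses earlier on the rising edge (monotone in m)", {
  set.seed(3)
  ch <- channel_spec(1, list(path_component(0.08, 0.9)), snr_db = 10)
  tr <- matched_filter(propagate(std_chirp(), ch, noise_seed = 9),
                       std_chirp())
  toas <- vapply(c(1, 1.5, 2, 3, 4), function(m) {
    detect_fractional_peak(tr, toa_config(m))$toa
  }, numeric(1))
  expect_true(all(diff(toas) <= 1e-12))
})

test_that("constant detector bias cancels in differential ranging", {
  one_sample <- 345.3 / 125e3
  toa_at <- function(d, detector) {
    tr <- matched_filter(propagate(std_chirp(),
                                   channel_spec(d, snr_db = Inf)),
                         std_chirp())
    detector(tr)
  }
  detectors <- list(
    peak_env = function(tr) detect_peak(tr, "envelope")$toa,
    earliest = function(tr) detect_earliest_peak(tr, toa_config())$toa,
    frac_m15 = function(tr) detect_fractional_peak(tr, toa_config(1.5))$toa,
    frac_m2 = function(tr) detect_fractional_peak(tr, toa_config(2))$toa,
    frac_m4 = function(tr) detect_fractional_peak(tr, toa_config(4))$toa
  )
  for (det in detectors) {
    diff_m <- (toa_at(1.7, det) - toa_at(0.8, det)) * 345.3
    expect_equal(diff_m, 0.9, tolerance = one_sample / 0.9)
  }
  # the raw-correlation classical peak snaps to carrier half-cycles, so its
  # differential carries up to ~two carrier periods of quantization
  diff_raw <- (toa_at(1.7, function(tr) detect_peak(tr)$toa) -
               toa_at(0.8, function(tr) detect_peak(tr)$toa)) * 345.3
  expect_equal(diff_raw, 0.9, tolerance = 2 * 345.3 / 40e3 / 0.9)
})

test_that("fractional-peak detection beats the classical peak under close
           multipath (noiseless oracle over an extra-distance grid)", {
  # constant-offset calibration measured on a clean channel
  clean <- matched_filter(propagate(std_chirp(),
                                    channel_spec(1, snr_db = Inf)),
                          std_chirp())
  off_pk <- detect_peak(clean)$toa * 345.3 - 1
  off_fr <- detect_fractional_peak(clean, toa_config(2))$toa * 345.3 - 1
  grid <- seq(0.02, 0.17, by = 0.01)
  errs <- t(vapply(grid, function(extra) {
    ch <- channel_spec(1, list(path_component(extra, 0.9)), snr_db = Inf)
    tr <- matched_filter(propagate(std_chirp(), ch), std_chirp())
    c(pk = abs(detect_peak(tr)$toa * 345.3 - 1 - off_pk),
      fr = abs(detect_fractional_peak(tr, toa_config(2))$toa * 345.3 - 1 -
               off_fr))
  }, c(pk = 0, fr = 0)))
  i60 <- which(abs(grid - 0.06) < 1e-9)
  expect_lt(errs[i60, "fr"], errs[i60, "pk"])     # the 60 mm case
  expect_lt(mean(errs[, "fr"]), mean(errs[, "pk"]))  # and on average
})
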