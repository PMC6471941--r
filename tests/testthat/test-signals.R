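test_that("make_chirp produces the specified pulse", {
  spec <- std_chirp_spec()
  tx <- make_chirp(spec)
  expect_length(tx$samples, 875)            # 0.007 * 125000
  expect_equal(tx$samples[1], 1)            # rectangular window, phi = 0
  expect_true(all(abs(tx$samples) <= 1 + 1e-12))

  # instantaneous frequency from the phase derivative of the analytic signal
  a <- chirpgait:::analytic_signal(tx$samples)
  fi <- diff(signal::unwrap(Arg(a))) * 125e3 / (2 * pi)
  expect_lt(abs(mean(fi[5:15]) - 39e3), 50)
  expect_lt(abs(mean(fi[860:870]) - 41e3), 50)
})

test_that("frequencies at or beyond Nyquist are rejected by name", {
  expect_error(chirp_spec(39e3, 70e3, 7e-3, 125e3), "Nyquist")
  expect_error(chirp_spec(-1, 41e3, 7e-3, 125e3), "Nyquist")
  expect_error(chirp_spec(40e3, 40e3, 7e-3, 125e3), "bandwidth")
})

test_that("nonlinear sweep laws follow their frequency trajectories", {
  laws <- list(
    logarithmic = function(u) 39e3 * (41 / 39)^u,
    quadratic = function(u) 39e3 + 2e3 * u^2
  )
  for (sweep in names(laws)) {
    tx <- make_chirp(chirp_spec(39e3, 41e3, 7e-3, 125e3, sweep = sweep))
    a <- chirpgait:::analytic_signal(tx$samples)
    fi <- diff(signal::unwrap(Arg(a))) * 125e3 / (2 * pi)
    f_law <- laws[[sweep]]
    # windows away from the edges, where the analytic signal is clean
    for (win in list(10:20, 432:442, 845:860)) {
      u_mid <- mean(win) / 875
      expect_lt(abs(mean(fi[win]) - f_law(u_mid)), 100)
    }
  }
  # the quadratic law is clearly distinguishable from linear at mid-pulse
  # (the logarithmic law over this narrow fractional bandwidth is not:
  # 39 * (41/39)^0.5 ~ 39.987 kHz, only 13 Hz from the linear mid)
  txq <- make_chirp(chirp_spec(39e3, 41e3, 7e-3, 125e3, sweep = "quadratic"))
  fiq <- diff(signal::unwrap(Arg(chirpgait:::analytic_signal(txq$samples)))) *
    125e3 / (2 * pi)
  expect_lt(mean(fiq[432:442]), 39.7e3)
})

test_that("matched-filter autocorrelation has the pulse-compression shape", {
  tx <- std_chirp()
  tr <- matched_filter(tx, tx)
  ipk <- which.max(tr$envelope)
  expect_equal(tr$lags[ipk], 0)                       # peak at zero lag
  expect_equal(max(tr$envelope), 14, tolerance = 0.01) # T*B = 0.007 * 2000

  # first nulls near +-1/B = +-0.5 ms
  right <- tr$envelope[ipk:(ipk + 120)]
  null_right <- tr$lags[ipk - 1 + which.min(right)]
  left <- tr$envelope[(ipk - 120):ipk]
  null_left <- tr$lags[ipk - 121 + which.min(left)]
  expect_lt(abs(null_right - 5e-4), 1e-4)
  expect_lt(abs(null_left + 5e-4), 1e-4)

  # support: nonzero over a 2T window
  nz <- range(which(tr$envelope > 1e-6 * max(tr$envelope)))
  expect_equal(diff(tr$lags[nz]), 2 * 7e-3, tolerance = 0.01)

  # envelope upper-bounds |values| away from the edges
  n <- length(tr$values)
  core <- ceiling(0.01 * n):floor(0.99 * n)
  expect_true(all(tr$envelope[core] >= abs(tr$values[core]) - 1e-9))
})

test_that("compression peak grows linearly with duration at fixed bandwidth", {
  peak_of <- function(T) {
    tx <- make_chirp(chirp_spec(39e3, 41e3, T, 125e3))
    max(matched_filter(tx, tx)$envelope)
  }
  expect_equal(peak_of(14e-3) / peak_of(7e-3), 2, tolerance = 0.01)
})

test_that("down-chirp is the time-reversed up-chirp up to carrier phase", {
  up <- std_chirp()
  dn <- std_chirp(down = TRUE)
  rev_up <- waveform(rev(up$samples), 125e3)
  e1 <- matched_filter(dn, dn)$envelope
  e2 <- matched_filter(rev_up, rev_up)$envelope
  expect_equal(e1 / max(e1), e2 / max(e2), tolerance = 1e-3)
})

test_that("matched_filter rejects mismatched sample rates", {
  expect_error(matched_filter(waveform(1:10, 1e5), waveform(1:10, 2e5)),
               "sample rate")
})

test_that("range resolution is v over bandwidth", {
  expect_identical(floor(range_resolution(345.3, 2000) * 1e3), 172)
  expect_equal(range_resolution(343, 343), 1)
  expect_equal(range_resolution(343, 4000),
               range_resolution(343, 2000) / 2)
})

test_that("waveforms round-trip through WAV and CSV", {
  tx <- std_chirp()
  wav <- withr::local_tempfile(fileext = ".wav")
  write_wav(tx, wav)
  back <- read_wav(wav)
  expect_equal(back$sample_rate, 125e3)
  expect_equal(back$samples, tx$samples, tolerance = 1e-4)  # 16-bit depth

  csv <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(tx, csv)
  back2 <- read_waveform_csv(csv)
  expect_equal(back2$samples, tx$samples)
  expect_equal(back2$sample_rate, 125e3, tolerance = 1e-6)
})
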