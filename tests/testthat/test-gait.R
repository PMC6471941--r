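sinusoid_traj <- function(amp_mm = 250, period = 1.2, dur = 6, fs = 25,
                          z = 0) {
  t <- seq(0, dur, by = 1 / fs)
  trajectory(t, cbind(amp_mm / 1e3 * sin(2 * pi * t / period), 0,
                      if (length(z) == 1) rep(z, length(t)) else z))
}

test_that("events of a sinusoidal x trace are its analytic extrema", {
  traj <- sinusoid_traj()
  ev <- detect_events(traj)
  expect_equal(length(ev$x_min_times), 5)   # minima at 0.9 + 1.2 k <= 6
  expect_equal(diff(ev$x_min_times), rep(1.2, 4), tolerance = 0.05)
  # alternation: exactly one maximum between consecutive minima
  for (i in seq_len(length(ev$x_min_times) - 1)) {
    n_between <- sum(ev$x_max_times > ev$x_min_times[i] &
                     ev$x_max_times < ev$x_min_times[i + 1])
    expect_equal(n_between, 1)
  }
})

test_that("constant x reports insufficient cycles", {
  t <- (0:100) * 0.04
  flat <- trajectory(t, cbind(rep(0.1, 101), 0, 0))
  expect_error(detect_events(flat), "insufficient cycles")
})

test_that("event detection is robust to 5 mm noise", {
  traj <- sinusoid_traj()
  set.seed(21)
  noisy <- trajectory(traj$timestamps,
                      traj$positions +
                        matrix(stats::rnorm(3 * nrow(traj$positions),
                                            sd = 0.005), ncol = 3))
  ev0 <- detect_events(traj)
  ev1 <- detect_events(noisy)
  expect_equal(length(ev1$x_min_times), length(ev0$x_min_times))
  expect_equal(length(ev1$x_max_times), length(ev0$x_max_times))
})

test_that("parameters of a symmetric sinusoid match the closed form", {
  traj <- sinusoid_traj(z = 0)
  # add a z bump with 140 mm excursion per cycle
  z <- 0.070 * (1 - cos(2 * pi * traj$timestamps / 1.2))
  traj <- trajectory(traj$timestamps,
                     cbind(traj$positions[, 1:2], z))
  par <- compute_parameters(traj, detect_events(traj))
  expect_equal(mean(par$stride_time), 1.2, tolerance = 0.05)
  expect_equal(mean(par$half_excursion), 500, tolerance = 0.01)
  expect_equal(mean(par$stride_length), 1000, tolerance = 0.01)
  expect_equal(mean(par$swing_time), 0.6, tolerance = 0.07)
  expect_equal(mean(par$stance_time), 0.6, tolerance = 0.07)
  expect_equal(mean(par$max_foot_clearance), 140, tolerance = 0.01)
  # stride time = swing + stance exactly, by event arithmetic
  expect_equal(par$stride_time, par$swing_time + par$stance_time)
})

test_that("parameters are invariant to time shifts and scale with x", {
  traj <- sinusoid_traj()
  par0 <- compute_parameters(traj, detect_events(traj))

  shifted <- trajectory(traj$timestamps + 17.3, traj$positions)
  par1 <- compute_parameters(shifted, detect_events(shifted))
  expect_equal(par1[c("stride_time", "swing_time", "stance_time",
                      "stride_length")],
               par0[c("stride_time", "swing_time", "stance_time",
                      "stride_length")])

  scaled <- trajectory(traj$timestamps,
                       cbind(2 * traj$positions[, 1],
                             traj$positions[, 2:3]))
  par2 <- compute_parameters(scaled, detect_events(scaled))
  expect_equal(par2$stride_length, 2 * par0$stride_length)
  expect_equal(par2$stride_time, par0$stride_time)
})

test_that("gait summary reports mean and sd per parameter", {
  traj <- sinusoid_traj()
  par <- compute_parameters(traj, detect_events(traj))
  s <- gait_summary(par)
  expect_setequal(s$parameter,
                  c("stride_time", "half_excursion", "stride_length",
                    "swing_time", "stance_time", "max_foot_clearance"))
  expect_equal(s$mean[s$parameter == "stride_length"],
               mean(par$stride_length))
})
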