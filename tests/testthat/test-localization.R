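test_that("the measurement function returns anchor distances", {
  anch <- anchor_array()
  at_anchor1 <- c(anch$positions[1, ], 0, 0, 0)
  expect_equal(measurement_fn(at_anchor1, anch)[1], 0)

  origin_anchor <- anchor_array(rbind(c(0, 0, 0), c(1, 0, 0),
                                      c(0, 1, 0), c(0, 0, 1)))
  expect_equal(measurement_fn(c(1, 0, 0), origin_anchor)[1], 1)

  # permuting anchors permutes outputs identically
  perm <- c(3, 1, 4, 2)
  a2 <- anchor_array(anch$positions[perm, ])
  s <- c(0.05, 0.2, -0.03)
  expect_equal(measurement_fn(s, a2), measurement_fn(s, anch)[perm])
})

test_that("anchor arrays with coincident anchors are rejected", {
  p <- default_anchors()
  p[2, ] <- p[1, ]
  expect_error(anchor_array(p), "distinct")
})

test_that("tracking exact ranges recovers static and moving nodes", {
  anch <- anchor_array()
  # a static node is modelled with a near-zero acceleration scale
  cfg <- state_space_config(process_noise_scale = 0.1)
  truth_p <- c(0.03, 0.05, -0.02)
  d <- matrix(rep(measurement_fn(truth_p, anch), each = 100), 100, 4)
  tr <- track(d, anch, cfg)
  final_err <- sqrt(sum((tr$positions[100, ] - truth_p)^2))
  expect_lt(final_err * 1e3, 1)

  # constant velocity 0.5 m/s along x
  t <- (0:99) * cfg$dt
  pos <- cbind(-1 + 0.5 * t, 0, 0)
  d2 <- t(apply(cbind(pos, 0, 0, 0), 1, measurement_fn, anchors = anch))
  tr2 <- track(d2, anch, state_space_config(process_noise_scale = 1))
  rmse <- sqrt(mean((tr2$positions - pos)^2))
  expect_lt(rmse * 1e3, 2)
})

test_that("smoothing beats raw trilateration under range noise", {
  anch <- anchor_array()
  cfg <- state_space_config(process_noise_scale = 0.1)
  truth_p <- c(0.05, 0.1, 0.02)
  set.seed(11)
  d_true <- measurement_fn(truth_p, anch)
  d <- matrix(rep(d_true, each = 80), 80, 4) +
    matrix(stats::rnorm(320, sd = 0.005), 80, 4)
  tr <- track(d, anch, cfg)
  rmse_smooth <- sqrt(mean((t(t(tr$positions) - truth_p))^2))
  raw <- t(apply(d, 1, trilaterate, anchors = anch))
  rmse_raw <- sqrt(mean((t(t(raw) - truth_p))^2))
  expect_lt(rmse_smooth, rmse_raw)

  # and the smoother does not do worse than the filter (across seeds)
  worse <- 0
  for (s in 1:20) {
    set.seed(s)
    d_s <- matrix(rep(d_true, each = 40), 40, 4) +
      matrix(stats::rnorm(160, sd = 0.005), 40, 4)
    e_sm <- sqrt(mean((t(t(track(d_s, anch, cfg)$positions) - truth_p))^2))
    e_fi <- sqrt(mean((t(t(track(d_s, anch, cfg,
                                 smooth = FALSE)$positions) - truth_p))^2))
    if (e_sm > e_fi) worse <- worse + 1
  }
  expect_lt(worse, 3)
})

test_that("missing cycles are bridged by prediction", {
  anch <- anchor_array()
  truth_p <- c(0, 0.05, 0)
  d <- matrix(rep(measurement_fn(truth_p, anch), each = 60), 60, 4)
  d[25:30, ] <- NA
  tr <- track(d, anch, state_space_config(process_noise_scale = 0.1))
  expect_equal(nrow(tr$positions), 60)
  expect_lt(sqrt(sum((tr$positions[60, ] - truth_p)^2)) * 1e3, 1)
})

test_that("translating anchors and ranges translates the estimate", {
  anch <- anchor_array()
  truth_p <- c(0.02, 0.08, 0.01)
  d <- matrix(rep(measurement_fn(truth_p, anch), each = 50), 50, 4)
  shift <- c(0.5, -0.2, 0.3)
  anch2 <- anchor_array(sweep(anch$positions, 2, -shift))
  tr1 <- track(d, anch, state_space_config(process_noise_scale = 0.1))
  tr2 <- track(d, anch2, state_space_config(process_noise_scale = 0.1))
  expect_equal(sweep(tr2$positions, 2, shift), tr1$positions,
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("the low-pass filter has the expected frequency response", {
  t <- (0:499) * 0.04                      # 25 Hz sampling
  dc <- trajectory(t, cbind(rep(0.3, 500), 0, 0))
  expect_equal(lowpass(dc, 10)$positions[, 1], rep(0.3, 500),
               tolerance = 1e-6)

  probe <- function(f_hz) {
    x <- sin(2 * pi * f_hz * t)
    filt <- lowpass(trajectory(t, cbind(x, 0, 0)), 10)
    core <- 100:400
    sqrt(mean(filt$positions[core, 1]^2)) / sqrt(mean(x[core]^2))
  }
  expect_gt(probe(1), 0.99)
  expect_lt(probe(12), 10^(-3 / 20))       # > 3 dB down
  expect_error(lowpass(dc, 13), "Nyquist")
})
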