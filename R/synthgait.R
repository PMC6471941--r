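#' Synthetic gait specification
#'
#' Parameters of the belt-frame kinematic foot model used to generate
#' ground-truth trajectories: one cycle runs toe-off -> swing -> heel-strike
#' -> stance -> toe-off. During swing the foot moves forward following a
#' raised-cosine profile and lifts off the belt with a sin^2 clearance bump;
#' during stance it drifts backward linearly with the belt at constant speed.
#' The defaults emulate slow treadmill walking (a 1 m stride every 1.2 s is
#' about 3 kph).
#'
#' @param stride_length Stride length in mm (the foot's belt-frame x
#'   excursion is half of it).
#' @param stride_time Stride (cycle) duration in seconds.
#' @param duty_factor Stance share of the cycle, in (0, 1).
#' @param foot_clearance Peak swing-phase foot lift in mm.
#' @param n_strides Number of strides to generate.
#' @param lateral_sway Amplitude of the sinusoidal mediolateral sway in mm.
#' @param range_noise_std Gaussian noise added to geometric-fidelity ranges,
#'   mm.
#' @param sample_rate Trajectory sampling rate in Hz (the ranging update
#'   rate).
#' @param seed Integer seed for range noise.
#' @return An object of class `synth_gait_spec`.
#' @export
synth_gait_spec <- function(stride_length = 1000, stride_time = 1.2,
                            duty_factor = 0.6, foot_clearance = 140,
                            n_strides = 10, lateral_sway = 10,
                            range_noise_std = 5, sample_rate = 25,
                            seed = 1) {
  stopifnot(stride_length > 0, stride_time > 0, foot_clearance >= 0,
            n_strides >= 1, range_noise_std >= 0)
  if (duty_factor <= 0 || duty_factor >= 1) {
    stop("duty_factor must lie in (0, 1)")
  }
  if (stride_time * sample_rate < 4) {
    stop("stride_time must span at least 4 samples")
  }
  structure(list(stride_length = stride_length, stride_time = stride_time,
                 duty_factor = duty_factor, foot_clearance = foot_clearance,
                 n_strides = n_strides, lateral_sway = lateral_sway,
                 range_noise_std = range_noise_std,
                 sample_rate = sample_rate, seed = seed),
            class = "synth_gait_spec")
}

#' Generate a ground-truth foot trajectory
#'
#' @param spec A [synth_gait_spec()].
#' @return List with `trajectory` (a [trajectory()], metres) and `truth`
#'   (data.frame of the exact per-cycle parameters implied by construction:
#'   stride_time s, stride_length mm, swing_time s, stance_time s,
#'   max_foot_clearance mm).
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synth_gait_spec"))
  T <- spec$stride_time
  d <- spec$duty_factor
  S <- spec$stride_length / 2 / 1e3        # half-stride x excursion, m
  clr <- spec$foot_clearance / 1e3
  t <- seq(0, spec$n_strides * T, by = 1 / spec$sample_rate)
  u <- (t %% T) / T                         # cycle phase, 0 = toe-off
  swing <- u < (1 - d)
  us <- u / (1 - d)                         # swing fraction
  x <- numeric(length(t))
  # swing: raised-cosine advance from -S/2 to +S/2
  x[swing] <- -S / 2 + S * (1 - cos(pi * us[swing])) / 2
  # stance: linear belt drift from +S/2 back to -S/2
  ust <- (u[!swing] - (1 - d)) / d
  x[!swing] <- S / 2 - S * ust
  z <- numeric(length(t))
  z[swing] <- clr * sin(pi * us[swing])^2
  y <- spec$lateral_sway / 1e3 * sin(2 * pi * t / T)
  truth <- data.frame(
    stride_time = T,
    stride_length = 2 * S * 1e3,
    swing_time = (1 - d) * T,
    stance_time = d * T,
    max_foot_clearance = clr * 1e3
  )
  list(trajectory = trajectory(t, cbind(x, y, z)), truth = truth)
}

#' Peak swing-phase acceleration implied by a gait spec
#'
#' The raised-cosine swing profile reaches its peak acceleration
#' S/2 * (pi / T_swing)^2 (S = half-stride excursion). This is the natural
#' setting for the tracker's process-noise scale: the constant-velocity
#' filter's white-noise acceleration should bracket the acceleration the
#' target actually exhibits.
#'
#' @param spec A [synth_gait_spec()].
#' @return Peak swing acceleration in m/s^2.
#' @export
swing_peak_acceleration <- function(spec) {
  s_half <- spec$stride_length / 2 / 1e3 / 2
  t_swing <- (1 - spec$duty_factor) * spec$stride_time
  s_half * (pi / t_swing)^2
}

#' Convert a trajectory to per-cycle anchor ranges
#'
#' Geometric fidelity computes exact anchor distances plus Gaussian noise
#' (and optional per-anchor constant offsets). Acoustic fidelity synthesizes,
#' for every cycle and anchor, a full up/down-chirp interrogation through an
#' acoustic channel whose line-of-sight distance and Doppler velocity follow
#' the trajectory, then detects arrivals and applies the up/down
#' compensation, so the full ranging chain (waveform, channel, detector) is
#' exercised.
#'
#' @param traj A [trajectory()].
#' @param anchors An [anchor_array()].
#' @param spec A [synth_gait_spec()] (noise level, seed).
#' @param fidelity `"geometric"` or `"acoustic"`.
#' @param anchor_offsets Optional length-4 vector of constant per-anchor
#'   range offsets in metres (geometric fidelity only).
#' @param channel_args Named list of [channel_spec()] overrides for acoustic
#'   fidelity (e.g. `snr_db`, `paths` as a list of per-anchor path lists).
#' @param toa_cfg,method Detector configuration for acoustic fidelity.
#' @param offset Calibration range offset (metres) subtracted from acoustic
#'   ranges; see [calibrate_offset()].
#' @return n x 4 matrix of ranges in metres.
#' @export
trajectory_to_ranges <- function(traj, anchors = anchor_array(),
                                 spec = synth_gait_spec(),
                                 fidelity = c("geometric", "acoustic"),
                                 anchor_offsets = rep(0, 4),
                                 channel_args = list(),
                                 toa_cfg = toa_config(),
                                 method = "fractional", offset = 0) {
  fidelity <- match.arg(fidelity)
  n <- nrow(traj$positions)
  d_true <- t(apply(traj$positions, 1, measurement_fn, anchors = anchors))
  if (fidelity == "geometric") {
    noise <- with_local_seed(derive_seed(spec$seed, "ranges"), {
      matrix(stats::rnorm(n * 4, sd = spec$range_noise_std / 1e3), n, 4)
    })
    return(d_true + noise + matrix(anchor_offsets, n, 4, byrow = TRUE))
  }
  # acoustic: per-anchor radial velocity by finite differences
  dt <- diff(traj$timestamps)
  ranges <- matrix(NA_real_, n, 4)
  per_anchor_paths <- channel_args$paths
  channel_args$paths <- NULL
  for (i in seq_len(n)) {
    for (k in 1:4) {
      rdot <- if (i == 1L) {
        (d_true[2, k] - d_true[1, k]) / dt[1]
      } else {
        (d_true[i, k] - d_true[i - 1L, k]) / dt[i - 1L]
      }
      args <- c(list(los_distance = d_true[i, k],
                     doppler_velocity = rdot),
                channel_args)
      if (!is.null(per_anchor_paths)) args$paths <- per_anchor_paths[[k]]
      ch <- do.call(channel_spec, args)
      cyc <- run_cycle(ch, toa_cfg = toa_cfg, method = method,
                       seed = derive_seed(spec$seed,
                                          sprintf("ac%d_%d", i, k)),
                       offset = offset)
      ranges[i, k] <- cyc$r_compensated
    }
  }
  ranges
}
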