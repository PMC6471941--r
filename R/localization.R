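#' Anchor array geometry
#'
#' Positions of the four fixed receiver nodes. The default geometry places
#' them at the corners of a 250 x 200 mm rectangle on a vertical board one
#' metre to the side of the walking line: x is the walking (anterior)
#' direction, y points toward the board, z is vertical.
#'
#' @param positions 4 x 3 numeric matrix of anchor coordinates in metres
#'   (rows = anchors, columns = x, y, z). No two anchors may coincide.
#' @return An object of class `anchor_array`.
#' @export
anchor_array <- function(positions = default_anchors()) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == 4L, ncol(positions) == 3L,
            all(is.finite(positions)))
  d <- as.matrix(stats::dist(positions))
  if (any(d[upper.tri(d)] < 1e-9)) stop("anchors must be distinct")
  colnames(positions) <- c("x", "y", "z")
  structure(list(positions = positions), class = "anchor_array")
}

#' @rdname anchor_array
#' @param width,height Rectangle extent in metres (x and z).
#' @param standoff Distance of the board from the walking line, metres.
#' @export
default_anchors <- function(width = 0.250, height = 0.200, standoff = 1) {
  matrix(c(-width / 2, standoff, -height / 2,
            width / 2, standoff, -height / 2,
           -width / 2, standoff,  height / 2,
            width / 2, standoff,  height / 2),
         nrow = 4, byrow = TRUE)
}

#' @export
print.anchor_array <- function(x, ...) {
  cat("<anchor_array>\n")
  print(round(x$positions, 4))
  invisible(x)
}

#' Range measurement function
#'
#' Euclidean distances from a position (or the position block of a 6-d
#' state) to each of the four anchors: the nonlinear measurement model of
#' the tracking state space.
#'
#' @param state Numeric vector; the first three elements are x, y, z in
#'   metres.
#' @param anchors An [anchor_array()].
#' @return Numeric vector of four ranges in metres.
#' @export
measurement_fn <- function(state, anchors) {
  p <- state[1:3]
  sqrt(colSums((t(anchors$positions) - p)^2))
}

#' Tracking state-space configuration
#'
#' Constant-velocity model: state X = (x, y, z, xdot, ydot, zdot), transition
#' X_i = A X_{i-1} + q with A = [[I, dt I], [0, I]], measurements the four
#' anchor ranges with independent Gaussian noise of standard deviation
#' `meas_noise_e`. The process noise Q uses the discrete white-noise
#' acceleration form scaled by `process_noise_scale`.
#'
#' @param dt Cycle period in seconds (25 Hz ranging -> 0.040 s).
#' @param meas_noise_e Range measurement noise standard deviation, metres.
#' @param process_noise_scale White-noise acceleration standard deviation in
#'   m/s^2. Set it to the acceleration scale of the tracked target: the
#'   default 10 matches peak foot acceleration during the swing phase of slow
#'   walking (a 0.5 m half-stride excursion in a ~0.5 s swing is ~10 m/s^2);
#'   a static or slowly drifting node is better modelled with ~0.1.
#' @param ukf_alpha,ukf_beta,ukf_kappa Scaled unscented-transform parameters
#'   (sigma-point spread, prior-knowledge weight, secondary scaling).
#' @return An object of class `state_space_config`.
#' @export
state_space_config <- function(dt = 0.040, meas_noise_e = 0.005,
                               process_noise_scale = 10, ukf_alpha = 0.1,
                               ukf_beta = 2, ukf_kappa = 0) {
  stopifnot(dt > 0, meas_noise_e > 0, process_noise_scale > 0)
  structure(list(dt = dt, meas_noise_e = meas_noise_e,
                 process_noise_scale = process_noise_scale,
                 ukf_alpha = ukf_alpha, ukf_beta = ukf_beta,
                 ukf_kappa = ukf_kappa),
            class = "state_space_config")
}

transition_matrix <- function(dt) {
  A <- diag(6)
  A[1:3, 4:6] <- dt * diag(3)
  A
}

process_noise_cov <- function(dt, q_scale) {
  q <- q_scale^2
  Qp <- q * dt^4 / 4 * diag(3)
  Qpv <- q * dt^3 / 2 * diag(3)
  Qv <- q * dt^2 * diag(3)
  rbind(cbind(Qp, Qpv), cbind(Qpv, Qv))
}

#' Trajectory container
#'
#' @param timestamps Strictly increasing sample times in seconds.
#' @param positions n x 3 matrix of x, y, z in metres.
#' @param velocities Optional n x 3 matrix of velocities in m/s.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(timestamps, positions, velocities = NULL) {
  positions <- as.matrix(positions)
  stopifnot(length(timestamps) == nrow(positions), ncol(positions) == 3L)
  if (any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  colnames(positions) <- c("x", "y", "z")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    stopifnot(nrow(velocities) == nrow(positions), ncol(velocities) == 3L)
    colnames(velocities) <- c("vx", "vy", "vz")
  }
  structure(list(timestamps = as.numeric(timestamps), positions = positions,
                 velocities = velocities),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples over %.2f s\n",
              length(x$timestamps), diff(range(x$timestamps))))
  invisible(x)
}

# --- scaled unscented transform machinery ------------------------------------

sigma_weights <- function(n, alpha, beta, kappa) {
  lambda <- alpha^2 * (n + kappa) - n
  wm <- c(lambda / (n + lambda), rep(1 / (2 * (n + lambda)), 2 * n))
  wc <- wm
  wc[1] <- wc[1] + (1 - alpha^2 + beta)
  list(lambda = lambda, wm = wm, wc = wc)
}

# Columns are the 2n+1 sigma points of N(mean, cov).
sigma_points <- function(mean, cov, lambda) {
  n <- length(mean)
  S <- t(chol((n + lambda) * (cov + 1e-12 * diag(n))))
  cbind(mean, mean + S, mean - S)
}

#' Nonlinear least-squares trilateration of a single range set
#'
#' @param ranges Four measured ranges in metres.
#' @param anchors An [anchor_array()].
#' @param init Starting position; defaults to the origin (the tracked side
#'   of the anchor board).
#' @return Position estimate (x, y, z) in metres.
#' @export
trilaterate <- function(ranges, anchors, init = c(0, 0, 0)) {
  obj <- function(p) sum((measurement_fn(p, anchors) - ranges)^2)
  gr <- function(p) {
    d <- measurement_fn(p, anchors)
    resid <- d - ranges
    g <- numeric(3)
    for (k in 1:4) {
      g <- g + 2 * resid[k] * (p - anchors$positions[k, ]) / max(d[k], 1e-12)
    }
    g
  }
  stats::optim(init, obj, gr, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-12))$par
}

#' Track a trajectory from anchor-range streams
#'
#' Forward unscented Kalman filter over the constant-velocity state space,
#' followed by a backward unscented Rauch-Tung-Striebel smoothing pass.
#' Cycles with any missing range (detector reported no arrival) are handled
#' as prediction-only steps. Divergent cycles (normalized innovation beyond
#' `gate` for more than `max_gate_fail` consecutive steps) abort the filter;
#' the partial trajectory up to that point is returned with a warning.
#'
#' @param ranges n x 4 matrix of measured ranges in metres (NA = missing).
#' @param anchors An [anchor_array()].
#' @param cfg A [state_space_config()].
#' @param t0 Time of the first cycle in seconds.
#' @param smooth If FALSE, return the forward-filter estimates (mainly for
#'   comparing the smoother against the filter).
#' @param gate Innovation gate in standard deviations.
#' @param max_gate_fail Consecutive gated cycles tolerated before aborting.
#' @return A [trajectory()] with positions and velocities.
#' @export
track <- function(ranges, anchors = anchor_array(),
                  cfg = state_space_config(), t0 = 0, smooth = TRUE,
                  gate = 25, max_gate_fail = 10) {
  ranges <- as.matrix(ranges)
  stopifnot(ncol(ranges) == 4L, nrow(ranges) >= 2L)
  n_cyc <- nrow(ranges)
  nx <- 6L
  A <- transition_matrix(cfg$dt)
  Q <- process_noise_cov(cfg$dt, cfg$process_noise_scale)
  R <- diag(rep(cfg$meas_noise_e^2, 4))
  w <- sigma_weights(nx, cfg$ukf_alpha, cfg$ukf_beta, cfg$ukf_kappa)

  first <- which(stats::complete.cases(ranges))[1]
  if (is.na(first)) stop("no complete range cycle to initialize from")
  x <- c(trilaterate(ranges[first, ], anchors), 0, 0, 0)
  P <- diag(c(rep(0.1^2, 3), rep(1^2, 3)))

  xf <- matrix(NA_real_, n_cyc, nx)   # filtered means
  Pf <- array(NA_real_, c(nx, nx, n_cyc))
  xp <- matrix(NA_real_, n_cyc, nx)   # predicted means (for smoother)
  Pp <- array(NA_real_, c(nx, nx, n_cyc))
  n_fail <- 0L
  last <- n_cyc

  for (i in seq_len(n_cyc)) {
    if (i == 1L) {
      x_pred <- x; P_pred <- P
    } else {
      x_pred <- as.numeric(A %*% x)
      P_pred <- A %*% P %*% t(A) + Q
    }
    xp[i, ] <- x_pred; Pp[, , i] <- P_pred
    y <- ranges[i, ]
    if (!anyNA(y)) {
      X <- sigma_points(x_pred, P_pred, w$lambda)
      Z <- apply(X, 2, measurement_fn, anchors = anchors)
      z_hat <- as.numeric(Z %*% w$wm)
      dz <- Z - z_hat
      dx <- X - x_pred
      S <- dz %*% (w$wc * t(dz)) + R
      Cxz <- dx %*% (w$wc * t(dz))
      K <- Cxz %*% solve(S)
      innov <- y - z_hat
      nis <- as.numeric(t(innov) %*% solve(S, innov))
      if (nis > gate^2) {
        n_fail <- n_fail + 1L
        if (n_fail > max_gate_fail) {
          warning(sprintf("filter diverged at cycle %d; returning partial trajectory", i))
          last <- i - 1L
          break
        }
        x <- x_pred; P <- P_pred   # reject measurement
      } else {
        n_fail <- 0L
        x <- x_pred + as.numeric(K %*% innov)
        P <- P_pred - K %*% S %*% t(K)
      }
    } else {
      x <- x_pred; P <- P_pred
    }
    xf[i, ] <- x; Pf[, , i] <- P
  }

  idx <- seq_len(last)
  xs <- xf[idx, , drop = FALSE]
  if (smooth && last >= 2L) {
    for (i in (last - 1L):1L) {
      # unscented RTS pass: with a linear transition the sigma-point
      # propagation reduces to the linear smoother gain
      G <- Pf[, , i] %*% t(A) %*% solve(Pp[, , i + 1L])
      xs[i, ] <- xf[i, ] + as.numeric(G %*% (xs[i + 1L, ] - xp[i + 1L, ]))
    }
  }
  trajectory(t0 + (idx - 1L) * cfg$dt, xs[, 1:3, drop = FALSE],
             xs[, 4:6, drop = FALSE])
}

#' Zero-phase Butterworth low-pass of a trajectory
#'
#' @param traj A [trajectory()] with uniform sampling.
#' @param cutoff Cut-off frequency in Hz (must be below Nyquist).
#' @param order Filter order (applied forward and backward).
#' @return The filtered [trajectory()].
#' @export
lowpass <- function(traj, cutoff = 10, order = 4) {
  dt <- diff(traj$timestamps)
  if (max(abs(dt - dt[1])) > 1e-9) stop("trajectory must be uniformly sampled")
  fs <- 1 / dt[1]
  if (cutoff >= fs / 2) {
    stop(sprintf("cutoff %g Hz must be below Nyquist %g Hz", cutoff, fs / 2))
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- nrow(traj$positions)
  npad <- min(n - 1L, max(100L, ceiling(10 * fs / cutoff)))
  pos <- apply(traj$positions, 2, function(col) {
    # odd-symmetric reflection padding suppresses filtfilt edge transients
    head_pad <- 2 * col[1] - col[(npad + 1L):2]
    tail_pad <- 2 * col[n] - col[(n - 1L):(n - npad)]
    y <- as.numeric(signal::filtfilt(bf, c(head_pad, col, tail_pad)))
    y[(npad + 1L):(npad + n)]
  })
  trajectory(traj$timestamps, pos, traj$velocities)
}
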