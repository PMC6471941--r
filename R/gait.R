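#' Gait event detection from the walking-direction coordinate
#'
#' On a treadmill, the foot's anterior (x) coordinate oscillates once per
#' stride: its local maxima serve as heel-strike proxies and its local minima
#' as toe-off proxies. Extrema are accepted only with a minimum time
#' separation of half the expected stride and a prominence of at least 10%
#' of the peak-to-peak x excursion; strict max/min alternation is enforced by
#' dropping the weaker of adjacent same-type extrema.
#'
#' @param traj A [trajectory()] spanning at least two strides.
#' @param min_stride Smallest plausible stride time in seconds.
#' @return An object of class `gait_events`: list with `x_max_times` and
#'   `x_min_times` (seconds, strictly increasing, alternating).
#' @export
detect_events <- function(traj, min_stride = 0.6) {
  x <- traj$positions[, "x"]
  t <- traj$timestamps
  p2p <- diff(range(x))
  if (p2p <= 0) stop("insufficient cycles: x coordinate is constant")
  prom <- 0.1 * p2p
  dt <- stats::median(diff(t))
  min_sep <- max(1L, round(min_stride / 2 / dt))

  pick <- function(sig) {
    idx <- local_maxima(sig)
    idx <- idx[vapply(idx, function(i) {
      lo <- max(1L, i - min_sep); hi <- min(length(sig), i + min_sep)
      sig[i] >= max(sig[lo:hi]) &&
        sig[i] - min(sig[lo:hi]) >= prom
    }, logical(1))]
    idx
  }
  imax <- pick(x)
  imin <- pick(-x)
  if (length(imin) < 2L) stop("insufficient cycles: fewer than 2 x minima")

  # enforce alternation: between consecutive events of one type there must be
  # exactly one of the other; drop the weaker of adjacent same-type extrema
  ev <- rbind(data.frame(i = imax, type = "max", val = x[imax]),
              data.frame(i = imin, type = "min", val = -x[imin]))
  ev <- ev[order(ev$i), ]
  keep <- rep(TRUE, nrow(ev))
  k <- 1L
  while (k < nrow(ev)) {
    nxt <- which(keep & seq_len(nrow(ev)) > k)[1]
    if (is.na(nxt)) break
    if (ev$type[k] == ev$type[nxt]) {
      drop <- if (ev$val[k] >= ev$val[nxt]) nxt else k
      keep[drop] <- FALSE
      if (drop == k) k <- nxt
    } else {
      k <- nxt
    }
  }
  ev <- ev[keep, ]
  structure(list(x_max_times = t[ev$i[ev$type == "max"]],
                 x_min_times = t[ev$i[ev$type == "min"]]),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d heel-strike proxies (x maxima), %d toe-off proxies (x minima)\n",
              length(x$x_max_times), length(x$x_min_times)))
  invisible(x)
}

#' Spatiotemporal gait parameters per cycle
#'
#' Each gait cycle runs from one x minimum to the next. Per cycle i:
#' stride time ST = t(min_{i+1}) - t(min_i); half excursion
#' S = max(x) - min(x) within the cycle and stride length SL = 2 S (belt
#' frame: the foot's excursion is half the stride); swing time
#' SW = t(max_i) - t(min_i); stance time STT = t(min_{i+1}) - t(max_i);
#' maximum foot clearance MFC = max(z) - min(z) within the cycle.
#' ST = SW + STT holds exactly by construction.
#'
#' @param traj A [trajectory()].
#' @param events A `gait_events` from [detect_events()].
#' @param sl_offset Constant offset in mm subtracted from every stride
#'   length (0 by default). Range-based foot tracking tends to over-estimate
#'   stride length by a constant; subtracting a per-subject calibration
#'   constant removes it.
#' @return data.frame with one row per cycle: cycle, stride_time (s),
#'   half_excursion (mm), stride_length (mm), swing_time (s), stance_time
#'   (s), max_foot_clearance (mm). Cycles without an interior x maximum are
#'   skipped with a warning.
#' @export
compute_parameters <- function(traj, events, sl_offset = 0) {
  t <- traj$timestamps
  x <- traj$positions[, "x"]
  z <- traj$positions[, "z"]
  mins <- events$x_min_times
  maxs <- events$x_max_times
  rows <- list()
  for (i in seq_len(length(mins) - 1L)) {
    t0 <- mins[i]; t1 <- mins[i + 1L]
    mx <- maxs[maxs > t0 & maxs < t1]
    if (length(mx) != 1L) {
      warning(sprintf("cycle %d has %d interior x maxima; skipped",
                      i, length(mx)))
      next
    }
    inside <- t >= t0 & t < t1
    s_mm <- (max(x[inside]) - min(x[inside])) * 1e3
    rows[[length(rows) + 1L]] <- data.frame(
      cycle = i,
      stride_time = t1 - t0,
      half_excursion = s_mm,
      stride_length = 2 * s_mm,
      swing_time = mx - t0,
      stance_time = t1 - mx,
      max_foot_clearance = (max(z[inside]) - min(z[inside])) * 1e3
    )
  }
  if (length(rows) == 0L) stop("no valid gait cycles")
  out <- do.call(rbind, rows)
  out$stride_length <- out$stride_length - sl_offset
  out
}

#' Summary of gait parameters across cycles
#'
#' @param params data.frame from [compute_parameters()].
#' @return data.frame with mean and sd per parameter.
#' @export
gait_summary <- function(params) {
  cols <- setdiff(names(params), "cycle")
  data.frame(parameter = cols,
             mean = vapply(params[cols], mean, numeric(1)),
             sd = vapply(params[cols], stats::sd, numeric(1)),
             row.names = NULL)
}
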