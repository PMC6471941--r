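#' Multipath component of an acoustic channel
#'
#' One non-line-of-sight (NLOS) echo, described by the extra distance it
#' travels beyond the direct path and the amplitude scaling of the reflection.
#'
#' @param extra_distance Extra path length beyond the LOS distance, metres
#'   (>= 0; 0 identifies the LOS path itself).
#' @param reflection_coefficient Amplitude scaling of the reflection, in
#'   (0, 1].
#' @return An object of class `path_component`.
#' @export
path_component <- function(extra_distance, reflection_coefficient = 0.9) {
  stopifnot(is.numeric(extra_distance), is.numeric(reflection_coefficient))
  if (extra_distance < 0) stop("extra_distance must be >= 0")
  if (reflection_coefficient <= 0 || reflection_coefficient > 1) {
    stop("reflection_coefficient must lie in (0, 1]")
  }
  structure(list(extra_distance = extra_distance,
                 reflection_coefficient = reflection_coefficient),
            class = "path_component")
}

#' Ultrasonic propagation channel specification
#'
#' Direct-path distance plus any number of NLOS echoes, exponential amplitude
#' attenuation through air, additive white Gaussian noise at a specified SNR,
#' and optional Doppler from a constant radial velocity of the transmitter.
#'
#' @param los_distance Line-of-sight distance in metres (> 0).
#' @param paths List of [path_component()] objects (NLOS echoes).
#' @param speed_of_sound Speed of sound v in m/s.
#' @param attenuation_const Amplitude attenuation constant gamma in Np/m:
#'   an amplitude A0 arrives as A0 * exp(-gamma * distance).
#' @param snr_db Channel SNR in dB, referenced to the mean power of the LOS
#'   component over its own support; use `Inf` (or `"noiseless"`) for no
#'   noise.
#' @param doppler_velocity Radial velocity Rdot in m/s, positive receding;
#'   modelled as time-scaling of the waveform by 1 + Rdot/v.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(los_distance, paths = list(), speed_of_sound = 345.3,
                         attenuation_const = 0.17, snr_db = Inf,
                         doppler_velocity = 0) {
  if (identical(snr_db, "noiseless")) snr_db <- Inf
  stopifnot(is.numeric(los_distance), is.numeric(snr_db))
  if (los_distance <= 0) stop("los_distance must be > 0")
  if (attenuation_const < 0) stop("attenuation_const must be >= 0")
  if (inherits(paths, "path_component")) paths <- list(paths)
  stopifnot(all(vapply(paths, inherits, TRUE, "path_component")))
  structure(list(los_distance = los_distance, paths = paths,
                 speed_of_sound = speed_of_sound,
                 attenuation_const = attenuation_const, snr_db = snr_db,
                 doppler_velocity = doppler_velocity),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel_spec> LOS %.3f m, %d NLOS path(s), gamma %.2f Np/m, SNR %s dB, Rdot %.2f m/s\n",
              x$los_distance, length(x$paths), x$attenuation_const,
              format(x$snr_db), x$doppler_velocity))
  invisible(x)
}

#' Exponential amplitude attenuation in air
#'
#' @param amplitude Transmitted amplitude (unitless).
#' @param distance Distance travelled in metres (>= 0).
#' @param gamma Attenuation constant in Np/m.
#' @return `amplitude * exp(-gamma * distance)`.
#' @examples
#' attenuate(1, 1, 0.17)  # exp(-0.17)
#' @export
attenuate <- function(amplitude, distance, gamma) {
  if (any(distance < 0)) stop("distance must be >= 0")
  amplitude * exp(-gamma * distance)
}

# One delayed/scaled/time-scaled copy of tx placed into a record of n samples.
# delay in seconds, amp unitless, alpha = 1 + Rdot/v time-scaling factor.
# Without Doppler: whole-sample shift + linear interpolation (vectorised).
# With Doppler: cubic spline evaluation of tx((t - delay)/alpha).
place_path <- function(tx, n, delay, amp, alpha = 1) {
  fr <- tx$sample_rate
  x <- tx$samples
  nt <- length(x)
  out <- numeric(n)
  if (alpha == 1) {
    d <- delay * fr
    k <- floor(d)
    f <- d - k
    if (k + 1L > n) return(out)
    idx0 <- (k + 1L):min(n, k + nt)        # aligned copy
    src <- seq_len(length(idx0))
    out[idx0] <- out[idx0] + (1 - f) * x[src]
    idx1 <- (k + 2L):min(n, k + nt + 1L)
    src1 <- seq_len(length(idx1))
    out[idx1] <- out[idx1] + f * x[src1]
    out
  } else {
    t <- (seq_len(n) - 1L) / fr
    u <- (t - delay) / alpha
    inside <- u >= 0 & u <= (nt - 1L) / fr
    if (any(inside)) {
      sf <- stats::splinefun((seq_len(nt) - 1L) / fr, x, method = "natural")
      out[inside] <- sf(u[inside])
    }
    out
  }
  out * amp
}

#' Propagate a waveform through a multipath channel
#'
#' Superposes the line-of-sight arrival and every NLOS echo, each delayed by
#' its total path length over the speed of sound and attenuated as
#' exp(-gamma * distance) (times the reflection coefficient for echoes),
#' applies Doppler time-scaling when the radial velocity is nonzero, and adds
#' white Gaussian noise realizing the requested SNR against the LOS
#' component's mean power over its own support.
#'
#' @param tx Transmitted [waveform()].
#' @param spec A [channel_spec()].
#' @param noise_seed Integer seed for the noise realization (ignored when the
#'   channel is noiseless).
#' @param max_record Maximum record length in seconds; a path delayed beyond
#'   it is an error.
#' @return The received [waveform()] (t0 = 0), long enough to contain every
#'   echo.
#' @export
propagate <- function(tx, spec, noise_seed = NULL, max_record = 0.5) {
  stopifnot(inherits(tx, "waveform"), inherits(spec, "channel_spec"))
  fr <- tx$sample_rate
  v <- spec$speed_of_sound
  gamma <- spec$attenuation_const
  alpha <- 1 + spec$doppler_velocity / v

  dists <- c(spec$los_distance,
             spec$los_distance +
               vapply(spec$paths, `[[`, numeric(1), "extra_distance"))
  refl <- c(1, vapply(spec$paths, `[[`, numeric(1), "reflection_coefficient"))
  delays <- dists / v
  if (max(delays) > max_record) {
    stop(sprintf("path delay %.4f s exceeds max_record = %g s",
                 max(delays), max_record))
  }
  dur <- (length(tx$samples) - 1L) / fr
  n <- ceiling((max(delays) + dur * max(alpha, 1) + 1e-3) * fr) + 1L

  rec <- numeric(n)
  los <- NULL
  for (i in seq_along(dists)) {
    comp <- place_path(tx, n, delays[i], attenuate(refl[i], dists[i], gamma),
                       alpha)
    if (i == 1L) los <- comp
    rec <- rec + comp
  }

  if (is.finite(spec$snr_db)) {
    support <- which(abs(los) > 0)
    p_los <- mean(los[support]^2)
    sigma <- sqrt(p_los / 10^(spec$snr_db / 10))
    if (!is.null(noise_seed)) {
      rec <- rec + with_local_seed(noise_seed, stats::rnorm(n, sd = sigma))
    } else {
      rec <- rec + stats::rnorm(n, sd = sigma)
    }
  }
  waveform(rec, fr)
}

#' Draw a random close NLOS component
#'
#' Extra path length uniform on (eps, max_extra], where eps is one sample's
#' worth of distance (v / sample_rate), with a fixed reflection coefficient.
#' Used by the Monte-Carlo study to place an unresolvable echo within the
#' chirp's range resolution.
#'
#' @param max_extra Upper bound on the extra path length in metres.
#' @param reflection Reflection coefficient passed through.
#' @param speed_of_sound,sample_rate Used for the lower support bound eps.
#' @return A [path_component()].
#' @export
sample_nlos <- function(max_extra, reflection = 0.9, speed_of_sound = 345.3,
                        sample_rate = 125e3) {
  stopifnot(max_extra > 0)
  eps <- speed_of_sound / sample_rate
  path_component(stats::runif(1, eps, max_extra), reflection)
}
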