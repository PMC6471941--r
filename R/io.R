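# Waveform, range and trajectory I/O.
#
# WAV support is a minimal mono 16-bit PCM RIFF reader/writer: enough to
# exchange simulated receiver waveforms with audio tooling.

#' Write a waveform as mono 16-bit PCM WAV
#'
#' Samples are scaled by `scale` (default: the maximum absolute amplitude)
#' to the full 16-bit range.
#'
#' @param wf A [waveform()].
#' @param path Output file path.
#' @param scale Amplitude mapped to full scale; defaults to `max(abs(samples))`.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(wf, path, scale = NULL) {
  stopifnot(inherits(wf, "waveform"))
  if (is.null(scale)) scale <- max(abs(wf$samples), 1e-12)
  pcm <- as.integer(round(pmax(pmin(wf$samples / scale, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  fr <- as.integer(round(wf$sample_rate))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(fr, con, size = 4, endian = "little")
  writeBin(fr * 2L, con, size = 4, endian = "little")   # byte rate
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file as a waveform
#'
#' @param path Input file path.
#' @return A [waveform()] with amplitudes in [-1, 1].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only mono PCM supported")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      ba_bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (ba_bits[2] != 16L) stop("only 16-bit PCM supported")
      if (sz > 16L) invisible(readBin(con, raw(), n = sz - 16L))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2L, size = 2, signed = TRUE,
                     endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
  if (is.null(sample_rate)) stop("fmt chunk missing")
  waveform(pcm / 32767, sample_rate)
}

#' Waveform CSV export/import
#'
#' Two-column CSV: time (s), amplitude.
#'
#' @param wf A [waveform()].
#' @param path File path.
#' @return `write_waveform_csv()`: invisibly, `path`;
#'   `read_waveform_csv()`: a [waveform()].
#' @export
write_waveform_csv <- function(wf, path) {
  stopifnot(inherits(wf, "waveform"))
  utils::write.csv(data.frame(time = waveform_times(wf),
                              amplitude = wf$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  dt <- diff(d$time)
  waveform(d$amplitude, 1 / stats::median(dt), t0 = d$time[1])
}

#' Range-stream CSV export/import
#'
#' One row per ranging cycle: cycle index, time, and per-anchor ranges in mm
#' (columns r1..r4, or r_up/r_down/r0 triplets when detail is requested).
#'
#' @param ranges n x 4 matrix of ranges in metres.
#' @param path File path.
#' @param dt Cycle period in seconds.
#' @param t0 Time of the first cycle.
#' @return `write_ranges_csv()`: invisibly, `path`;
#'   `read_ranges_csv()`: n x 4 matrix of ranges in metres.
#' @export
write_ranges_csv <- function(ranges, path, dt = 0.040, t0 = 0) {
  ranges <- as.matrix(ranges)
  d <- data.frame(cycle = seq_len(nrow(ranges)),
                  t = t0 + (seq_len(nrow(ranges)) - 1) * dt)
  for (k in seq_len(ncol(ranges))) d[[paste0("r", k)]] <- ranges[, k] * 1e3
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranges_csv
#' @export
read_ranges_csv <- function(path) {
  d <- utils::read.csv(path)
  as.matrix(d[grep("^r[0-9]+$", names(d))]) / 1e3
}

#' Trajectory CSV export/import
#'
#' Columns: t (s), x, y, z (mm).
#'
#' @param traj A [trajectory()].
#' @param path File path.
#' @return `write_trajectory_csv()`: invisibly, `path`;
#'   `read_trajectory_csv()`: a [trajectory()] (metres).
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(data.frame(t = traj$timestamps,
                              x = traj$positions[, 1] * 1e3,
                              y = traj$positions[, 2] * 1e3,
                              z = traj$positions[, 3] * 1e3),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  trajectory(d$t, cbind(d$x, d$y, d$z) / 1e3)
}
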