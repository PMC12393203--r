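#' Multi-channel RF pulse on a shared time base
#'
#' The unpacked form of a pTx pulse: one complex envelope per transmit
#' channel, each given by a peak-normalized magnitude sequence, a phase
#' sequence (radians) and a time-index sequence (RF raster units, strictly
#' increasing within a channel). A global amplitude (Hz) scales all channels;
#' per-event frequency/phase offsets apply uniformly to every channel.
#'
#' Sample `i` of a channel occupies the raster cells `(t[i-1], t[i]]` (with
#' `t[0] = 0`), so a sparse time shape with a terminal zero-magnitude sample
#' fills the remaining duration with zero RF. The pulse ends at the latest
#' time index used by any channel; [pack_ptx()] requires every channel to end
#' there (use [pad_channels()] first).
#'
#' @param mag,phase Lists with one numeric vector per channel (or a matrix
#'   with one column per channel). Magnitudes in `[0, 1]`, phases in radians.
#' @param time Optional list of time-index vectors; default is the regular
#'   raster `1:n` per channel.
#' @param amplitude Peak amplitude in Hz (gamma * B1 of a magnitude-1 sample).
#' @param raster RF raster time in seconds.
#' @param delay,freq_offset,phase_offset Scalar event fields (s, Hz, rad).
#' @return A `ptx_rf` object.
#' @export
multichannel_rf <- function(mag, phase, time = NULL, amplitude, raster = 1e-6,
                            delay = 0, freq_offset = 0, phase_offset = 0) {
  as_chan_list <- function(x) {
    if (is.matrix(x)) lapply(seq_len(ncol(x)), function(j) x[, j])
    else if (is.list(x)) lapply(x, as.numeric)
    else list(as.numeric(x))
  }
  mag <- as_chan_list(mag)
  phase <- as_chan_list(phase)
  if (length(mag) != length(phase)) stop("mag and phase must have the same number of channels")
  n_channels <- length(mag)
  if (is.null(time)) {
    time <- lapply(mag, function(m) as.numeric(seq_along(m)))
  } else {
    time <- as_chan_list(time)
    if (length(time) != n_channels) stop("time must have one vector per channel")
  }
  for (c in seq_len(n_channels)) {
    if (length(mag[[c]]) != length(phase[[c]]) || length(mag[[c]]) != length(time[[c]]))
      stop(sprintf("channel %d: magnitude, phase and time sequences differ in length", c))
    if (length(time[[c]]) == 0) stop(sprintf("channel %d is empty", c))
    if (any(diff(time[[c]]) <= 0))
      stop(sprintf("channel %d: time indices must be strictly increasing", c))
    if (any(mag[[c]] < -1e-12 | mag[[c]] > 1 + 1e-9))
      stop(sprintf("channel %d: magnitude samples must lie in [0, 1]", c))
  }
  structure(list(n_channels = n_channels, raster = raster,
                 amplitude = amplitude, delay = delay,
                 freq_offset = freq_offset, phase_offset = phase_offset,
                 mag = mag, phase = phase, time = time),
            class = "ptx_rf")
}

rf_final_times <- function(rf) vapply(rf$time, function(t) t[length(t)], numeric(1))

#' Duration of a (packed or unpacked) pTx pulse in seconds
#'
#' Matches reference-interpreter decompression semantics: the duration is the
#' final time point of the time shape times the RF raster.
#' @param rf A `ptx_rf` or `ptx_packed` object.
#' @export
ptx_duration <- function(rf) {
  tmax <- if (inherits(rf, "ptx_packed")) max(rf$time) else max(rf_final_times(rf))
  tmax * rf$raster
}

#' @export
print.ptx_rf <- function(x, ...) {
  cat(sprintf("<ptx_rf> %d channel(s), raster %.3g us, amplitude %.4g Hz, duration %.4g ms\n",
              x$n_channels, x$raster * 1e6, x$amplitude, ptx_duration(x) * 1e3))
  invisible(x)
}

#' Pad all channels to the common final time point
#'
#' Every channel whose time sequence ends before the global latest time point
#' gains one terminal zero-magnitude sample (phase 0) at that point. All
#' channels then end together, as the packed encoding requires. Idempotent.
#'
#' @param rf A `ptx_rf`.
#' @export
pad_channels <- function(rf) {
  finals <- rf_final_times(rf)
  tmax <- max(finals)
  for (c in seq_len(rf$n_channels)) {
    if (finals[c] < tmax) {
      rf$mag[[c]] <- c(rf$mag[[c]], 0)
      rf$phase[[c]] <- c(rf$phase[[c]], 0)
      rf$time[[c]] <- c(rf$time[[c]], tmax)
    }
  }
  rf
}

#' Pack per-channel RF waveforms into a single Pulseq-compliant event
#'
#' The channels are concatenated in order in the magnitude and phase shapes
#' while the time shape repeats each channel's time range. Because Pulseq
#' time shapes may legally store repeated (restarting) time points, the
#' result is an ordinary RF event with no new entry fields; a one-channel
#' input yields the plain encoding of the same pulse.
#'
#' @param rf A `ptx_rf` whose channels all end at the same final time point
#'   (see [pad_channels()]).
#' @return A `ptx_packed` object holding the concatenated magnitude, phase
#'   (radians) and time sequences plus the scalar event fields.
#' @export
pack_ptx <- function(rf) {
  stopifnot(inherits(rf, "ptx_rf"))
  finals <- rf_final_times(rf)
  if (any(finals != finals[1]))
    stop("channels end at different time points; call pad_channels() first")
  structure(list(n_channels = rf$n_channels, raster = rf$raster,
                 amplitude = rf$amplitude, delay = rf$delay,
                 freq_offset = rf$freq_offset, phase_offset = rf$phase_offset,
                 mag = unlist(rf$mag, use.names = FALSE),
                 phase = unlist(rf$phase, use.names = FALSE),
                 time = unlist(rf$time, use.names = FALSE)),
            class = "ptx_packed")
}

#' @export
print.ptx_packed <- function(x, ...) {
  cat(sprintf("<ptx_packed> %d channel(s) in %d samples, duration %.4g ms\n",
              x$n_channels, length(x$mag), ptx_duration(x) * 1e3))
  invisible(x)
}

#' Number of transmit channels encoded in a time shape
#'
#' A packed pTx time shape repeats each channel's time range, so a new
#' channel starts wherever the time index fails to increase strictly.
#'
#' @param time_samples Numeric vector of time-shape samples (raster units).
#' @return `1 + number of non-increasing steps`.
#' @export
infer_channel_count <- function(time_samples) {
  if (length(time_samples) == 0) stop("empty time shape")
  1L + sum(diff(time_samples) <= 0)
}

#' Unpack a pTx RF event into per-channel waveforms
#'
#' Splits the concatenated shapes at the channel boundaries detected in the
#' time shape (positions where the time index restarts). All channel segments
#' must end at the same final time point; the pulse duration is that final
#' time point times the raster.
#'
#' @param packed A `ptx_packed` object (see [pack_ptx()] and [seq_get_rf()]).
#' @return A `ptx_rf`.
#' @export
unpack_ptx <- function(packed) {
  stopifnot(inherits(packed, "ptx_packed"))
  t <- packed$time
  starts <- c(1L, which(diff(t) <= 0) + 1L)
  ends <- c(starts[-1] - 1L, length(t))
  finals <- t[ends]
  if (any(finals != finals[1]))
    stop("inconsistent packed structure: channel segments end at different time points")
  mag <- phase <- time <- vector("list", length(starts))
  for (c in seq_along(starts)) {
    idx <- starts[c]:ends[c]
    mag[[c]] <- packed$mag[idx]
    phase[[c]] <- packed$phase[idx]
    time[[c]] <- t[idx]
  }
  multichannel_rf(mag, phase, time, amplitude = packed$amplitude,
                  raster = packed$raster, delay = packed$delay,
                  freq_offset = packed$freq_offset,
                  phase_offset = packed$phase_offset)
}

## ---- sequence-document integration ------------------------------------

#' Attach an RF pulse to a sequence document
#'
#' Registers the magnitude, phase and time shapes (phase stored as
#' radians / 2 pi, wrapped into `[0, 1)`) and the RF event. `ptx_rf` inputs
#' are packed first.
#'
#' @param doc A `pulseq_seq`.
#' @param rf A `ptx_rf` or `ptx_packed`.
#' @param use Pulseq v1.5.0 use tag (single character, e.g. "e" excitation).
#' @return `list(doc, id)` with the updated document and the RF event id.
#' @export
seq_add_rf <- function(doc, rf, use = "e") {
  if (inherits(rf, "ptx_rf")) rf <- pack_ptx(rf)
  stopifnot(inherits(rf, "ptx_packed"))
  s1 <- add_shape(doc, rf$mag); doc <- s1$doc
  s2 <- add_shape(doc, (rf$phase / (2 * pi)) %% 1); doc <- s2$doc
  s3 <- add_shape(doc, rf$time); doc <- s3$doc
  ev <- rf_event(amplitude = rf$amplitude, mag_id = s1$id, phase_id = s2$id,
                 time_id = s3$id, center = ptx_duration(rf) / 2,
                 delay = rf$delay, freq_offset = rf$freq_offset,
                 phase_offset = rf$phase_offset, use = use)
  r <- add_event(doc, "rf", ev)
  list(doc = r$doc, id = r$id)
}

#' Extract an RF event from a sequence document in packed form
#'
#' @param doc A `pulseq_seq`.
#' @param rf_id RF event id in the document's RF table.
#' @return A `ptx_packed`; events without a time shape decode as a single
#'   channel on the regular raster.
#' @export
seq_get_rf <- function(doc, rf_id) {
  ev <- doc$rf[[as.character(rf_id)]]
  if (is.null(ev)) stop("no RF event with id ", rf_id)
  mag <- decompress_shape(doc$shapes[[as.character(ev$mag_id)]])
  phase <- 2 * pi * decompress_shape(doc$shapes[[as.character(ev$phase_id)]])
  time <- if (ev$time_id > 0) {
    decompress_shape(doc$shapes[[as.character(ev$time_id)]])
  } else {
    seq_along(mag)
  }
  if (min(time) == 0) time <- time + 1  # normalize 0-based third-party shapes
  structure(list(n_channels = infer_channel_count(time),
                 raster = seq_rasters(doc)$rf, amplitude = ev$amplitude,
                 delay = ev$delay, freq_offset = ev$freq_offset,
                 phase_offset = ev$phase_offset,
                 mag = mag, phase = phase, time = time),
            class = "ptx_packed")
}
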