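#' Zero-phase Butterworth filtering with reflective padding
#'
#' Both pipeline filters are applied forward-backward (zero phase): the
#' downstream timing indices (burst on/off phases, coherence epoch
#' placement) are sensitive to group delay, and zero-phase filtering keeps
#' burst timing aligned with the raw signal. The effective attenuation is
#' therefore that of a 6th-order filter. One settling length of the signal
#' is reflect-padded at each end to suppress onset/offset transients on
#' short walks.
#'
#' @keywords internal
#' @noRd
zero_phase_butter <- function(x, fs, cutoff, type) {
  n <- length(x)
  settle <- ceiling(3 * fs / cutoff)
  assert_that(n >= 2L && n > settle %/% 3, "too_short_signal",
              "signal too short (%d samples) for a %g Hz filter at fs=%g",
              n, cutoff, fs)
  pad <- min(n - 1L, settle)
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  b <- signal::butter(3, cutoff / (fs / 2), type = type)
  yp <- signal::filtfilt(b, xp)
  yp[(pad + 1L):(pad + n)]
}

#' High-pass filter raw EMG at 20 Hz
#'
#' First stage of the standard pre-processing chain: 3rd-order Butterworth
#' high-pass at 20 Hz, zero-phase. Removes movement artifact and baseline
#' drift while keeping the physiological EMG band. Also used on its own to
#' prepare signals for intermuscular coherence, where the 4 Hz envelope
#' smoothing must not be applied.
#'
#' @param raw numeric signal.
#' @param fs sampling rate (samples/second).
#' @param cutoff high-pass cutoff in Hz (default 20).
#' @return filtered signal, same length.
#' @export
highpass_only <- function(raw, fs, cutoff = 20) {
  assert_that(fs > 2 * cutoff, "bad_rate",
              "sampling rate %g too low for %g Hz cutoff", fs, cutoff)
  zero_phase_butter(as.numeric(raw), fs, cutoff, "high")
}

#' Compute the linear envelope of a raw EMG channel
#'
#' Applies, in order: 3rd-order Butterworth high-pass at 20 Hz, full-wave
#' rectification, and 3rd-order Butterworth low-pass at 4 Hz (all
#' zero-phase). Negative residuals from low-pass ringing are clamped to 0,
#' so the envelope is non-negative everywhere.
#'
#' @param raw numeric signal.
#' @param fs sampling rate (samples/second).
#' @param highpass_cutoff Hz, default 20.
#' @param lowpass_cutoff Hz, default 4.
#' @param source optional \code{channel_label} recorded in the result.
#' @return an \code{envelope_signal}: list with \code{values},
#'   \code{sampling_rate}, \code{source}.
#' @export
compute_envelope <- function(raw, fs, highpass_cutoff = 20,
                             lowpass_cutoff = 4, source = NULL) {
  hp <- highpass_only(raw, fs, highpass_cutoff)
  env <- zero_phase_butter(abs(hp), fs, lowpass_cutoff, "low")
  env[env < 0] <- 0
  structure(list(values = env, sampling_rate = fs, source = source),
            class = "envelope_signal")
}

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf("<envelope %s: %d samples @ %g Hz, peak %.4g>\n",
              if (!is.null(x$source)) format(x$source) else "?",
              length(x$values), x$sampling_rate, max(x$values, 0)))
  invisible(x)
}

#' Envelopes for every channel of a recording
#' @param rec an \code{emg_recording}.
#' @param ... passed to \code{compute_envelope}.
#' @return named list of \code{envelope_signal}s, one per channel.
#' @export
recording_envelopes <- function(rec, ...) {
  out <- lapply(seq_along(rec$channels), function(i)
    compute_envelope(rec$samples[, i], rec$sampling_rate,
                     source = rec$channels[[i]], ...))
  names(out) <- colnames(rec$samples)
  out
}
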