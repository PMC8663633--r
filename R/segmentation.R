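#' Detect SOL deactivation events with a moving-window adaptive threshold
#'
#' The step trigger: the soleus is monophasically active once per
#' physiological gait cycle, so each transition of its envelope from active
#' to inactive marks one step. The threshold at sample t is \code{k} times
#' the mean of the envelope over the trailing \code{window} seconds (the
#' window is truncated near the start), so detection is invariant to
#' uniform amplitude scaling. A deactivation event fires at the first
#' sample of every run where the envelope stays below threshold for at
#' least \code{min_off} seconds and that is preceded by an above-threshold
#' run (a drop from activity, not the initial rest). Events closer than
#' \code{refractory} seconds are merged, keeping the first.
#'
#' @param env an \code{envelope_signal} (or numeric vector with \code{fs}).
#' @param window trailing-mean window in seconds.
#' @param k threshold factor relative to the trailing mean.
#' @param min_off minimum below-threshold dwell in seconds.
#' @param refractory merge distance in seconds.
#' @param fs sampling rate, required when \code{env} is a bare vector.
#' @param noise_floor absolute level below which the whole envelope is
#'   considered silence (no detectable activity).
#' @return integer vector of event sample indices, strictly increasing.
#' @export
detect_deactivations <- function(env, window = 2, k = 0.5, min_off = 0.1,
                                 refractory = 0.3, fs = NULL,
                                 noise_floor = 1e-10) {
  if (inherits(env, "envelope_signal")) {
    fs <- env$sampling_rate
    env <- env$values
  }
  assert_that(!is.null(fs) && fs > 0, "bad_rate", "sampling rate required")
  assert_that(length(env) > 0 && window > 0, "too_short_signal",
              "empty envelope or non-positive window")
  assert_that(max(env) > noise_floor, "no_activity",
              "envelope everywhere below the noise floor")
  n <- length(env)
  w <- max(1L, round(window * fs))
  cs <- cumsum(env)
  idx <- seq_len(n)
  lo <- pmax(0L, idx - w)
  trail_mean <- (cs - c(0, cs)[lo + 1L]) / (idx - lo)
  below <- env < k * trail_mean
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_off_n <- max(1L, round(min_off * fs))
  keep <- r$values & r$lengths >= min_off_n & starts > 1L
  events <- starts[keep]
  if (length(events) > 1L) {
    ref_n <- round(refractory * fs)
    kept <- events[1L]
    for (e in events[-1L]) if (e - kept[length(kept)] >= ref_n)
      kept <- c(kept, e)
    events <- kept
  }
  as.integer(events)
}

#' Build a step segmentation from deactivation events
#'
#' Step k is the half-open sample interval [event_k, event_{k+1}); samples
#' before the first and after the last event are discarded. The same
#' segmentation is applied to every channel of a recording. Because steps
#' start at a SOL deactivation, the segmented cycle is rotated relative to
#' the conventional heel-strike cycle; \code{anchor_offset_pct} records the
#' heel-strike-frame percent at which the cycle starts (about toe-off,
#' ~50\% with the default activation templates) so phase windows stated in
#' the heel-strike frame can be mapped into segmented profiles.
#'
#' @param events strictly increasing event sample indices (>= 2 of them).
#' @param n_samples total samples in the recording.
#' @param reference_channel the \code{channel_label} the events came from.
#' @param anchor_offset_pct heel-strike-frame percent of the cycle at which
#'   each segmented step begins.
#' @return a \code{step_segmentation}: events, a (start, end) step matrix,
#'   \code{n_detected} (the detected step count = number of deactivation
#'   events), the reference channel and the anchor offset.
#' @export
segment_steps <- function(events, n_samples, reference_channel = NULL,
                          anchor_offset_pct = 50) {
  events <- as.integer(events)
  assert_that(length(events) >= 2L, "too_few_events",
              "need at least 2 deactivation events, got %d", length(events))
  assert_that(all(diff(events) > 0), "too_few_events",
              "events must be strictly increasing")
  assert_that(events[length(events)] <= n_samples, "too_few_events",
              "event index beyond recording end")
  steps <- cbind(start = events[-length(events)], end = events[-1L])
  structure(list(events = events, steps = steps,
                 n_detected = length(events),
                 reference_channel = reference_channel,
                 anchor_offset_pct = anchor_offset_pct %% 100),
            class = "step_segmentation")
}

#' @export
print.step_segmentation <- function(x, ...) {
  cat(sprintf("<step_segmentation: %d events, %d steps, ref %s, anchor %+g%%>\n",
              length(x$events), nrow(x$steps),
              if (!is.null(x$reference_channel)) format(x$reference_channel)
              else "?", x$anchor_offset_pct))
  invisible(x)
}

#' Segment a recording from its SOL envelope
#'
#' Picks the reference soleus channel (right SOL for healthy subjects; the
#' non-paretic SOL for patients, since the monophasic SOL burst remains
#' reliable on the unaffected side), computes its envelope, detects
#' deactivations and segments steps. The segmentation applies to all
#' channels of the recording.
#'
#' @param rec an \code{emg_recording}.
#' @param reference optional explicit channel name (e.g. "R_SOL").
#' @param anchor_offset_pct see \code{\link{segment_steps}}.
#' @param ... passed to \code{\link{detect_deactivations}}.
#' @return a \code{step_segmentation}.
#' @export
segment_recording <- function(rec, reference = NULL, anchor_offset_pct = 50,
                              ...) {
  if (is.null(reference)) {
    sol <- Filter(function(ch) ch$muscle == "SOL", rec$channels)
    assert_that(length(sol) > 0, "missing_channel", "no SOL channel")
    if (rec$group == "HEALTHY") {
      pick <- Filter(function(ch) ch$side == "R", sol)
      ref_ch <- if (length(pick)) pick[[1]] else sol[[1]]
    } else {
      pick <- Filter(function(ch) ch$role == "NON_PARETIC", sol)
      ref_ch <- if (length(pick)) pick[[1]] else sol[[1]]
    }
  } else {
    ref_ch <- rec$channels[[match(reference, colnames(rec$samples))]]
    assert_that(!is.null(ref_ch), "missing_channel",
                "no channel '%s'", reference)
  }
  env <- compute_envelope(channel_signal(rec, ref_ch), rec$sampling_rate,
                          source = ref_ch)
  ev <- detect_deactivations(env, ...)
  segment_steps(ev, n_samples(rec), reference_channel = ref_ch,
                anchor_offset_pct = anchor_offset_pct)
}

#' Step-count accuracy of a segmentation against footswitch truth
#'
#' The validation the footswitch permits: compare how many steps the
#' EMG-driven algorithm found with the number of footswitch-recorded steps,
#' as \code{100 * (1 - |detected - true| / true)}, floored at 0.
#'
#' @param detected a \code{step_segmentation} or a detected step count.
#' @param footswitch_steps true step count (>= 1).
#' @return accuracy percentage in [0, 100].
#' @export
segmentation_accuracy <- function(detected, footswitch_steps) {
  if (inherits(detected, "step_segmentation")) detected <- detected$n_detected
  assert_that(footswitch_steps >= 1, "bad_footswitch",
              "footswitch step count must be >= 1")
  max(0, 100 * (1 - abs(detected - footswitch_steps) / footswitch_steps))
}

#' Count steps recorded by the footswitch
#'
#' One step per stance onset (0 -> 1 transition; a recording that begins in
#' stance counts that stance as a step).
#'
#' @param footswitch binary 0/1 vector.
#' @return integer step count.
#' @export
count_footswitch_steps <- function(footswitch) {
  assert_that(all(footswitch %in% c(0, 1)), "bad_footswitch",
              "footswitch values must be 0 or 1")
  sum(diff(c(0L, as.integer(footswitch))) == 1L)
}
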