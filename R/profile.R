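#' Time-normalize per-step envelopes onto a common gait-cycle grid
#'
#' Each segmented step is linearly resampled to \code{grid} points spanning
#' 0--100\% of the cycle, after which all steps notionally share the target
#' duration (the healthy cohort's mean step duration in the full pipeline).
#' Linear interpolation is adequate because the envelope is 4 Hz
#' band-limited.
#'
#' @param env an \code{envelope_signal} (or numeric vector).
#' @param seg a \code{step_segmentation}.
#' @param grid number of grid points G (default 1000, 0.1\% resolution).
#' @return numeric matrix, one row per step, G columns.
#' @export
time_normalize <- function(env, seg, grid = 1000) {
  values <- if (inherits(env, "envelope_signal")) env$values else env
  steps <- seg$steps
  out <- matrix(0, nrow = nrow(steps), ncol = grid)
  for (i in seq_len(nrow(steps))) {
    a <- steps[i, 1]
    b <- steps[i, 2]
    len <- b - a
    assert_that(len >= 2, "degenerate_step",
                "step %d has fewer than 2 samples", i)
    seg_vals <- values[a:(b - 1L)]
    out[i, ] <- stats::approx(seq(0, 1, length.out = len), seg_vals,
                              xout = seq(0, 1, length.out = grid))$y
  }
  out
}

#' Average steps and rescale to unit peak
#'
#' Pointwise mean across steps, then divided by its own maximum so the
#' profile peaks at 1. An identically-zero input stays all-zero (and is
#' flagged by attribute \code{"silent"}).
#'
#' @param step_matrix matrix from \code{\link{time_normalize}}.
#' @param muscle optional \code{channel_label}.
#' @param anchor cycle anchor tag ("TOE_OFF", "LOADING_RESPONSE" or
#'   "HEEL_STRIKE").
#' @return a \code{gait_cycle_profile}: values in [0, 1] on the grid,
#'   muscle, anchor and \code{n_steps_averaged}.
#' @export
average_and_scale <- function(step_matrix, muscle = NULL,
                              anchor = "TOE_OFF") {
  step_matrix <- rbind(step_matrix)
  assert_that(nrow(step_matrix) >= 1, "degenerate_step",
              "need at least one step")
  m <- colMeans(step_matrix)
  peak <- max(m)
  silent <- peak <= 0
  if (!silent) m <- m / peak
  structure(list(values = m, muscle = muscle, anchor = anchor,
                 n_steps_averaged = nrow(step_matrix), silent = silent),
            class = "gait_cycle_profile")
}

#' @export
print.gait_cycle_profile <- function(x, ...) {
  cat(sprintf("<gait_cycle_profile %s: G=%d, %d steps, anchor %s%s>\n",
              if (!is.null(x$muscle)) format(x$muscle) else "?",
              length(x$values), x$n_steps_averaged, x$anchor,
              if (isTRUE(x$silent)) ", silent" else ""))
  invisible(x)
}

#' Binary activation mask of a profile
#'
#' A grid point is "on" when the profile value strictly exceeds
#' \code{threshold_fraction} of the profile peak (40\% by default, the
#' conventional activation threshold for gait EMG); ties fall off. The
#' mask length equals the profile grid length.
#'
#' @param profile a \code{gait_cycle_profile} or numeric vector.
#' @param threshold_fraction fraction of peak, default 0.40.
#' @return an \code{activation_mask}: integer 0/1 vector \code{on},
#'   threshold used, grid length N.
#' @export
activation_mask <- function(profile, threshold_fraction = 0.40) {
  v <- if (inherits(profile, "gait_cycle_profile")) profile$values
       else as.numeric(profile)
  peak <- max(v)
  on <- if (peak <= 0) rep(0L, length(v))
        else as.integer(v > threshold_fraction * peak)
  structure(list(on = on, threshold_fraction = threshold_fraction,
                 N = length(v)),
            class = "activation_mask")
}

#' @export
print.activation_mask <- function(x, ...) {
  cat(sprintf("<activation_mask: N=%d, on %.1f%% of cycle (thr %g)>\n",
              x$N, 100 * mean(x$on), x$threshold_fraction))
  invisible(x)
}

#' Build a normative profile from healthy subjects
#'
#' Pointwise mean of the healthy subjects' per-muscle profiles, rescaled to
#' unit peak, with its 40\% activation mask. Stores the cohort's mean step
#' duration, to be used as the time-normalization target for patients.
#'
#' @param profiles list of \code{gait_cycle_profile}s, one per subject,
#'   same muscle, grid and anchor.
#' @param mean_step_duration cohort mean step duration in seconds.
#' @param threshold_fraction activation threshold, default 0.40.
#' @return a \code{normative_profile}: profile, mask, cohort_size,
#'   mean_step_duration.
#' @export
build_normative <- function(profiles, mean_step_duration = NA_real_,
                            threshold_fraction = 0.40) {
  assert_that(length(profiles) >= 1, "degenerate_step",
              "need at least one subject profile")
  g <- length(profiles[[1]]$values)
  anchor <- profiles[[1]]$anchor
  mus <- profiles[[1]]$muscle
  for (p in profiles) {
    assert_that(length(p$values) == g, "grid_mismatch",
                "profiles on different grids")
    assert_that(identical(p$anchor, anchor), "mixed_anchors",
                "profiles with different cycle anchors")
    if (!is.null(mus) && !is.null(p$muscle))
      assert_that(identical(p$muscle$muscle, mus$muscle), "mixed_muscles",
                  "profiles from different muscles")
  }
  m <- colMeans(do.call(rbind, lapply(profiles, `[[`, "values")))
  prof <- average_and_scale(matrix(m, nrow = 1), muscle = mus,
                            anchor = anchor)
  prof$n_steps_averaged <- length(profiles)
  structure(list(profile = prof,
                 mask = activation_mask(prof, threshold_fraction),
                 cohort_size = length(profiles),
                 mean_step_duration = mean_step_duration),
            class = "normative_profile")
}

#' Per-muscle gait-cycle profiles and masks for a recording
#'
#' Convenience wrapper running envelope extraction, time normalization,
#' averaging and masking for every channel under one segmentation.
#'
#' @param rec an \code{emg_recording}.
#' @param seg a \code{step_segmentation} of \code{rec}.
#' @param grid grid length G.
#' @param threshold_fraction activation threshold.
#' @return named list (by channel) of lists with \code{profile} and
#'   \code{mask}.
#' @export
recording_profiles <- function(rec, seg, grid = 1000,
                               threshold_fraction = 0.40) {
  envs <- recording_envelopes(rec)
  out <- lapply(names(envs), function(key) {
    mat <- time_normalize(envs[[key]], seg, grid = grid)
    prof <- average_and_scale(mat, muscle = envs[[key]]$source,
                              anchor = "TOE_OFF")
    list(profile = prof,
         mask = activation_mask(prof, threshold_fraction))
  })
  names(out) <- names(envs)
  out
}
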