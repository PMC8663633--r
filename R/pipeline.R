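#' Simulate a healthy cohort
#'
#' One synthetic recording per subject, independent seeds derived from
#' \code{seed}.
#'
#' @param n_subjects cohort size (default 7).
#' @param seed base RNG seed.
#' @param ... passed to \code{\link{simulate_recording}}.
#' @return list of \code{simulate_recording} results.
#' @export
simulate_healthy_cohort <- function(n_subjects = 7, seed = 1, ...) {
  lapply(seq_len(n_subjects), function(i)
    simulate_recording(seed = seed * 1000L + i,
                       subject_id = sprintf("H%02d", i),
                       group = "HEALTHY", ...))
}

#' Build per-muscle normative profiles from healthy recordings
#'
#' Segments each healthy recording from its right SOL, computes gait-cycle
#' profiles for the reference side, and averages across subjects per
#' muscle. The cohort's mean step duration is stored as the
#' time-normalization target for patients.
#'
#' @param recordings list of healthy \code{emg_recording}s.
#' @param side body side used for the normative profiles (default "R").
#' @param grid profile grid length.
#' @param threshold_fraction activation threshold, default 0.40.
#' @param ... passed to \code{\link{segment_recording}}.
#' @return named list (by muscle) of \code{normative_profile}s, plus
#'   attribute \code{"mean_step_duration"}.
#' @export
build_normative_set <- function(recordings, side = "R", grid = 1000,
                                threshold_fraction = 0.40, ...) {
  per_subject <- list()
  durations <- numeric(0)
  for (rec in recordings) {
    seg <- segment_recording(rec, ...)
    durations <- c(durations,
                   mean(seg$steps[, 2] - seg$steps[, 1]) / rec$sampling_rate)
    profs <- recording_profiles(rec, seg, grid = grid,
                                threshold_fraction = threshold_fraction)
    per_subject[[length(per_subject) + 1L]] <- profs
  }
  muscles <- intersect(MUSCLES, unique(vapply(
    recordings[[1]]$channels, function(ch) ch$muscle, "")))
  out <- lapply(muscles, function(mus) {
    key <- paste(side, mus, sep = "_")
    build_normative(lapply(per_subject, function(p) p[[key]]$profile),
                    mean_step_duration = mean(durations),
                    threshold_fraction = threshold_fraction)
  })
  names(out) <- muscles
  attr(out, "mean_step_duration") <- mean(durations)
  out
}

#' Gait Metric and BDSI of one recording against a normative set
#'
#' Runs segmentation, profiling and masking, then scores every requested
#' muscle of the given side against its normative profile.
#'
#' @param rec an \code{emg_recording}.
#' @param normatives named list of \code{normative_profile}s by muscle.
#' @param side body side to score (default "R").
#' @param grid profile grid length.
#' @param seg optional precomputed \code{step_segmentation}.
#' @param ... passed to \code{\link{segment_recording}}.
#' @return data frame: muscle, gm, gm_magnitude, gm_timing, bdsi, n_steps.
#' @export
pattern_indices <- function(rec, normatives, side = "R", grid = 1000,
                            seg = NULL, ...) {
  if (is.null(seg)) seg <- segment_recording(rec, ...)
  profs <- recording_profiles(rec, seg, grid = grid)
  rows <- lapply(names(normatives), function(mus) {
    key <- paste(side, mus, sep = "_")
    if (!key %in% names(profs)) return(NULL)
    g <- gait_metric(profs[[key]]$profile, profs[[key]]$mask,
                     normatives[[mus]])
    b <- bdsi(profs[[key]]$mask, normatives[[mus]]$mask)
    data.frame(muscle = mus, gm = g$gm, gm_magnitude = g$M,
               gm_timing = g$T, bdsi = b$bdsi,
               n_steps = nrow(seg$steps), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a result object as JSON
#'
#' Serializes any of the pipeline's result objects (profiles, masks,
#' coherence results, scores, index tables) to a JSON file.
#'
#' @param x object to serialize.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_result_json <- function(x, path) {
  if (inherits(x, c("gait_cycle_profile", "activation_mask", "gm_result",
                    "bdsi_result", "coherence_result", "capacity_score",
                    "capacity_change", "step_segmentation",
                    "synthetic_ground_truth")))
    x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}
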