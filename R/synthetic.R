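#' Muscle activation template
#'
#' Describes when in the gait cycle a muscle is active. Each burst window is
#' a (start, end) pair in percent of the cycle, heel-strike anchored; a
#' window may wrap past heel strike by giving \code{end > 100} (e.g.
#' \code{c(85, 110)} means 85--100\% wrapping into 0--10\% of the next
#' cycle). \code{tonic_floor} is the baseline activation off-burst as a
#' fraction of the burst peak; 0 means fully silent between bursts.
#'
#' @param muscle "TA", "SOL", "RF" or "ST".
#' @param burst_windows list of numeric (start, end) pairs, start in
#'   [0, 100), end > start, width at most 100.
#' @param burst_amplitudes relative peak per burst (max rescaled to 1).
#' @param tonic_floor baseline fraction in [0, 1).
#' @return a \code{muscle_template}.
#' @export
muscle_template <- function(muscle, burst_windows, burst_amplitudes = NULL,
                            tonic_floor = 0) {
  assert_that(muscle %in% MUSCLES, "unknown_muscle",
              "unknown muscle '%s'", muscle)
  if (is.null(burst_amplitudes))
    burst_amplitudes <- rep(1, length(burst_windows))
  assert_that(length(burst_amplitudes) == length(burst_windows),
              "invalid_template", "one amplitude per burst window required")
  assert_that(tonic_floor >= 0 && tonic_floor < 1, "invalid_template",
              "tonic_floor must be in [0, 1)")
  for (w in burst_windows) {
    assert_that(length(w) == 2L && w[1] >= 0 && w[1] < 100 && w[2] > w[1] &&
                  (w[2] - w[1]) <= 100, "invalid_template",
                "burst window must satisfy 0 <= start < 100 < start+width <= start+100")
  }
  if (max(burst_amplitudes) > 0)
    burst_amplitudes <- burst_amplitudes / max(burst_amplitudes)
  structure(list(muscle = muscle, burst_windows = burst_windows,
                 burst_amplitudes = burst_amplitudes,
                 tonic_floor = tonic_floor),
            class = "muscle_template")
}

#' Default healthy activation templates
#'
#' Plateau bursts with raised-cosine edges, heel-strike anchored, in the
#' physiological co-activation slots gait analysis exploits: TA through
#' swing and loading response (60\% wrapping to 12\%), SOL monophasic in
#' stance (10--50\%), RF in pre-swing (55--70\%) and from terminal swing
#' through loading (82\% wrapping to 15\%), ST from terminal swing into
#' early stance (85\% wrapping to 10\%). The RF and ST windows overlap
#' around heel strike, giving the terminal-swing co-activation slot used
#' for proximal intermuscular coherence.
#'
#' @return named list of \code{muscle_template}s.
#' @export
default_templates <- function() {
  list(
    TA  = muscle_template("TA",  list(c(60, 112))),
    SOL = muscle_template("SOL", list(c(10, 50))),
    RF  = muscle_template("RF",  list(c(55, 70), c(82, 115)),
                          burst_amplitudes = c(0.8, 1)),
    ST  = muscle_template("ST",  list(c(85, 110)))
  )
}

#' Common narrow-band drive between an agonist--antagonist pair
#'
#' Emulates a shared oscillatory neural drive: within the given gait-cycle
#' phase window, the broadband carriers of both muscles are amplitude
#' modulated by one narrow-band noise process. Because the analysis
#' rectifies the EMG before computing coherence, common amplitude
#' modulation is what surfaces as intermuscular coherence at the drive
#' frequency; \code{coupling} scales the modulation depth (coupling 1 =
#' modulation index 0.5).
#'
#' @param pair character vector of two muscles, e.g. \code{c("RF", "ST")}.
#' @param center_frequency Hz; must be below Nyquist.
#' @param coupling fraction in [0, 1]; 0 disables the drive.
#' @param bandwidth full bandwidth of the drive in Hz.
#' @param phase_window (start, end) percent of the heel-strike cycle where
#'   the drive is injected; end may exceed 100 to wrap.
#' @return a \code{common_drive} spec.
#' @export
common_drive <- function(pair, center_frequency, coupling,
                         bandwidth = 4, phase_window = c(85, 110)) {
  assert_that(all(pair %in% MUSCLES) && length(pair) == 2L, "invalid_drive",
              "pair must name two muscles")
  assert_that(coupling >= 0 && coupling <= 1, "invalid_drive",
              "coupling must be in [0, 1]")
  assert_that(center_frequency > 0, "invalid_drive",
              "center_frequency must be positive")
  structure(list(pair = pair, center_frequency = center_frequency,
                 coupling = coupling, bandwidth = bandwidth,
                 phase_window = phase_window),
            class = "common_drive")
}

#' @keywords internal
#' @noRd
render_template <- function(tpl, pct, taper = 0.25) {
  g <- rep(0, length(pct))
  for (b in seq_along(tpl$burst_windows)) {
    w <- tpl$burst_windows[[b]]
    amp <- tpl$burst_amplitudes[[b]]
    width <- w[2] - w[1]
    # position within the (possibly wrapped) burst, NA when outside
    u <- (pct - w[1]) %% 100 / width
    inside <- u >= 0 & u <= 1
    edge <- taper / 2
    shape <- rep(0, length(pct))
    shape[inside] <- 1
    lo <- inside & u < edge
    hi <- inside & u > 1 - edge
    shape[lo] <- 0.5 * (1 - cos(pi * u[lo] / edge))
    shape[hi] <- 0.5 * (1 - cos(pi * (1 - u[hi]) / edge))
    g <- pmax(g, amp * shape)
  }
  tpl$tonic_floor + (1 - tpl$tonic_floor) * pmin(g, 1)
}

#' @keywords internal
#' @noRd
bandlimited_noise <- function(n, fs, low, high) {
  x <- stats::rnorm(n)
  b <- signal::butter(3, c(low, high) / (fs / 2), type = "pass")
  y <- signal::filtfilt(b, x)
  y / stats::sd(y)
}

#' Simulate a gait-EMG recording with known ground truth
#'
#' Each channel is a smooth per-step activation envelope (rendered from its
#' \code{muscle_template}) multiplying a broadband carrier (Gaussian noise
#' band-limited to 20--450 Hz), optionally amplitude-modulated by shared
#' narrow-band drives within their phase windows, plus additive white
#' measurement noise. A footswitch channel is 1 during stance. Step
#' durations are jittered multiplicatively (lognormal), keeping them
#' positive. The returned ground truth records every step boundary, the
#' template activation windows, the drive specs, and the gait-cycle percent
#' at which SOL deactivates (the anchor offset linking the heel-strike
#' frame to the segmented-cycle frame).
#'
#' @param templates named list of \code{muscle_template}s (default
#'   \code{default_templates()}).
#' @param n_steps number of gait cycles (>= 1).
#' @param step_duration nominal cycle duration in seconds.
#' @param jitter lognormal sigma of the per-step duration multiplier
#'   (0.05 = ~5\% step-to-step variability).
#' @param drives list of \code{common_drive} specs.
#' @param noise_level additive white-noise SD as a fraction of burst peak.
#' @param seed integer RNG seed; identical seeds give identical recordings.
#' @param sides which body sides to synthesize.
#' @param fs sampling rate in samples/second.
#' @param stance_fraction fraction of the cycle with the foot on the ground.
#' @param subject_id,timepoint,group recording metadata.
#' @return list with \code{recording} (an \code{emg_recording}) and
#'   \code{truth} (a \code{synthetic_ground_truth}).
#' @export
simulate_recording <- function(templates = default_templates(),
                               n_steps = 20, step_duration = 1.1,
                               jitter = 0.05, drives = list(),
                               noise_level = 0.05, seed = 1,
                               sides = c("L", "R"), fs = 1000,
                               stance_fraction = 0.6,
                               subject_id = "SYN", timepoint = "T0",
                               group = "HEALTHY") {
  assert_that(n_steps >= 1, "invalid_template", "n_steps must be >= 1")
  assert_that(step_duration > 0, "invalid_template",
              "step_duration must be positive")
  for (d in drives)
    assert_that(d$center_frequency < fs / 2, "invalid_drive",
                "drive frequency above Nyquist")
  set.seed(as.integer(seed))
  mult <- if (jitter > 0) stats::rlnorm(n_steps, 0, jitter) else rep(1, n_steps)
  n_per_step <- round(step_duration * mult * fs)
  n_per_step[n_per_step < 2L] <- 2L
  boundaries <- cumsum(n_per_step)
  n_total <- boundaries[n_steps]
  step_of <- rep(seq_len(n_steps), n_per_step)
  start_of <- c(0L, boundaries[-n_steps])
  pct <- (seq_len(n_total) - 1L - start_of[step_of]) / n_per_step[step_of] * 100

  in_window <- function(w) {
    u <- (pct - w[1]) %% 100
    u <= (w[2] - w[1])
  }

  chans <- list()
  sigs <- list()
  for (side in sides) {
    # one narrow-band drive realization per spec per limb
    mods <- list()
    for (d in drives) {
      if (d$coupling <= 0) next
      half <- d$bandwidth / 2
      dn <- bandlimited_noise(n_total, fs,
                              max(0.5, d$center_frequency - half),
                              d$center_frequency + half)
      m <- 1 + (d$coupling / 2) * dn * in_window(d$phase_window)
      m[m < 0] <- 0
      for (mus in d$pair) {
        key <- mus
        mods[[key]] <- if (is.null(mods[[key]])) m else mods[[key]] * m
      }
    }
    for (mus in names(templates)) {
      g <- render_template(templates[[mus]], pct)
      carrier <- bandlimited_noise(n_total, fs, 20, 450)
      if (!is.null(mods[[mus]])) carrier <- carrier * mods[[mus]]
      x <- g * carrier + noise_level * stats::rnorm(n_total)
      chans <- c(chans, list(channel_label(side, mus)))
      sigs <- c(sigs, list(x))
    }
  }
  footswitch <- as.integer(pct < stance_fraction * 100)
  rec <- emg_recording(do.call(cbind, sigs), chans, sampling_rate = fs,
                       footswitch = footswitch, subject_id = subject_id,
                       timepoint = timepoint, group = group)
  sol_deact <- if ("SOL" %in% names(templates))
    max(vapply(templates$SOL$burst_windows, function(w) w[2] %% 100, 0))
  else NA_real_
  truth <- structure(list(
    step_boundaries = boundaries,
    step_starts = start_of + 1L,
    n_steps = n_steps,
    activation_windows = lapply(templates, function(t) t$burst_windows),
    tonic_floors = vapply(templates, function(t) t$tonic_floor, 0),
    drives = drives,
    sol_deactivation_pct = sol_deact,
    stance_fraction = stance_fraction,
    seed = seed), class = "synthetic_ground_truth")
  list(recording = rec, truth = truth)
}

#' Apply a stroke-like perturbation to activation templates
#'
#' Three qualitative impairment modes seen in hemiparetic gait:
#' \describe{
#'   \item{TONIC_ST}{the semitendinosus loses its activation/deactivation
#'     cycle and stays contracted through stance and swing: its
#'     \code{tonic_floor} is raised toward 1.}
#'   \item{SHIFTED_TIMING}{burst windows of every muscle are displaced
#'     around the cycle (up to 25\% of the cycle at severity 1).}
#'   \item{REDUCED_MODULATION}{the dynamic range between baseline and burst
#'     peak is compressed for every muscle.}
#' }
#' Severity 0 is the identity in all modes.
#'
#' @param templates named list of \code{muscle_template}s.
#' @param mode "TONIC_ST", "SHIFTED_TIMING" or "REDUCED_MODULATION".
#' @param severity in [0, 1].
#' @return perturbed template list.
#' @export
stroke_perturbation <- function(templates, mode, severity) {
  assert_that(severity >= 0 && severity <= 1, "invalid_template",
              "severity must be in [0, 1]")
  mode <- match.arg(mode, c("TONIC_ST", "SHIFTED_TIMING",
                            "REDUCED_MODULATION"))
  eps <- 0.02
  if (mode == "TONIC_ST") {
    if ("ST" %in% names(templates)) {
      f <- templates$ST$tonic_floor
      templates$ST$tonic_floor <- f + severity * (1 - eps - f)
    }
    return(templates)
  }
  if (mode == "SHIFTED_TIMING") {
    shift <- severity * 25
    for (m in names(templates)) {
      templates[[m]]$burst_windows <- lapply(
        templates[[m]]$burst_windows, function(w) {
          w <- w + shift
          if (w[1] >= 100) w <- w - 100
          w
        })
    }
    return(templates)
  }
  for (m in names(templates)) {
    f <- templates[[m]]$tonic_floor
    templates[[m]]$tonic_floor <- 1 - (1 - f) * (1 - severity * (1 - eps))
  }
  templates
}
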