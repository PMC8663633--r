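#' Frequency bands for intermuscular coherence
#'
#' Alpha 5--10 Hz (spinal drive), beta 15--30 Hz and gamma 30--45 Hz
#' (cortical drive). Bands are treated as closed intervals; at the 5 Hz
#' resolution of 200 ms epochs the 30 Hz bin therefore contributes to both
#' beta and gamma (configurable by passing custom bands).
#'
#' @return named list of (low, high) Hz pairs.
#' @export
coherence_bands <- function() {
  list(alpha = c(5, 10), beta = c(15, 30), gamma = c(30, 45))
}

#' Default gait-phase windows for coherence epochs
#'
#' Heel-strike-anchored percent ranges in which the two muscles of each
#' couple are expected to be simultaneously active: the initial part of
#' mid-stance for TA-SOL, and terminal swing wrapping through loading
#' response for RF-ST (ends above 100 wrap into the next cycle).
#'
#' @return named list of (start, end) percent pairs.
#' @export
coherence_phase_ranges <- function() {
  list(TA_SOL = c(10, 30), RF_ST = c(85, 110))
}

#' Extract phase-locked 200 ms epoch pairs for coherence
#'
#' For every segmented step, locates the earliest span of \code{duration}
#' seconds lying inside the requested gait-phase range during which both
#' muscles' activation masks are on for its entirety, and extracts that
#' span from the high-pass-filtered, full-wave-rectified signals (not the
#' 4 Hz envelope, which would annihilate the beta and gamma bands). Steps
#' without a qualifying span are skipped; if fewer than \code{min_steps}
#' steps qualify the couple has no usable co-activation slot and an error
#' of class \code{emgait_no_common_slot} is raised (the situation in which
#' participants had to be excluded from coherence analysis).
#'
#' @param rec an \code{emg_recording}.
#' @param seg a \code{step_segmentation} of \code{rec}.
#' @param masks named list of \code{activation_mask}s by channel name (as
#'   from \code{\link{recording_profiles}}).
#' @param pair two muscles, e.g. \code{c("TA", "SOL")}.
#' @param side "L" or "R".
#' @param phase_range (start, end) percent, heel-strike anchored; end may
#'   exceed 100 to wrap. Defaults per pair from
#'   \code{\link{coherence_phase_ranges}}.
#' @param duration epoch duration in seconds (default 0.2).
#' @param min_steps minimum qualifying steps for a valid estimate.
#' @return a \code{coherence_input}: epoch matrices \code{x} and \code{y}
#'   (one row per step), \code{L}, \code{fs}, pair and side.
#' @export
extract_epochs <- function(rec, seg, masks, pair, side = "R",
                           phase_range = NULL, duration = 0.2,
                           min_steps = 5) {
  assert_that(length(pair) == 2L && all(pair %in% MUSCLES), "missing_muscle",
              "pair must name two muscles")
  if (is.null(phase_range)) {
    phase_range <- if (all(pair %in% c("TA", "SOL")))
      coherence_phase_ranges()$TA_SOL else coherence_phase_ranges()$RF_ST
  }
  keys <- paste(side, pair, sep = "_")
  for (k in keys)
    assert_that(k %in% names(masks) && k %in% colnames(rec$samples),
                "missing_channel", "no channel/mask '%s'", k)
  mask_a <- masks[[keys[1]]]
  mask_b <- masks[[keys[2]]]
  if (!inherits(mask_a, "activation_mask")) mask_a <- mask_a$mask
  if (!inherits(mask_b, "activation_mask")) mask_b <- mask_b$mask
  G <- mask_a$N
  assert_that(mask_b$N == G, "grid_mismatch", "masks on different grids")
  fs <- rec$sampling_rate
  dn <- round(duration * fs)
  # phase range mapped from the heel-strike frame into the segmented frame
  rs <- (phase_range[1] - seg$anchor_offset_pct) %% 100
  re <- rs + (phase_range[2] - phase_range[1])
  hx <- abs(highpass_only(channel_signal(rec, keys[1]), fs))
  hy <- abs(highpass_only(channel_signal(rec, keys[2]), fs))
  joint <- mask_a$on == 1L & mask_b$on == 1L
  ex <- list()
  ey <- list()
  for (i in seq_len(nrow(seg$steps))) {
    a <- seg$steps[i, 1]
    b <- seg$steps[i, 2]
    len <- b - a
    if (len < dn) next
    pct <- (seq_len(len) - 1L) / len * 100
    gi <- pmin(G, floor(pct / 100 * G) + 1L)
    ok <- joint[gi] & pct >= rs & pct <= re
    # earliest start of a run of dn consecutive qualifying samples
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cand <- which(r$values & r$lengths >= dn)
    if (!length(cand)) next
    j <- a + starts[cand[1]] - 1L
    ex[[length(ex) + 1L]] <- hx[j:(j + dn - 1L)]
    ey[[length(ey) + 1L]] <- hy[j:(j + dn - 1L)]
  }
  assert_that(length(ex) >= min_steps, "no_common_slot",
              "only %d of %d steps have a common %g ms activation slot for %s-%s",
              length(ex), nrow(seg$steps), duration * 1000, pair[1], pair[2])
  coherence_input(do.call(rbind, ex), do.call(rbind, ey), fs = fs,
                  pair = pair, side = side)
}

#' Construct a coherence input from epoch matrices
#' @param x,y numeric matrices, one epoch per row, equal dimensions.
#' @param fs sampling rate.
#' @param pair,side metadata.
#' @return a \code{coherence_input}.
#' @export
coherence_input <- function(x, y, fs, pair = c("?", "?"), side = "?") {
  x <- rbind(x)
  y <- rbind(y)
  assert_that(all(dim(x) == dim(y)), "grid_mismatch",
              "epoch matrices differ in shape")
  assert_that(nrow(x) >= 2, "too_few_epochs",
              "need at least 2 epochs, got %d", nrow(x))
  structure(list(x = x, y = y, L = nrow(x), fs = fs, pair = pair,
                 side = side),
            class = "coherence_input")
}

#' 95\% confidence limit for multi-trial coherence
#'
#' Under independence, magnitude-squared coherence estimated from L
#' disjoint epochs exceeds 1 - 0.05^(1/(L-1)) with probability 0.05.
#' Strictly decreasing in L; equals 0.95 at L = 2.
#'
#' @param L number of epochs (>= 2).
#' @return the confidence limit in (0, 1).
#' @export
confidence_limit <- function(L) {
  assert_that(all(L >= 2), "domain_error", "L must be >= 2")
  1 - 0.05^(1 / (L - 1))
}

#' Magnitude-squared coherence from phase-locked epochs
#'
#' Multi-trial estimator: each epoch is one disjoint segment; per-segment
#' mean removal and a Hann taper, cross- and auto-spectra averaged over
#' the L segments, coherence(f) = |S_xy|^2 / (S_xx S_yy). With 200 ms
#' epochs the frequency resolution is 5 Hz.
#'
#' @param input a \code{coherence_input}.
#' @param taper "hann" or "none".
#' @param bands named list of (low, high) Hz pairs, default
#'   \code{\link{coherence_bands}}.
#' @return a \code{coherence_result}: \code{frequencies}, \code{coherence}
#'   per bin, \code{confidence_limit}, \code{band_areas},
#'   \code{band_significant}, \code{L}.
#' @export
coherence_spectrum <- function(input, taper = "hann",
                               bands = coherence_bands()) {
  taper <- match.arg(taper, c("hann", "none"))
  x <- input$x
  y <- input$y
  L <- nrow(x)
  n <- ncol(x)
  w <- if (taper == "hann")
    0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1))) else rep(1, n)
  sxx <- syy <- numeric(n)
  sxy <- rep(0 + 0i, n)
  for (l in seq_len(L)) {
    xf <- stats::fft((x[l, ] - mean(x[l, ])) * w)
    yf <- stats::fft((y[l, ] - mean(y[l, ])) * w)
    sxx <- sxx + Mod(xf)^2
    syy <- syy + Mod(yf)^2
    sxy <- sxy + xf * Conj(yf)
  }
  nb <- n %/% 2 + 1L
  freq <- (seq_len(nb) - 1L) * input$fs / n
  denom <- (sxx * syy)[seq_len(nb)]
  coh <- ifelse(denom > 0, Mod(sxy[seq_len(nb)])^2 / denom, 0)
  coh <- pmin(1, pmax(0, coh))
  cl <- confidence_limit(L)
  res <- structure(list(frequencies = freq, coherence = coh,
                        confidence_limit = cl, L = L, pair = input$pair,
                        side = input$side, bands = bands),
                   class = "coherence_result")
  res$band_areas <- vapply(bands, function(b) band_area(res, b), 0)
  res$band_significant <- vapply(bands, function(b)
    band_significant(res, b), FALSE)
  res
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence %s-%s (%s): L=%d, CL=%.3f>\n",
              x$pair[1], x$pair[2], x$side, x$L, x$confidence_limit))
  if (!is.null(x$band_areas)) {
    sig <- ifelse(x$band_significant, "*", "")
    cat(sprintf("  %s: area %.3f%s\n", names(x$band_areas),
                x$band_areas, sig), sep = "")
  }
  invisible(x)
}

#' Area under the coherence curve within a band
#'
#' Trapezoidal integral of the coherence over the frequency bins falling
#' in the closed band interval.
#'
#' @param result a \code{coherence_result}.
#' @param band (low, high) in Hz, or a band name from the result's bands.
#' @return area in coherence x Hz units.
#' @export
band_area <- function(result, band) {
  if (is.character(band)) band <- result$bands[[band]]
  sel <- which(result$frequencies >= band[1] & result$frequencies <= band[2])
  assert_that(length(sel) >= 2, "empty_band",
              "fewer than 2 frequency bins in [%g, %g] Hz", band[1], band[2])
  f <- result$frequencies[sel]
  c_ <- result$coherence[sel]
  sum(diff(f) * (c_[-1] + c_[-length(c_)]) / 2)
}

#' Is coherence significant anywhere within a band?
#'
#' TRUE iff at least one bin inside the closed band exceeds the 95\%
#' confidence limit. With \code{boundary = "exclude"} (the default) a bin
#' lying inside two adjacent bands (the 30 Hz bin is the upper edge of
#' beta and the lower edge of gamma at 5 Hz resolution) is excluded from
#' both bands' significance tests: a band-level claim should not hinge on
#' a bin it shares with its neighbour, and keeping each band's test to its
#' unambiguous bins keeps the per-band false-alarm rate in check. Band
#' areas, by contrast, always integrate the full closed interval
#' (\code{\link{band_area}}).
#'
#' @param result a \code{coherence_result}.
#' @param band (low, high) Hz or a band name.
#' @param boundary "exclude" (drop bins shared with another band) or
#'   "include" (test every bin in the closed interval).
#' @return logical.
#' @export
band_significant <- function(result, band, boundary = "exclude") {
  boundary <- match.arg(boundary, c("exclude", "include"))
  if (is.character(band)) band <- result$bands[[band]]
  sel <- which(result$frequencies >= band[1] & result$frequencies <= band[2])
  assert_that(length(sel) >= 1, "empty_band",
              "no frequency bins in [%g, %g] Hz", band[1], band[2])
  if (boundary == "exclude" && length(result$bands)) {
    others <- Filter(function(b) !identical(b, band), result$bands)
    shared <- vapply(result$frequencies[sel], function(f)
      any(vapply(others, function(b) f >= b[1] && f <= b[2], FALSE)), FALSE)
    if (!all(shared)) sel <- sel[!shared]
  }
  any(result$coherence[sel] > result$confidence_limit)
}

#' Equalize epoch counts between two timepoints
#'
#' Truncates both inputs to the smaller epoch count (earliest epochs kept)
#' so the confidence limits at T0 and T1 are identical and band
#' significance is comparable within subject.
#'
#' @param input_t0,input_t1 \code{coherence_input}s.
#' @return list with trimmed \code{t0} and \code{t1}.
#' @export
match_step_counts <- function(input_t0, input_t1) {
  L <- min(input_t0$L, input_t1$L)
  trim <- function(inp) {
    inp$x <- inp$x[seq_len(L), , drop = FALSE]
    inp$y <- inp$y[seq_len(L), , drop = FALSE]
    inp$L <- L
    inp
  }
  list(t0 = trim(input_t0), t1 = trim(input_t1))
}

#' Classify coherence change T0 -> T1 as a clinical improvement
#'
#' Alpha-band (spinal) coherence is physiologically present: improvement
#' means gaining significance (not significant at T0, significant at T1).
#' Beta- and gamma-band (cortical) coherence between antagonists is
#' pathological after stroke: improvement means losing significance
#' (significant at T0, not at T1).
#'
#' @param sig_t0,sig_t1 logical significance flags at the two timepoints.
#' @param band "alpha", "beta" or "gamma".
#' @return logical: improved or not.
#' @export
classify_improvement <- function(sig_t0, sig_t1, band) {
  band <- match.arg(band, c("alpha", "beta", "gamma"))
  if (band == "alpha") !sig_t0 && sig_t1 else sig_t0 && !sig_t1
}
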