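#' Gait Metric: similarity of a patient pattern to the normative pattern
#'
#' A scalar in [0, 1] combining a magnitude and a timing component.
#' The magnitude component M = A_in / (A_in + A_out) rewards EMG area
#' falling where the normative pattern is active (A_in) and penalizes area
#' where it is inactive (A_out); M = 0 when both areas are 0. The timing
#' component T is the fraction of the cycle where the patient's on/off
#' state matches the normative mask, so it rewards both in-phase activity
#' and joint silence. The default composition is the arithmetic mean
#' gm = (M + T) / 2; "product" and "geometric" compositions are available
#' for sensitivity checks. The metric is invariant to amplitude scaling of
#' the patient envelope.
#'
#' @param profile patient \code{gait_cycle_profile}.
#' @param mask patient \code{activation_mask}.
#' @param normative a \code{normative_profile} (or a list with a mask).
#' @param composition "mean" (default), "product" or "geometric".
#' @return a \code{gm_result}: \code{gm}, components \code{M} and \code{T},
#'   and the muscle id.
#' @export
gait_metric <- function(profile, mask, normative, composition = "mean") {
  composition <- match.arg(composition, c("mean", "product", "geometric"))
  nm <- if (inherits(normative, "normative_profile")) normative$mask
        else normative
  if (!inherits(nm, "activation_mask") && !is.null(nm$mask)) nm <- nm$mask
  v <- profile$values
  assert_that(length(v) == nm$N && mask$N == nm$N, "grid_mismatch",
              "patient and normative grids differ (%d, %d, %d)",
              length(v), mask$N, nm$N)
  on <- nm$on == 1L
  a_in <- sum(v[on])
  a_out <- sum(v[!on])
  M <- if (a_in + a_out > 0) a_in / (a_in + a_out) else 0
  Tm <- mean(mask$on == nm$on)
  gm <- switch(composition,
               mean = (M + Tm) / 2,
               product = M * Tm,
               geometric = sqrt(M * Tm))
  structure(list(gm = gm, M = M, T = Tm,
                 muscle = if (!is.null(profile$muscle))
                   format(profile$muscle) else NA_character_,
                 composition = composition),
            class = "gm_result")
}

#' @export
print.gm_result <- function(x, ...) {
  cat(sprintf("<GM %s: %.3f (M=%.3f, T=%.3f)>\n",
              x$muscle, x$gm, x$M, x$T))
  invisible(x)
}

#' Burst Duration Similarity Index
#'
#' Percentage of the gait cycle over which two activation patterns are in
#' the same state: BDSI = (sum(ON_timing) + sum(OFF_timing)) / N * 100,
#' where ON_timing marks grid points where both patterns are on and
#' OFF_timing where both are off. 100 means identical burst timing, 0
#' means the patterns are complementary everywhere.
#'
#' @param mask_patient,mask_normative \code{activation_mask}s on the same
#'   grid (plain 0/1 vectors are accepted).
#' @return a \code{bdsi_result}: \code{bdsi} in [0, 100],
#'   \code{on_matches}, \code{off_matches}, grid length \code{N}.
#' @export
bdsi <- function(mask_patient, mask_normative) {
  a <- if (inherits(mask_patient, "activation_mask")) mask_patient$on
       else as.integer(mask_patient)
  b <- if (inherits(mask_normative, "activation_mask")) mask_normative$on
       else as.integer(mask_normative)
  assert_that(length(a) == length(b), "grid_mismatch",
              "masks differ in length (%d vs %d)", length(a), length(b))
  n <- length(a)
  assert_that(n >= 1, "grid_mismatch", "empty masks")
  on_matches <- sum(a == 1L & b == 1L)
  off_matches <- sum(a == 0L & b == 0L)
  structure(list(bdsi = (on_matches + off_matches) / n * 100,
                 on_matches = on_matches, off_matches = off_matches, N = n),
            class = "bdsi_result")
}

#' @export
print.bdsi_result <- function(x, ...) {
  cat(sprintf("<BDSI %.2f (on %d + off %d of N=%d)>\n",
              x$bdsi, x$on_matches, x$off_matches, x$N))
  invisible(x)
}

#' Muscle-couple groupings used in cohort analysis
#' @return named list mapping group name to its two muscles.
#' @export
muscle_groups <- function() {
  list(PROXIMAL = c("RF", "ST"), DISTAL = c("TA", "SOL"),
       AGONISTS = c("RF", "SOL"), ANTAGONISTS = c("ST", "TA"))
}

#' Pool a per-muscle index over a muscle couple
#'
#' Unweighted mean of the two muscles' index values for the requested
#' couple: proximal (RF-ST), distal (TA-SOL), agonist (RF-SOL) or
#' antagonist (ST-TA).
#'
#' @param values named numeric vector of per-muscle index values (names
#'   "TA", "SOL", "RF", "ST").
#' @param grouping one of "PROXIMAL", "DISTAL", "AGONISTS", "ANTAGONISTS".
#' @return pooled value.
#' @export
group_index <- function(values, grouping) {
  grouping <- match.arg(grouping, names(muscle_groups()))
  members <- muscle_groups()[[grouping]]
  assert_that(all(members %in% names(values)), "missing_muscle",
              "grouping %s needs muscles %s", grouping,
              paste(members, collapse = ", "))
  mean(unlist(values[members]))
}
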