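#' Default clinical scale registry
#'
#' The six lower-limb scales entering the Capacity Score, each with its
#' admissible range, healthy reference and minimum detectable change (MDC).
#' For the four bounded scales the healthy reference is the maximum
#' achievable score; for the walk tests it is a literature value for
#' healthy adults (1.40 m/s comfortable speed for the 10 m walk test,
#' 500 m for the 6 min walk test), both overridable. MDCs: 7.84 points
#' (5-item Barthel), 12.92 points (Motricity Index), 0.11 m/s (10 m walk),
#' 60.98 m (6 min walk); for FAC and Trunk Control Test the MDC is the
#' minimum difference between two consecutive achievable scores.
#'
#' @return data frame with one row per scale: name, min, max,
#'   healthy_reference, mdc, units.
#' @export
scale_registry <- function() {
  data.frame(
    name = c("BARTHEL_5ITEM", "MOTRICITY_INDEX", "WALK_10M_SPEED",
             "WALK_6MIN_DISTANCE", "FAC", "TRUNK_CONTROL"),
    min = c(0, 0, 0, 0, 0, 0),
    max = c(55, 100, Inf, Inf, 5, 100),
    healthy_reference = c(55, 100, 1.40, 500, 5, 100),
    mdc = c(7.84, 12.92, 0.11, 60.98, 1, 1),
    units = c("points", "points", "m/s", "m", "category", "points"),
    stringsAsFactors = FALSE
  )
}

#' Construct a clinical assessment
#'
#' One subject at one timepoint: all six scale values, with range checks.
#'
#' @param subject_id subject identifier.
#' @param timepoint "T0" or "T1".
#' @param values named numeric vector or list covering every scale in the
#'   registry (10 m walk as m/s, 6 min walk as m, others raw scores).
#' @param registry scale registry, default \code{\link{scale_registry}}.
#' @return a \code{clinical_assessment}.
#' @export
clinical_assessment <- function(subject_id, timepoint, values,
                                registry = scale_registry()) {
  assert_that(timepoint %in% TIMEPOINTS, "bad_timepoint",
              "timepoint must be T0 or T1")
  values <- unlist(values)
  missing <- setdiff(registry$name, names(values))
  assert_that(length(missing) == 0, "missing_scale",
              "missing scale(s): %s", paste(missing, collapse = ", "))
  for (i in seq_len(nrow(registry))) {
    nm <- registry$name[i]
    v <- values[[nm]]
    assert_that(is.finite(v) && v >= registry$min[i] && v <= registry$max[i],
                "out_of_range", "%s = %g outside [%g, %g]", nm, v,
                registry$min[i], registry$max[i])
  }
  structure(list(subject_id = subject_id, timepoint = timepoint,
                 values = values[registry$name], registry = registry),
            class = "clinical_assessment")
}

#' Capacity Score: equal-weighted composite of six clinical scales
#'
#' In the default RATIO_TO_HEALTHY mode each scale contributes its value
#' divided by the healthy reference, so an assessment at the healthy
#' reference on every scale scores exactly 6 and complete impairment
#' scores 0. In MDC_UNITS mode each scale contributes its value in units
#' of its minimum detectable change, capped at the healthy reference; this
#' expresses the score in "detectable steps" rather than fractions of
#' normal. Components are equally weighted in both modes, and the score is
#' monotone non-decreasing in every scale value.
#'
#' @param a a \code{clinical_assessment}.
#' @param mode "RATIO_TO_HEALTHY" (default) or "MDC_UNITS".
#' @return a \code{capacity_score}: \code{score}, per-scale
#'   \code{components}, mode and the assessment.
#' @export
capacity_score <- function(a, mode = "RATIO_TO_HEALTHY") {
  mode <- match.arg(mode, c("RATIO_TO_HEALTHY", "MDC_UNITS"))
  reg <- a$registry
  v <- a$values
  comp <- if (mode == "RATIO_TO_HEALTHY") {
    v / reg$healthy_reference
  } else {
    pmin(v / reg$mdc, reg$healthy_reference / reg$mdc)
  }
  names(comp) <- reg$name
  structure(list(score = sum(comp), components = comp, mode = mode,
                 assessment = a),
            class = "capacity_score")
}

#' @export
print.capacity_score <- function(x, ...) {
  cat(sprintf("<capacity_score %s/%s: %.3f (%s)>\n",
              x$assessment$subject_id, x$assessment$timepoint, x$score,
              x$mode))
  invisible(x)
}

#' Functional change between two Capacity Scores
#'
#' T1 minus T0 composite change, plus per-scale raw deltas with a flag
#' marking scales whose absolute change reaches the minimum detectable
#' change (a real change beyond measurement error).
#'
#' @param t0,t1 \code{capacity_score}s of the same subject in the same
#'   mode.
#' @return a \code{capacity_change}: \code{delta}, per-scale
#'   \code{raw_deltas} and \code{detectable} flags.
#' @export
capacity_change <- function(t0, t1) {
  assert_that(identical(t0$assessment$subject_id, t1$assessment$subject_id),
              "subject_mismatch", "scores belong to different subjects")
  assert_that(identical(t0$mode, t1$mode), "subject_mismatch",
              "scores computed in different modes")
  reg <- t0$assessment$registry
  raw <- t1$assessment$values - t0$assessment$values
  structure(list(delta = t1$score - t0$score,
                 raw_deltas = raw,
                 detectable = abs(raw) >= reg$mdc,
                 subject_id = t0$assessment$subject_id),
            class = "capacity_change")
}

#' @export
print.capacity_change <- function(x, ...) {
  cat(sprintf("<capacity_change %s: %+0.3f; detectable: %s>\n",
              x$subject_id, x$delta,
              paste(names(x$detectable)[x$detectable], collapse = ", ")))
  invisible(x)
}
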