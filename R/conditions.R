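#' @keywords internal
#' @noRd
emgait_error <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("emgait_", class), "emgait_error")))
}

#' @keywords internal
#' @noRd
assert_that <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) emgait_error(class, msg, ...)
  invisible(TRUE)
}

MUSCLES <- c("TA", "SOL", "RF", "ST")
SIDES <- c("L", "R")
GROUPS <- c("CG", "EG", "HEALTHY")
TIMEPOINTS <- c("T0", "T1")
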