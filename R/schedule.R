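# Treatment schedules: time-windowed OV dose rate and CTLA-4 blockade.

#' Construct a treatment schedule
#'
#' A schedule applies a constant oncolytic-virus administration rate `s_dose`
#' (PFU/day) and a CTLA-4 blockade fraction `u_block` (dimensionless, in
#' \[0, 1\]) over the half-open calendar window
#' \[`start_day`, `start_day + duration`); outside the window both are zero.
#' The default window (day 8 for 5 days) matches the murine experiment the
#' model was validated against.
#'
#' @param s_dose OV administration rate while active, PFU/day (>= 0).
#' @param u_block CTLA-4 blockade fraction while active, in \[0, 1\].
#' @param start_day calendar day (post-implantation) treatment begins.
#' @param duration treatment length in days (>= 0).
#' @return An object of class `"ovt_schedule"`.
#' @examples
#' ovt_schedule(s_dose = 2e6, u_block = 0.76)
#' @export
ovt_schedule <- function(s_dose = 0, u_block = 0, start_day = 8,
                         duration = 5) {
  stopifnot(length(s_dose) == 1, length(u_block) == 1,
            length(start_day) == 1, length(duration) == 1)
  if (!is.finite(s_dose) || s_dose < 0) {
    stop("s_dose must be a finite nonnegative number", call. = FALSE)
  }
  if (!is.finite(u_block) || u_block < 0 || u_block > 1) {
    stop("u_block must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(duration) || duration < 0) {
    stop("duration must be >= 0", call. = FALSE)
  }
  structure(list(s_dose = as.numeric(s_dose), u_block = as.numeric(u_block),
                 start_day = as.numeric(start_day),
                 duration = as.numeric(duration)),
            class = "ovt_schedule")
}

#' Evaluate a schedule at a calendar time
#'
#' @param schedule an [ovt_schedule()].
#' @param t calendar day.
#' @return Named numeric vector `c(s = , u = )` giving the effective dose rate
#'   and blockade fraction at `t`.
#' @export
schedule_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "ovt_schedule"))
  active <- t >= schedule$start_day &
    t < schedule$start_day + schedule$duration
  c(s = if (active) schedule$s_dose else 0,
    u = if (active) schedule$u_block else 0)
}

#' @export
print.ovt_schedule <- function(x, ...) {
  cat(sprintf(
    "Treatment schedule: s = %g PFU/day, u = %g, days [%g, %g)\n",
    x$s_dose, x$u_block, x$start_day, x$start_day + x$duration))
  invisible(x)
}
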