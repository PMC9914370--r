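# Named validation scenarios, dose/blockade sweeps, single-parameter response
# curves, and bisection search for eradication thresholds.

.ovt_arms <- list(
  mock      = c(s = 0,   u = 0),
  ov        = c(s = 2e6, u = 0),
  ov_actla4 = c(s = 2e6, u = 0.76)
)

#' Define a treatment scenario
#'
#' The three built-in arms reproduce the validation experiment: `mock`
#' (carrier fluid), `ov` (2e6 PFU/day of oncolytic virus) and `ov_actla4`
#' (the same dose plus CTLA-4 blockade at fraction 0.76), all administered
#' over days 8-13 post-implantation. `custom` scenarios supply their own
#' schedule.
#'
#' @param name one of `"mock"`, `"ov"`, `"ov_actla4"`, `"custom"`.
#' @param schedule an [ovt_schedule()]; required for `"custom"`, otherwise
#'   derived from the arm.
#' @param overrides named list of parameter overrides applied to the baseline
#'   parameter set.
#' @param report_days calendar days at which the state is reported.
#' @return An object of class `"ovt_scenario"`.
#' @export
ovt_scenario <- function(name = c("mock", "ov", "ov_actla4", "custom"),
                         schedule = NULL, overrides = list(),
                         report_days = 18) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(schedule)) stop("custom scenarios need a schedule",
                                call. = FALSE)
  } else if (is.null(schedule)) {
    arm <- .ovt_arms[[name]]
    schedule <- ovt_schedule(s_dose = arm[["s"]], u_block = arm[["u"]],
                             start_day = 8, duration = 5)
  }
  if (length(overrides)) {
    bad <- setdiff(names(overrides), ovt_param_table()$name)
    if (length(bad)) stop("unknown parameter name(s) in overrides: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!length(report_days) || any(!is.finite(report_days))) {
    stop("report_days must be finite", call. = FALSE)
  }
  structure(list(name = name, schedule = schedule, overrides = overrides,
                 report_days = sort(unique(report_days))),
            class = "ovt_scenario")
}

#' Run a scenario and report states at its report days
#'
#' Simulates from day 8 with the validated initial state (4e7 susceptible
#' tumor cells, 250 CD8+ and CD4+ T cells, 1e4 NK cells).
#'
#' @param scenario an [ovt_scenario()] or an arm name.
#' @param ... solver options forwarded to [ovt_simulate()].
#' @return A data frame with one row per report day: `day` plus the nine
#'   compartments. The trajectory is attached as attribute `"trajectory"`.
#' @examples
#' run_scenario("ov")[["Tu"]]  # ~1.14e9 at day 18
#' @export
run_scenario <- function(scenario, ...) {
  if (is.character(scenario)) scenario <- ovt_scenario(scenario)
  stopifnot(inherits(scenario, "ovt_scenario"))
  params <- ovt_params(overrides = scenario$overrides)
  end <- max(scenario$report_days)
  if (min(scenario$report_days) < 8) {
    stop("report_days must be on/after the day-8 start", call. = FALSE)
  }
  traj <- ovt_simulate(params = params, schedule = scenario$schedule,
                       start_day = 8, end_day = end, ...)
  states <- t(vapply(scenario$report_days, function(d) state_at(traj, d),
                     numeric(9)))
  res <- data.frame(day = scenario$report_days, states)
  attr(res, "trajectory") <- traj
  res
}

# shared single-point runner used by all sweeps (same code path as
# run_scenario's ov_actla4 arm when s = 2e6, u = 0.76)
.tu_at_day <- function(s, u, day = 18, overrides = list(), ...) {
  sc <- ovt_scenario("custom",
                     schedule = ovt_schedule(s_dose = s, u_block = u,
                                             start_day = 8, duration = 5),
                     overrides = overrides, report_days = day)
  run_scenario(sc, ...)[["Tu"]][1]
}

#' Sweep the OV dose rate at fixed blockade
#'
#' One combined-therapy run per dose value, everything else at baseline;
#' reports the susceptible tumor size at the query day.
#'
#' @param s_values OV dose rates (PFU/day, >= 0).
#' @param u_fixed blockade fraction held fixed (default 0.76).
#' @param day report day (default 18).
#' @param ... solver options forwarded to [ovt_simulate()].
#' @return Data frame with columns `s`, `Tu`.
#' @export
dose_sweep <- function(s_values, u_fixed = 0.76, day = 18, ...) {
  if (any(s_values < 0)) stop("doses must be >= 0", call. = FALSE)
  data.frame(s = s_values,
             Tu = vapply(s_values, .tu_at_day, numeric(1), u = u_fixed,
                         day = day, ...))
}

#' Sweep the CTLA-4 blockade fraction at fixed OV dose
#'
#' @param u_values blockade fractions in \[0, 1\].
#' @param s_fixed OV dose rate held fixed (default 2e6 PFU/day).
#' @param day report day (default 18).
#' @param ... solver options forwarded to [ovt_simulate()].
#' @return Data frame with columns `u`, `Tu`.
#' @export
blockade_sweep <- function(u_values, s_fixed = 2e6, day = 18, ...) {
  if (any(u_values < 0 | u_values > 1)) {
    stop("blockade fractions must lie in [0, 1]", call. = FALSE)
  }
  data.frame(u = u_values,
             Tu = vapply(u_values, function(u) .tu_at_day(s_fixed, u,
                                                          day = day, ...),
                         numeric(1)))
}

#' Single-parameter response of the day-18 tumor size
#'
#' One combined-therapy run (s = 2e6, u = 0.76 unless overridden) per value,
#' with only the named parameter changed from baseline.
#'
#' @param param_name ASCII parameter name, e.g. `"gamma_c"`.
#' @param values parameter values to scan.
#' @param s_dose,u_block treatment applied days 8-13.
#' @param day report day (default 18).
#' @param ... solver options forwarded to [ovt_simulate()].
#' @return Data frame with columns `param`, `value`, `Tu`.
#' @export
parameter_response <- function(param_name, values, s_dose = 2e6,
                               u_block = 0.76, day = 18, ...) {
  if (!param_name %in% ovt_param_table()$name) {
    stop("unknown parameter name: ", param_name, call. = FALSE)
  }
  tu <- vapply(values, function(v) {
    ov <- stats::setNames(list(v), param_name)
    .tu_at_day(s_dose, u_block, day = day, overrides = ov, ...)
  }, numeric(1))
  data.frame(param = param_name, value = values, Tu = tu,
             stringsAsFactors = FALSE)
}

#' Bisection search for the eradication threshold
#'
#' Finds the minimal OV dose rate (or blockade fraction) for which the
#' susceptible tumor falls below one cell at the query day, holding the other
#' treatment variable fixed.
#'
#' @param free which variable to search over: `"s"` or `"u"`.
#' @param fixed_value the value of the other variable.
#' @param bounds length-2 interval bracketing the threshold: eradication must
#'   differ between the endpoints.
#' @param tol relative tolerance on the threshold (default 1e-3).
#' @param day evaluation day (default 18).
#' @param ... solver options forwarded to [ovt_simulate()].
#' @return The threshold estimate (numeric scalar) with attribute
#'   `"bracket"`, the final bracketing interval.
#' @export
eradication_search <- function(free = c("s", "u"), fixed_value, bounds,
                               tol = 1e-3, day = 18, ...) {
  free <- match.arg(free)
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  erad <- function(v) {
    if (free == "s") .tu_at_day(v, fixed_value, day = day, ...) < 1
    else .tu_at_day(fixed_value, v, day = day, ...) < 1
  }
  lo <- bounds[1]; hi <- bounds[2]
  e_lo <- erad(lo); e_hi <- erad(hi)
  if (e_lo == e_hi) {
    stop("eradication does not differ across the bounds; no bracket",
         call. = FALSE)
  }
  # treatment intensity is eradicating at the high end in all supported cases
  if (e_lo) stop("lower bound already eradicates; extend the bracket down",
                 call. = FALSE)
  while ((hi - lo) > tol * max(abs(hi), 1)) {
    mid <- (lo + hi) / 2
    if (erad(mid)) hi <- mid else lo <- mid
  }
  structure(hi, bracket = c(lo, hi))
}

#' Convert between cell counts and tumor volume
#'
#' Uses the reporting convention 1 cm^3 = 1e9 cells, i.e. 1 mm^3 = 1e6 cells.
#'
#' @param cells number of tumor cells.
#' @param mm3 tumor volume in cubic millimetres.
#' @return The converted quantity.
#' @export
cells_to_mm3 <- function(cells) cells / 1e6

#' @rdname cells_to_mm3
#' @export
mm3_to_cells <- function(mm3) mm3 * 1e6
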