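# Stiff integration of the tumor-immune system and day-indexed trajectory
# queries.

#' Integrate the tumor-immune model over a calendar horizon
#'
#' Integrates the nine-equation system with a variable-order BDF method (the
#' stiff ode15s analogue) from `start_day` to `end_day`. The treatment-window
#' boundaries are explicit integration breakpoints, so the discontinuity in
#' the dose terms never straddles a solver step. The output grid contains
#' every multiple of `grid_step` plus every integer day, giving exact (to
#' solver accuracy) day queries via [state_at()].
#'
#' @param params an [ovt_params()] vector.
#' @param schedule an [ovt_schedule()].
#' @param init initial state, see [ovt_init()]; must satisfy nonnegativity and
#'   `Tu + Ti <= K_t`.
#' @param start_day,end_day calendar horizon in days post-implantation
#'   (`end_day > start_day`).
#' @param rtol,atol relative and absolute solver tolerances.
#' @param hini initial step size hint; the default avoids the otherwise
#'   overly conservative automatic choice at segment starts.
#' @param grid_step spacing of the stored output grid in days.
#' @param x_prolif CD8+ proliferation form, see [ovt_rhs()].
#' @param compiled use the compiled right-hand side (default); the pure-R
#'   closure gives bitwise-comparable results and serves as a cross-check.
#' @return An object of class `"ovt_trajectory"`: a data frame with column
#'   `day` and the nine compartments, one row per grid point, carrying the
#'   schedule, parameters and solver options as attributes.
#' @examples
#' tr <- ovt_simulate(schedule = ovt_schedule(2e6, 0.76), end_day = 18)
#' state_at(tr, 18)[["Tu"]]
#' @export
ovt_simulate <- function(params = ovt_params(), schedule = ovt_schedule(),
                         init = ovt_init(Kt = params[["K_t"]]),
                         start_day = 8, end_day = 18,
                         rtol = 1e-8, atol = 1e-8, hini = 1e-6,
                         grid_step = 0.25,
                         x_prolif = c("antigen_only", "x_scaled"),
                         compiled = TRUE) {
  x_prolif <- match.arg(x_prolif)
  validate_ovt_params(params)
  stopifnot(inherits(schedule, "ovt_schedule"))
  if (!(end_day > start_day)) stop("end_day must exceed start_day",
                                   call. = FALSE)
  init <- validate_ovt_state(init, Kt = params[["K_t"]])
  p <- as.numeric(params[.ovt_param_table()$name])  # canonical order
  names(p) <- .ovt_param_table()$name
  xs <- (x_prolif == "x_scaled")
  deriv <- if (compiled) NULL else .ovt_make_deriv(p, x_scaled = xs)

  # breakpoints: window edges clipped to the horizon
  edges <- c(schedule$start_day, schedule$start_day + schedule$duration)
  edges <- edges[edges > start_day & edges < end_day]
  segs <- sort(unique(c(start_day, edges, end_day)))

  grid <- sort(unique(c(seq(start_day, end_day, by = grid_step),
                        seq(ceiling(start_day), floor(end_day), by = 1),
                        segs)))

  out <- matrix(NA_real_, nrow = length(grid), ncol = 9,
                dimnames = list(NULL, .ovt_state_names))
  out[1, ] <- as.numeric(init)
  y <- as.numeric(init)
  for (k in seq_len(length(segs) - 1)) {
    a <- segs[k]; b <- segs[k + 1]
    # evaluate s, u at the segment midpoint: constant within a segment
    su <- schedule_at(schedule, (a + b) / 2)
    s_seg <- su[["s"]]; u_seg <- su[["u"]]
    tt <- grid[grid >= a & grid <= b]
    if (tt[1] > a) tt <- c(a, tt)
    if (compiled) {
      sol <- deSolve::ode(y = y, times = tt, func = "ovt_derivs",
                          dllname = "ovtsim", initfunc = "ovt_initmod",
                          parms = c(p, s_seg, u_seg, as.numeric(xs)),
                          method = "bdf", rtol = rtol, atol = atol,
                          hini = hini, maxsteps = 500000)
    } else {
      f <- function(t, y, parms) {
        d <- deriv(y, s_seg, u_seg)
        if (any(!is.finite(d))) {
          stop("non-finite derivative at t = ", format(t), call. = FALSE)
        }
        list(d)
      }
      sol <- deSolve::ode(y = y, times = tt, func = f, parms = p,
                          method = "bdf", rtol = rtol, atol = atol,
                          hini = hini, maxsteps = 500000)
    }
    diagn <- attributes(sol)$istate
    if (!is.null(diagn) && diagn[1] < 0) {
      stop("stiff integration failed near t = ",
           format(sol[nrow(sol), 1]), " (solver state ", diagn[1], ")",
           call. = FALSE)
    }
    st <- sol[, -1, drop = FALSE]
    if (any(!is.finite(st))) {
      stop("non-finite state produced in segment [", a, ", ", b, "]",
           call. = FALSE)
    }
    idx <- match(round(sol[, 1], 10), round(grid, 10))
    keep <- !is.na(idx)
    out[idx[keep], ] <- st[keep, , drop = FALSE]
    y <- pmax(st[nrow(st), ], 0)  # clamp solver undershoot at the breakpoint
  }

  traj <- data.frame(day = grid, out, check.names = FALSE)
  attr(traj, "schedule") <- schedule
  attr(traj, "params") <- params
  attr(traj, "solver") <- list(method = "bdf", rtol = rtol, atol = atol,
                               hini = hini, grid_step = grid_step,
                               x_prolif = x_prolif)
  attr(traj, "params_hash") <- paste(
    formatC(as.numeric(params), digits = 17, format = "g"), collapse = ",")
  class(traj) <- c("ovt_trajectory", "data.frame")
  traj
}

#' Query a trajectory at a calendar day
#'
#' Exact at grid points; linear interpolation between them (the stored grid is
#' dense enough that interpolation error is below solver tolerance). Negative
#' solver undershoot within tolerance is clamped to zero at query time; the
#' stored trajectory keeps the raw solver output.
#'
#' @param traj an `ovt_trajectory`.
#' @param day calendar day within the simulated horizon.
#' @return Named state vector at `day`.
#' @export
state_at <- function(traj, day) {
  stopifnot(inherits(traj, "ovt_trajectory"))
  d <- traj$day
  if (length(day) != 1 || !is.finite(day) || day < d[1] - 1e-12 ||
      day > d[length(d)] + 1e-12) {
    stop("day must lie within [", d[1], ", ", d[length(d)], "]",
         call. = FALSE)
  }
  hit <- which(abs(d - day) < 1e-10)
  v <- if (length(hit)) {
    stats::setNames(as.numeric(traj[hit[1], .ovt_state_names]),
                    .ovt_state_names)
  } else {
    vapply(.ovt_state_names,
           function(nm) stats::approx(d, traj[[nm]], xout = day)$y,
           numeric(1))
  }
  ifelse(v < 0 & v > -1e-5, 0, v)  # within-tolerance undershoot only
}

#' Eradication test
#'
#' The tumor counts as eradicated when the susceptible compartment is below
#' one cell (strictly) at the queried day.
#'
#' @param traj an `ovt_trajectory`.
#' @param day calendar day within the horizon.
#' @return Logical: `Tu(day) < 1`.
#' @export
eradicated <- function(traj, day) {
  state_at(traj, day)[["Tu"]] < 1
}

#' @export
print.ovt_trajectory <- function(x, ...) {
  sc <- attr(x, "schedule")
  cat(sprintf(
    "Tumor-immune trajectory: day %g to %g (%d grid points)\n",
    x$day[1], x$day[nrow(x)], nrow(x)))
  print(sc)
  fin <- state_at(x, x$day[nrow(x)])
  cat(sprintf("Final state: Tu = %.5g, Ti = %.5g, V = %.5g, N = %.5g\n",
              fin[["Tu"]], fin[["Ti"]], fin[["V"]], fin[["N"]]))
  invisible(x)
}

#' @export
summary.ovt_trajectory <- function(object, ...) {
  days <- object$day[object$day == floor(object$day)]
  t(vapply(days, function(d) state_at(object, d), numeric(9))) |>
    (\(m) data.frame(day = days, m))()
}

#' Plot a trajectory
#'
#' All nine compartments on a log10 scale against calendar day.
#'
#' @param x an `ovt_trajectory`.
#' @param log10 plot log10(1 + value) instead of raw values.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ovt_trajectory <- function(x, log10 = TRUE, ...) {
  m <- as.matrix(x[, .ovt_state_names])
  if (log10) m <- log10(1 + pmax(m, 0))
  graphics::matplot(x$day, m, type = "l", lty = 1,
                    col = grDevices::hcl.colors(9, "Dark 3"),
                    xlab = "day post-implantation",
                    ylab = if (log10) "log10(1 + value)" else "value", ...)
  graphics::legend("topright", legend = .ovt_state_names, lty = 1, cex = 0.7,
                   col = grDevices::hcl.colors(9, "Dark 3"))
  invisible(x)
}
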