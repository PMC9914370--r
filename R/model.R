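# The nine-compartment tumor-immune ODE system, its tumor-free equilibrium
# and the local stability conditions.

.ovt_state_names <- c("Tu", "Ti", "V", "X", "Y", "C", "W", "Z", "N")

#' Initial state vector
#'
#' The nine model compartments: susceptible tumor cells `Tu`, infected tumor
#' cells `Ti`, free oncolytic virions `V` (PFU), CD8+ T cells `X`, CD4+ T
#' cells `Y`, IFN-gamma concentration `C` (pg/mL), CTLA-4 molecules `W`,
#' anti-viral immune cells `Z`, and natural killer cells `N`. Defaults are
#' the validated day-8 post-implantation state: a 40 mm^3 tumor (4e7 cells),
#' 250 CD8+ and CD4+ T cells each, 1e4 NK cells, everything else zero.
#'
#' @param Tu,Ti,V,X,Y,C,W,Z,N compartment values (all >= 0).
#' @param Kt tumor carrying capacity used to check `Tu + Ti <= Kt`.
#' @return Named numeric vector of length 9.
#' @export
ovt_init <- function(Tu = 4e7, Ti = 0, V = 0, X = 250, Y = 250,
                     C = 0, W = 0, Z = 0, N = 1e4, Kt = ovt_params()[["K_t"]]) {
  y <- c(Tu = Tu, Ti = Ti, V = V, X = X, Y = Y, C = C, W = W, Z = Z, N = N)
  validate_ovt_state(y, Kt = Kt)
  y
}

#' Validate a state vector
#'
#' @param state named numeric vector over the nine compartments.
#' @param Kt if non-`NULL`, additionally require `Tu + Ti <= Kt` (the
#'   initial-condition constraint).
#' @return `state`, invisibly; errors on violation, naming the component.
#' @export
validate_ovt_state <- function(state, Kt = NULL) {
  if (is.null(names(state)) || !all(.ovt_state_names %in% names(state))) {
    stop("state must be named over: ",
         paste(.ovt_state_names, collapse = ", "), call. = FALSE)
  }
  state <- state[.ovt_state_names]
  if (any(!is.finite(state))) {
    stop("non-finite state component(s): ",
         paste(names(state)[!is.finite(state)], collapse = ", "),
         call. = FALSE)
  }
  if (any(state < 0)) {
    stop("negative state component(s): ",
         paste(names(state)[state < 0], collapse = ", "), call. = FALSE)
  }
  if (!is.null(Kt) && state[["Tu"]] + state[["Ti"]] > Kt) {
    stop("Tu + Ti exceeds the carrying capacity K_t", call. = FALSE)
  }
  invisible(state)
}

# Rate-evaluation factory used inside the integrator. All 45 parameters are
# unpacked into closure locals once, so the per-step cost is pure scalar
# arithmetic. `y` is positional in .ovt_state_names order; small solver
# undershoots below zero are clamped for rate evaluation only.
.ovt_make_deriv <- function(p, x_scaled = FALSE) {
  env <- list2env(as.list(p), parent = environment())
  with(env, {
    function(y, s, u) {
      y <- pmax(y, 0)
      Tu <- y[1]; Ti <- y[2]; V <- y[3]; X <- y[4]; Y <- y[5]
      C <- y[6]; W <- y[7]; Z <- y[8]; N <- y[9]
      Tt <- Tu + Ti
      infect <- beta_t * Tu * V / (m_v + Tu)
      cd8_kill <- delta_x * X / (m_x + X)
      prolif <- a_x * Tt / (h_x + Tt)
      if (x_scaled) prolif <- prolif * X
      cfac <- 1 + nu * W
      avNV <- a_v * N * V
      dTu <- r_u * Tu * (1 - Tt / K_t) - infect -
        delta_c * Tu * C / (m_t + Tu) - cd8_kill * Tu - d_u * N * Tu
      dTi <- r_i * Ti * (1 - Tt / K_t) + infect - a_t * Ti -
        cd8_kill * Ti - delta_c * Ti * C / (m_t + Ti) -
        delta_z * Z * Ti - d_i * N * Ti
      dV <- b_t * a_t * Ti - delta_v * V * Z - gamma_v * V - d_v * N * V + s
      dX <- avNV + prolif - gamma_x * X
      dY <- avNV / cfac + a_y * Tt / ((h_y + Tt) * cfac) * C - gamma_y * Y
      dC <- alpha_n * Tt * N / (1 + b_n * W) +
        alpha_x * Tt * X / (1 + b_x * W) +
        alpha_y * Tt * Y / (1 + b_y * W) - gamma_c * C
      dW <- r_x * (1 - u) * X + r_y * (1 - u) * Y - gamma_w * W
      dZ <- p_v * Ti - gamma_z * Z
      dN <- s_n + r_n * N * (1 - N / K_n) * (Ti / (Ti + m_n)) +
        zeta * C * N / (C + h_n) - delta_n * Tt * N - gamma_n * N
      c(dTu, dTi, dV, dX, dY, dC, dW, dZ, dN)
    }
  })
}

# one-shot convenience wrapper (validation-free slow path)
.ovt_deriv <- function(y, p, s, u, x_scaled = FALSE) {
  .ovt_make_deriv(p, x_scaled)(y, s, u)
}

#' Right-hand side of the tumor-immune ODE system
#'
#' Evaluates the nine instantaneous per-day rates at time `t`, with the OV
#' dose rate `s` and the blockade fraction `u` taken from the schedule. The
#' CD8+ proliferation term is antigen-saturated,
#' `a_x (Tu+Ti)/(h_x + Tu + Ti)`; setting `x_prolif = "x_scaled"` multiplies
#' it by `X` (an alternative reading that does not reproduce the validation
#' data and is retained only for comparison).
#'
#' @param state named state vector (see [ovt_init()]).
#' @param t calendar time in days (>= 0).
#' @param params an [ovt_params()] vector.
#' @param schedule an [ovt_schedule()].
#' @param x_prolif `"antigen_only"` (default) or `"x_scaled"`; form of the
#'   CD8+ proliferation term.
#' @param clamp_tol components in `(-clamp_tol, 0)` are treated as 0 (stiff
#'   solvers may undershoot zero within tolerance); components below
#'   `-1000 * clamp_tol` raise an invalid-state error.
#' @return Named numeric vector of the nine rates.
#' @examples
#' ovt_rhs(ovt_init(), t = 8, ovt_params(), ovt_schedule(2e6, 0.76))
#' @export
ovt_rhs <- function(state, t, params = ovt_params(),
                    schedule = ovt_schedule(),
                    x_prolif = c("antigen_only", "x_scaled"),
                    clamp_tol = 1e-8) {
  x_prolif <- match.arg(x_prolif)
  if (length(t) != 1 || !is.finite(t)) stop("t must be a finite scalar",
                                            call. = FALSE)
  if (t < 0) stop("t precedes the simulation origin (t >= 0 days)",
                  call. = FALSE)
  if (is.null(names(state)) || !all(.ovt_state_names %in% names(state))) {
    stop("state must be named over: ",
         paste(.ovt_state_names, collapse = ", "), call. = FALSE)
  }
  y <- as.numeric(state[.ovt_state_names])
  if (any(!is.finite(y))) {
    stop("non-finite state component(s): ",
         paste(.ovt_state_names[!is.finite(y)], collapse = ", "),
         call. = FALSE)
  }
  if (any(y < -1000 * clamp_tol)) {
    stop("state component(s) below the clamping floor: ",
         paste(.ovt_state_names[y < -1000 * clamp_tol], collapse = ", "),
         call. = FALSE)
  }
  su <- schedule_at(schedule, t)
  d <- .ovt_deriv(y, params, su[["s"]], su[["u"]],
                  x_scaled = (x_prolif == "x_scaled"))
  stats::setNames(d, .ovt_state_names)
}

#' Tumor-free equilibrium
#'
#' With no OV administration the system has a unique tumor-free equilibrium:
#' every compartment zero except the NK cells at `N = s_n / gamma_n`.
#'
#' @param params an [ovt_params()] vector.
#' @return Named state vector of the equilibrium.
#' @examples
#' tumor_free_equilibrium(ovt_params())[["N"]]  # ~7.767e4
#' @export
tumor_free_equilibrium <- function(params = ovt_params()) {
  if (params[["gamma_n"]] <= 0) {
    stop("gamma_n must be > 0 for the tumor-free equilibrium", call. = FALSE)
  }
  e0 <- stats::setNames(numeric(9), .ovt_state_names)
  e0[["N"]] <- params[["s_n"]] / params[["gamma_n"]]
  e0
}

#' Local stability conditions of the tumor-free equilibrium
#'
#' The equilibrium is locally asymptotically stable when both strict
#' inequalities hold: the susceptible growth rate is below the NK killing
#' pressure at the equilibrium (`r_u < d_u * s_n / gamma_n`) and the infected
#' growth rate is below the infected death rate (`r_i < a_t`).
#'
#' @param params an [ovt_params()] vector.
#' @return List with logicals `stable`, `condition_growth_u`,
#'   `condition_growth_i`.
#' @examples
#' tumor_free_stability(ovt_params())$stable  # FALSE at baseline
#' @export
tumor_free_stability <- function(params = ovt_params()) {
  nbar <- tumor_free_equilibrium(params)[["N"]]
  cu <- params[["r_u"]] < params[["d_u"]] * nbar
  ci <- params[["r_i"]] < params[["a_t"]]
  list(stable = cu && ci, condition_growth_u = cu, condition_growth_i = ci)
}
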