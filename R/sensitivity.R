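# Global sensitivity analysis: Latin hypercube sampling over parameter
# ranges and partial rank correlation coefficients with a dummy-parameter
# significance floor.

#' Latin hypercube sample over parameter bounds
#'
#' Plain (maximin-free) LHS: each column is a random permutation of the n
#' equal-probability strata with uniform jitter inside each stratum, scaled
#' to the parameter bounds. Reproducible for a given seed.
#'
#' @param bounds data frame with columns `name`, `low`, `high` (one row per
#'   sampled parameter), e.g. from [ovt_param_bounds()].
#' @param n number of samples (>= 2).
#' @param seed RNG seed.
#' @return An object of class `"ovt_lhs"`: list with `parameter_names`,
#'   `bounds`, `samples` (an `n` x `p` matrix with named columns), `seed`,
#'   `n`.
#' @export
lhs_sample <- function(bounds, n, seed = 1) {
  stopifnot(is.data.frame(bounds), all(c("name", "low", "high") %in%
                                         names(bounds)))
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  degen <- bounds$low >= bounds$high
  if (any(degen)) {
    stop("degenerate bounds (low >= high) for: ",
         paste(bounds$name[degen], collapse = ", "),
         "; exclude these parameters from the design", call. = FALSE)
  }
  p <- nrow(bounds)
  set.seed(seed)
  unit <- lhs::randomLHS(n, p)
  samples <- sweep(unit, 2, bounds$high - bounds$low, `*`)
  samples <- sweep(samples, 2, bounds$low, `+`)
  colnames(samples) <- bounds$name
  structure(list(parameter_names = bounds$name, bounds = bounds,
                 samples = samples, seed = seed, n = n),
            class = "ovt_lhs")
}

# rank-transform with average ties, then residualize each column on all the
# others (plus intercept); PRCC_j = cor of the two residual vectors
.prcc_coefs <- function(X, y) {
  R <- apply(X, 2, rank, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  p <- ncol(R)
  vapply(seq_len(p), function(j) {
    Zj <- cbind(1, R[, -j, drop = FALSE])
    qr_j <- qr(Zj)
    rx <- qr.resid(qr_j, R[, j])
    rr <- qr.resid(qr_j, ry)
    stats::cor(rx, rr)
  }, numeric(1))
}

#' Partial rank correlation coefficients against a dummy floor
#'
#' For each sampled parameter, all columns and the output are rank-transformed
#' (average ranks on ties); the parameter ranks and the output ranks are each
#' regressed on all remaining parameter ranks, and the PRCC is the Pearson
#' correlation of the two residual vectors. A parameter is flagged significant
#' when its |PRCC| exceeds that of the dummy parameter, a sampled column with
#' no model effect.
#'
#' @param design an [lhs_sample()] design whose columns include the dummy.
#' @param outputs numeric vector of model outputs, one per design row. Rows
#'   with non-finite outputs are dropped listwise and counted.
#' @param dummy_name column name of the dummy parameter (default `"dummy"`).
#' @return An object of class `"ovt_prcc"`: data frame with columns
#'   `parameter`, `prcc`, `significant`, plus attributes `dummy_value`,
#'   `n_used`, `n_dropped`.
#' @export
prcc <- function(design, outputs, dummy_name = "dummy") {
  stopifnot(inherits(design, "ovt_lhs"))
  X <- design$samples
  if (length(outputs) != nrow(X)) {
    stop("outputs length must equal the design sample count", call. = FALSE)
  }
  ok <- is.finite(outputs)
  n_dropped <- sum(!ok)
  X <- X[ok, , drop = FALSE]
  y <- outputs[ok]
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2) {
    stop("insufficient samples: need n > p + 2 (n = ", n, ", p = ", p, ")",
         call. = FALSE)
  }
  const <- apply(X, 2, function(v) max(v) == min(v))
  if (any(const)) {
    stop("rank-degenerate (constant) column(s): ",
         paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  }
  co <- .prcc_coefs(X, y)
  names(co) <- colnames(X)
  if (!dummy_name %in% names(co)) {
    stop("design has no '", dummy_name, "' column", call. = FALSE)
  }
  dummy_value <- co[[dummy_name]]
  res <- data.frame(parameter = names(co), prcc = as.numeric(co),
                    significant = abs(co) > abs(dummy_value),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "dummy_value") <- dummy_value
  attr(res, "n_used") <- n
  attr(res, "n_dropped") <- n_dropped
  class(res) <- c("ovt_prcc", "data.frame")
  res
}

# parameters tied to the oncolytic virus itself: infection, burst, clearance,
# viral immunogenicity and the anti-viral response
.ovt_ov_params <- c("b_t", "gamma_v", "delta_v", "d_v", "a_v", "beta_t",
                    "m_v", "a_t", "p_v", "gamma_z")

#' Global sensitivity analysis of the day-18 tumor size
#'
#' Draws a Latin hypercube over the parameter ranges (published interval where
#' one exists, otherwise baseline/10 to 2 x baseline), appends a dummy column
#' on (0, 1), simulates each virtual subject from day 8 to the endpoint, and
#' returns PRCCs of the susceptible tumor size against every parameter.
#'
#' @param scenario `"ovt_only"` (s = 2e6, u = 0), `"combined"`
#'   (s = 2e6, u = 0.76), or `"ov_params_only"` (combined therapy, but only
#'   virus-related parameters are sampled; all others stay at baseline).
#' @param n virtual cohort size (default 500).
#' @param seed RNG seed for the hypercube.
#' @param day endpoint calendar day (default 18, i.e. 10 days of simulation).
#' @param rtol,atol solver tolerances for the cohort runs. Ranks are
#'   insensitive to integration error well below the spacing of outputs, so
#'   these default looser than single-run reporting tolerances.
#' @param max_fail_frac abort when more than this fraction of cohort runs
#'   fails (default 0.05).
#' @return An [prcc()] result with attributes `scenario`, `endpoint_day`,
#'   `seed`, `design`.
#' @examples
#' \donttest{
#' gsa <- gsa_run("combined", n = 100, seed = 1)
#' head(gsa[order(-abs(gsa$prcc)), ])
#' }
#' @export
gsa_run <- function(scenario = c("ovt_only", "combined", "ov_params_only"),
                    n = 500, seed = 1, day = 18, rtol = 1e-6, atol = 1e-6,
                    max_fail_frac = 0.05) {
  scenario <- match.arg(scenario)
  su <- switch(scenario,
               ovt_only = c(s = 2e6, u = 0),
               combined = ,
               ov_params_only = c(s = 2e6, u = 0.76))
  bounds <- ovt_param_bounds()
  if (scenario == "ov_params_only") {
    bounds <- bounds[bounds$name %in% .ovt_ov_params, ]
  }
  bounds <- rbind(bounds, data.frame(name = "dummy", low = 0, high = 1))
  design <- lhs_sample(bounds, n = n, seed = seed)

  sched <- ovt_schedule(s_dose = su[["s"]], u_block = su[["u"]],
                        start_day = 8, duration = 5)
  base <- ovt_params()
  outputs <- vapply(seq_len(n), function(i) {
    row <- design$samples[i, ]
    pars <- base
    nm <- setdiff(colnames(design$samples), "dummy")
    pars[nm] <- row[nm]
    tryCatch({
      tr <- ovt_simulate(params = pars, schedule = sched, start_day = 8,
                         end_day = day, rtol = rtol, atol = atol,
                         grid_step = 0.5)
      state_at(tr, day)[["Tu"]]
    }, error = function(e) NA_real_)
  }, numeric(1))

  n_fail <- sum(!is.finite(outputs))
  if (n_fail > max_fail_frac * n) {
    stop("too many failed cohort runs (", n_fail, "/", n, ")", call. = FALSE)
  }
  res <- prcc(design, outputs)
  attr(res, "scenario") <- scenario
  attr(res, "endpoint_day") <- day
  attr(res, "seed") <- seed
  attr(res, "design") <- design
  res
}

#' @export
print.ovt_prcc <- function(x, ...) {
  cat("PRCC sensitivity analysis")
  sc <- attr(x, "scenario")
  if (!is.null(sc)) cat(" (", sc, ", day ", attr(x, "endpoint_day"), ")",
                        sep = "")
  cat("\n  n =", attr(x, "n_used"), "used,", attr(x, "n_dropped"),
      "dropped; dummy PRCC =", signif(attr(x, "dummy_value"), 3), "\n")
  ord <- order(-abs(x$prcc))
  top <- utils::head(data.frame(x)[ord, ], 8)
  print(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot PRCC coefficients
#'
#' Horizontal bar chart ordered by |PRCC|, with the dummy-parameter floor
#' marked.
#'
#' @param x an `ovt_prcc` result.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ovt_prcc <- function(x, ...) {
  ord <- order(abs(x$prcc))
  graphics::barplot(x$prcc[ord], names.arg = x$parameter[ord], horiz = TRUE,
                    las = 1, cex.names = 0.6, xlab = "PRCC", ...)
  graphics::abline(v = c(-1, 1) * abs(attr(x, "dummy_value")), lty = 2)
  invisible(x)
}
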