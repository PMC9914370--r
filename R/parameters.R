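# Model parameterization: baseline values, plausible ranges, units.

# One row per model constant. `low`/`high` hold the published plausible range
# where a genuine interval exists; for point-valued parameters low == high ==
# baseline and sampling bounds fall back to (baseline/10, 2*baseline).
.ovt_param_table <- function() {
  tab <- read.csv(text = '
name,baseline,low,high,units,description
r_u,0.924,0.12,1.2,1/day,Uninfected tumor growth rate
K_t,3.3e9,1e8,9.7e9,cells,Tumor carrying capacity
beta_t,0.0038,0.0038,0.0038,cells/PFU/day,Infection rate of tumor cells by the oncolytic virus
m_v,1,1,1,cells,Half-saturation constant for tumor cell infection
delta_c,0.2,0.2,0.2,cells/day/(pg/mL),Tumor killing rate by cytokines
m_t,1e5,1e5,1e5,cells,Half-saturation constant for tumor killing by immune cells and cytokines
delta_x,2,0.0096,4.8,1/day,Lysis rate of tumor cells by CD8+ T cells
m_x,1e3,1e3,1e3,cells,Half-saturation constant of cytotoxic killing by CD8+ T cells
d_u,8.68e-10,8.68e-10,8.68e-10,1/cell/day,Killing rate of uninfected tumor cells by NK cells
r_i,0.924,0.12,1.2,1/day,Infected tumor growth rate
a_t,1,0.5,2.6667,1/day,Death rate of infected tumor cells
delta_z,1,0.0096,4.8,1/cell/day,Lysis rate of infected tumor cells by anti-viral immune cells
d_i,8.68e-10,8.68e-10,8.68e-10,1/cell/day,Killing rate of infected tumor cells by NK cells
b_t,1949,10,1949,PFU/cell,Viral burst size per lysed infected tumor cell
gamma_v,2.55,0.024,24,1/day,Viral clearance rate
delta_v,2.4e-4,2.4e-5,0.024,1/cell/day,Virus killing rate by anti-viral immune cells
d_v,0.12,0.024,48,1/cell/day,Killing rate of virions by NK cells
a_v,2e-6,2e-6,2e-6,1/PFU/day,T-cell recruitment rate through interactions with the virus
a_x,0.0375,2.4e-4,2.4,1/cell/day,Anti-tumor (CD8+) immune cell proliferation rate
h_x,40,40,1e5,cells,Half-saturation constant of tumor antigen-driven CD8+ proliferation
gamma_x,0.1,0.1,0.1,1/day,Death rate of CD8+ effector cells
nu,1e-3,1e-3,1e-3,1/molecule,Measure of CTLA-4 inhibition of CD4+ T-cell activation
a_y,0.09,2.4e-4,2.4,cells/day/(pg/mL),Proliferation rate of CD4+ (Th) cells
h_y,1e3,40,1e5,cells,Half-saturation constant for tumor detection by CD4+ T cells
gamma_y,0.1,0.1,0.1,1/day,Apoptosis rate of CD4+ (Th) cells
alpha_n,0.4,0.4,0.4,(pg/mL)/day/cell/cell,IFN-gamma production rate by NK cells
b_n,1e-3,1e-3,1e-3,1/molecule,CTLA-4-mediated inhibition of IFN-gamma produced by NK cells
alpha_x,9,9,9,(pg/mL)/day/cell/cell,IFN-gamma production rate by CD8+ T cells
b_x,1e-3,1e-3,1e-3,1/molecule,CTLA-4-mediated inhibition of IFN-gamma produced by CD8+ T cells
alpha_y,9,9,9,(pg/mL)/day/cell/cell,IFN-gamma production rate by CD4+ T cells
b_y,1e-3,1e-3,1e-3,1/molecule,CTLA-4-mediated inhibition of IFN-gamma produced by CD4+ T cells
gamma_c,34,34,34,1/day,Natural degradation rate of IFN-gamma
r_x,800,400,800,molecules/day/cell,CTLA-4 expression rate per CD8+ T cell
r_y,5000,2500,5000,molecules/day/cell,CTLA-4 expression rate per CD4+ T cell
gamma_w,8.3178,8.3178,8.3178,1/day,Degradation rate of CTLA-4
p_v,0.6,0.6,2.5,1/day,Proliferation rate of virus-specific immune cells
gamma_z,0.13296,0.13296,0.13296,1/day,Decay rate of anti-viral immune cells
s_n,3.2e3,3.2e3,3.2e4,cells/day,Constant influx of NK cells
r_n,1e-5,1e-5,1e-5,1/day,Recruitment rate of NK cells via immunogenic cell death
K_n,6.63e10,6.63e10,6.63e10,cells,Carrying capacity of the NK cell population
m_n,1e4,1e4,1e4,cells,Half-saturation constant of infected tumor cells for NK recruitment
delta_n,1e-7,1e-7,1e-7,1/cell/day,Inactivation rate of NK cells by tumor cells
zeta,0.5,0.5,0.5,1/day,Stimulation and recruitment rate of NK cells by IFN-gamma
h_n,3e2,3e2,3e2,pg/mL,Half-saturation constant for NK activation by cytokines
gamma_n,4.12e-2,4.12e-2,4.12e-2,1/day,Natural death rate of NK cells
', stringsAsFactors = FALSE, strip.white = TRUE)
  tab
}

# half-saturation constants that must stay strictly positive
.ovt_halfsat <- c("m_v", "m_t", "m_x", "h_x", "h_y", "m_n", "h_n")

#' Model parameter descriptions, baselines and plausible ranges
#'
#' Returns the full parameterization of the tumor-immune model as a data
#' frame: one row per parameter with its ASCII name, baseline value, the
#' published plausible range (equal to the baseline where only a point value
#' is available), units and a short description.
#'
#' @return A data frame with columns `name`, `baseline`, `low`, `high`,
#'   `units`, `description`.
#' @seealso [ovt_params()], [ovt_param_bounds()]
#' @export
ovt_param_table <- function() .ovt_param_table()

#' Construct a validated model parameter set
#'
#' Baseline values correspond to the murine B16 melanoma calibration of the
#' combined oncolytic-virotherapy / anti-CTLA-4 model. Any parameter can be
#' overridden by name; unknown names are rejected.
#'
#' @param ... named numeric overrides, e.g. `gamma_c = 68`.
#' @param overrides optional named list or named numeric vector of overrides,
#'   merged after `...`.
#' @return A named numeric vector of length 45 with class `"ovt_params"`.
#' @examples
#' p <- ovt_params()
#' p["gamma_c"]
#' p2 <- ovt_params(delta_c = 0.02)
#' @export
ovt_params <- function(..., overrides = NULL) {
  tab <- .ovt_param_table()
  p <- stats::setNames(tab$baseline, tab$name)
  ov <- c(list(...), as.list(overrides))
  if (length(ov)) {
    nm <- names(ov)
    if (is.null(nm) || any(nm == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    bad <- setdiff(nm, tab$name)
    if (length(bad)) {
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    vals <- vapply(ov, function(v) as.numeric(v)[1], numeric(1))
    p[nm] <- vals
  }
  validate_ovt_params(p)
  class(p) <- "ovt_params"
  p
}

#' Validate a parameter set
#'
#' Checks finiteness, nonnegativity, positivity of the carrying capacities and
#' of all half-saturation constants.
#'
#' @param p named numeric vector as produced by [ovt_params()].
#' @return `p`, invisibly; errors on violation.
#' @export
validate_ovt_params <- function(p) {
  tab <- .ovt_param_table()
  missing <- setdiff(tab$name, names(p))
  if (length(missing)) {
    stop("parameter set is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(p))) {
    stop("non-finite parameter value(s): ",
         paste(names(p)[!is.finite(p)], collapse = ", "), call. = FALSE)
  }
  if (any(p < 0)) {
    stop("negative parameter value(s): ",
         paste(names(p)[p < 0], collapse = ", "), call. = FALSE)
  }
  for (nm in c("K_t", "K_n", .ovt_halfsat)) {
    if (p[[nm]] <= 0) stop(nm, " must be > 0", call. = FALSE)
  }
  invisible(p)
}

#' Sampling bounds for global sensitivity analysis
#'
#' For parameters with a genuine published interval the interval is used;
#' point-valued parameters get (baseline/10, 2 x baseline), the convention
#' used for the virtual-cohort sensitivity analysis.
#'
#' @param params parameter set whose values replace the table baselines for
#'   the fallback rule (default: baseline set).
#' @return A data frame with columns `name`, `low`, `high`.
#' @export
ovt_param_bounds <- function(params = ovt_params()) {
  tab <- .ovt_param_table()
  low <- tab$low
  high <- tab$high
  point <- tab$low == tab$high
  b <- as.numeric(params[tab$name])
  low[point] <- b[point] / 10
  high[point] <- 2 * b[point]
  data.frame(name = tab$name, low = low, high = high,
             stringsAsFactors = FALSE)
}

#' @export
print.ovt_params <- function(x, ...) {
  tab <- .ovt_param_table()
  base <- stats::setNames(tab$baseline, tab$name)
  changed <- names(x)[as.numeric(x) != base[names(x)]]
  cat("Tumor-immune model parameter set (", length(x), " parameters)\n",
      sep = "")
  if (length(changed)) {
    cat("Non-baseline values:\n")
    for (nm in changed) {
      cat(sprintf("  %-8s %g (baseline %g)\n", nm, x[[nm]], base[[nm]]))
    }
  } else {
    cat("All parameters at baseline.\n")
  }
  invisible(x)
}

#' Read or write a parameter set as a plain-text config file
#'
#' The format is one `name: value` pair per line, ASCII parameter names
#' (e.g. `delta_c` for the cytokine killing rate). Lines that are empty or
#' start with `#` are ignored on read. Unknown keys are rejected.
#'
#' @param path file path.
#' @param params parameter set to write.
#' @return `read_params` returns an `ovt_params` vector; `write_params`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- grepl(":", lines, fixed = TRUE) & !grepl("^\\s*#", lines)
  kv <- strsplit(lines[keep], ":", fixed = TRUE)
  bad <- which(lengths(kv) != 2)
  if (length(bad)) {
    stop("cannot parse line ", which(keep)[bad[1]], ": ",
         lines[keep][bad[1]], call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2))))
  if (anyNA(vals)) {
    stop("non-numeric value for key '", keys[which(is.na(vals))[1]], "'",
         call. = FALSE)
  }
  ovt_params(overrides = stats::setNames(as.list(vals), keys))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  lines <- sprintf("%s: %s", names(params),
                   formatC(as.numeric(params), digits = 17, format = "g"))
  writeLines(lines, path)
  invisible(path)
}
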