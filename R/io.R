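# Run configuration files, result serialization and metadata sidecars.

.ovt_config_keys <- c("scenario", "s_dose", "u_block", "start_day",
                      "duration", "report_days", "rtol", "atol", "seed",
                      "out")

#' Build a validated run configuration
#'
#' With no fields set, the configuration reproduces the validation setting:
#' baseline parameters, mock arm, report day 18. Parameter overrides use the
#' ASCII names of [ovt_param_table()].
#'
#' @param scenario arm name (`"mock"`, `"ov"`, `"ov_actla4"`) or `"custom"`.
#' @param s_dose,u_block,start_day,duration schedule fields for custom runs
#'   (defaults: the named arm's schedule).
#' @param overrides named list of parameter overrides.
#' @param report_days days at which states are reported.
#' @param rtol,atol solver tolerances (> 0).
#' @param seed RNG seed recorded with outputs (the ODE pipeline itself is
#'   deterministic; only the LHS design consumes it).
#' @param out optional output path.
#' @return An object of class `"ovt_config"` (a validated list).
#' @export
ovt_config <- function(scenario = "mock", s_dose = NULL, u_block = NULL,
                       start_day = 8, duration = 5, overrides = list(),
                       report_days = 18, rtol = 1e-8, atol = 1e-8,
                       seed = 1, out = NULL) {
  if (!scenario %in% c(names(.ovt_arms), "custom")) {
    stop("unknown scenario '", scenario, "'", call. = FALSE)
  }
  if (scenario != "custom") {
    arm <- .ovt_arms[[scenario]]
    if (is.null(s_dose)) s_dose <- arm[["s"]]
    if (is.null(u_block)) u_block <- arm[["u"]]
  } else {
    if (is.null(s_dose)) s_dose <- 0
    if (is.null(u_block)) u_block <- 0
  }
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0", call. = FALSE)
  sched <- ovt_schedule(s_dose, u_block, start_day, duration)  # range checks
  if (length(overrides)) {
    bad <- setdiff(names(overrides), ovt_param_table()$name)
    if (length(bad)) stop("unknown parameter name(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(scenario = scenario, schedule = sched,
                 overrides = overrides,
                 report_days = sort(unique(report_days)),
                 rtol = rtol, atol = atol, seed = seed, out = out),
            class = "ovt_config")
}

#' Load a run configuration from a plain-text file
#'
#' Format: one `key: value` pair per line; `#` starts a comment. Recognized
#' keys are the [ovt_config()] fields (`report_days` comma-separated) plus any
#' parameter name, which becomes an override. Unknown keys are rejected with
#' the offending key named; an empty file yields the default configuration.
#'
#' @param path file path.
#' @return An `ovt_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  args <- list()
  overrides <- list()
  pnames <- ovt_param_table()$name
  for (i in keep) {
    kv <- strsplit(lines[i], ":", fixed = TRUE)[[1]]
    if (length(kv) != 2) {
      stop("parse error at line ", i, ": '", trimws(lines[i]), "'",
           call. = FALSE)
    }
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key %in% pnames) {
      overrides[[key]] <- as.numeric(val)
      if (is.na(overrides[[key]])) {
        stop("non-numeric value for parameter '", key, "' at line ", i,
             call. = FALSE)
      }
    } else if (key %in% .ovt_config_keys) {
      args[[key]] <- switch(key,
        scenario = val,
        out = val,
        report_days = as.numeric(strsplit(val, ",")[[1]]),
        as.numeric(val))
      if (key != "scenario" && key != "out" && anyNA(args[[key]])) {
        stop("non-numeric value for '", key, "' at line ", i, call. = FALSE)
      }
    } else {
      stop("unknown config key '", key, "' at line ", i, call. = FALSE)
    }
  }
  args$overrides <- overrides
  do.call(ovt_config, args)
}

#' Serialize a run configuration
#'
#' Writes a config that [load_config()] round-trips losslessly.
#'
#' @param config an `ovt_config`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ovt_config"))
  num <- function(x) formatC(x, digits = 17, format = "g")
  lines <- c(
    paste0("scenario: ", config$scenario),
    paste0("s_dose: ", num(config$schedule$s_dose)),
    paste0("u_block: ", num(config$schedule$u_block)),
    paste0("start_day: ", num(config$schedule$start_day)),
    paste0("duration: ", num(config$schedule$duration)),
    paste0("report_days: ", paste(num(config$report_days), collapse = ",")),
    paste0("rtol: ", num(config$rtol)),
    paste0("atol: ", num(config$atol)),
    paste0("seed: ", num(config$seed)))
  if (length(config$overrides)) {
    lines <- c(lines, sprintf("%s: %s", names(config$overrides),
                              num(unlist(config$overrides))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Execute a run configuration
#'
#' @param config an `ovt_config` (or a path to one).
#' @return The [run_scenario()] result, with the configuration attached.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "ovt_config"))
  sc <- ovt_scenario("custom", schedule = config$schedule,
                     overrides = config$overrides,
                     report_days = config$report_days)
  res <- run_scenario(sc, rtol = config$rtol, atol = config$atol)
  attr(res, "config") <- config
  res
}

# metadata sidecar written next to every output file
.write_sidecar <- function(path, extra = list()) {
  meta <- c(list(software = paste0("ovtsim ",
                                   as.character(utils::packageVersion("ovtsim"))),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            extra)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.traj_meta <- function(traj, seed = NULL) {
  sc <- attr(traj, "schedule")
  list(schedule = sc[c("s_dose", "u_block", "start_day", "duration")],
       solver = attr(traj, "solver"),
       parameters = as.list(attr(traj, "params")),
       seed = seed)
}

#' Write a trajectory as CSV
#'
#' Header `day,Tu,Ti,V,X,Y,C,W,Z,N`, one row per grid point, full double
#' precision (17 significant digits). A `<path>.meta.json` sidecar records the
#' parameters, schedule, solver options and seed.
#'
#' @param traj an `ovt_trajectory`.
#' @param path output CSV path.
#' @param seed optional seed to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, seed = NULL) {
  stopifnot(inherits(traj, "ovt_trajectory"))
  m <- as.matrix(traj[, c("day", .ovt_state_names)])
  lines <- c(paste(colnames(m), collapse = ","),
             apply(m, 1, function(r)
               paste(formatC(r, digits = 17, format = "g"), collapse = ",")))
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  .write_sidecar(path, .traj_meta(traj, seed))
  invisible(path)
}

#' Write a sweep table as CSV
#'
#' Header `param,value,Tu_day18`; one row per swept value.
#'
#' @param sweep a [dose_sweep()], [blockade_sweep()] or
#'   [parameter_response()] result.
#' @param path output CSV path.
#' @param param swept-quantity label; inferred from the table when absent.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path, param = NULL) {
  if (is.null(param)) {
    param <- if ("param" %in% names(sweep)) as.character(sweep$param[1])
             else intersect(c("s", "u", "value"), names(sweep))[1]
  }
  vcol <- intersect(c("s", "u", "value"), names(sweep))[1]
  lines <- c("param,value,Tu_day18",
             sprintf("%s,%s,%s", param,
                     formatC(sweep[[vcol]], digits = 17, format = "g"),
                     formatC(sweep$Tu, digits = 17, format = "g")))
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  .write_sidecar(path, list(rows = nrow(sweep)))
  invisible(path)
}

#' Write PRCC results as CSV
#'
#' Header `parameter,prcc,significant`; the sidecar records the scenario,
#' endpoint day, seed, cohort size and dummy PRCC.
#'
#' @param res an `ovt_prcc` result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_prcc <- function(res, path) {
  stopifnot(inherits(res, "ovt_prcc"))
  lines <- c("parameter,prcc,significant",
             sprintf("%s,%s,%s", res$parameter,
                     formatC(res$prcc, digits = 17, format = "g"),
                     res$significant))
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  .write_sidecar(path, list(scenario = attr(res, "scenario"),
                            endpoint_day = attr(res, "endpoint_day"),
                            seed = attr(res, "seed"),
                            n_used = attr(res, "n_used"),
                            n_dropped = attr(res, "n_dropped"),
                            dummy_prcc = attr(res, "dummy_value")))
  invisible(path)
}
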