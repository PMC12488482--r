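# YAML run configuration and the pinned CSV trace-table dialect
# (comma-separated, dot decimal, fixed header, %.17g numerics so that
# write -> read round-trips are exact).

#' Default run configuration
#'
#' The fully populated configuration used when a config file omits keys:
#' the published model constants, S = 3 with phosphatase onset at 4 h, the
#' default scenario suite (control, rapamycin at stimulation, phosphatase
#' inhibitor, CDH1-T129A), reporter mechanics defaults, population
#' settings, and the analysis windows/thresholds.
#'
#' @return Nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    model = unclass(kinetic_parameters()),
    protocols = list(
      control = list(),
      rapamycin_0h = list(rapamycin_time = 0),
      phosphatase_inhibitor = list(phosphatase_inhibitor_time = 0),
      t129a = list(cdh1_phospho_blocked = TRUE)
    ),
    reporter = list(synthesis_rate = 1, max_degradation_rate = 1,
                    mg132_time = NULL, initial_level = NULL),
    population = list(n_cells = 200, parameter_cv = 0.15, noise_sd = 0.05,
                      sampling_interval = 0.2, duration = 24,
                      generator_mode = "model_direct"),
    analysis = list(pre_window = c(1, 5), post_window_gap = 0.5,
                    post_window_span = 2, terminal_fraction = 0.5,
                    smooth_window = 5, min_prominence = NULL,
                    epsilon_fraction = 0.05, sustain_points = 3,
                    cdk2_threshold = 1),
    output_dir = "apcpulse_run",
    seed = 1L
  ), class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills every omitted key with its default
#' from [default_config()], and validates the result. Unknown keys are
#' rejected by name; invalid values (e.g. a negative time constant) fail
#' with the offending field named. An empty file yields the full default
#' configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user, path = "")
  validate_config(cfg)
  cfg
}

# Recursive default-filling merge; any key absent from the defaults is an
# error naming the full path. Protocols are user-named, so their children
# are validated against the stimulus_protocol fields instead.
merge_config <- function(defaults, user, path) {
  if (!is.list(user)) {
    stop(sprintf("config section `%s` must be a mapping", path), call. = FALSE)
  }
  out <- defaults
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (path == "protocols") {
      out[[key]] <- check_protocol_keys(user[[key]], full)
    } else if (!key %in% names(defaults) &&
               !(path == "" && key == "protocols")) {
      stop(sprintf("unknown config key `%s`", full), call. = FALSE)
    } else if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      out[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      out[[key]] <- user[[key]]
    }
  }
  if (path == "protocols") out <- out[names(user)] %||% out
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

check_protocol_keys <- function(proto, full) {
  allowed <- names(formals(stimulus_protocol))
  if (is.null(proto)) return(list())
  bad <- setdiff(names(proto), allowed)
  if (length(bad)) {
    stop(sprintf("unknown config key `%s.%s`", full, bad[1]), call. = FALSE)
  }
  proto
}

validate_config <- function(cfg) {
  do.call(kinetic_parameters, cfg$model)
  for (nm in names(cfg$protocols)) {
    do.call(stimulus_protocol, cfg$protocols[[nm]])
  }
  do.call(reporter_parameters, cfg$reporter)
  do.call(population_config, c(cfg$population, list(seed = cfg$seed)))
  an <- cfg$analysis
  if (an$epsilon_fraction <= 0) stop("`analysis.epsilon_fraction` must be > 0",
                                     call. = FALSE)
  if (an$sustain_points < 1) stop("`analysis.sustain_points` must be >= 1",
                                  call. = FALSE)
  if (anyDuplicated(names(cfg$protocols))) {
    stop("scenario names must be unique", call. = FALSE)
  }
  invisible(cfg)
}

trace_header <- c("cell_id", "scenario", "time_h", "channel", "value")

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a tidy trace table
#'
#' Trace tables are stored as comma-separated text with the fixed header
#' `cell_id,scenario,time_h,channel,value`, dot decimal separator and
#' full-precision (`%.17g`) numerics, so `read_traces(write_traces(x))`
#' reproduces `x` exactly, including row order. Per-cell truth metadata is
#' written to a `<path>.meta.csv` sidecar and re-attached on read.
#'
#' @param table A `trace_table` (see [generate_population()]).
#' @param path Output CSV path.
#' @return `write_traces()` returns `path` invisibly; `read_traces()`
#'   returns the `trace_table`.
#' @export
write_traces <- function(table, path) {
  lines <- c(paste(trace_header, collapse = ","),
             if (nrow(table) > 0L) {
               paste(table$cell_id, table$scenario, fmt_num(table$time_h),
                     table$channel, fmt_num(table$value), sep = ",")
             })
  writeLines(lines, path, useBytes = TRUE)
  info <- cell_info(table)
  if (!is.null(info)) {
    num <- vapply(info, is.numeric, logical(1))
    info_chr <- info
    for (j in which(num)) info_chr[[j]] <- fmt_num(info[[j]])
    utils::write.csv(info_chr, paste0(path, ".meta.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), trace_header)) {
    stop(sprintf("malformed trace header: expected `%s`, found `%s`",
                 paste(trace_header, collapse = ","),
                 paste(names(raw), collapse = ",")), call. = FALSE)
  }
  parse_numeric <- function(col, name) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !is.na(col))
    if (length(bad)) {
      stop(sprintf("non-numeric `%s` value on line %d of %s", name,
                   bad[1] + 1L, path), call. = FALSE)
    }
    v
  }
  tab <- tibble::tibble(cell_id = raw$cell_id, scenario = raw$scenario,
                        time_h = parse_numeric(raw$time_h, "time_h"),
                        channel = raw$channel,
                        value = parse_numeric(raw$value, "value"))
  meta_path <- paste0(path, ".meta.csv")
  info <- if (file.exists(meta_path)) {
    m <- utils::read.csv(meta_path, colClasses = "character",
                         check.names = FALSE)
    for (j in seq_along(m)) {
      v <- suppressWarnings(as.numeric(m[[j]]))
      if (!anyNA(v[!(m[[j]] %in% c("NA", ""))]) &&
          !names(m)[j] %in% c("cell_id", "scenario", "true_class")) {
        m[[j]] <- v
      }
    }
    tibble::as_tibble(m)
  } else NULL
  new_trace_table(tab, info)
}
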