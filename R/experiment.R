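# Experiment runner: model -> population generator -> analytics for each
# named scenario in a run configuration, with all outputs written as
# delimited text plus a JSON manifest.

#' Run a scenario suite end to end
#'
#' For every protocol named in `cfg$protocols`: simulates the model, writes
#' the trajectory (tidy `time_h,variable,value` CSV), generates the noisy
#' single-cell population, writes the trace table, and runs the per-cell
#' analytics. A cross-scenario summary (transient fractions, normalisation
#' to the control, divergence times of scenario medians against the
#' control median) and a JSON run manifest are written last. Every output
#' byte except the manifest timestamps is determined by (config, seed).
#'
#' @param cfg A `run_config` from [load_config()] / [default_config()].
#' @param control Name of the control scenario used for normalisation and
#'   divergence (default `"control"`; skipped if absent).
#' @return The manifest, invisibly (list: config echo, package version,
#'   seed, per-stage file list, timestamps).
#' @export
run_experiment <- function(cfg = default_config(), control = "control") {
  validate_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  params <- do.call(kinetic_parameters, cfg$model)
  rp <- do.call(reporter_parameters, cfg$reporter)
  started <- Sys.time()
  files <- character(0)
  tables <- list()
  analytics <- list()

  for (nm in names(cfg$protocols)) {
    protocol <- do.call(stimulus_protocol, cfg$protocols[[nm]])
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("scenario `%s`, stage %s: %s", nm, what,
                     conditionMessage(e)), call. = FALSE)
      })
    }
    traj <- stage("simulate",
                  iffl_simulate(params, protocol, t_end = cfg$population$duration,
                                output_dt = cfg$population$sampling_interval))
    traj_path <- file.path(cfg$output_dir, paste0("trajectory_", nm, ".csv"))
    td <- as.data.frame(traj)
    writeLines(c("time_h,variable,value",
                 paste(fmt_num(td$time_h), td$variable, fmt_num(td$value),
                       sep = ",")), traj_path, useBytes = TRUE)
    pop_cfg <- do.call(population_config,
                       c(cfg$population, list(seed = cfg$seed, scenario = nm)))
    tab <- stage("generate", generate_population(params, protocol, rp, pop_cfg))
    trace_path <- file.path(cfg$output_dir, paste0("traces_", nm, ".csv"))
    write_traces(tab, trace_path)
    an <- cfg$analysis
    res <- stage("analyze",
                 analyze_cells(tab, mg132_time = cfg$reporter$mg132_time,
                               min_prominence = an$min_prominence,
                               terminal_fraction = an$terminal_fraction,
                               smooth_window = an$smooth_window,
                               pre_window = an$pre_window))
    an_path <- file.path(cfg$output_dir, paste0("analytics_", nm, ".csv"))
    utils::write.csv(res, an_path, row.names = FALSE, quote = FALSE)
    files <- c(files, traj_path, trace_path, an_path)
    tables[[nm]] <- tab
    analytics[[nm]] <- res
  }

  summary_tab <- summarize_scenarios(analytics, tables, cfg,
                                     control = control)
  summary_path <- file.path(cfg$output_dir, "summary.csv")
  utils::write.csv(summary_tab, summary_path, row.names = FALSE, quote = FALSE)
  files <- c(files, summary_path)

  manifest <- list(
    package_version = as.character(utils::packageVersion("apcpulse")),
    seed = cfg$seed,
    config = unclass(cfg),
    files = files,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  tmp <- paste0(manifest_path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, null = "null",
                       pretty = TRUE, digits = NA)
  file.rename(tmp, manifest_path)
  invisible(manifest)
}

#' Cross-scenario summary table
#'
#' One row per scenario: transient fraction, transient fraction normalised
#' to the control, median percent inactivation (when slope-ratio analytics
#' were run), and the divergence time of the scenario median trace from
#' the control median (epsilon = `analysis.epsilon_fraction` of the control
#' dynamic range).
#'
#' @param analytics Named list of per-cell analytics tibbles
#'   ([analyze_cells()]).
#' @param tables Named list of the corresponding `trace_table`s.
#' @param cfg The `run_config` used.
#' @param control Control scenario name; must be present when more than
#'   one scenario is summarised.
#' @return Tibble with one row per scenario.
#' @export
summarize_scenarios <- function(analytics, tables, cfg, control = "control") {
  if (length(analytics) == 0L) stop("no analytics to summarize", call. = FALSE)
  have_control <- control %in% names(analytics)
  if (!have_control && length(analytics) > 1L) {
    stop(sprintf("control scenario `%s` missing; cannot normalize", control),
         call. = FALSE)
  }
  f_control <- if (have_control) {
    fraction_transient(analytics[[control]]$label)
  } else {
    fraction_transient(analytics[[1]]$label)
  }
  ctrl_median <- if (have_control) median_trace(tables[[control]]) else NULL
  eps <- if (!is.null(ctrl_median)) {
    cfg$analysis$epsilon_fraction * diff(range(ctrl_median$value))
  } else NA_real_

  rows <- lapply(names(analytics), function(nm) {
    res <- analytics[[nm]]
    f <- fraction_transient(res$label)
    div <- if (!is.null(ctrl_median) && nm != control) {
      m <- median_trace(tables[[nm]])
      divergence_time(ctrl_median$time_h, ctrl_median$value, m$value,
                      epsilon = eps,
                      sustain_points = cfg$analysis$sustain_points)$divergence_time
    } else NA_real_
    tibble::tibble(
      scenario = nm,
      n_cells = length(unique(res$cell_id)),
      fraction_transient = f,
      fraction_normalized = if (f_control > 0)
        normalize_to_control(f, f_control) else NA_real_,
      median_percent_inactivation = if ("percent_inactivation" %in% names(res))
        low_median(res$percent_inactivation) else NA_real_,
      divergence_vs_control_h = div)
  })
  do.call(rbind, rows)
}
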