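# Synthetic single-cell populations. One root seed; each cell draws from a
# substream seeded deterministically from (root seed, cell index), so the
# first k cells are identical whatever n_cells is.

#' Population generator settings
#'
#' Settings for synthesising a heterogeneous population of single-cell
#' biosensor traces sampled on the live-imaging cadence (one frame every
#' 12 min by default). Cell-to-cell variability is a lognormal
#' multiplicative scaling of the per-cell rates (unit mean, coefficient of
#' variation `parameter_cv`); measurement noise is multiplicative Gaussian,
#' truncated at zero.
#'
#' @param n_cells Number of cells (>= 1).
#' @param parameter_cv Coefficient of variation of per-cell lognormal rate
#'   scalings (default 0.15).
#' @param noise_sd Multiplicative measurement-noise SD as a fraction of the
#'   signal (default 0.05).
#' @param sampling_interval Hours between frames (default 0.2, i.e. 12 min).
#' @param duration Hours of imaging (default 24).
#' @param seed Integer root seed.
#' @param scenario Label tying the population to a stimulus protocol.
#' @param generator_mode `"model_direct"` emits the model substrate
#'   (geminin) variable scaled per cell -- the printed model has no MG132
#'   term, so MG132 is rejected in this mode; `"reporter_mechanics"` runs
#'   the constant-synthesis / APC-proportional-degradation reporter and
#'   supports MG132.
#' @return Object of class `population_config`.
#' @export
population_config <- function(n_cells = 200, parameter_cv = 0.15,
                              noise_sd = 0.05, sampling_interval = 0.2,
                              duration = 24, seed = 1,
                              scenario = "control",
                              generator_mode = c("model_direct",
                                                 "reporter_mechanics")) {
  generator_mode <- match.arg(generator_mode)
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  if (parameter_cv < 0) stop("`parameter_cv` must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (sampling_interval <= 0) stop("`sampling_interval` must be > 0",
                                   call. = FALSE)
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), parameter_cv = parameter_cv,
                 noise_sd = noise_sd, sampling_interval = sampling_interval,
                 duration = duration, seed = as.integer(seed),
                 scenario = scenario, generator_mode = generator_mode),
            class = "population_config")
}

# Deterministic per-cell substream seed (kept < 2^31).
cell_seed <- function(root_seed, cell_index) {
  as.integer((abs(as.numeric(root_seed)) * 7919 + cell_index * 104729) %%
               2147483647)
}

# Lognormal multiplier with unit mean and given coefficient of variation.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Multiplicative measurement noise
#'
#' Applies `value * (1 + eps)`, `eps ~ Normal(0, noise_sd)`, then truncates
#' at zero. Deterministic when `seed` is given.
#'
#' @param values Numeric trace values.
#' @param noise_sd Fractional noise SD (>= 0).
#' @param seed Optional integer seed.
#' @return Noisy values, same length.
#' @export
add_noise <- function(values, noise_sd, seed = NULL) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (noise_sd == 0) return(values)
  if (!is.null(seed)) set.seed(seed)
  pmax(0, values * (1 + stats::rnorm(length(values), 0, noise_sd)))
}

new_trace_table <- function(records, cell_info) {
  tab <- tibble::as_tibble(records)
  attr(tab, "cell_info") <- if (is.null(cell_info)) NULL else
    tibble::as_tibble(cell_info)
  class(tab) <- c("trace_table", class(tab))
  tab
}

#' Per-cell ground-truth metadata of a trace table
#'
#' @param table A `trace_table`.
#' @return Tibble with one row per cell: per-cell parameter draws and, for
#'   CDK2 populations, the true cycling label.
#' @export
cell_info <- function(table) {
  attr(table, "cell_info")
}

#' Generate a synthetic APC/C biosensor population
#'
#' Runs the feedforward-loop model once under `protocol`, then emits
#' `cfg$n_cells` noisy single-cell traces on the imaging grid. In
#' `model_direct` mode each cell is a lognormally scaled copy of the model
#' substrate (geminin) series; in `reporter_mechanics` mode each cell runs
#' the degron-reporter mechanics ([reporter_from_apc()]) with per-cell
#' synthesis and degradation rates, which is the mode that supports MG132
#' and slope-ratio experiments. Multiplicative measurement noise is applied
#' last. Identical (config, seed) gives identical output.
#'
#' @param params [kinetic_parameters()].
#' @param protocol [stimulus_protocol()].
#' @param rp [reporter_parameters()]; only used (and only allowed to carry
#'   `mg132_time`) in `reporter_mechanics` mode.
#' @param cfg [population_config()].
#' @return A `trace_table`: tibble with columns `cell_id`, `scenario`,
#'   `time_h`, `channel`, `value`; per-cell truth metadata via
#'   [cell_info()].
#' @export
generate_population <- function(params = kinetic_parameters(),
                                protocol = stimulus_protocol(),
                                rp = reporter_parameters(),
                                cfg = population_config()) {
  stopifnot(inherits(cfg, "population_config"))
  if (cfg$generator_mode == "model_direct" && !is.null(rp$mg132_time)) {
    stop(paste("MG132 has no representation in the substrate equation;",
               "use generator_mode = \"reporter_mechanics\""), call. = FALSE)
  }
  traj <- iffl_simulate(params, protocol, t_end = cfg$duration,
                        output_dt = cfg$sampling_interval)
  times <- traj$times
  n_t <- length(times)

  records <- vector("list", cfg$n_cells)
  info <- vector("list", cfg$n_cells)
  for (i in seq_len(cfg$n_cells)) {
    set.seed(cell_seed(cfg$seed, i))
    if (cfg$generator_mode == "model_direct") {
      scale <- rlnorm_cv(1, cfg$parameter_cv)
      clean <- scale * traj$state$geminin
      info[[i]] <- list(cell_id = sprintf("cell_%04d", i),
                        scenario = cfg$scenario, scale = scale,
                        synthesis_scale = NA_real_,
                        degradation_scale = NA_real_)
    } else {
      sc <- rlnorm_cv(2, cfg$parameter_cv)
      rp_i <- reporter_parameters(
        synthesis_rate = rp$synthesis_rate * sc[1],
        max_degradation_rate = rp$max_degradation_rate * sc[2],
        mg132_time = rp$mg132_time,
        initial_level = if (is.null(rp$initial_level)) NULL else
          rp$initial_level * sc[1] / sc[2])
      clean <- reporter_from_apc(times, traj$state$apc, rp_i)
      info[[i]] <- list(cell_id = sprintf("cell_%04d", i),
                        scenario = cfg$scenario, scale = NA_real_,
                        synthesis_scale = sc[1], degradation_scale = sc[2])
    }
    noisy <- add_noise(clean, cfg$noise_sd)
    records[[i]] <- tibble::tibble(
      cell_id = sprintf("cell_%04d", i), scenario = cfg$scenario,
      time_h = times, channel = "apc_reporter", value = noisy)
  }
  new_trace_table(do.call(rbind, records),
                  do.call(rbind, lapply(info, tibble::as_tibble)))
}

#' CDK2-trace generator settings
#'
#' Phenomenological shape for CDK2-activity biosensor traces: quiescent
#' cells sit at a low constant activity; cells entering the cycle follow a
#' saturating ramp from the quiescent level towards a plateau, starting at
#' a per-cell onset drawn from a (clamped) normal distribution.
#'
#' @param quiescent_level Activity of quiescent cells (default 0.5).
#' @param cycling_plateau Asymptotic activity of cycling cells (default 1.5).
#' @param rise_onset_mean,rise_onset_sd Hours; onset draw, clamped to keep
#'   the ramp observable within the trace (default mean 6, sd 2).
#' @param rise_rate 1/h ramp rate (default 1).
#' @param fraction_cycling_true Probability a cell is truly cycling
#'   (default 0.7).
#' @return Object of class `cdk2_parameters`.
#' @export
cdk2_parameters <- function(quiescent_level = 0.5, cycling_plateau = 1.5,
                            rise_onset_mean = 6, rise_onset_sd = 2,
                            rise_rate = 1, fraction_cycling_true = 0.7) {
  if (cycling_plateau <= quiescent_level) {
    stop("`cycling_plateau` must exceed `quiescent_level`", call. = FALSE)
  }
  if (fraction_cycling_true < 0 || fraction_cycling_true > 1) {
    stop("`fraction_cycling_true` must be in [0, 1]", call. = FALSE)
  }
  if (rise_rate <= 0) stop("`rise_rate` must be > 0", call. = FALSE)
  structure(list(quiescent_level = quiescent_level,
                 cycling_plateau = cycling_plateau,
                 rise_onset_mean = rise_onset_mean,
                 rise_onset_sd = rise_onset_sd,
                 rise_rate = rise_rate,
                 fraction_cycling_true = fraction_cycling_true),
            class = "cdk2_parameters")
}

#' Generate a synthetic CDK2-activity population
#'
#' Each cell is labelled cycling with probability
#' `cp$fraction_cycling_true`. Cycling cells ramp from the quiescent level
#' towards the plateau, `q + (p - q) * (1 - exp(-rate * (t - onset)))` for
#' `t >= onset`; quiescent cells stay flat. Noise as in
#' [generate_population()]; truth labels are stored in [cell_info()].
#'
#' @param cp [cdk2_parameters()].
#' @param cfg [population_config()].
#' @return A `trace_table` with channel `"cdk2_activity"`.
#' @export
generate_cdk2_population <- function(cp = cdk2_parameters(),
                                     cfg = population_config()) {
  stopifnot(inherits(cp, "cdk2_parameters"),
            inherits(cfg, "population_config"))
  times <- seq(0, cfg$duration, by = cfg$sampling_interval)
  onset_max <- max(0.5, cfg$duration - 6)
  records <- vector("list", cfg$n_cells)
  info <- vector("list", cfg$n_cells)
  for (i in seq_len(cfg$n_cells)) {
    set.seed(cell_seed(cfg$seed, i))
    cycling <- stats::runif(1) < cp$fraction_cycling_true
    onset <- min(onset_max, max(0.5, stats::rnorm(1, cp$rise_onset_mean,
                                                  cp$rise_onset_sd)))
    clean <- if (cycling) {
      cp$quiescent_level + (cp$cycling_plateau - cp$quiescent_level) *
        (1 - exp(-cp$rise_rate * pmax(0, times - onset)))
    } else {
      rep(cp$quiescent_level, length(times))
    }
    noisy <- add_noise(clean, cfg$noise_sd)
    records[[i]] <- tibble::tibble(
      cell_id = sprintf("cell_%04d", i), scenario = cfg$scenario,
      time_h = times, channel = "cdk2_activity", value = noisy)
    info[[i]] <- list(cell_id = sprintf("cell_%04d", i),
                      scenario = cfg$scenario,
                      true_class = if (cycling) "cycling" else "quiescent",
                      rise_onset = if (cycling) onset else NA_real_)
  }
  new_trace_table(do.call(rbind, records),
                  do.call(rbind, lapply(info, tibble::as_tibble)))
}
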