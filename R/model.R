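# Five-variable incoherent feedforward loop:
#   mitogens -> mTOR (fast) -| APC/C via pCDH1
#   mitogens -> PP   (delayed) -> dephosphorylates CDH1, reactivating APC/C
# Every drive is a Hill fraction, every variable relaxes first-order, so the
# dynamics map [0,1]^5 into itself.

# Drive regime at time t: which inputs are switched on. Kept separate from
# the rate function so the integrator can freeze a regime per smooth segment.
protocol_regime <- function(protocol, t) {
  list(
    mitogen_on = t >= protocol$mitogen_onset,
    pp_on = t >= protocol$pp_onset_time &&
      (is.null(protocol$phosphatase_inhibitor_time) ||
         t < protocol$phosphatase_inhibitor_time),
    rapamycin_on = !is.null(protocol$rapamycin_time) &&
      t >= protocol$rapamycin_time,
    pcdh1_blocked = isTRUE(protocol$cdh1_phospho_blocked)
  )
}

iffl_rates <- function(state, params, protocol, regime) {
  p <- params
  S <- if (regime$mitogen_on) protocol$mitogen_level else 0
  mtor_drive <- if (regime$rapamycin_on) 0 else hill_up(S, p$k1, p$n1)
  pp_drive <- if (regime$pp_on) hill_up(S, p$k2, p$n2) else 0
  pcdh1_drive <- if (regime$pcdh1_blocked) 0 else
    hill_up(state[["mtor"]], p$k3, p$n3) * hill_down(state[["pp"]], p$k4, p$n4)
  c(mtor = (mtor_drive - state[["mtor"]]) / p$tau_mtor,
    pp = (pp_drive - state[["pp"]]) / p$tau_pp,
    pcdh1 = (pcdh1_drive - state[["pcdh1"]]) / p$tau_pcdh1,
    apc = (hill_down(state[["pcdh1"]], p$k5, p$n5) - state[["apc"]]) / p$tau_apc,
    geminin = (hill_down(state[["apc"]], p$k6, p$n6) - state[["geminin"]]) /
      p$tau_geminin)
}

#' Instantaneous rates of the feedforward-loop model
#'
#' Evaluates the right-hand side of the five ODEs at time `t` under a given
#' protocol. Drive switches (mitogen onset, phosphatase onset, rapamycin,
#' phosphatase inhibitor) use the half-open convention: a switch at time
#' `t0` is active for all `t >= t0`.
#'
#' @param state Named numeric state (see [iffl_state()]).
#' @param t Time in hours (>= 0).
#' @param params [kinetic_parameters()].
#' @param protocol [stimulus_protocol()].
#' @return Named numeric vector of rates (1/h) for mtor, pp, pcdh1, apc,
#'   geminin.
#' @examples
#' iffl_derivatives(initial_state(), 0, kinetic_parameters(),
#'                  stimulus_protocol())
#' @export
iffl_derivatives <- function(state, t, params, protocol) {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(protocol, "stimulus_protocol"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("`t` must be a single non-negative time in hours", call. = FALSE)
  }
  state <- as_state_vector(state)
  iffl_rates(state, params, protocol, protocol_regime(protocol, t))
}

as_state_vector <- function(state) {
  vars <- c("mtor", "pp", "pcdh1", "apc", "geminin")
  s <- unclass(state)
  if (is.null(names(s)) && length(s) == 5L) names(s) <- vars
  if (!all(vars %in% names(s))) {
    stop("state must have components mtor, pp, pcdh1, apc, geminin",
         call. = FALSE)
  }
  if (any(!is.finite(s[vars]))) stop("state components must be finite",
                                     call. = FALSE)
  s[vars]
}

#' Simulate the feedforward-loop model
#'
#' Integrates the five ODEs with LSODA (via \pkg{deSolve}), piecewise
#' between drive discontinuities: the time axis is segmented at mitogen
#' onset, phosphatase onset, rapamycin addition and phosphatase-inhibitor
#' addition, and each smooth segment is integrated separately so the
#' adaptive solver never steps across a switch. Output is reported on a
#' uniform grid.
#'
#' @param params [kinetic_parameters()].
#' @param protocol [stimulus_protocol()].
#' @param initial Initial state, default [initial_state()].
#' @param t_end End of the simulation, hours.
#' @param output_dt Output grid spacing, hours (default 0.05; use 0.2 to
#'   match the 12-min imaging cadence when feeding the trace generator).
#' @param rtol,atol Solver tolerances.
#' @return An `iffl_trajectory`: list with `times` (hours), `state` (a
#'   data frame with columns mtor, pp, pcdh1, apc, geminin aligned to
#'   `times`), and the `params`/`protocol` used.
#' @examples
#' traj <- iffl_simulate(kinetic_parameters(), stimulus_protocol(),
#'                       t_end = 12)
#' min(traj$state$apc)  # transient partial APC/C inactivation
#' @export
iffl_simulate <- function(params = kinetic_parameters(),
                          protocol = stimulus_protocol(),
                          initial = initial_state(),
                          t_end = 24, output_dt = 0.05,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(protocol, "stimulus_protocol"))
  if (t_end <= 0) stop("`t_end` must be > 0", call. = FALSE)
  if (output_dt <= 0 || output_dt > t_end) {
    stop("`output_dt` must be in (0, t_end]", call. = FALSE)
  }
  y0 <- as_state_vector(initial)
  grid <- seq(0, t_end, by = output_dt)

  events <- c(protocol$mitogen_onset, protocol$pp_onset_time,
              protocol$rapamycin_time, protocol$phosphatase_inhibitor_time)
  breaks <- sort(unique(c(0, events[events > 0 & events < t_end], t_end)))

  out_times <- numeric(0)
  out_state <- NULL
  y <- y0
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]
    b <- breaks[i + 1L]
    regime <- protocol_regime(protocol, (a + b) / 2)
    if (regime$rapamycin_on && protocol$rapamycin_mode == "clamp" &&
        !is.null(protocol$rapamycin_time) && a >= protocol$rapamycin_time) {
      y[["mtor"]] <- 0
    }
    seg_grid <- grid[grid > a + 1e-12 & grid <= b + 1e-12]
    seg_times <- sort(unique(c(a, seg_grid, b)))
    rhs <- function(t, y, parms) list(iffl_rates(y, params, protocol, regime))
    sol <- deSolve::ode(y = y, times = seg_times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (any(!is.finite(sol)) || nrow(sol) < length(seg_times)) {
      stop(sprintf(
        "ODE integration failed on segment [%g, %g] h: %s", a, b,
        paste(utils::capture.output(deSolve::diagnostics(sol)), collapse = "\n")),
        call. = FALSE)
    }
    keep <- sol[, 1] %in% seg_grid | (i == 1L & sol[, 1] == 0)
    out_times <- c(out_times, sol[keep, 1])
    out_state <- rbind(out_state, sol[keep, -1, drop = FALSE])
    y <- sol[nrow(sol), -1]
  }
  dup <- duplicated(out_times)
  structure(list(times = out_times[!dup],
                 state = as.data.frame(out_state[!dup, , drop = FALSE]),
                 params = params, protocol = protocol),
            class = "iffl_trajectory")
}

#' Analytic fixed point of the cascade
#'
#' The feedforward loop is a pure cascade, so its steady state under a
#' constant mitogen level follows by forward substitution through the Hill
#' drives: mTOR*, then PP* (zero when the phosphatase arm is off), then
#' pCDH1*, APC/C* and the substrate level.
#'
#' @param params [kinetic_parameters()].
#' @param S Constant mitogen level (>= 0).
#' @param pp_active Is the phosphatase arm engaged? `FALSE` reproduces the
#'   pre-onset (or phosphatase-inhibited) branch.
#' @return An [iffl_state()] at the fixed point.
#' @examples
#' iffl_steady_state(kinetic_parameters(), S = 3, pp_active = TRUE)
#' @export
iffl_steady_state <- function(params = kinetic_parameters(), S = 3,
                              pp_active = TRUE) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S) || S < 0) {
    stop("`S` must be a single non-negative number", call. = FALSE)
  }
  p <- params
  mtor <- hill_up(S, p$k1, p$n1)
  pp <- if (isTRUE(pp_active)) hill_up(S, p$k2, p$n2) else 0
  pcdh1 <- hill_up(mtor, p$k3, p$n3) * hill_down(pp, p$k4, p$n4)
  apc <- hill_down(pcdh1, p$k5, p$n5)
  geminin <- hill_down(apc, p$k6, p$n6)
  iffl_state(mtor = mtor, pp = pp, pcdh1 = pcdh1, apc = apc,
             geminin = geminin)
}

#' Pulse metrics of a trajectory variable
#'
#' Quantifies the pulse shape of one state variable: the interior extremum
#' (endpoints excluded), its time, the initial value as baseline, and the
#' terminal value. A monotone series has no interior extremum.
#'
#' @param traj An `iffl_trajectory`.
#' @param variable One of `"mtor"`, `"pp"`, `"pcdh1"`, `"apc"`, `"geminin"`.
#' @param mode `"minimum"` (e.g. the APC/C dip) or `"maximum"` (e.g. the
#'   substrate pulse).
#' @return List of class `pulse_metrics`: `extremum_value`, `extremum_time`,
#'   `baseline`, `recovery_value`, `has_interior_extremum`.
#' @examples
#' traj <- iffl_simulate(t_end = 12)
#' pulse_metrics(traj, "apc", "minimum")
#' @export
pulse_metrics <- function(traj, variable, mode = c("minimum", "maximum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "iffl_trajectory"))
  if (!variable %in% names(traj$state)) {
    stop(sprintf("unknown trajectory variable `%s`", variable), call. = FALSE)
  }
  v <- traj$state[[variable]]
  n <- length(v)
  if (n < 3L) stop("need at least 3 time points", call. = FALSE)
  inner <- v[2:(n - 1L)]
  idx <- if (mode == "minimum") which.min(inner) + 1L else which.max(inner) + 1L
  interior <- if (mode == "minimum") {
    v[idx] < v[1] && v[idx] < v[n]
  } else {
    v[idx] > v[1] && v[idx] > v[n]
  }
  structure(list(extremum_value = v[idx],
                 extremum_time = traj$times[idx],
                 baseline = v[1],
                 recovery_value = v[n],
                 has_interior_extremum = interior),
            class = "pulse_metrics")
}

#' Tidy export of a trajectory
#'
#' @param x An `iffl_trajectory`.
#' @param ... Unused.
#' @return Data frame with columns `time_h`, `variable`, `value` (long
#'   format, one row per variable per time point).
#' @export
as.data.frame.iffl_trajectory <- function(x, ...) {
  vars <- names(x$state)
  data.frame(
    time_h = rep(x$times, times = length(vars)),
    variable = rep(vars, each = length(x$times)),
    value = unlist(x$state, use.names = FALSE)
  )
}

#' @export
print.iffl_trajectory <- function(x, ...) {
  cat(sprintf("IFFL trajectory: %d points over [%g, %g] h\n",
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  final state: %s\n",
              paste(sprintf("%s=%.4f", names(x$state),
                            unlist(x$state[nrow(x$state), ])),
                    collapse = ", ")))
  invisible(x)
}
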