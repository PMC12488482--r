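# Independent reference integration for the feedforward-loop ODEs:
# fixed-step classical RK4 with a hand-written right-hand side using the
# published constants directly. Kept deliberately separate from the package
# implementation (different integrator, independently coded rates) so it can
# serve as the oracle for the adaptive LSODA path. Integration is segmented
# at drive-switch times with the regime frozen per segment, matching the
# half-open t >= switch convention.

ref_rhs <- function(flags, S = 3) {
  function(t, y, parms) {
    mtor_drive <- if (flags$rapamycin) 0 else S / (0.2 + S)
    pp_drive <- if (flags$pp) S / (0.2 + S) else 0
    pcdh1_drive <- if (flags$blocked) 0 else
      (y[1] / (0.3 + y[1])) * (0.04 / (0.04 + y[2]^2))
    list(c((mtor_drive - y[1]) / 0.5,
           (pp_drive - y[2]) / 0.5,
           (pcdh1_drive - y[3]) / 0.5,
           (0.8 / (0.8 + y[3]) - y[4]) / 0.5,
           (0.064 / (0.064 + y[4]^3) - y[5]) / 0.3))
  }
}

# Returns the state matrix (columns mtor, pp, pcdh1, apc, geminin) sampled
# at `grid` (every grid time must be a multiple of `dt`).
ref_simulate <- function(t_end = 12, dt = 1e-4, grid = seq(0, t_end, by = 0.05),
                         S = 3, pp_onset = 4, rapamycin = Inf,
                         ppase_inhibitor = Inf, blocked = FALSE) {
  breaks <- sort(unique(c(0, pp_onset, rapamycin, ppase_inhibitor, t_end)))
  breaks <- breaks[breaks >= 0 & breaks <= t_end]
  y <- c(0, 0, 0, 1, 0)
  out_t <- numeric(0)
  out_y <- NULL
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]
    b <- breaks[i + 1L]
    mid <- (a + b) / 2
    flags <- list(pp = mid >= pp_onset && mid < ppase_inhibitor,
                  rapamycin = mid >= rapamycin, blocked = blocked)
    tt <- seq(a, b, by = dt)
    if (tt[length(tt)] < b - dt / 2) tt <- c(tt, b)
    sol <- deSolve::ode(y, tt, ref_rhs(flags, S), NULL, method = "rk4")
    out_t <- c(out_t, sol[, 1])
    out_y <- rbind(out_y, unname(sol[, -1, drop = FALSE]))
    y <- sol[nrow(sol), -1]
  }
  dup <- duplicated(round(out_t, 10))
  out_t <- out_t[!dup]
  out_y <- out_y[!dup, , drop = FALSE]
  idx <- match(round(grid, 10), round(out_t, 10))
  stopifnot(!anyNA(idx))
  colnames(out_y) <- c("mtor", "pp", "pcdh1", "apc", "geminin")
  out_y[idx, , drop = FALSE]
}

# Convert a stimulus_protocol into ref_simulate() arguments.
ref_args <- function(protocol) {
  list(S = protocol$mitogen_level,
       pp_onset = protocol$pp_onset_time,
       rapamycin = if (is.null(protocol$rapamycin_time)) Inf else
         protocol$rapamycin_time,
       ppase_inhibitor = if (is.null(protocol$phosphatase_inhibitor_time)) Inf
         else protocol$phosphatase_inhibitor_time,
       blocked = isTRUE(protocol$cdh1_phospho_blocked))
}

# The perturbation matrix exercised by the oracle-equivalence checks.
scenario_matrix <- function() {
  c(list(control = stimulus_protocol(),
         ppase_inhibitor = stimulus_protocol(phosphatase_inhibitor_time = 0),
         t129a = stimulus_protocol(cdh1_phospho_blocked = TRUE)),
    stats::setNames(
      lapply(c(0, 0.5, 1, 2, 4),
             function(rt) stimulus_protocol(rapamycin_time = rt)),
      paste0("rapamycin_", c(0, 0.5, 1, 2, 4), "h")))
}
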