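#' Kinetic parameters of the feedforward-loop model
#'
#' Constructor for the parameter set of the five-variable incoherent
#' feedforward loop (IFFL) controlling APC/C activity during cell-cycle
#' entry. Each arm of the cascade is a first-order relaxation towards a
#' Hill-function drive: `k1..k6` are half-maximal constants, `n1..n6` Hill
#' coefficients, and the five `tau_*` are relaxation time constants in
#' hours. The defaults are the published model constants and reproduce the
#' transient, partial APC/C inactivation pulse between roughly 1 and 6 h
#' after mitogen stimulation.
#'
#' @param k1,k2,k3,k4,k5,k6 Half-maximal constants (dimensionless, > 0).
#' @param n1,n2,n3,n4,n5,n6 Hill coefficients (dimensionless, >= 1).
#' @param tau_mtor,tau_pp,tau_pcdh1,tau_apc,tau_geminin Relaxation time
#'   constants in hours (> 0).
#' @return An object of class `kinetic_parameters` (named list).
#' @examples
#' p <- kinetic_parameters()
#' p$k4
#' @export
kinetic_parameters <- function(k1 = 0.2, n1 = 1, tau_mtor = 0.5,
                               k2 = 0.2, n2 = 1, tau_pp = 0.5,
                               k3 = 0.3, n3 = 1, tau_pcdh1 = 0.5,
                               k4 = 0.2, n4 = 2, tau_apc = 0.5,
                               k5 = 0.8, n5 = 1, tau_geminin = 0.3,
                               k6 = 0.4, n6 = 3) {
  p <- list(k1 = k1, n1 = n1, tau_mtor = tau_mtor,
            k2 = k2, n2 = n2, tau_pp = tau_pp,
            k3 = k3, n3 = n3, tau_pcdh1 = tau_pcdh1,
            k4 = k4, n4 = n4, tau_apc = tau_apc,
            k5 = k5, n5 = n5, tau_geminin = tau_geminin,
            k6 = k6, n6 = n6)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("parameter `%s` must be a single finite number", nm),
           call. = FALSE)
    }
  }
  for (nm in grep("^k", names(p), value = TRUE)) {
    if (p[[nm]] <= 0) stop(sprintf("`%s` must be > 0", nm), call. = FALSE)
  }
  for (nm in grep("^n", names(p), value = TRUE)) {
    if (p[[nm]] < 1) stop(sprintf("`%s` must be >= 1", nm), call. = FALSE)
  }
  for (nm in grep("^tau", names(p), value = TRUE)) {
    if (p[[nm]] <= 0) stop(sprintf("`%s` must be > 0", nm), call. = FALSE)
  }
  structure(p, class = "kinetic_parameters")
}

#' Model state vector
#'
#' The five state variables of the feedforward loop, each a dimensionless
#' activity or level in \[0, 1\]: mTOR kinase activity, protein phosphatase
#' (PP) activity, phosphorylated CDH1 (pCDH1), APC/C activity and the
#' APC/C-substrate level (geminin). `initial_state()` returns the published
#' initial condition for a quiescent cell: everything off, APC/C fully
#' active, no substrate. Note geminin = 0 is the printed initial condition
#' even though the quiescent fixed point of the substrate equation is
#' about 0.0602; the model is implemented as printed.
#'
#' @param mtor,pp,pcdh1,apc,geminin Component values in \[0, 1\].
#' @return Named numeric vector of class `iffl_state`.
#' @examples
#' initial_state()
#' @export
iffl_state <- function(mtor = 0, pp = 0, pcdh1 = 0, apc = 1, geminin = 0) {
  s <- c(mtor = mtor, pp = pp, pcdh1 = pcdh1, apc = apc, geminin = geminin)
  if (any(!is.finite(s))) stop("state components must be finite", call. = FALSE)
  if (any(s < 0) || any(s > 1)) {
    stop("state components must lie in [0, 1]", call. = FALSE)
  }
  structure(s, class = "iffl_state")
}

#' @rdname iffl_state
#' @export
initial_state <- function() iffl_state()

#' Stimulus protocol and perturbation scenario
#'
#' Describes the experimental scenario applied to the model: the mitogen
#' level S (serum stimulation), when it is applied, the delayed onset of
#' protein-phosphatase activity, and the drug/mutant perturbations used in
#' the study. Times are hours from the start of the simulation.
#'
#' Perturbations:
#' \describe{
#'   \item{`rapamycin_time`}{mTORC1 inhibition. From this time the mTOR
#'     drive is set to zero so existing mTOR activity relaxes away with
#'     `tau_mtor` (`rapamycin_mode = "drive"`, the default, modelling a
#'     block of kinase activation); `rapamycin_mode = "clamp"` instead
#'     resets mTOR activity to zero instantaneously.}
#'   \item{`phosphatase_inhibitor_time`}{pan-phosphatase inhibition; the PP
#'     drive is zero from this time onward, so CDH1 dephosphorylation never
#'     builds up and APC/C inactivation becomes sustained.}
#'   \item{`cdh1_phospho_blocked`}{dominant-negative, non-phosphorylatable
#'     CDH1 (T129A): the pCDH1 drive is forced to zero for all time.}
#' }
#'
#' @param mitogen_level Dimensionless mitogen input S (default 3, the value
#'   used for mitogen stimulation).
#' @param mitogen_onset Hours at which S switches on (default 0).
#' @param pp_onset_time Hours before which the PP drive is held at zero
#'   (default 4, the measured delay of phosphatase action).
#' @param rapamycin_time Optional hours; `NULL` for no rapamycin.
#' @param phosphatase_inhibitor_time Optional hours; `NULL` for none.
#' @param cdh1_phospho_blocked Logical flag for the T129A scenario.
#' @param rapamycin_mode `"drive"` or `"clamp"`, see Details.
#' @return Object of class `stimulus_protocol`.
#' @examples
#' stimulus_protocol()                         # control
#' stimulus_protocol(rapamycin_time = 0)       # rapamycin at stimulation
#' stimulus_protocol(phosphatase_inhibitor_time = 0)
#' @export
stimulus_protocol <- function(mitogen_level = 3,
                              mitogen_onset = 0,
                              pp_onset_time = 4,
                              rapamycin_time = NULL,
                              phosphatase_inhibitor_time = NULL,
                              cdh1_phospho_blocked = FALSE,
                              rapamycin_mode = c("drive", "clamp")) {
  rapamycin_mode <- match.arg(rapamycin_mode)
  chk_time <- function(x, nm, optional = FALSE) {
    if (is.null(x)) {
      if (optional) return(invisible(NULL))
      stop(sprintf("`%s` must not be NULL", nm), call. = FALSE)
    }
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
      stop(sprintf("`%s` must be a single non-negative number", nm),
           call. = FALSE)
    }
  }
  chk_time(mitogen_level, "mitogen_level")
  chk_time(mitogen_onset, "mitogen_onset")
  chk_time(pp_onset_time, "pp_onset_time")
  chk_time(rapamycin_time, "rapamycin_time", optional = TRUE)
  chk_time(phosphatase_inhibitor_time, "phosphatase_inhibitor_time",
           optional = TRUE)
  if (!is.logical(cdh1_phospho_blocked) || length(cdh1_phospho_blocked) != 1L ||
      is.na(cdh1_phospho_blocked)) {
    stop("`cdh1_phospho_blocked` must be TRUE or FALSE", call. = FALSE)
  }
  structure(list(mitogen_level = mitogen_level,
                 mitogen_onset = mitogen_onset,
                 pp_onset_time = pp_onset_time,
                 rapamycin_time = rapamycin_time,
                 phosphatase_inhibitor_time = phosphatase_inhibitor_time,
                 cdh1_phospho_blocked = cdh1_phospho_blocked,
                 rapamycin_mode = rapamycin_mode),
            class = "stimulus_protocol")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("IFFL kinetic parameters\n")
  cat(sprintf("  k: %s\n", paste(unlist(x[grep("^k", names(x))]), collapse = ", ")))
  cat(sprintf("  n: %s\n", paste(unlist(x[grep("^n", names(x))]), collapse = ", ")))
  cat(sprintf("  tau (h): %s\n",
              paste(unlist(x[grep("^tau", names(x))]), collapse = ", ")))
  invisible(x)
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("Stimulus protocol\n")
  cat(sprintf("  S = %g from t = %g h; PP onset %g h\n",
              x$mitogen_level, x$mitogen_onset, x$pp_onset_time))
  if (!is.null(x$rapamycin_time)) {
    cat(sprintf("  rapamycin at %g h (%s)\n", x$rapamycin_time, x$rapamycin_mode))
  }
  if (!is.null(x$phosphatase_inhibitor_time)) {
    cat(sprintf("  phosphatase inhibitor at %g h\n",
                x$phosphatase_inhibitor_time))
  }
  if (isTRUE(x$cdh1_phospho_blocked)) cat("  CDH1 phosphorylation blocked (T129A)\n")
  invisible(x)
}
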