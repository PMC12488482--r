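# Quantitative trace procedures: windowed slope fits, the MG132 slope-ratio
# percent-inactivation statistic, transient/sustained classification,
# population fractions, median traces, divergence timing, and CDK2 cycling
# calls. All windows are half-open [start, end) so adjacent windows
# partition the sampling grid.

#' Ordinary least-squares slope over a time window
#'
#' Fits a line to the samples with `start <= time < end`. The accumulation
#' slope of a constitutively expressed degron reporter is the readout of
#' relative APC/C activity, so this fit is the primitive behind the
#' percent-inactivation statistic.
#'
#' @param times,values Single-cell series (hours, signal).
#' @param window `c(start, end)` hours, half-open.
#' @return List of class `slope_fit`: `window`, `slope` (units/h),
#'   `intercept`, `residual_sd`, `n_points`.
#' @examples
#' fit_slope(0:10, 2 + 3 * (0:10), c(0, 11))$slope
#' @export
fit_slope <- function(times, values, window) {
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("`window` must be c(start, end) with end > start", call. = FALSE)
  }
  keep <- times >= window[1] & times < window[2]
  if (sum(keep) < 2L) {
    stop(sprintf("fewer than 2 samples in window [%g, %g)",
                 window[1], window[2]), call. = FALSE)
  }
  t <- times[keep]
  v <- values[keep]
  fit <- stats::lm.fit(cbind(1, t), v)
  rsd <- if (length(v) > 2L) {
    sqrt(sum(fit$residuals^2) / (length(v) - 2L))
  } else 0
  structure(list(window = window,
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 residual_sd = rsd,
                 n_points = length(v)),
            class = "slope_fit")
}

#' Percent APC/C inactivation from the MG132 slope ratio
#'
#' Compares the reporter accumulation slope during cell-cycle entry
#' (default window 1--5 h after mitogen stimulation) with the accumulation
#' slope after proteasome inhibition, which blocks all reporter degradation
#' and so equals the synthesis rate -- the 100% inhibition reference:
#' `percent_inactivation = 100 * (1 - slope_pre / slope_post)`.
#'
#' @param times,values Single-cell reporter series.
#' @param mg132_time Hours at which MG132 was added.
#' @param pre_window Half-open fit window before MG132 (default `c(1, 5)`).
#' @param post_window Half-open fit window after MG132; default starts
#'   0.5 h after `mg132_time` (equilibration gap) and spans 2 h.
#' @return List of class `inactivation_estimate`: `slope_pre`,
#'   `slope_post`, `percent_inactivation`.
#' @examples
#' tt <- seq(0, 10, by = 0.2)
#' vv <- ifelse(tt < 5, 2 * tt, 10 + 3 * (tt - 5))
#' percent_inactivation(tt, vv, mg132_time = 5)$percent_inactivation # 33.3
#' @export
percent_inactivation <- function(times, values, mg132_time,
                                 pre_window = c(1, 5),
                                 post_window = mg132_time + c(0.5, 2.5)) {
  if (pre_window[2] > mg132_time) {
    stop("`pre_window` must end at or before `mg132_time`", call. = FALSE)
  }
  if (post_window[1] < mg132_time) {
    stop("`post_window` must start at or after `mg132_time`", call. = FALSE)
  }
  pre <- fit_slope(times, values, pre_window)
  post <- fit_slope(times, values, post_window)
  if (post$slope <= 0) {
    stop("post-MG132 slope is not positive; MG132 reference failed",
         call. = FALSE)
  }
  structure(list(slope_pre = pre$slope, slope_post = post$slope,
                 percent_inactivation = 100 * (1 - pre$slope / post$slope)),
            class = "inactivation_estimate")
}

# Robust per-sample noise scale: MAD of first differences.
diff_noise_scale <- function(values) {
  stats::mad(diff(values))
}

#' Classify a reporter trace as transient, sustained, or none
#'
#' After moving-median smoothing, the trace is `"none"` when the rise above
#' baseline (first smoothed value) never exceeds `min_prominence`;
#' `"transient"` when the smoothed peak is interior and the terminal value
#' has decayed back below `baseline + terminal_fraction * (peak -
#' baseline)`; `"sustained"` otherwise. The default prominence threshold is
#' 3x a robust noise scale (MAD of the first differences of the raw
#' trace), so flat noisy traces are not called.
#'
#' @param times,values Single-cell series (>= 5 samples).
#' @param min_prominence Units; `NULL` for the adaptive default.
#' @param terminal_fraction Decay criterion for the transient call
#'   (default 0.5).
#' @param smooth_window Odd moving-median width in samples (default 5).
#' @return List of class `trace_class`: `label`, `peak_value`, `baseline`,
#'   `terminal_value`, `peak_time`, `prominence`.
#' @export
classify_trace <- function(times, values, min_prominence = NULL,
                           terminal_fraction = 0.5, smooth_window = 5) {
  n <- length(values)
  if (n < 5L) stop("need at least 5 samples", call. = FALSE)
  if (smooth_window >= n) stop("`smooth_window` must be shorter than the trace",
                               call. = FALSE)
  if (is.null(min_prominence)) {
    min_prominence <- 3 * diff_noise_scale(values)
  }
  sm <- as.numeric(stats::runmed(values, k = smooth_window))
  baseline <- sm[1]
  peak_idx <- which.max(sm)
  peak <- sm[peak_idx]
  terminal <- sm[n]
  prominence <- peak - baseline
  label <- if (prominence < min_prominence) {
    "none"
  } else if (peak_idx > 1L && peak_idx < n &&
             terminal <= baseline + terminal_fraction * prominence) {
    "transient"
  } else {
    "sustained"
  }
  structure(list(label = label, peak_value = peak, baseline = baseline,
                 terminal_value = terminal, peak_time = times[peak_idx],
                 prominence = prominence),
            class = "trace_class")
}

#' Fraction of transient calls in a population
#'
#' @param classes List of `trace_class` objects or a character vector of
#'   labels.
#' @return Fraction of `"transient"` labels among all cells.
#' @export
fraction_transient <- function(classes) {
  labels <- extract_labels(classes)
  mean(labels == "transient")
}

#' Fraction of cycling calls in a population
#'
#' @param labels Character vector (or list) of `"cycling"` / `"quiescent"`
#'   labels.
#' @return Fraction labelled `"cycling"`.
#' @export
fraction_cycling <- function(labels) {
  labels <- extract_labels(labels)
  mean(labels == "cycling")
}

extract_labels <- function(classes) {
  if (length(classes) == 0L) stop("empty collection", call. = FALSE)
  if (is.character(classes)) return(classes)
  vapply(classes, function(x) if (is.list(x)) x$label else as.character(x),
         character(1))
}

#' Normalise a population fraction to a control
#'
#' @param f_condition,f_control Fractions; `f_control` must be > 0.
#' @return `f_condition / f_control`.
#' @export
normalize_to_control <- function(f_condition, f_control) {
  if (!is.numeric(f_control) || f_control <= 0) {
    stop("`f_control` must be > 0", call. = FALSE)
  }
  f_condition / f_control
}

#' Pointwise median trace of a population
#'
#' All cells must share the sampling grid; no interpolation is performed.
#' For an even cell count the lower of the two middle values is taken, so
#' the result is always an observed value and runs are bit-reproducible.
#'
#' @param table A `trace_table` (or tibble with `cell_id`, `time_h`,
#'   `value`), already restricted to one channel/scenario.
#' @return Tibble with columns `time_h`, `value`.
#' @export
median_trace <- function(table) {
  if (nrow(table) == 0L) stop("empty trace table", call. = FALSE)
  if (length(unique(table$channel)) > 1L) {
    stop("restrict the table to a single channel first", call. = FALSE)
  }
  grids <- split(table$time_h, table$cell_id)
  g0 <- grids[[1]]
  for (g in grids) {
    if (length(g) != length(g0) || any(g != g0)) {
      stop("cells are not on a common sampling grid", call. = FALSE)
    }
  }
  m <- matrix(NA_real_, nrow = length(g0), ncol = length(grids))
  vals <- split(table$value, table$cell_id)
  for (j in seq_along(vals)) m[, j] <- vals[[j]]
  med <- apply(m, 1, low_median)
  tibble::tibble(time_h = g0, value = med)
}

low_median <- function(x) {
  sort(x)[floor((length(x) + 1) / 2)]
}

#' Divergence time between two median traces
#'
#' Earliest grid time at which the two aligned series differ by at least
#' `epsilon` for `sustain_points` consecutive samples. Used to locate when
#' a phosphatase-inhibited population peels away from the control -- the
#' in-silico counterpart of the 4-h divergence of median biosensor traces.
#'
#' @param times Common time grid.
#' @param a,b Aligned series.
#' @param epsilon Difference threshold (> 0), same units as the series.
#' @param sustain_points Consecutive samples required (>= 1, default 3).
#' @return List of class `divergence_result`: `divergence_time` (hours or
#'   `NA` if the series never diverge), `epsilon`, `sustain_points`.
#' @export
divergence_time <- function(times, a, b, epsilon, sustain_points = 3) {
  if (length(a) != length(b) || length(a) != length(times)) {
    stop("`times`, `a` and `b` must be aligned", call. = FALSE)
  }
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  if (sustain_points < 1) stop("`sustain_points` must be >= 1", call. = FALSE)
  hit <- abs(a - b) >= epsilon
  run <- 0L
  idx <- NA_integer_
  for (i in seq_along(hit)) {
    run <- if (hit[i]) run + 1L else 0L
    if (run >= sustain_points) {
      idx <- i - sustain_points + 1L
      break
    }
  }
  structure(list(divergence_time = if (is.na(idx)) NA_real_ else times[idx],
                 epsilon = epsilon, sustain_points = sustain_points),
            class = "divergence_result")
}

#' Classify a CDK2-activity trace as cycling or quiescent
#'
#' A cell is called cycling when its activity stays at or above `threshold`
#' for `sustain_points` consecutive samples, mirroring how rising CDK2
#' activity marks commitment to the cell cycle while quiescent cells hover
#' at low activity.
#'
#' @param values Activity series.
#' @param threshold Activity units (default 1, midway between the default
#'   quiescent level and cycling plateau of the generator).
#' @param sustain_points Consecutive samples required (default 3).
#' @return `"cycling"` or `"quiescent"`.
#' @export
classify_cdk2 <- function(values, threshold = 1, sustain_points = 3) {
  if (length(values) < sustain_points) {
    stop("series shorter than `sustain_points`", call. = FALSE)
  }
  hit <- values >= threshold
  run <- 0L
  for (h in hit) {
    run <- if (h) run + 1L else 0L
    if (run >= sustain_points) return("cycling")
  }
  "quiescent"
}

#' Per-cell analytics over a trace table
#'
#' Applies [classify_trace()] (and, when `mg132_time` is given,
#' [percent_inactivation()]) to every cell of one scenario/channel slice.
#'
#' @param table A `trace_table` slice (one scenario, one channel).
#' @param mg132_time Optional MG132 time for slope-ratio estimation.
#' @param min_prominence,terminal_fraction,smooth_window Passed to
#'   [classify_trace()].
#' @param pre_window Passed to [percent_inactivation()].
#' @return Tibble with one row per cell: `cell_id`, `scenario`, `label`,
#'   `peak_time`, `prominence`, and (if requested) `slope_pre`,
#'   `slope_post`, `percent_inactivation`.
#' @export
analyze_cells <- function(table, mg132_time = NULL, min_prominence = NULL,
                          terminal_fraction = 0.5, smooth_window = 5,
                          pre_window = c(1, 5)) {
  cells <- split(seq_len(nrow(table)), table$cell_id)
  rows <- lapply(names(cells), function(id) {
    idx <- cells[[id]]
    tt <- table$time_h[idx]
    vv <- table$value[idx]
    cl <- classify_trace(tt, vv, min_prominence = min_prominence,
                         terminal_fraction = terminal_fraction,
                         smooth_window = smooth_window)
    row <- tibble::tibble(cell_id = id, scenario = table$scenario[idx[1]],
                          label = cl$label, peak_time = cl$peak_time,
                          prominence = cl$prominence)
    if (!is.null(mg132_time)) {
      est <- percent_inactivation(tt, vv, mg132_time, pre_window = pre_window)
      row$slope_pre <- est$slope_pre
      row$slope_post <- est$slope_post
      row$percent_inactivation <- est$percent_inactivation
    }
    row
  })
  do.call(rbind, rows)
}
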