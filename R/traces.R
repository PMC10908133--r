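#' Evoked concentration-versus-time trace
#'
#' The horizontal section of a color plot at the analyte's oxidation
#' potential, expressed in concentration units: the \eqn{C(t)} of the
#' two-uptake Michaelis-Menten model.
#'
#' @param time Uniformly-sampled time axis (s).
#' @param concentration Concentration per sample (nM); finite.
#' @param stim_window Stimulation (start, duration) in seconds; default a 2 s
#'   pulse starting at 0. Must lie within the time range.
#' @return An object of class \code{evoked_trace}.
#' @export
evoked_trace <- function(time, concentration, stim_window = c(0, 2)) {
  stop_if(length(time) != length(concentration),
          "time and concentration must have equal length")
  stop_if(!all(is.finite(concentration)), "concentrations must be finite")
  dt <- diff(time)
  stop_if(length(dt) > 0 && (any(dt <= 0) || diff(range(dt)) > 1e-8 * max(dt)),
          "trace must be uniformly sampled with increasing time")
  stop_if(stim_window[1] < time[1] - 1e-9 ||
            stim_window[1] > time[length(time)],
          "stimulation window must start within the time range")
  structure(list(time = as.numeric(time),
                 concentration = as.numeric(concentration),
                 stim_window = as.numeric(stim_window)),
            class = "evoked_trace")
}

#' @export
print.evoked_trace <- function(x, ...) {
  cat(sprintf("<evoked_trace> %d samples over %.1f s, stim %g s @ t=%g s\n",
              length(x$time), diff(range(x$time)), x$stim_window[2],
              x$stim_window[1]))
  invisible(x)
}

#' Convert FSCV current to concentration
#'
#' Applies the electrode calibration factor of 49.5 nM per nA.
#'
#' @param i Current in nA (vectorised).
#' @return Concentration in nM.
#' @export
#' @examples
#' current_to_concentration(1) # 49.5
current_to_concentration <- function(i) {
  stop_if(!all(is.finite(i)), "currents must be finite")
  49.5 * i
}

#' Extract the evoked trace at a potential
#'
#' Takes the color-plot row nearest the requested potential (ties broken
#' toward the lower row index) and converts current to concentration with the
#' 49.5 nM/nA factor. Default potential is the serotonin oxidation centre.
#'
#' @param plot A [color_plot()].
#' @param potential Potential (V) at which to section the plot; must lie
#'   within the waveform range.
#' @return An [evoked_trace()] whose stimulation window starts at the plot's
#'   \code{t0_stim}.
#' @export
extract_trace <- function(plot, potential = 0.65) {
  stopifnot(inherits(plot, "color_plot"))
  rng <- range(plot$potential_axis)
  stop_if(potential < rng[1] || potential > rng[2],
          "requested potential outside the waveform range")
  # search the anodic segment so oxidation rows are preferred
  anodic <- anodic_indices(plot$potential_axis)
  d <- abs(plot$potential_axis[anodic] - potential)
  row <- anodic[which.min(d)] # which.min returns the first (lowest) index
  evoked_trace(plot$time_axis,
               current_to_concentration(plot$current[row, ]),
               stim_window = c(plot$t0_stim, 2))
}

#' Maximum evoked amplitude above baseline
#'
#' Amp_max: the maximum concentration inside a search window after
#' stimulation onset, minus the pre-stimulation baseline (mean over the
#' second preceding onset; zero if the trace starts at onset).
#'
#' @param trace An [evoked_trace()].
#' @param search_window Seconds after stimulation onset to search (default 15).
#' @param baseline_window Seconds before onset averaged as baseline (default 1).
#' @return Amp_max in nM.
#' @export
peak_amplitude <- function(trace, search_window = 15, baseline_window = 1) {
  stopifnot(inherits(trace, "evoked_trace"))
  t0 <- trace$stim_window[1]
  pre <- trace$time < t0 & trace$time >= t0 - baseline_window
  baseline <- if (any(pre)) mean(trace$concentration[pre]) else 0
  sel <- trace$time >= t0 & trace$time <= t0 + search_window
  stop_if(!any(sel), "empty post-stimulation search window")
  max(trace$concentration[sel]) - baseline
}

#' Area under the trace by composite Simpson's rule
#'
#' Integrates the concentration over a time window with composite Simpson's
#' rule; when the window holds an odd number of intervals, the final interval
#' is handled with the trapezoid rule.
#'
#' @param trace An [evoked_trace()].
#' @param window Time window \code{c(from, to)} in seconds; default the whole
#'   trace. Must contain at least 3 samples.
#' @return Integral in nM s.
#' @export
auc_simpson <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "evoked_trace"))
  window <- window %||% range(trace$time)
  sel <- which(trace$time >= window[1] - 1e-12 & trace$time <= window[2] + 1e-12)
  stop_if(length(sel) < 3, "integration window must contain at least 3 samples")
  y <- trace$concentration[sel]
  h <- trace$time[sel][2] - trace$time[sel][1]
  n_int <- length(y) - 1
  total <- 0
  if (n_int %% 2 == 1) { # odd interval count: trapezoid on the last interval
    total <- total + h * (y[length(y) - 1] + y[length(y)]) / 2
    y <- y[-length(y)]
    n_int <- n_int - 1
  }
  if (n_int >= 2) {
    i <- seq(1, n_int - 1, by = 2)
    total <- total + sum(h / 3 * (y[i] + 4 * y[i + 1] + y[i + 2]))
  }
  total
}

#' Post-peak decay half-life
#'
#' Fits an exponential decay \eqn{c(t) = c_{peak} e^{-kt}} to the segment
#' after the trace maximum by log-linear least squares (restricted to samples
#' above 5% of the peak so that tail noise does not dominate) and returns
#' \eqn{t_{1/2} = \ln 2 / k}.
#'
#' @param trace An [evoked_trace()].
#' @param floor_frac Fraction of the peak below which post-peak samples are
#'   dropped from the fit (default 0.05).
#' @return Half-life in seconds.
#' @export
half_life <- function(trace, floor_frac = 0.05) {
  stopifnot(inherits(trace, "evoked_trace"))
  conc <- trace$concentration
  ipk <- which.max(conc)
  peak <- conc[ipk]
  stop_if(peak <= 0, "trace has no positive maximum to decay from")
  post <- seq(ipk, length(conc))
  keep <- post[conc[post] > floor_frac * peak & conc[post] > 0]
  stop_if(length(keep) < 5, "need at least 5 usable post-peak samples")
  tt <- trace$time[keep] - trace$time[ipk]
  fit <- lm(log(conc[keep]) ~ tt)
  k <- -coef(fit)[[2]]
  stop_if(k <= 0, sprintf(
    "post-peak segment does not decay (fitted k = %.3g <= 0)", k))
  log(2) / k
}

#' Write / read an evoked trace as CSV
#'
#' Columns \code{time_s} and \code{concentration_nM}; the stimulation window
#' is carried in a comment-free pair of extra columns on the first row would
#' be fragile, so it is stored in a JSON sidecar like color plots.
#'
#' @param trace An [evoked_trace()].
#' @param path CSV path.
#' @return \code{write_trace} returns \code{path} invisibly; \code{read_trace}
#'   an [evoked_trace()].
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time,
                              concentration_nM = trace$concentration),
                   path, row.names = FALSE)
  jsonlite::write_json(list(stim_window = trace$stim_window),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  sw <- if (file.exists(side_path)) {
    unlist(jsonlite::read_json(side_path, simplifyVector = TRUE)$stim_window)
  } else c(0, 2)
  evoked_trace(df$time_s, df$concentration_nM, stim_window = sw)
}
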