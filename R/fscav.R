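#' FSCAV electrode calibration
#'
#' Post-calibration line mapping integrated charge (pC) to ambient
#' concentration (nM) by ordinary least squares over standard solutions. The
#' default standards are 10, 25, 50 and 100 nM serotonin in Tris buffer.
#'
#' @param concentration Standard concentrations (nM), length >= 2.
#' @param charge Measured charges (pC) for the standards; must not be all
#'   equal.
#' @return An object of class \code{fscav_calibration} with the standards and
#'   the fitted \code{slope} (nM/pC, must be positive) and \code{intercept}
#'   (nM).
#' @export
fscav_calibration <- function(concentration = c(10, 25, 50, 100),
                              charge = c(10, 25, 50, 100) / 2) {
  stop_if(length(concentration) < 2 || length(charge) != length(concentration),
          "need at least two (concentration, charge) standards")
  stop_if(diff(range(charge)) == 0,
          "degenerate standards: charges are all equal")
  fit <- lm(concentration ~ charge)
  slope <- coef(fit)[[2]]
  stop_if(slope <= 0, "calibration slope must be positive")
  structure(list(standards = data.frame(concentration = concentration,
                                        charge = charge),
                 slope = slope, intercept = coef(fit)[[1]]),
            class = "fscav_calibration")
}

#' Convert integrated charge to ambient concentration
#'
#' Applies the calibration line \code{concentration = slope * charge +
#' intercept}.
#'
#' @param calib An [fscav_calibration()].
#' @param charge Charge(s) in pC.
#' @return Concentration(s) in nM.
#' @export
calibrate_fscav <- function(calib, charge) {
  stopifnot(inherits(calib, "fscav_calibration"))
  calib$slope * charge + calib$intercept
}

#' Integrate the serotonin oxidation charge of a CV
#'
#' Integrates the baseline-subtracted current over the anodic samples whose
#' applied potential lies in the 0.4-0.8 V window (the serotonin oxidation
#' peak region). The baseline is the straight line joining the currents at
#' the window edges. Returns charge in pC (current in nA, time from the
#' sweep's sample spacing).
#'
#' @param current Per-sample current vector of one sweep (nA).
#' @param potential_axis Applied potential per sample (V); must cover the
#'   integration window on the anodic segment.
#' @param sample_rate Samples per second used to convert samples to time.
#' @param window Potential window (V), default \code{c(0.4, 0.8)}.
#' @return Charge in pC.
#' @export
fscav_charge <- function(current, potential_axis, sample_rate = 1e5,
                         window = c(0.4, 0.8)) {
  stop_if(length(current) != length(potential_axis),
          "current and potential axis must have equal length")
  anodic <- anodic_indices(potential_axis)
  pa <- potential_axis[anodic]
  stop_if(min(pa) > window[1] || max(pa) < window[2],
          "anodic sweep does not cover the integration window")
  sel <- anodic[pa >= window[1] & pa <= window[2]]
  stop_if(length(sel) < 3, "integration window contains too few samples")
  i_win <- current[sel]
  baseline <- seq(i_win[1], i_win[length(i_win)], length.out = length(i_win))
  dt <- 1 / sample_rate
  # trapezoid over the window; nA * s = nC -> pC
  y <- i_win - baseline
  1000 * sum((y[-1] + y[-length(y)]) / 2 * dt)
}

#' Ambient-serotonin (FSCAV) time series
#'
#' One-sample-per-minute series of integrated charge and calibrated
#' concentration, with dosing events.
#'
#' @param time Minutes (monotone, unit spacing).
#' @param concentration Ambient concentration (nM).
#' @param charge Integrated charge (pC).
#' @param events data.frame with \code{time} (min) and \code{label}.
#' @param epochs data.frame describing the acquisition epochs.
#' @return Object of class \code{fscav_series}.
#' @export
fscav_series <- function(time, concentration, charge, events = NULL,
                         epochs = NULL) {
  stop_if(any(diff(time) <= 0), "time must be strictly increasing")
  stop_if(any(abs(diff(time) - 1) > 1e-9), "series must have one sample per minute")
  structure(list(time = time, concentration = concentration, charge = charge,
                 events = events, epochs = epochs),
            class = "fscav_series")
}

#' Simulate an ambient-serotonin FSCAV experiment
#'
#' Piecewise-linear mean concentration plus Gaussian noise, one sample per
#' minute, emulating the experiment's structure: a 30 min control epoch, a
#' 30 min epoch after a saline injection and a 60 min epoch after
#' escitalopram during which ambient serotonin ramps up. Group defaults:
#' control baseline 32.65 nM with a post-SSRI slope of 0.39 nM/min; MPTP
#' baseline 11.46 nM with slope 0.21 nM/min. Charges are back-computed
#' through the supplied calibration line.
#'
#' @param group \code{"control"} or \code{"mptp"} (sets defaults), or supply
#'   \code{baseline}/\code{slopes} directly.
#' @param baseline Ambient baseline (nM), >= 0.
#' @param epoch_minutes Named epoch durations in minutes (ordered in time).
#' @param slopes Mean slope per epoch (nM/min), same length as
#'   \code{epoch_minutes}.
#' @param noise_sd Gaussian measurement noise SD (nM).
#' @param calibration [fscav_calibration()] used to back-compute charge.
#' @param seed Integer seed.
#' @return An [fscav_series()]; events mark the saline and escitalopram doses.
#' @export
generate_fscav_series <- function(group = c("control", "mptp"),
                                  baseline = NULL,
                                  epoch_minutes = c(control = 30, saline = 30,
                                                    escit = 60),
                                  slopes = NULL, noise_sd = 2,
                                  calibration = fscav_calibration(),
                                  seed = NULL) {
  group <- match.arg(group)
  baseline <- baseline %||% switch(group, control = 32.65, mptp = 11.46)
  slopes <- slopes %||% c(0, 0, switch(group, control = 0.39, mptp = 0.21))
  stop_if(baseline < 0, "baseline must be non-negative")
  stop_if(length(slopes) != length(epoch_minutes),
          "one slope per epoch required")
  stop_if(noise_sd < 0, "noise_sd must be non-negative")
  starts <- cumsum(c(0, epoch_minutes[-length(epoch_minutes)]))
  total <- sum(epoch_minutes)
  tt <- seq_len(total) - 1
  mean_conc <- numeric(total)
  level <- baseline
  for (k in seq_along(epoch_minutes)) {
    in_ep <- tt >= starts[k] & tt < starts[k] + epoch_minutes[k]
    mean_conc[in_ep] <- level + slopes[k] * (tt[in_ep] - starts[k])
    level <- level + slopes[k] * epoch_minutes[k]
  }
  conc <- mean_conc +
    with_seed(seed, if (noise_sd > 0) rnorm(total, 0, noise_sd) else 0)
  conc <- pmax(conc, 0)
  charge <- (conc - calibration$intercept) / calibration$slope
  nm <- names(epoch_minutes) %||% paste0("epoch", seq_along(epoch_minutes))
  events <- data.frame(time = starts[-1], label = nm[-1])
  epochs <- data.frame(label = nm, start = starts,
                       end = starts + as.numeric(epoch_minutes),
                       slope = slopes)
  fscav_series(tt, conc, charge, events = events, epochs = epochs)
}

#' @export
print.fscav_series <- function(x, ...) {
  cat(sprintf("<fscav_series> %d min, %.1f-%.1f nM\n", length(x$time),
              min(x$concentration), max(x$concentration)))
  invisible(x)
}

#' Per-epoch least-squares slopes of an FSCAV series
#'
#' @param series An [fscav_series()] carrying an \code{epochs} table.
#' @return data.frame with \code{label}, \code{slope} (nM/min) and
#'   \code{intercept}.
#' @export
fscav_epoch_slopes <- function(series) {
  stopifnot(inherits(series, "fscav_series"))
  stop_if(is.null(series$epochs), "series has no epoch table")
  ep <- series$epochs
  out <- lapply(seq_len(nrow(ep)), function(k) {
    sel <- series$time >= ep$start[k] & series$time < ep$end[k]
    fit <- lm(series$concentration[sel] ~ series$time[sel])
    data.frame(label = ep$label[k], slope = coef(fit)[[2]],
               intercept = coef(fit)[[1]])
  })
  do.call(rbind, out)
}

#' Summarise the ambient-serotonin response to escitalopram
#'
#' Computes per-group after-minus-before differences of ambient serotonin
#' means and, when a simulated series is supplied, the per-epoch
#' least-squares slopes.
#'
#' @param before,after Named numeric vectors of group means (nM); names must
#'   match.
#' @param series Optional [fscav_series()] for epoch slopes.
#' @return List with \code{differences} (data.frame \code{group},
#'   \code{before}, \code{after}, \code{difference}) and \code{slopes}
#'   (or \code{NULL}).
#' @export
#' @examples
#' means <- fscav_reference_means()
#' escit_effect_summary(setNames(means$before, means$group),
#'                      setNames(means$after, means$group))
escit_effect_summary <- function(before, after, series = NULL) {
  stop_if(is.null(names(before)) || is.null(names(after)) ||
            !identical(sort(names(before)), sort(names(after))),
          "before/after group labels must match")
  after <- after[names(before)]
  diffs <- data.frame(group = names(before), before = as.numeric(before),
                      after = as.numeric(after),
                      difference = as.numeric(after - before))
  list(differences = diffs,
       slopes = if (!is.null(series)) fscav_epoch_slopes(series) else NULL)
}

#' Write / read an FSCAV series as CSV
#'
#' Columns \code{time_min}, \code{charge_pC}, \code{concentration_nM},
#' \code{event}.
#'
#' @param series An [fscav_series()].
#' @param path CSV path.
#' @return \code{write_fscav_series} returns \code{path} invisibly;
#'   \code{read_fscav_series} an [fscav_series()] (epoch table not
#'   round-tripped).
#' @export
write_fscav_series <- function(series, path) {
  ev <- rep("", length(series$time))
  if (!is.null(series$events)) {
    ev[match(series$events$time, series$time)] <- series$events$label
  }
  utils::write.csv(data.frame(time_min = series$time,
                              charge_pC = series$charge,
                              concentration_nM = series$concentration,
                              event = ev),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fscav_series
#' @export
read_fscav_series <- function(path) {
  df <- utils::read.csv(path)
  has_ev <- !is.na(df$event) & nzchar(df$event)
  events <- if (any(has_ev)) {
    data.frame(time = df$time_min[has_ev], label = df$event[has_ev])
  } else NULL
  fscav_series(df$time_min, df$concentration_nM, df$charge_pC,
               events = events)
}
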