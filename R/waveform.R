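#' Serotonin scan waveform specification
#'
#' Describes the triangular ("N"-shaped) potential waveform applied to the
#' carbon-fibre microelectrode. The default is the serotonin waveform:
#' 0.2 V -> 1.0 V -> -0.1 V -> 0.2 V at a scan rate of 1000 V/s, applied at
#' 10 Hz and digitised at 100 kHz.
#'
#' @param vertices Numeric vector of waveform vertex potentials (V). The
#'   waveform must be closed: first and last vertex equal.
#' @param scan_rate Scan rate in V/s (> 0).
#' @param sample_rate Digitisation rate in samples/s.
#' @param repetition_hz Waveform application frequency in Hz (spacing of
#'   color-plot columns is \code{1/repetition_hz}).
#'
#' @return An object of class \code{waveform_spec}.
#' @export
#' @examples
#' ws <- waveform_spec()
#' sweep_duration(ws) # 2.2 ms
waveform_spec <- function(vertices = c(0.2, 1.0, -0.1, 0.2),
                          scan_rate = 1000,
                          sample_rate = 1e5,
                          repetition_hz = 10) {
  stop_if(length(vertices) < 2, "waveform needs at least two vertices")
  stop_if(vertices[1] != vertices[length(vertices)],
          "waveform must be closed: first vertex must equal last vertex")
  stop_if(scan_rate <= 0, "scan_rate must be positive")
  stop_if(sample_rate <= 0, "sample_rate must be positive")
  stop_if(repetition_hz <= 0, "repetition_hz must be positive")
  structure(
    list(vertices = as.numeric(vertices), scan_rate = scan_rate,
         sample_rate = sample_rate, repetition_hz = repetition_hz),
    class = "waveform_spec"
  )
}

#' Duration of one potential sweep
#'
#' Total path length over the waveform vertices divided by the scan rate.
#'
#' @param spec A [waveform_spec()].
#' @return Sweep duration in seconds.
#' @export
sweep_duration <- function(spec) {
  sum(abs(diff(spec$vertices))) / spec$scan_rate
}

#' Number of potential samples in one sweep
#'
#' @param spec A [waveform_spec()].
#' @return Integer sample count (duration times sample rate).
#' @export
sweep_samples <- function(spec) {
  as.integer(round(sweep_duration(spec) * spec$sample_rate))
}

#' Build the applied-potential axis of one sweep
#'
#' Piecewise-linear ramp through the waveform vertices at the specified scan
#' rate. With \code{n_samples} given, the sweep is resampled to that many
#' points (used by reduced-resolution simulation profiles); otherwise the
#' native count \code{sweep_duration * sample_rate} is used.
#'
#' @param spec A [waveform_spec()].
#' @param n_samples Optional number of samples along the sweep.
#' @return Numeric vector of potentials (V), one per sample. The first and
#'   last values equal the (shared) first/last vertex.
#' @export
#' @examples
#' axis <- build_waveform(waveform_spec())
#' length(axis) # 220
#' range(axis)  # -0.1 .. 1.0
build_waveform <- function(spec, n_samples = NULL) {
  stopifnot(inherits(spec, "waveform_spec"))
  n <- n_samples %||% sweep_samples(spec)
  stop_if(n < length(spec$vertices), "too few samples for the waveform")
  seg_len <- abs(diff(spec$vertices))
  t_vert <- c(0, cumsum(seg_len)) / spec$scan_rate # time at each vertex
  tt <- seq(0, t_vert[length(t_vert)], length.out = n)
  stats::approx(t_vert, spec$vertices, xout = tt, rule = 2)$y
}

# Indices of the anodic (first, rising) segment of the sweep.
anodic_indices <- function(potential_axis) {
  peak <- which.max(potential_axis)[1]
  seq_len(peak)
}

#' Analyte cyclic-voltammogram template
#'
#' Parametric description of the oxidation/reduction signature of an analyte
#' along the sweep: a Gaussian oxidation bump on the anodic segment and a
#' Gaussian reduction trough on the cathodic segment, scaled to unit peak
#' amplitude by [make_template()]. Serotonin's oxidation peak must lie inside
#' the 0.4-0.8 V window used for FSCAV charge integration; dopamine's default
#' centre is placed lower, so that a serotonin-to-dopamine transition shifts
#' the oxidation potential.
#'
#' @param analyte Label, \code{"serotonin"} or \code{"dopamine"}.
#' @param ox_center,ox_width Oxidation peak centre and Gaussian width (V).
#' @param red_center,red_width Reduction trough centre and width (V).
#' @param ox_red_amplitude_ratio Oxidation-to-reduction amplitude ratio.
#' @return An object of class \code{analyte_template}.
#' @export
analyte_template <- function(analyte = c("serotonin", "dopamine"),
                             ox_center = NULL, ox_width = 0.06,
                             red_center = NULL, red_width = 0.08,
                             ox_red_amplitude_ratio = 3) {
  analyte <- match.arg(analyte)
  defaults <- switch(analyte,
    serotonin = list(ox = 0.65, red = -0.05),
    dopamine  = list(ox = 0.45, red = 0.05)
  )
  ox_center <- ox_center %||% defaults$ox
  red_center <- red_center %||% defaults$red
  stop_if(ox_width <= 0 || red_width <= 0, "template widths must be positive")
  stop_if(analyte == "serotonin" && (ox_center < 0.4 || ox_center > 0.8),
          "serotonin oxidation centre must lie in [0.4, 0.8] V")
  stop_if(ox_red_amplitude_ratio <= 0, "ox_red_amplitude_ratio must be positive")
  structure(
    list(analyte = analyte, ox_center = ox_center, ox_width = ox_width,
         red_center = red_center, red_width = red_width,
         ox_red_amplitude_ratio = ox_red_amplitude_ratio),
    class = "analyte_template"
  )
}

#' Per-sample CV signature of an analyte
#'
#' Evaluates an [analyte_template()] along a waveform: Gaussian oxidation
#' bump on the anodic (rising) segment, negative reduction trough on the
#' cathodic (falling) segment, normalised so that \code{max(abs(.)) == 1}
#' (oxidation peak positive). An \code{amplitude_scale} of 0 returns an
#' all-zero signature.
#'
#' @param template An [analyte_template()].
#' @param spec A [waveform_spec()].
#' @param n_samples Optional sweep resolution (see [build_waveform()]).
#' @param amplitude_scale Overall multiplier applied after normalisation.
#' @return Numeric vector, one value per potential sample.
#' @export
make_template <- function(template, spec = waveform_spec(), n_samples = NULL,
                          amplitude_scale = 1) {
  stopifnot(inherits(template, "analyte_template"))
  axis <- build_waveform(spec, n_samples)
  rng <- range(axis)
  stop_if(template$ox_center < rng[1] || template$ox_center > rng[2],
          "oxidation centre outside the waveform potential range")
  stop_if(template$red_center < rng[1] || template$red_center > rng[2],
          "reduction centre outside the waveform potential range")
  n <- length(axis)
  anodic <- seq_len(n) %in% anodic_indices(axis)
  ox <- exp(-(axis - template$ox_center)^2 / (2 * template$ox_width^2))
  red <- exp(-(axis - template$red_center)^2 / (2 * template$red_width^2))
  sig <- ifelse(anodic, ox, 0) -
    ifelse(!anodic, red, 0) / template$ox_red_amplitude_ratio
  m <- max(abs(sig))
  if (m > 0) sig <- sig / m
  sig * amplitude_scale
}
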