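#' FSCV color plot container
#'
#' A color plot is the raw unit of FSCV data: a 2-D current matrix whose rows
#' are potential samples within one sweep and whose columns are successive
#' sweep applications (time frames, spaced \code{1/repetition_hz}).
#'
#' @param current Numeric matrix of currents (nA), rows = potential samples,
#'   columns = time frames. All entries must be finite.
#' @param potential_axis Applied potential per row (V); length must match
#'   \code{nrow(current)}.
#' @param time_axis Acquisition time per column (s); defaults to frames at the
#'   waveform repetition rate starting at 0.
#' @param t0_stim Stimulation onset (s) on the time axis.
#' @param waveform The [waveform_spec()] that generated the sweep.
#' @param meta Free-form provenance list (animal id, analyte, ...).
#' @return An object of class \code{color_plot}.
#' @export
color_plot <- function(current, potential_axis, time_axis = NULL,
                       t0_stim = 0, waveform = waveform_spec(), meta = list()) {
  current <- as.matrix(current)
  stop_if(!all(is.finite(current)), "color plot currents must be finite")
  stop_if(length(potential_axis) != nrow(current),
          "potential axis length must equal the row count")
  time_axis <- time_axis %||%
    ((seq_len(ncol(current)) - 1) / waveform$repetition_hz)
  stop_if(length(time_axis) != ncol(current),
          "time axis length must equal the column count")
  structure(
    list(current = current, potential_axis = as.numeric(potential_axis),
         time_axis = as.numeric(time_axis), t0_stim = t0_stim,
         waveform = waveform, meta = meta),
    class = "color_plot"
  )
}

#' @export
print.color_plot <- function(x, ...) {
  cat(sprintf("<color_plot> %d potential samples x %d frames, %.2f s span\n",
              nrow(x$current), ncol(x$current), diff(range(x$time_axis))))
  if (!is.null(x$meta$analyte))
    cat("  analyte:", x$meta$analyte,
        if (!is.null(x$meta$animal)) sprintf("(animal %s)", x$meta$animal), "\n")
  invisible(x)
}

#' @export
dim.color_plot <- function(x) dim(x$current)

#' Simulate an evoked FSCV color plot
#'
#' Builds a synthetic color plot as the outer product of an analyte CV
#' signature and an evoked concentration transient, plus linear drift and
#' white noise:
#' \deqn{I_{ij} = T_i \, C(t_j)/49.5 + d \cdot t_j + \epsilon_{ij}}
#' where \eqn{T} is the unit-amplitude template, \eqn{C(t)} the transient in
#' nM (divided by the 49.5 nM/nA calibration factor to express current in
#' nA), \eqn{d} the drift in nA/s and \eqn{\epsilon} iid Gaussian noise.
#'
#' @param template An [analyte_template()].
#' @param transient An [evoked_trace()] (concentration in nM); its length must
#'   equal \code{n_frames} and its sampling must match the repetition rate.
#' @param spec A [waveform_spec()].
#' @param n_rows Sweep resolution (rows); defaults to the native count.
#' @param noise_sd Gaussian current noise SD (nA), >= 0.
#' @param drift Linear drift (nA/s) added uniformly across all rows.
#' @param seed Integer seed; the output is a pure function of the arguments
#'   and this seed.
#' @param meta Provenance list stored on the plot.
#' @return A [color_plot()].
#' @export
simulate_color_plot <- function(template, transient, spec = waveform_spec(),
                                n_rows = NULL, noise_sd = 0, drift = 0,
                                seed = NULL, meta = list()) {
  stop_if(noise_sd < 0, "noise_sd must be non-negative")
  stopifnot(inherits(transient, "evoked_trace"))
  sig <- make_template(template, spec, n_rows)
  conc <- transient$concentration
  tt <- transient$time
  n <- length(sig)
  m <- length(conc)
  current <- outer(sig, conc / 49.5) +
    matrix(drift * tt, n, m, byrow = TRUE)
  if (noise_sd > 0) {
    current <- current + with_seed(seed, matrix(rnorm(n * m, 0, noise_sd), n, m))
  }
  meta$analyte <- meta$analyte %||% template$analyte
  color_plot(current, build_waveform(spec, n_rows), time_axis = tt,
             t0_stim = transient$stim_window[1], waveform = spec, meta = meta)
}

#' Standardize a color plot
#'
#' Rescales the current matrix to zero mean and unit standard deviation
#' (population form consistent with \code{sd()}), the preprocessing applied
#' to every source plot before convex mixing so that amplitude differences
#' between acquisitions do not leak into the mixture labels. Standardisation
#' is idempotent and invariant to affine transforms of the input.
#'
#' @param plot A [color_plot()] with at least two distinct values.
#' @return A standardized [color_plot()] (mean 0, SD 1 within 1e-9).
#' @export
standardize_plot <- function(plot) {
  stopifnot(inherits(plot, "color_plot"))
  x <- plot$current
  s <- sd(x)
  stop_if(!is.finite(s) || s == 0,
          "cannot standardize a constant color plot (zero variance)")
  plot$current <- (x - mean(x)) / s
  plot$meta$standardized <- TRUE
  plot
}

# ---- on-disk dialect: CSV matrix + JSON sidecar --------------------------

#' Write / read a color plot (CSV matrix + JSON sidecar)
#'
#' The current matrix is stored as a headerless CSV; axes, stimulation onset,
#' waveform and metadata go to \code{<path>.json}.
#'
#' @param plot A [color_plot()].
#' @param path CSV file path (sidecar written next to it).
#' @return \code{write_color_plot} returns \code{path} invisibly;
#'   \code{read_color_plot} returns the reconstructed [color_plot()].
#' @export
write_color_plot <- function(plot, path) {
  stopifnot(inherits(plot, "color_plot"))
  # %.17g round-trips doubles exactly, so a plot read back predicts
  # bit-identically to the in-memory original
  chr <- matrix(sprintf("%.17g", plot$current), nrow(plot$current))
  utils::write.table(chr, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  side <- list(
    potential_axis = plot$potential_axis, time_axis = plot$time_axis,
    t0_stim = plot$t0_stim, waveform = unclass(plot$waveform),
    meta = plot$meta
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_color_plot
#' @export
read_color_plot <- function(path) {
  cur <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(cur) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  wf <- do.call(waveform_spec, side$waveform)
  color_plot(cur, side$potential_axis, side$time_axis, side$t0_stim, wf,
             meta = as.list(side$meta))
}
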