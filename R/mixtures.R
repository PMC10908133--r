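#' Convex mixture of two standardized color plots
#'
#' The augmentation primitive: given a standardized serotonin plot \eqn{A} and
#' a standardized dopamine plot \eqn{B}, the synthetic plot with label
#' \eqn{r} is \deqn{X = r A + (1-r) B.} Endpoints are exact: \eqn{r=1} returns
#' \eqn{A} and \eqn{r=0} returns \eqn{B}. Mixtures are not re-standardized
#' (their mean stays 0 by linearity but the SD generally drops below 1).
#'
#' @param A,B Standardized [color_plot()]s of identical shape (serotonin and
#'   dopamine source, respectively).
#' @param r Mixing ratio in \[0, 1\]: 1 = pure serotonin, 0 = pure dopamine.
#' @return An object of class \code{synthetic_mixture} with elements
#'   \code{plot} (the mixed [color_plot()]), \code{ratio} and \code{parents}.
#' @export
mix_plots <- function(A, B, r) {
  stopifnot(inherits(A, "color_plot"), inherits(B, "color_plot"))
  stop_if(!all(dim(A$current) == dim(B$current)),
          "source plots must have identical shape")
  stop_if(r < 0 || r > 1, "mixing ratio must lie in [0, 1]")
  check_std <- function(p, lab) {
    stop_if(abs(mean(p$current)) > 1e-6 || abs(sd(p$current) - 1) > 1e-6,
            paste(lab, "plot must be standardized (mean 0, SD 1)"))
  }
  check_std(A, "serotonin")
  check_std(B, "dopamine")
  mixed <- A
  mixed$current <- r * A$current + (1 - r) * B$current
  mixed$meta <- list(analyte = "mixture", ratio = r)
  structure(list(plot = mixed, ratio = r,
                 parents = c(serotonin = A$meta$id %||% NA_character_,
                             dopamine = B$meta$id %||% NA_character_)),
            class = "synthetic_mixture")
}

#' Generate a labeled mixture training set
#'
#' Draws, for each synthetic plot, one serotonin source, one dopamine source
#' (both uniformly) and a mixing ratio \eqn{r \sim U(0,1)}, and forms the
#' convex mixture with [mix_plots()]. Source plots are standardized first if
#' they are not already. The default size is 5000 plots per serotonin animal;
#' \code{n_total} overrides the total outright (used by the reduced test
#' profile). Input-side Gaussian noise is *not* baked in here; the trainer
#' adds fresh noise to every batch so that each presented signal is unique.
#'
#' @param serotonin_plots,dopamine_plots Non-empty lists of [color_plot()]s.
#' @param n_per_animal Mixtures per serotonin animal (default 5000).
#' @param n_total Optional total count overriding \code{n_per_animal}.
#' @param seed Integer seed (the set is a pure function of inputs and seed).
#' @return A \code{mixture_set}: list with \code{x} (array
#'   \code{height x width x n}), \code{ratio} (labels), \code{parents}
#'   (data.frame of source indices) and \code{dims}.
#' @export
generate_training_set <- function(serotonin_plots, dopamine_plots,
                                  n_per_animal = 5000, n_total = NULL,
                                  seed = NULL) {
  stop_if(length(serotonin_plots) == 0 || length(dopamine_plots) == 0,
          "both source plot lists must be non-empty")
  std <- function(p) if (isTRUE(p$meta$standardized)) p else standardize_plot(p)
  serotonin_plots <- lapply(serotonin_plots, std)
  dopamine_plots <- lapply(dopamine_plots, std)
  animals <- unique(vapply(serotonin_plots,
                           function(p) as.character(p$meta$animal %||% "a1"),
                           character(1)))
  n <- n_total %||% (n_per_animal * length(animals))
  d <- dim(serotonin_plots[[1]]$current)
  stop_if(!all(vapply(dopamine_plots,
                      function(p) all(dim(p$current) == d), logical(1))),
          "all source plots must share one shape")
  with_seed(seed, {
    ia <- sample.int(length(serotonin_plots), n, replace = TRUE)
    ib <- sample.int(length(dopamine_plots), n, replace = TRUE)
    r <- runif(n)
    x <- array(0, c(d[1], d[2], n))
    for (k in seq_len(n)) {
      x[, , k] <- r[k] * serotonin_plots[[ia[k]]]$current +
        (1 - r[k]) * dopamine_plots[[ib[k]]]$current
    }
    structure(list(x = x, ratio = r,
                   parents = data.frame(serotonin = ia, dopamine = ib),
                   dims = d),
              class = "mixture_set")
  })
}

#' @export
print.mixture_set <- function(x, ...) {
  cat(sprintf("<mixture_set> %d mixtures of %d x %d standardized plots\n",
              length(x$ratio), x$dims[1], x$dims[2]))
  invisible(x)
}

#' Generate the synthetic source-plot cohort
#'
#' Emulates the study's source data: 28 hippocampal serotonin color plots
#' (7 animals, 4 repetitions each) and 21 striatal dopamine color plots
#' (3 animals, 7 repetitions each). Each animal carries jittered template and
#' kinetic parameters; each repetition adds amplitude jitter, drift and
#' current noise. Serotonin transients follow the two-uptake
#' Michaelis-Menten model with the saline group kinetics; dopamine transients
#' use faster, higher-capacity uptake typical of the striatum.
#'
#' @param seed Integer seed.
#' @param spec A [waveform_spec()].
#' @param n_rows,n_frames Plot dimensions (defaults: native 220 rows, 300
#'   frames = 30 s at 10 Hz).
#' @param t0_stim Stimulation onset (s) within the plot.
#' @param noise_sd Current noise SD in nA.
#' @param drift_sd SD of the per-repetition linear drift rate (nA/s).
#' @return List with elements \code{serotonin} and \code{dopamine}, each a
#'   list of [color_plot()]s with \code{animal}/\code{rep} metadata.
#' @export
generate_fixture_cohort <- function(seed = 1, spec = waveform_spec(),
                                    n_rows = 220, n_frames = 300,
                                    t0_stim = 5, noise_sd = 0.05,
                                    drift_sd = 0.002) {
  rep_hz <- spec$repetition_hz
  duration <- n_frames / rep_hz
  make_group <- function(analyte, n_animals, n_reps, base_mm, base_rmax,
                         seed0) {
    plots <- list()
    for (a in seq_len(n_animals)) {
      sa <- child_seed(seed0, a)
      animal_pars <- with_seed(sa, list(
        ox_jit = rnorm(1, 0, 0.01),
        w_jit = exp(rnorm(1, 0, 0.08)),
        vmax_jit = exp(rnorm(1, 0, 0.08)),
        rmax_jit = exp(rnorm(1, 0, 0.10))
      ))
      tpl <- analyte_template(
        analyte,
        ox_center = (if (analyte == "serotonin") 0.65 else 0.45) +
          animal_pars$ox_jit,
        ox_width = 0.06 * animal_pars$w_jit
      )
      pars <- base_mm
      pars$vmax1 <- pars$vmax1 * animal_pars$vmax_jit
      pars$rmax <- base_rmax * animal_pars$rmax_jit
      for (r in seq_len(n_reps)) {
        sr <- child_seed(sa, 100 + r)
        rep_scale <- with_seed(sr, exp(rnorm(1, 0, 0.05)))
        prs <- pars
        prs$rmax <- prs$rmax * rep_scale
        tr <- simulate_mm(prs, duration = duration - t0_stim,
                          dt = 1 / rep_hz)
        conc <- c(rep(0, round(t0_stim * rep_hz)), tr$concentration)
        conc <- conc[seq_len(n_frames)]
        transient <- evoked_trace((seq_len(n_frames) - 1) / rep_hz, conc,
                                  stim_window = c(t0_stim, 2))
        drift <- with_seed(child_seed(sr, 1), rnorm(1, 0, drift_sd))
        plots[[length(plots) + 1]] <- simulate_color_plot(
          tpl, transient, spec, n_rows = n_rows, noise_sd = noise_sd,
          drift = drift, seed = child_seed(sr, 2),
          meta = list(analyte = analyte, animal = paste0(analyte, "_", a),
                      rep = r, id = paste0(analyte, "_", a, "_", r))
        )
      }
    }
    plots
  }
  saline <- mm_params(vmax1 = 11.13, km1 = 2.40, vmax2 = 780, km2 = 170,
                      rmax = 38.40)
  dop <- mm_params(vmax1 = 3500, km1 = 200, vmax2 = 0, km2 = 170,
                   rmax = 2000)
  list(
    serotonin = make_group("serotonin", 7, 4, saline, 38.40,
                           child_seed(seed, 11)),
    dopamine = make_group("dopamine", 3, 7, dop, 2000,
                          child_seed(seed, 22))
  )
}
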