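#' SNc-to-DRN stimulation function
#'
#' Firing drive delivered to dorsal-raphe serotonin neurons by the surviving
#' substantia-nigra population:
#' \deqn{stim = f \left(1.5 - \frac{c^2}{0.000968^2 + c^2}\right)}
#' where \eqn{f} is the fraction of SNc cells alive and \eqn{c} the DRN
#' serotonin concentration in uM (0.000968 uM is its healthy equilibrium, at
#' which the drive equals \eqn{f}). An optional \code{non_snc_drive} fraction
#' models DRN input that does not originate in the SNc (default 0: all drive
#' comes from the SNc).
#'
#' @param f Fraction of SNc cells alive, in \[0, 1\].
#' @param c_uM DRN serotonin concentration (uM), >= 0.
#' @param gain Drive ceiling constant (default 1.5).
#' @param c_eq_uM DRN equilibrium concentration (uM).
#' @param non_snc_drive Fraction of drive independent of SNc survival.
#' @return Dimensionless drive.
#' @export
#' @examples
#' stimulation(1, 0.000968) # 1
stimulation <- function(f, c_uM, gain = 1.5, c_eq_uM = 0.000968,
                        non_snc_drive = 0) {
  stop_if(any(f < 0 | f > 1), "f must lie in [0, 1]")
  stop_if(any(c_uM < 0), "concentration must be non-negative")
  eff <- (1 - non_snc_drive) * f + non_snc_drive
  eff * (gain - c_uM^2 / (c_eq_uM^2 + c_uM^2))
}

#' Parameters of the reduced serotonin-dopamine hippocampus model
#'
#' A reduced monoamine projection model with three tissue compartments
#' (DRN serotonin, hippocampal extracellular serotonin and dopamine),
#' vesicular serotonin/dopamine pools inside serotonergic terminals, a
#' cytosolic L-DOPA pool, and the escitalopram pharmacokinetic/SERT-binding
#' states E (drug), F (free SERT) and B (bound SERT). Rates are per hour,
#' concentrations in nM (the DRN value is converted to uM inside
#' [stimulation()]).
#'
#' Free gains (\code{synthesis}, \code{da_release}, DRN uptake constants and
#' the escitalopram input amplitude \code{escit_I0}) are left \code{NA} here
#' and solved by [calibrate_monoamine()] from the anchors: 35 nM hippocampal
#' serotonin and 0.000968 uM DRN serotonin at \eqn{f = 1}, and 50% peak SERT
#' occupancy after a dose.
#'
#' @param c_eq_uM,gain Stimulation constants (see [stimulation()]).
#' @param drn_release DRN serotonin release gain (nM/h per unit drive).
#' @param sert_vmax,sert_km Hippocampal SERT uptake (nM/h, nM).
#' @param diffusion_5ht First-order serotonin diffusion loss (1/h).
#' @param vesicle_leak Leakage rate out of the vesicular pools (1/h),
#'   default 40.
#' @param vesicle_release Firing-gated vesicular release rate constant (1/h).
#' @param serotonin_target Healthy ambient hippocampal serotonin (nM).
#' @param dat_vmax,dat_km DAT uptake at full SNc survival (nM/h, nM); the
#'   capacity scales with \code{f} because transporter density tracks the
#'   surviving terminals.
#' @param diffusion_da First-order dopamine diffusion loss (1/h).
#' @param dopamine_target Healthy ambient hippocampal dopamine (nM).
#' @param ldopa_absorption L-DOPA absorption rate into the terminals (1/h).
#' @param aadc_rate First-order AADC conversion of cytosolic L-DOPA (1/h).
#' @param escit_elimination,escit_k1,escit_k2 Escitalopram elimination (1/h),
#'   SERT binding (per concentration per h) and unbinding (1/h) constants.
#' @param escit_absorption Rate constant of the single-exponential drug input
#'   (1/h).
#' @param sert_total Total SERT concentration F + B (conserved; normalised
#'   to 1).
#' @param non_snc_drive Fraction of DRN drive independent of the SNc.
#' @param synthesis,da_release,drn_vmax,drn_km,escit_I0 Calibrated constants
#'   (leave \code{NA}).
#' @return An object of class \code{monoamine_params}.
#' @export
monoamine_params <- function(c_eq_uM = 0.000968, gain = 1.5,
                             drn_release = 9.68,
                             sert_vmax = 1000, sert_km = 170,
                             diffusion_5ht = 0.5,
                             vesicle_leak = 40, vesicle_release = 2,
                             serotonin_target = 35,
                             dat_vmax = 4000, dat_km = 200,
                             diffusion_da = 1, dopamine_target = 5,
                             ldopa_absorption = 2, aadc_rate = 2,
                             escit_elimination = 0.371, escit_k1 = 7,
                             escit_k2 = 20, escit_absorption = 2,
                             sert_total = 1, non_snc_drive = 0,
                             synthesis = NA, da_release = NA,
                             drn_vmax = NA, drn_km = NA, escit_I0 = NA) {
  p <- as.list(environment())
  rates <- c(p$drn_release, p$sert_vmax, p$diffusion_5ht, p$vesicle_leak,
             p$vesicle_release, p$dat_vmax, p$diffusion_da,
             p$ldopa_absorption, p$aadc_rate, p$escit_elimination,
             p$escit_k1, p$escit_k2, p$escit_absorption)
  stop_if(any(rates < 0), "rate constants must be non-negative")
  stop_if(p$c_eq_uM <= 0, "DRN equilibrium concentration must be positive")
  structure(p, class = "monoamine_params")
}

#' Calibrate the free gains of the monoamine model
#'
#' Solves the model's free constants from its anchors: the DRN uptake is set
#' so the drive equals 1 exactly at the healthy equilibrium (Km equal to the
#' equilibrium concentration, Vmax twice the release gain); the vesicular
#' synthesis rate is solved so hippocampal serotonin settles at
#' \code{serotonin_target} (35 nM) at \eqn{f = 1}; the dopamine release gain
#' so dopamine settles at \code{dopamine_target}; and the escitalopram input
#' amplitude \code{escit_I0} is found by scalar root-finding so that peak
#' SERT occupancy over the simulated dose equals 50%.
#'
#' @param params A [monoamine_params()].
#' @param occupancy_target Peak bound-SERT fraction (default 0.5).
#' @return The calibrated \code{monoamine_params} (fields filled in,
#'   \code{calibrated = TRUE}).
#' @export
calibrate_monoamine <- function(params = monoamine_params(),
                                occupancy_target = 0.5) {
  stopifnot(inherits(params, "monoamine_params"))
  p <- params
  c_eq <- p$c_eq_uM * 1000 # nM
  p$drn_km <- c_eq
  p$drn_vmax <- 2 * p$drn_release # drive 1 balances uptake at c_eq
  s <- p$serotonin_target
  release_needed <- p$sert_vmax * s / (p$sert_km + s) + p$diffusion_5ht * s
  v5_eq <- release_needed / p$vesicle_release # at drive 1
  p$synthesis <- v5_eq * (p$vesicle_leak + p$vesicle_release)
  d <- p$dopamine_target
  p$da_release <- p$dat_vmax * d / (p$dat_km + d) + p$diffusion_da * d
  p$escit_I0 <- uniroot(
    function(i0) peak_occupancy(p, i0) - occupancy_target,
    c(1e-3, 1e4), tol = 1e-10
  )$root
  p$calibrated <- TRUE
  p
}

# escitalopram input from blood to extracellular space: single-exponential
# absorption pulse starting at the dose time
escit_input <- function(t, i0, ka, dose_time = 0) {
  ifelse(t >= dose_time, i0 * exp(-ka * (t - dose_time)), 0)
}

#' Escitalopram pharmacokinetic / SERT-binding derivatives
#'
#' Right-hand side of the three drug states: extracellular escitalopram E is
#' driven by the blood input I(t) and eliminated at 0.371/h; free (F) and
#' bound (B) SERT exchange by mass action with binding constant k1 = 7 and
#' unbinding k2 = 20. dF/dt and dB/dt are exact negatives, so F + B is
#' conserved identically.
#'
#' @param state Named vector or list with \code{E}, \code{F}, \code{B}
#'   (non-negative).
#' @param t Time (h).
#' @param params A [monoamine_params()].
#' @param dose_time Dose time (h).
#' @return Named vector \code{c(dE, dF, dB)} (per hour).
#' @export
escit_rhs <- function(state, t, params = monoamine_params(), dose_time = 0) {
  stopifnot(inherits(params, "monoamine_params"))
  E <- state[["E"]]; Fr <- state[["F"]]; B <- state[["B"]]
  stop_if(any(c(E, Fr, B) < 0), "drug states must be non-negative")
  i0 <- params$escit_I0
  inp <- if (is.na(i0)) 0 else escit_input(t, i0, params$escit_absorption,
                                           dose_time)
  bind <- params$escit_k1 * E * Fr - params$escit_k2 * B
  c(dE = inp - params$escit_elimination * E, dF = -bind, dB = bind)
}

# Integrate only (E, B) with F = sert_total - B (structural conservation)
# and return the trajectory of the occupancy B/(F+B).
simulate_occupancy <- function(params, i0, duration_h = 24, dose_time = 0,
                               dt = 0.01) {
  rhs <- function(t, y, p) {
    E <- max(y[1], 0); B <- min(max(y[2], 0), p$sert_total)
    dE <- escit_input(t, i0, p$escit_absorption, dose_time) -
      p$escit_elimination * E
    dB <- p$escit_k1 * E * (p$sert_total - B) - p$escit_k2 * B
    list(c(dE, dB))
  }
  times <- seq(dose_time, dose_time + duration_h, by = dt)
  sol <- deSolve::lsoda(c(0, 0), times, rhs, params, rtol = 1e-10,
                        atol = 1e-12)
  data.frame(time = sol[, 1], E = sol[, 2],
             occupancy = sol[, 3] / params$sert_total)
}

peak_occupancy <- function(params, i0, duration_h = 24) {
  max(simulate_occupancy(params, i0, duration_h)$occupancy)
}

# ---- full reduced model ---------------------------------------------------

# state vector: c (DRN 5-HT, nM), s (hipp 5-HT, nM), d (hipp DA, nM),
# v5, vda (vesicular pools), L (cytosolic L-DOPA), E, B (escitalopram).
# F = sert_total - B is reconstructed, so F + B is conserved exactly.
monoamine_state_names <- c("c_drn", "s_hipp", "d_hipp", "v5", "vda", "L",
                           "E", "B")

monoamine_rhs <- function(t, y, parms) {
  p <- parms$p
  f <- parms$f
  inputs <- parms$inputs
  y <- pmax(y, 0)
  c_drn <- y[1]; s <- y[2]; d <- y[3]; v5 <- y[4]; vda <- y[5]
  L <- y[6]; E <- y[7]; B <- min(y[8], p$sert_total)
  phi <- stimulation(f, c_drn / 1000, p$gain, p$c_eq_uM, p$non_snc_drive)
  free_frac <- (p$sert_total - B) / p$sert_total

  dc <- p$drn_release * phi - p$drn_vmax * c_drn / (p$drn_km + c_drn)
  ds <- p$vesicle_release * phi * v5 -
    p$sert_vmax * free_frac * s / (p$sert_km + s) - p$diffusion_5ht * s
  dv5 <- p$synthesis - p$vesicle_leak * v5 - p$vesicle_release * phi * v5
  dvda <- p$aadc_rate * L - p$vesicle_leak * vda -
    p$vesicle_release * phi * vda
  dd <- p$da_release * f + p$vesicle_release * phi * vda -
    p$dat_vmax * f * d / (p$dat_km + d) - p$diffusion_da * d
  u_ld <- if (inputs$ldopa_dose > 0 && t >= inputs$ldopa_time) {
    inputs$ldopa_dose * p$ldopa_absorption *
      exp(-p$ldopa_absorption * (t - inputs$ldopa_time))
  } else 0
  dL <- u_ld - p$aadc_rate * L
  i_es <- if (inputs$escit && t >= inputs$escit_time) {
    escit_input(t, p$escit_I0, p$escit_absorption, inputs$escit_time)
  } else 0
  dE <- i_es - p$escit_elimination * E
  dB <- p$escit_k1 * E * (p$sert_total - B) - p$escit_k2 * B
  list(c(dc, ds, dd, dv5, dvda, dL, dE, dB))
}

no_inputs <- function() {
  list(ldopa_dose = 0, ldopa_time = 0, escit = FALSE, escit_time = 0)
}

integrate_model <- function(y0, times, p, f, inputs = no_inputs(),
                            rtol = 1e-8, atol = 1e-12) {
  parms <- list(p = p, f = f, inputs = inputs)
  breaks <- sort(unique(c(times[1], times[length(times)],
                          if (inputs$escit) inputs$escit_time,
                          if (inputs$ldopa_dose > 0) inputs$ldopa_time)))
  breaks <- breaks[breaks >= times[1] & breaks <= times[length(times)]]
  out <- matrix(NA_real_, length(times), length(y0))
  out[1, ] <- y0
  y <- y0
  for (k in seq_len(length(breaks) - 1)) {
    seg <- times[times >= breaks[k] - 1e-12 & times <= breaks[k + 1] + 1e-12]
    seg <- sort(unique(c(breaks[k], seg, breaks[k + 1])))
    sol <- deSolve::lsoda(y, seg, monoamine_rhs, parms, rtol = rtol,
                          atol = atol)
    hit <- match(signif(times, 12), signif(sol[, 1], 12), nomatch = 0)
    out[hit > 0, ] <- sol[hit, -1, drop = FALSE]
    y <- sol[nrow(sol), -1]
  }
  colnames(out) <- monoamine_state_names
  cbind(time = times, out)
}

#' Equilibrium of the monoamine model at a given SNc survival
#'
#' Integrates the drug-free reduced model to equilibrium (long integration
#' followed by a Newton polish on the algebraic fixed point), at tolerance
#' 1e-10 on the scaled derivative norm. At \eqn{f = 1} the calibrated model
#' settles at 35 nM hippocampal serotonin and 0.000968 uM DRN serotonin.
#'
#' @param f Fraction of SNc cells alive.
#' @param params Calibrated [monoamine_params()].
#' @param init Optional initial state (full 8-vector) for warm starts.
#' @param max_hours Abort if no equilibrium within this model time.
#' @return Named list: the equilibrium state (nM), \code{drive}, and
#'   \code{converged}.
#' @export
simulate_steady_state <- function(f, params = calibrate_monoamine(),
                                  init = NULL, max_hours = 1e4) {
  stopifnot(inherits(params, "monoamine_params"))
  stop_if(!isTRUE(params$calibrated), "params must be calibrated first")
  stop_if(f < 0 || f > 1, "f must lie in [0, 1]")
  y <- init %||% c(params$c_eq_uM * 1000, params$serotonin_target,
                   params$dopamine_target,
                   params$synthesis / params$vesicle_leak, 0, 0, 0, 0)
  parms <- list(p = params, f = f, inputs = no_inputs())
  resid <- function(y) unlist(monoamine_rhs(0, y, parms))
  tol_ok <- function(y) max(abs(resid(y)) / (1 + abs(y))) < 1e-10
  elapsed <- 0
  chunk <- 200
  while (!tol_ok(y) && elapsed < max_hours) {
    sol <- deSolve::lsoda(y, c(0, chunk), monoamine_rhs, parms,
                          rtol = 1e-10, atol = 1e-12)
    y <- pmax(sol[nrow(sol), -1], 0)
    elapsed <- elapsed + chunk
    # Newton polish on the fixed point (numerical Jacobian)
    for (it in 1:20) {
      r <- resid(y)
      if (max(abs(r) / (1 + abs(y))) < 1e-12) break
      n <- length(y)
      J <- matrix(0, n, n)
      for (j in seq_len(n)) {
        h <- 1e-7 * (1 + abs(y[j]))
        yp <- y; yp[j] <- yp[j] + h
        ym <- y; ym[j] <- ym[j] - h
        J[, j] <- (resid(yp) - resid(ym)) / (2 * h)
      }
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step)) break
      y_new <- pmax(y - step, 0)
      if (max(abs(resid(y_new))) <= max(abs(r))) y <- y_new else break
    }
  }
  stop_if(!tol_ok(y),
          sprintf("no equilibrium within %g model hours", max_hours))
  names(y) <- monoamine_state_names
  list(state = y, serotonin_nM = y[["s_hipp"]], dopamine_nM = y[["d_hipp"]],
       drn_uM = y[["c_drn"]] / 1000,
       drive = stimulation(f, y[["c_drn"]] / 1000, params$gain,
                           params$c_eq_uM, params$non_snc_drive),
       converged = TRUE)
}

#' Equilibrium serotonin and dopamine across SNc degeneration
#'
#' Computes the hippocampal serotonin and dopamine equilibria over a grid of
#' SNc survival fractions and normalises both to the healthy (\eqn{f = 1})
#' value. In the calibrated model serotonin declines almost linearly with
#' \eqn{f} while dopamine is homeostatic until the large majority of SNc
#' cells has died.
#'
#' @param f_grid Survival fractions in \[0, 1\] (1 is added if absent, for
#'   normalisation).
#' @param params Calibrated [monoamine_params()].
#' @return data.frame with \code{f}, \code{serotonin_nM}, \code{dopamine_nM},
#'   \code{serotonin_rel}, \code{dopamine_rel} (percent of the f = 1 value).
#' @export
degeneration_sweep <- function(f_grid = seq(0, 1, by = 0.05),
                               params = calibrate_monoamine()) {
  stop_if(length(f_grid) == 0, "empty survival grid")
  stop_if(any(f_grid < 0 | f_grid > 1), "f values must lie in [0, 1]")
  f_grid <- round(f_grid, 9) # snap seq() artefacts so f values match exactly
  ff <- sort(unique(c(f_grid, 1)), decreasing = TRUE)
  init <- NULL
  rows <- vector("list", length(ff))
  for (k in seq_along(ff)) {
    eq <- simulate_steady_state(ff[k], params, init = init)
    init <- eq$state # warm start the next (nearby) survival fraction
    rows[[k]] <- data.frame(f = ff[k], serotonin_nM = eq$serotonin_nM,
                            dopamine_nM = eq$dopamine_nM)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$f), ]
  ref <- out[out$f == 1, ]
  out$serotonin_rel <- 100 * out$serotonin_nM / ref$serotonin_nM
  out$dopamine_rel <- 100 * out$dopamine_nM / ref$dopamine_nM
  out[out$f %in% f_grid, , drop = FALSE]
}

#' Simulated escitalopram experiment
#'
#' Starts the model at the \eqn{f}-dependent equilibrium, runs a flat
#' pre-dose segment, doses escitalopram at \code{dose_time_min} and follows
#' hippocampal extracellular serotonin and SERT occupancy. SERT uptake is
#' scaled by the free-transporter fraction \eqn{F/(F+B)}.
#'
#' @param f Fraction of SNc cells alive (1 = control, 0.35 = MPTP condition).
#' @param dose_time_min Dose time in minutes (>= 0).
#' @param duration_min Total simulated minutes.
#' @param params Calibrated [monoamine_params()].
#' @return data.frame with \code{time_min}, \code{serotonin_nM},
#'   \code{occupancy}; attributes \code{peak_occupancy} and
#'   \code{baseline_nM}.
#' @export
simulate_escit_experiment <- function(f = 1, dose_time_min = 60,
                                      duration_min = 300,
                                      params = calibrate_monoamine()) {
  stop_if(dose_time_min < 0, "dose time must be non-negative")
  stop_if(duration_min <= dose_time_min, "duration must extend past the dose")
  eq <- simulate_steady_state(f, params)
  times <- seq(0, duration_min, by = 1) / 60
  inputs <- no_inputs()
  inputs$escit <- TRUE
  inputs$escit_time <- dose_time_min / 60
  sol <- integrate_model(eq$state, times, params, f, inputs)
  occ <- sol[, "B"] / params$sert_total
  out <- data.frame(time_min = sol[, "time"] * 60,
                    serotonin_nM = sol[, "s_hipp"],
                    occupancy = occ)
  attr(out, "peak_occupancy") <- max(occ)
  attr(out, "baseline_nM") <- eq$serotonin_nM
  out
}

#' Simulated L-DOPA experiment
#'
#' Doses L-DOPA at time zero on top of the \eqn{f}-dependent equilibrium and
#' follows hippocampal dopamine for \code{duration_h} hours. L-DOPA is
#' absorbed into serotonergic terminals, decarboxylated by AADC into a
#' vesicular dopamine pool and co-released with serotonin in proportion to
#' DRN firing; clearance combines \eqn{f}-scaled DAT uptake with diffusion
#' loss. The pulse amplitude is therefore non-monotone in \eqn{f}: moderate
#' degeneration removes DATs (bigger pulses) but severe degeneration removes
#' the firing drive (smaller pulses).
#'
#' @param f Fraction of SNc cells alive.
#' @param dose L-DOPA dose (nM equivalents delivered to the terminals);
#'   >= 0.
#' @param duration_h Simulated hours (default 8).
#' @param params Calibrated [monoamine_params()].
#' @return data.frame with \code{time_h}, \code{dopamine_nM},
#'   \code{serotonin_nM}; attributes \code{amplitude} (max minus baseline)
#'   and \code{baseline_nM}.
#' @export
simulate_ldopa <- function(f = 1, dose = 5000, duration_h = 8,
                           params = calibrate_monoamine()) {
  stop_if(dose < 0, "dose must be non-negative")
  eq <- simulate_steady_state(f, params)
  times <- seq(0, duration_h, by = 1 / 60)
  inputs <- no_inputs()
  inputs$ldopa_dose <- dose
  inputs$ldopa_time <- 0
  sol <- integrate_model(eq$state, times, params, f, inputs)
  out <- data.frame(time_h = sol[, "time"], dopamine_nM = sol[, "d_hipp"],
                    serotonin_nM = sol[, "s_hipp"])
  attr(out, "amplitude") <- max(out$dopamine_nM) - eq$dopamine_nM
  attr(out, "baseline_nM") <- eq$dopamine_nM
  out
}
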