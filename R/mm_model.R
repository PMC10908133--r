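#' Two-uptake Michaelis-Menten parameters
#'
#' Parameter set of the evoked release/reuptake model
#' \deqn{dC/dt = R(t)(1-A(t)) - \alpha \frac{V_{max1} C}{K_{m1}+C}
#'   - \beta \frac{V_{max2} C}{K_{m2}+C}}
#' where uptake 1 represents serotonin transporters (SERT) and uptake 2 the
#' other, low-affinity monoamine transporters. \eqn{R(t)} is modelled as a
#' rectangular pulse of height \code{rmax} over the stimulation window.
#'
#' @param vmax1,km1 SERT uptake capacity (nM/s) and affinity (nM).
#' @param vmax2,km2 Second-mechanism uptake capacity (nM/s) and affinity (nM);
#'   defaults 780 and 170, the values held fixed during fitting.
#' @param alpha,beta Weights of the two mechanisms (default 1; the printed
#'   Vmax values absorb them).
#' @param rmax Maximum evoked release rate (nM/s).
#' @return An object of class \code{mm_params}.
#' @export
mm_params <- function(vmax1 = 11.13, km1 = 2.40, vmax2 = 780, km2 = 170,
                      alpha = 1, beta = 1, rmax = 38.40) {
  v <- c(vmax1 = vmax1, km1 = km1, vmax2 = vmax2, km2 = km2,
         alpha = alpha, beta = beta, rmax = rmax)
  stop_if(any(!is.finite(v)) || any(v < 0), "parameters must be non-negative")
  stop_if(km1 <= 0 || km2 <= 0, "Michaelis constants must be positive")
  structure(as.list(v), class = "mm_params")
}

#' @export
print.mm_params <- function(x, ...) {
  cat(sprintf(
    paste0("<mm_params> Vmax1 %.4g nM/s, Km1 %.4g nM | Vmax2 %.4g, Km2 %.4g",
           " | alpha %.3g, beta %.3g | Rmax %.4g nM/s\n"),
    x$vmax1, x$km1, x$vmax2, x$km2, x$alpha, x$beta, x$rmax))
  invisible(x)
}

mm_par_vec <- function(p) {
  c(p$vmax1, p$km1, p$vmax2, p$km2, p$alpha, p$beta, p$rmax)
}

#' Simulate the two-uptake Michaelis-Menten model
#'
#' Integrates the evoked release model with \code{deSolve::lsoda} (rtol 1e-8,
#' atol 1e-12), splitting the integration at the stimulation edges so the
#' rectangular release pulse is handled exactly. Autoreceptor occupancy
#' \eqn{A(t)} is identically zero by default; an optional first-order
#' occupancy model \eqn{dA/dt = k_{on} C (1-A) - k_{off} A} can be switched on
#' via \code{autoreceptor = list(kon = ..., koff = ...)}.
#'
#' @param params An [mm_params()].
#' @param duration Simulated span (s) from stimulation onset.
#' @param dt Output sampling interval (s), default 0.1 (10 Hz).
#' @param c0 Initial concentration (nM).
#' @param stim_window Stimulation (start, duration) in seconds.
#' @param autoreceptor \code{NULL} (A = 0) or \code{list(kon, koff)}.
#' @return An [evoked_trace()] with non-negative concentrations.
#' @export
simulate_mm <- function(params, duration = 30, dt = 0.1, c0 = 0,
                        stim_window = c(0, 2), autoreceptor = NULL) {
  stopifnot(inherits(params, "mm_params"))
  stop_if(duration <= 0 || dt <= 0, "duration and dt must be positive")
  p <- params
  with_A <- !is.null(autoreceptor)
  rhs <- function(t, y, parms) {
    C <- max(y[1], 0)
    A <- if (with_A) min(max(y[2], 0), 1) else 0
    R <- if (t >= parms$t_on && t < parms$t_off) p$rmax else 0
    dC <- R * (1 - A) - p$alpha * p$vmax1 * C / (p$km1 + C) -
      p$beta * p$vmax2 * C / (p$km2 + C)
    if (with_A) {
      dA <- autoreceptor$kon * C * (1 - A) - autoreceptor$koff * A
      list(c(dC, dA))
    } else list(dC)
  }
  times <- seq(0, duration, by = dt)
  edges <- sort(unique(c(0, stim_window[1], sum(stim_window), duration)))
  edges <- edges[edges >= 0 & edges <= duration]
  y <- if (with_A) c(c0, 0) else c0
  out_c <- numeric(length(times))
  out_c[1] <- c0
  parms <- list(t_on = stim_window[1], t_off = sum(stim_window))
  for (k in seq_len(length(edges) - 1)) {
    seg <- times[times >= edges[k] - 1e-12 & times <= edges[k + 1] + 1e-12]
    seg <- sort(unique(c(edges[k], seg, edges[k + 1])))
    sol <- deSolve::lsoda(y, seg, rhs, parms, rtol = 1e-8, atol = 1e-12)
    keep <- match(round(times / dt), round(sol[, 1] / dt), nomatch = 0)
    out_c[keep > 0] <- sol[keep, 2]
    y <- sol[nrow(sol), -1]
  }
  evoked_trace(times, pmax(out_c, 0), stim_window = stim_window)
}

# Forward model + sensitivities on the trace's own grid, via the compiled
# fixed-step RK4 integrator. Returns concentration vector and the n x 7
# sensitivity matrix (columns in mm_par_vec order).
mm_forward_sens <- function(par_vec, trace, oversample = 5, c0 = 0) {
  tt <- trace$time
  .mm_sens_cpp(par_vec, c0, trace$stim_window[1], trace$stim_window[2],
               tt, as.integer(oversample))
}

#' Fit the Michaelis-Menten model to an evoked trace
#'
#' Gradient descent on the sum of squared residuals between the simulated and
#' observed trace. Gradients are exact, computed from forward sensitivity
#' equations integrated alongside the model; the descent operates on
#' log-parameters (which enforces positivity and equalises scales) with a
#' backtracking line search that grows the step after accepted moves. By
#' default only the SERT parameters and the release amplitude
#' (\code{vmax1}, \code{km1}, \code{rmax}) are free; the second uptake
#' mechanism and the weights are held fixed, mirroring the assumption that
#' the number of uptake-2 transporters does not change.
#'
#' @param trace An [evoked_trace()] to fit.
#' @param init An [mm_params()] with strictly positive starting values for the
#'   free parameters.
#' @param free Character vector of free parameter names (subset of
#'   \code{vmax1, km1, vmax2, km2, alpha, beta, rmax}).
#' @param max_iter Iteration cap (default 10000).
#' @param grad_tol Stop when the infinity norm of the log-space gradient falls
#'   below this (default 1e-6).
#' @param oversample RK4 sub-steps per trace sample (default 5).
#' @return A \code{mm_fit} list: \code{params} ([mm_params()]),
#'   \code{residual_norm} (RMS residual, nM), \code{sse}, \code{iterations},
#'   \code{converged}, \code{free}, and \code{trace_hat} (fitted trace).
#' @export
fit_mm <- function(trace, init = mm_params(vmax1 = 10, km1 = 5, rmax = 20),
                   free = c("vmax1", "km1", "rmax"),
                   max_iter = 10000, grad_tol = 1e-6, oversample = 5) {
  stopifnot(inherits(trace, "evoked_trace"), inherits(init, "mm_params"))
  names7 <- c("vmax1", "km1", "vmax2", "km2", "alpha", "beta", "rmax")
  stop_if(!all(free %in% names7), "unknown free parameter name")
  idx <- match(free, names7)
  theta <- mm_par_vec(init)
  stop_if(any(theta[idx] <= 0), "free parameters need positive starting values")
  y <- trace$concentration

  eval_sse <- function(th) {
    sim <- mm_forward_sens(th, trace, oversample)
    r <- sim$concentration - y
    list(sse = sum(r * r), r = r, S = sim$sensitivity,
         conc = sim$concentration)
  }

  grad_at <- function(cur, th_free) {
    2 * as.numeric(crossprod(cur$S[, idx, drop = FALSE], cur$r)) * th_free
  }

  # Steepest descent on the log-parameters with Barzilai-Borwein spectral
  # step lengths and a monotone backtracking safeguard. The BB step adapts
  # the step length to the local curvature, which copes with the strong
  # anisotropy between the release and affinity directions.
  p <- log(theta[idx])
  cur <- eval_sse(theta)
  g <- grad_at(cur, exp(p))
  gamma <- 0.1
  p_prev <- NULL
  g_prev <- NULL
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    if (max(abs(g)) < grad_tol) {
      converged <- TRUE
      break
    }
    if (!is.null(p_prev)) {
      sdiff <- p - p_prev
      ydiff <- g - g_prev
      bb <- sum(sdiff * ydiff)
      gamma <- if (is.finite(bb) && bb > 0) sum(sdiff * sdiff) / bb else 0.1
      gamma <- min(max(gamma, 1e-10), 1e4)
    }
    accepted <- FALSE
    step <- gamma
    for (ls in 1:50) {
      p_new <- p - step * g
      th_new <- theta
      th_new[idx] <- exp(p_new)
      cand <- eval_sse(th_new)
      if (is.finite(cand$sse) && cand$sse < cur$sse) {
        p_prev <- p
        g_prev <- g
        p <- p_new
        theta <- th_new
        cur <- cand
        g <- grad_at(cur, exp(p))
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break # step collapsed: stationary to machine precision
  }
  fitted <- do.call(mm_params, as.list(setNames(theta, names7)))
  structure(list(
    params = fitted,
    residual_norm = sqrt(cur$sse / length(y)),
    sse = cur$sse,
    iterations = iter,
    converged = converged,
    free = free,
    trace_hat = evoked_trace(trace$time, pmax(cur$conc, 0),
                             stim_window = trace$stim_window)
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> %s after %d iterations, RMS residual %.3g nM\n",
              if (x$converged) "converged" else "stopped",
              x$iterations, x$residual_norm))
  cat("  free:", paste(x$free, collapse = ", "), "\n")
  print(x$params)
  invisible(x)
}

#' Reference kinetic and ambient-serotonin values for the study conditions
#'
#' Group-level constants that define the simulated study conditions: fitted
#' two-uptake Michaelis-Menten parameters per treatment group (values in
#' nM/s and nM) and ambient FSCAV serotonin group means (nM) before and
#' 60 min after escitalopram. These serve as generator defaults and as inputs
#' to descriptive summaries such as [escit_effect_summary()].
#'
#' @return \code{mm_reference_params()}: data.frame with columns
#'   \code{group}, \code{phase}, \code{vmax1}, \code{km1}, \code{vmax2},
#'   \code{km2}, \code{rmax}. \code{fscav_reference_means()}: data.frame with
#'   \code{group}, \code{before}, \code{after}.
#' @export
mm_reference_params <- function() {
  data.frame(
    group = c("saline", "mptp", "saline", "mptp"),
    phase = c("pre", "pre", "post_escit", "post_escit"),
    vmax1 = c(14.67, 15.74, 4.40, 6.88),
    km1 = c(1.34, 2.30, 40.85, 33.93),
    vmax2 = 780, km2 = 170,
    rmax = c(35.20, 25.20, 32.50, 21.85)
  )
}

#' @rdname mm_reference_params
#' @export
fscav_reference_means <- function() {
  data.frame(group = c("control", "mptp"),
             before = c(32.65, 11.46),
             after = c(65.34, 26.69))
}

#' Group-average evoked kinetics (pooled FSCV fits)
#'
#' The pooled-group two-uptake parameters used by the synthetic generators:
#' saline and MPTP evoked serotonin kinetics.
#'
#' @return Named list of [mm_params()] (\code{saline}, \code{mptp}).
#' @export
mm_group_params <- function() {
  list(
    saline = mm_params(vmax1 = 11.13, km1 = 2.40, vmax2 = 780, km2 = 170,
                       rmax = 38.40),
    mptp = mm_params(vmax1 = 12.15, km1 = 2.61, vmax2 = 780, km2 = 170,
                     rmax = 27.20)
  )
}
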