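#' Stimulus specification
#'
#' Describes one stimulus applied to a compartment: a constant or stepped
#' current, a sinusoidal current, an alpha-shaped current transient, or an
#' alpha-shaped synaptic conductance
#' \eqn{g(t) = g_{max} (t/t_{peak}) e^{1 - t/t_{peak}}} with reversal
#' potential `E_syn` (an AMPAR-like synapse at the defaults
#' `g_max = 0.25` nS, `t_peak = 0.5` ms, `E_syn = 0` mV).
#'
#' @param kind one of `"constant_current"`, `"current_step"`,
#'   `"sinusoid_current"`, `"alpha_current"`, `"alpha_conductance"`.
#' @param site compartment index the stimulus is applied to.
#' @param amplitude current amplitude in nA (current stimuli).
#' @param frequency sinusoid frequency in Hz.
#' @param g_max peak conductance in nS (alpha conductance).
#' @param t_peak time-to-peak of the alpha function, ms.
#' @param onset stimulus onset, ms.
#' @param duration step duration, ms (current_step only).
#' @param E_syn synaptic reversal potential, mV (absolute).
#' @return a `stimulus` list.
#' @export
stimulus <- function(kind, site, amplitude = NULL, frequency = NULL,
                     g_max = NULL, t_peak = 0.5, onset = 0, duration = Inf,
                     E_syn = 0) {
  kind <- match.arg(kind, c("constant_current", "current_step",
                            "sinusoid_current", "alpha_current",
                            "alpha_conductance"))
  if (kind == "alpha_conductance") {
    if (is.null(g_max) || g_max <= 0) abort("alpha_conductance needs g_max > 0 (nS).")
    if (t_peak <= 0) abort("t_peak must be positive.")
  } else {
    if (is.null(amplitude) || amplitude <= 0) abort("current stimuli need amplitude > 0 (nA).")
    if (kind == "sinusoid_current" && (is.null(frequency) || frequency <= 0)) {
      abort("sinusoid_current needs frequency > 0 (Hz).")
    }
    if (kind == "alpha_current" && t_peak <= 0) abort("t_peak must be positive.")
  }
  structure(list(kind = kind, site = as.integer(site), amplitude = amplitude,
                 frequency = frequency, g_max = g_max, t_peak = t_peak,
                 onset = onset, duration = duration, E_syn = E_syn),
            class = "stimulus")
}

alpha_shape <- function(t, t_peak) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / t_peak) * exp(1 - t[pos] / t_peak)
  out
}

# injected current (nA) of a current-type stimulus at times t (ms)
stim_current <- function(st, t) {
  s <- t - st$onset
  switch(st$kind,
         constant_current = ifelse(s >= 0, st$amplitude, 0),
         current_step = ifelse(s >= 0 & s <= st$duration, st$amplitude, 0),
         sinusoid_current = ifelse(s >= 0, st$amplitude *
                                     sin(2 * pi * st$frequency * 1e-3 * s), 0),
         alpha_current = st$amplitude * alpha_shape(s, st$t_peak),
         abort("not a current stimulus."))
}

#' Steady-state solution of the passive system
#'
#' Solves \eqn{(G_{leak} + G_{axial}) V = I e_{site}} for the stationary
#' voltage deviation produced by a constant current injection.
#'
#' @param cm a `cable_model`.
#' @param site compartment index of the injection.
#' @param I injected current, nA.
#' @return voltage deviation per compartment, mV.
#' @export
solve_steady <- function(cm, site, I = 0.01) {
  sys <- assemble_system(cm)
  b <- numeric(nrow(cm$compartments))
  b[site] <- I
  drop(solve(sys$G, b))
}

#' Phasor (frequency-domain) solution
#'
#' Solves \eqn{(G + i 2 \pi f C) \tilde V = I e_{site}}; the modulus of
#' \eqn{\tilde V_j} is the steady sinusoidal voltage amplitude at
#' compartment `j` for a sinusoidal current of amplitude `I` at `site`.
#'
#' @param cm a `cable_model`.
#' @param site injection compartment.
#' @param f frequency, Hz.
#' @param I current amplitude, nA.
#' @return complex voltage vector, mV.
#' @export
solve_phasor <- function(cm, site, f = 50, I = 0.01) {
  if (f <= 0) abort("frequency must be positive.")
  sys <- assemble_system(cm)
  omega <- 2 * pi * f * 1e-3      # rad/ms
  A <- sys$G + 1i * omega * diag(sys$C, nrow = length(sys$C))
  b <- numeric(nrow(cm$compartments))
  b[site] <- I
  drop(solve(A, b))
}

#' Time-domain simulation (Crank-Nicolson)
#'
#' Integrates \eqn{C \dot V = -(G_{leak}+G_{axial}) V + I(t) - g_{syn}(t)
#' (V - (E_{syn} - E_{rest}))} with the unconditionally stable, second-order
#' Crank-Nicolson scheme; currents and synaptic conductances are evaluated at
#' half steps.  Voltages are deviations from rest; the resting potential only
#' enters through the synaptic driving force.
#'
#' @param cm a `cable_model`.
#' @param stimuli a [stimulus()] or list of stimuli.
#' @param t_stop simulation end, ms.
#' @param dt time step, ms (0.025 in all canonical runs).
#' @param record compartment indices to keep in the output (default all).
#' @return a `traces` object: `times` (ms), `v` (matrix, mV deviation from
#'   rest, one column per recorded compartment), `i_inj` (injected current per
#'   stimulus at the output times, nA), `rest` (mV), `dt`.
#' @export
simulate_traces <- function(cm, stimuli, t_stop, dt = 0.025, record = NULL) {
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  if (t_stop <= 0 || dt <= 0) abort("t_stop and dt must be positive.")
  for (st in stimuli) {
    if (st$onset >= t_stop) abort("stimulus onset must precede t_stop.")
  }
  sys <- assemble_system(cm)
  n <- length(sys$C)
  record <- record %||% seq_len(n)
  n_steps <- ceiling(t_stop / dt)
  times <- seq(0, by = dt, length.out = n_steps + 1L)
  t_half <- times[-1] - dt / 2

  Cdt <- sys$C / dt
  M1 <- sys$G / 2
  diag(M1) <- diag(M1) + Cdt
  B <- -sys$G / 2
  diag(B) <- diag(B) + Cdt
  Minv <- solve(M1)

  cur <- stimuli[vapply(stimuli, function(s) s$kind != "alpha_conductance", logical(1))]
  syn <- stimuli[vapply(stimuli, function(s) s$kind == "alpha_conductance", logical(1))]
  I_half <- matrix(0, n_steps, length(cur))
  cur_sites <- integer(length(cur))
  for (k in seq_along(cur)) {
    I_half[, k] <- stim_current(cur[[k]], t_half)
    cur_sites[k] <- cur[[k]]$site
  }
  syn_sites <- vapply(syn, function(s) s$site, integer(1))
  g_half <- matrix(0, n_steps, length(syn))   # uS
  e_drive <- numeric(length(syn))
  rest <- cm$params$E_leak
  for (k in seq_along(syn)) {
    g_half[, k] <- syn[[k]]$g_max * 1e-3 * alpha_shape(t_half - syn[[k]]$onset,
                                                       syn[[k]]$t_peak)
    e_drive[k] <- syn[[k]]$E_syn - rest
  }
  P <- if (length(syn)) Minv[, syn_sites, drop = FALSE] else NULL

  v <- numeric(n)
  out <- matrix(0, n_steps + 1L, length(record))
  for (it in seq_len(n_steps)) {
    rhs <- B %*% v
    for (k in seq_along(cur)) {
      rhs[cur_sites[k]] <- rhs[cur_sites[k]] + I_half[it, k]
    }
    if (length(syn)) {
      a <- g_half[it, ] / 2
      for (k in seq_along(syn)) {
        rhs[syn_sites[k]] <- rhs[syn_sites[k]] -
          a[k] * v[syn_sites[k]] + g_half[it, k] * e_drive[k]
      }
      y <- Minv %*% rhs
      if (any(a > 0)) {
        # rank-k Woodbury correction for the active synaptic conductances
        act <- which(a > 0)
        Sk <- diag(1 / a[act], nrow = length(act)) +
          Minv[syn_sites[act], syn_sites[act], drop = FALSE]
        v <- drop(y - P[, act, drop = FALSE] %*%
                    solve(Sk, y[syn_sites[act], drop = FALSE]))
      } else {
        v <- drop(y)
      }
    } else {
      v <- drop(Minv %*% rhs)
    }
    out[it + 1L, ] <- v[record]
  }
  if (any(!is.finite(out))) abort("non-finite voltages in simulation.")

  i_inj <- NULL
  if (length(cur)) {
    i_inj <- vapply(cur, function(s) stim_current(s, times), numeric(n_steps + 1L))
    colnames(i_inj) <- vapply(cur, function(s) sprintf("%s_site%d", s$kind, s$site), "")
  }
  structure(list(times = times, v = out, record = record, i_inj = i_inj,
                 rest = rest, dt = dt),
            class = "traces")
}

#' @export
print.traces <- function(x, ...) {
  cat(sprintf("<traces: %d compartments x %d steps, dt = %g ms, rest = %g mV>\n",
              ncol(x$v), length(x$times), x$dt, x$rest))
  invisible(x)
}

#' @export
as_tibble.traces <- function(x, ...) {
  v <- as.data.frame(x$v)
  names(v) <- sprintf("comp_%d", x$record)
  out <- tibble(time = x$times)
  dplyr::bind_cols(out, as_tibble(v))
}

#' Somatic input resistance and membrane time constant
#'
#' `input_resistance()` injects a small constant current at the soma and
#' returns the steady \eqn{\Delta V / I} (independent of amplitude for a
#' passive model).  `time_constant()` simulates the voltage response to a
#' depolarizing somatic current step and returns the time at which the soma
#' reaches 63% (\eqn{1 - e^{-1}}) of its peak depolarization, located by
#' linear interpolation between grid points.
#'
#' @param cm a `cable_model`.
#' @param I step amplitude, nA (10 pA default, matching the experimental
#'   protocol; results are amplitude-independent).
#' @param t_stop step duration, ms (200-ms steps as in the recordings).
#' @param dt integration step, ms.
#' @return `input_resistance()`: MOhm. `time_constant()`: ms.
#' @export
input_resistance <- function(cm, I = 0.01) {
  site <- if (!is.na(cm$soma)) cm$soma else 1L
  v <- solve_steady(cm, site, I)
  v[site] / I
}

#' @rdname input_resistance
#' @export
time_constant <- function(cm, I = 0.01, t_stop = 200, dt = 0.025) {
  site <- if (!is.na(cm$soma)) cm$soma else 1L
  tr <- simulate_traces(cm, stimulus("current_step", site, amplitude = I,
                                     duration = t_stop),
                        t_stop = t_stop, dt = dt, record = site)
  v <- tr$v[, 1]
  peak <- max(v)
  if (peak <= 0) abort("no depolarization measured.", class = "dendrisig_measurement_error")
  thr <- (1 - exp(-1)) * peak
  above <- which(v >= thr)
  if (length(above) == 0) abort("63% level not reached.", class = "dendrisig_measurement_error")
  i <- above[1]
  if (i == 1L) return(tr$times[1])
  t0 <- tr$times[i - 1L]; t1 <- tr$times[i]
  v0 <- v[i - 1L]; v1 <- v[i]
  t0 + (thr - v0) / (v1 - v0) * (t1 - t0)
}
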