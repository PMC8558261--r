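#' Membrane fit targets
#'
#' Somatic input resistance and membrane time constant a model neuron is
#' fitted to.  The group means of the study populations are 197 MOhm / 32.5
#' ms (wild type) and 228 MOhm / 35.2 ms (tau-mutant); each neuron in a
#' group is fitted to its group mean, mirroring the original procedure of
#' matching the electrophysiologically determined mean.
#'
#' @param target_Rin somatic input resistance target, MOhm.
#' @param target_tau membrane time constant target, ms.
#' @param tolerance relative tolerance of the fit.
#' @return a `fit_targets` list.
#' @export
fit_targets <- function(target_Rin, target_tau, tolerance = 1e-3) {
  if (target_Rin <= 0 || target_tau <= 0) abort("fit targets must be positive.")
  structure(list(target_Rin = target_Rin, target_tau = target_tau,
                 tolerance = tolerance), class = "fit_targets")
}

#' Two-step passive membrane fit
#'
#' Step 1 (`fit_Rm()`): the specific membrane resistance is varied until the
#' simulated somatic input resistance \eqn{R_{in} = \Delta V / I} matches the
#' target; the morphology is re-compartmentalized under the
#' `min(37 um, 0.2 lambda)` spacing rule at every candidate, because the
#' space constant itself depends on Rm.  Step 2 (`fit_Cm()`): with Rm fixed,
#' the specific capacitance is varied until the simulated 63%-of-peak time
#' constant of a 200-ms somatic current step matches the target.  Both maps
#' are strictly increasing, so a bracketed root find converges; for Cm the
#' passive system gives exact time-scaling (\eqn{\tau_{63} \propto C_m}),
#' which the solver exploits as the initial step.
#'
#' `fit_membrane()` composes the two steps and returns a `membrane_fit`
#' with [tidy()] and [glance()] methods.
#'
#' @param m a `morphology`.
#' @param targets a [fit_targets()] object.
#' @param p0 starting [membrane_params()] (carries Ra, rest and spine spec;
#'   the group spine density is folded in before fitting, so the fit absorbs
#'   spine load into Rm and Cm).
#' @param max_len compartment spacing cap, um.
#' @param dt integration step for the time-constant simulation, ms.
#' @return `fit_Rm()` and `fit_Cm()` return the fitted scalar; `fit_membrane()`
#'   returns a `membrane_fit` list with elements `params`, `model`,
#'   `achieved_Rin`, `achieved_tau`, `targets`, `iterations`.
#' @export
fit_Rm <- function(m, targets, p0, max_len = 37) {
  stopifnot(inherits(targets, "fit_targets"), inherits(p0, "membrane_params"))
  n_eval <- 0L
  f <- function(log10_Rm) {
    n_eval <<- n_eval + 1L
    p <- p0
    p$Rm <- 10^log10_Rm
    input_resistance(compartmentalize(m, p, max_len = max_len)) - targets$target_Rin
  }
  lo <- 3; hi <- 6
  if (f(lo) * f(hi) > 0) {   # widen the bracket once
    lo <- 2.5; hi <- 6.5
    if (f(lo) * f(hi) > 0) {
      abort("input-resistance target outside the achievable range.",
            class = "dendrisig_fit_error")
    }
  }
  root <- uniroot(f, c(lo, hi), tol = 1e-7)
  Rm <- 10^root$root
  attr(Rm, "iterations") <- n_eval
  Rm
}

#' @param p_fitted `membrane_params` carrying the Rm found in step 1.
#' @rdname fit_Rm
#' @export
fit_Cm <- function(m, targets, p_fitted, max_len = 37, dt = 0.025) {
  stopifnot(inherits(targets, "fit_targets"), inherits(p_fitted, "membrane_params"))
  tau_of <- function(Cm) {
    p <- p_fitted
    p$Cm <- Cm
    time_constant(compartmentalize(m, p, max_len = max_len), dt = dt)
  }
  cm0 <- p_fitted$Cm
  tau0 <- tau_of(cm0)
  Cm <- cm0 * targets$target_tau / tau0   # exact for the continuous system
  n_eval <- 1L
  for (k in 1:8) {
    tau <- tau_of(Cm)
    n_eval <- n_eval + 1L
    err <- (tau - targets$target_tau) / targets$target_tau
    if (abs(err) <= targets$tolerance / 4) break
    Cm <- Cm * targets$target_tau / tau
  }
  if (abs(err) > targets$tolerance) {
    abort("time-constant fit did not converge.", class = "dendrisig_fit_error")
  }
  attr(Cm, "iterations") <- n_eval
  Cm
}

#' @rdname fit_Rm
#' @export
fit_membrane <- function(m, targets, p0, max_len = 37, dt = 0.025) {
  Rm <- fit_Rm(m, targets, p0, max_len = max_len)
  p <- p0
  p$Rm <- as.numeric(Rm)
  Cm <- fit_Cm(m, targets, p, max_len = max_len, dt = dt)
  p$Cm <- as.numeric(Cm)
  model <- compartmentalize(m, p, max_len = max_len)
  fit <- structure(list(params = p, model = model,
                        achieved_Rin = input_resistance(model),
                        achieved_tau = time_constant(model, dt = dt),
                        targets = targets,
                        iterations = c(Rm = attr(Rm, "iterations"),
                                       Cm = attr(Cm, "iterations"))),
                   class = "membrane_fit")
  rel <- c(abs(fit$achieved_Rin - targets$target_Rin) / targets$target_Rin,
           abs(fit$achieved_tau - targets$target_tau) / targets$target_tau)
  if (any(rel > targets$tolerance)) {
    abort("membrane fit outside tolerance.", class = "dendrisig_fit_error")
  }
  fit
}

#' @export
print.membrane_fit <- function(x, ...) {
  cat(sprintf("<membrane_fit: Rm = %.1f Ohm cm^2, Cm = %.4f uF/cm^2 | Rin %.2f MOhm (target %.1f), tau %.3f ms (target %.1f)>\n",
              x$params$Rm, x$params$Cm, x$achieved_Rin, x$targets$target_Rin,
              x$achieved_tau, x$targets$target_tau))
  invisible(x)
}

#' @export
tidy.membrane_fit <- function(x, ...) {
  tibble(term = c("Rm", "Cm"),
         estimate = c(x$params$Rm, x$params$Cm),
         unit = c("Ohm*cm^2", "uF/cm^2"))
}

#' @export
glance.membrane_fit <- function(x, ...) {
  tibble(Rm = x$params$Rm, Cm = x$params$Cm,
         achieved_Rin = x$achieved_Rin, target_Rin = x$targets$target_Rin,
         achieved_tau = x$achieved_tau, target_tau = x$targets$target_tau,
         n_compartments = nrow(x$model$compartments),
         iterations = sum(x$iterations))
}
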