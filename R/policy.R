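# Dynamic-programming derivation of the earning-rate-optimal stopping policy.

#' Posterior over motion coherence given the decision-variable state
#'
#' p(coh | x, t) is proportional to N(x | kappa*coh*t, t) times the prior.
#' This holds regardless of the bound shape and of provisional deadlines,
#' because bound survival and deadline survival multiply the likelihood by
#' coherence-independent factors. At t = 0 the posterior equals the prior.
#'
#' @param x Accumulated evidence.
#' @param t Elapsed decision time, seconds (>= 0).
#' @param kappa Signal-to-noise parameter.
#' @param priors Data frame of signed coherences and prior weights.
#' @return Named vector of posterior probabilities over the coherences.
#' @export
coherence_posterior <- function(x, t, kappa, priors = coherence_set()) {
  stopifnot(length(x) == 1, length(t) == 1, t >= 0)
  if (t == 0) return(setNames(priors$weight, priors$value))
  # N(x | kappa*coh*t, t), common x^2/(2t) factor cancels in normalisation
  logw <- log(priors$weight) + x * kappa * priors$value -
    0.5 * t * (kappa * priors$value)^2
  w <- exp(logw - max(logw))
  setNames(w / sum(w), priors$value)
}

#' One-step transition kernel of the evidence state
#'
#' The distribution of the next evidence value after one time step of
#' continued accumulation, marginalised over the coherence posterior at the
#' current state: a mixture of discretised Gaussians with means
#' `kappa*coh*dt` and variance `dt`.
#'
#' @param x,t Current state.
#' @param kappa Signal-to-noise parameter.
#' @param priors Data frame of signed coherences and prior weights.
#' @param dx Evidence-grid spacing.
#' @param dt Time step, seconds.
#' @param width Kernel half-width in standard deviations.
#' @return A data frame with `x_next` and `prob` (summing to 1).
#' @export
transition_kernel <- function(x, t, kappa, priors = coherence_set(),
                              dx = 0.02, dt = 5e-4, width = 5) {
  post <- coherence_posterior(x, t, kappa, priors)
  sd <- sqrt(dt)
  w <- ceiling(width * sd / dx)
  off <- seq(-w, w) * dx
  prob <- numeric(length(off))
  for (k in seq_len(nrow(priors))) {
    g <- dnorm(off, kappa * priors$value[k] * dt, sd)
    prob <- prob + post[k] * g / sum(g)
  }
  data.frame(x_next = x + off, prob = prob)
}

#' Cancellation hazard on deadline-bearing phases
#'
#' Probability that the trial is cancelled in [t, t + dt), given that it has
#' survived to decision time t. The Rayleigh deadline acts on the reaction
#' time, so the hazard is shifted by the mean non-decision time; because only
#' a fraction of trials carries a deadline, the raw Rayleigh hazard is
#' weighted by the posterior probability that this trial has one, obtained by
#' Bayes' rule from the Rayleigh survival function.
#'
#' @param t Elapsed decision time(s), seconds.
#' @param spec A [deadline_spec()].
#' @param mu_nd Mean non-decision time, seconds.
#' @param deadline_fraction Prior probability that a trial has a deadline.
#' @param dt Width of the hazard interval, seconds.
#' @return Cancellation probabilities (same length as `t`).
#' @export
cancel_hazard <- function(t, spec, mu_nd, deadline_fraction = 0.5, dt = 5e-4) {
  stopifnot(inherits(spec, "deadline_spec"),
            deadline_fraction >= 0, deadline_fraction <= 1)
  u <- t - spec$t0 + mu_nd # deadline on RT = t + Tnd, i.e. shifted by mu_nd
  raw <- ifelse(u > 0, dt * u / spec$sigma_dl^2, 0)
  surv <- ifelse(u > 0, exp(-0.5 * (u / spec$sigma_dl)^2), 1)
  f <- deadline_fraction
  p_dplus <- f * surv / (f * surv + (1 - f))
  pmin(p_dplus * raw, 1)
}

#' Optimal stopping policy by dynamic programming
#'
#' Solves the Bellman equations of the sequential decision problem on the
#' state grid <x, t>: at every state the decision maker terminates (left or
#' right, collecting the expected points given the coherence posterior, then
#' paying the earning rate times the inter-trial latencies) or continues
#' accumulating for another `dt` (paying `rho * dt` and, on deadline phases,
#' risking cancellation). The optimal earning rate `rho*` is the root of
#' V(x = 0, t = 0) = 0, located by bisection; the policy's
#' terminate/continue frontier is returned as a bound curve.
#'
#' @param kappa Signal-to-noise parameter.
#' @param mu_nd Mean non-decision time, seconds.
#' @param task A [task_config()]; deadlines and the cancellation branch are
#'   included when `deadline_fraction > 0`.
#' @param priors Data frame of signed coherences and prior weights; defaults
#'   to the task's stimulus mixture.
#' @param dx Evidence-grid spacing (default 0.02).
#' @param x_max Evidence-grid half-width (default 4).
#' @param dt Time step, seconds (default 0.5 ms).
#' @param t_max Decision horizon, seconds; at the horizon only the terminal
#'   choices are available.
#' @param rho_bracket Bisection bracket for the earning rate, points/s.
#' @param rho_tol Bisection tolerance, points/s.
#' @return An object of class `ddm_policy`: optimal rate `rho` (points/s),
#'   `bounds` (a [bound_curve()] of the decision frontier, ending at 0 at the
#'   horizon), `value_origin`, and the solver settings.
#' @export
optimal_policy <- function(kappa, mu_nd, task = task_config(), priors = NULL,
                           dx = 0.02, x_max = 4, dt = 5e-4,
                           t_max = task$max_viewing_s,
                           rho_bracket = c(-0.5, 0.5), rho_tol = 1e-6) {
  stopifnot(inherits(task, "task_config"), kappa > 0, mu_nd >= 0)
  if (is.null(priors)) priors <- task$coherence_set
  n_t <- round(t_max / dt)
  pcancel <- numeric(0)
  if (task$deadline_fraction > 0)
    pcancel <- cancel_hazard(seq_len(n_t) * dt - dt, task$deadline,
                             mu_nd, task$deadline_fraction, dt)
  term_cost <- task$iti_s + task$misc_s + mu_nd
  cancel_cost <- task$iti_s + task$misc_cancel_s + mu_nd
  res <- cpp_solve_policy(kappa, priors$value, priors$weight, dx, x_max, dt,
                          t_max, term_cost, cancel_cost, task$reward_correct,
                          task$reward_error, task$reward_cancel, pcancel,
                          rho_bracket[1], rho_bracket[2], rho_tol)
  structure(list(rho = res$rho,
                 bounds = bound_curve(c(res$bounds, 0), dt),
                 value_origin = res$value_origin, kappa = kappa,
                 mu_nd = mu_nd, task = task, priors = priors,
                 settings = list(dx = dx, x_max = x_max, dt = dt,
                                 t_max = t_max, rho_tol = rho_tol)),
            class = "ddm_policy")
}

#' @export
print.ddm_policy <- function(x, ...) {
  cat("Earning-rate-optimal stopping policy\n")
  cat(sprintf("  rho* = %.4f points/s (%.2f points/min)\n", x$rho, 60 * x$rho))
  cat(sprintf("  kappa = %.2f, mu_nd = %.3f s, deadline fraction = %.2f\n",
              x$kappa, x$mu_nd, x$task$deadline_fraction))
  cat(sprintf("  frontier: B(0+) = %.2f, min before horizon = %.2f\n",
              x$bounds$values[2],
              min(head(x$bounds$values, -1))))
  invisible(x)
}

#' @export
plot.ddm_policy <- function(x, ...) {
  plot(x$bounds, main = "Optimal decision frontier", ...)
  invisible(x)
}
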