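#' Signed motion-coherence set of the random-dot task
#'
#' The stimulus set mixes six motion strengths (0, 3.2, 6.4, 12.8, 25.6 and
#' 51.2\%) in both directions with equal probability. Zero coherence appears
#' once with double weight (it belongs to both directions; the correct side is
#' drawn at random on those trials), so the eleven distinct signed values carry
#' twelve equal sampling slots.
#'
#' @param strengths Motion strengths as unsigned fractions.
#' @return A data frame with columns `value` (signed coherence) and `weight`
#'   (sampling probability, summing to one).
#' @export
#' @examples
#' coherence_set()
coherence_set <- function(strengths = c(0, 0.032, 0.064, 0.128, 0.256, 0.512)) {
  stopifnot(all(strengths >= 0), 0 %in% strengths)
  pos <- sort(strengths[strengths > 0])
  value <- c(-rev(pos), 0, pos)
  n_slot <- 2 * length(strengths)
  weight <- ifelse(value == 0, 2 / n_slot, 1 / n_slot)
  data.frame(value = value, weight = weight)
}

#' Provisional-deadline distribution
#'
#' Deadlines are drawn from a time-shifted Rayleigh distribution with density
#' \eqn{p(t) = ((t - t_0)/\sigma^2) \exp(-(t - t_0)^2 / (2\sigma^2))} for
#' \eqn{t \ge t_0}.
#'
#' @param t0 Time shift (minimum possible deadline), seconds.
#' @param sigma_dl Rayleigh scale parameter, seconds.
#' @return An object of class `deadline_spec`.
#' @export
deadline_spec <- function(t0, sigma_dl) {
  stopifnot(is.numeric(t0), t0 >= 0, is.numeric(sigma_dl), sigma_dl > 0)
  structure(list(t0 = t0, sigma_dl = sigma_dl), class = "deadline_spec")
}

#' Drift-diffusion model parameters
#'
#' The decision variable accumulates momentary evidence with drift
#' \eqn{\mu_d = \kappa \cdot coh} and unit diffusion (the diffusion standard
#' deviation is fixed at 1, since it is not jointly identifiable with kappa
#' and the bound height). The non-decision time is Gaussian, truncated at zero
#' when realised.
#'
#' @param kappa Signal-to-noise scaling (drift per unit coherence, 1/s).
#' @param mu_nd Mean non-decision time, seconds.
#' @param sigma_nd Standard deviation of the non-decision time, seconds.
#' @return An object of class `ddm_params`.
#' @export
ddm_params <- function(kappa, mu_nd, sigma_nd = 0) {
  stopifnot(kappa > 0, mu_nd > 0, sigma_nd >= 0)
  structure(list(kappa = unname(kappa), mu_nd = unname(mu_nd),
                 sigma_nd = unname(sigma_nd)),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("DDM parameters: kappa = %.3f, mu_nd = %.3f s, sigma_nd = %.3f s\n",
              x$kappa, x$mu_nd, x$sigma_nd))
  invisible(x)
}

#' Task configuration
#'
#' Time constants and the point economy of the reaction-time motion task. The
#' defaults are the constants used throughout: 2 s inter-trial interval,
#' 0.7 s of miscellaneous latencies on completed trials (fixation acquisition,
#' motion-onset delay, saccade validation), 0.4 s on cancelled trials, +1/-1/0
#' points for correct/error/cancelled outcomes, and a 5 s viewing limit.
#'
#' @param coherence_set Data frame of signed coherences and sampling weights.
#' @param max_viewing_s Maximum stimulus viewing time, seconds.
#' @param iti_s Mean inter-trial interval, seconds.
#' @param misc_s Mean miscellaneous latency on completed trials, seconds.
#' @param misc_cancel_s Mean miscellaneous latency on cancelled trials, seconds.
#' @param reward_correct,reward_error,reward_cancel Points for each outcome.
#' @param deadline_fraction Probability that a trial carries a provisional
#'   deadline (0.5 in Phase II, 0 otherwise).
#' @param deadline A [deadline_spec()], or `NULL` when no deadlines are used.
#' @param abort_rate Per-trial probability of an abort (blink or fixation
#'   break), modelled as an independent Bernoulli event.
#' @param abort_cost_s Time cost charged for an aborted trial, seconds.
#' @return An object of class `task_config`.
#' @export
task_config <- function(coherence_set = npbddm::coherence_set(),
                        max_viewing_s = 5, iti_s = 2, misc_s = 0.7,
                        misc_cancel_s = 0.4, reward_correct = 1,
                        reward_error = -1, reward_cancel = 0,
                        deadline_fraction = 0, deadline = NULL,
                        abort_rate = 0.03,
                        abort_cost_s = misc_cancel_s + iti_s) {
  stopifnot(abs(sum(coherence_set$weight) - 1) < 1e-8,
            max_viewing_s > 0, iti_s > 0, misc_s > 0, misc_cancel_s > 0,
            deadline_fraction >= 0, deadline_fraction <= 1,
            abort_rate >= 0, abort_rate < 1)
  if (deadline_fraction > 0 && is.null(deadline))
    stop("a deadline_spec is required when deadline_fraction > 0")
  structure(list(coherence_set = coherence_set, max_viewing_s = max_viewing_s,
                 iti_s = iti_s, misc_s = misc_s, misc_cancel_s = misc_cancel_s,
                 reward_correct = reward_correct, reward_error = reward_error,
                 reward_cancel = reward_cancel,
                 deadline_fraction = deadline_fraction, deadline = deadline,
                 abort_rate = abort_rate, abort_cost_s = abort_cost_s),
            class = "task_config")
}

#' Time-varying decision bound on a uniform grid
#'
#' A symmetric decision bound B(t) >= 0 sampled at t = 0, dt, 2 dt, ...
#' Values between nodes are obtained by linear interpolation; beyond the last
#' node the final value is held.
#'
#' @param values Bound heights at the grid nodes (all >= 0).
#' @param dt Grid step, seconds.
#' @return An object of class `bound_curve`.
#' @export
#' @examples
#' b <- bound_curve(c(1, 0.9, 0.8), dt = 0.5)
#' bound_at(b, c(0, 0.25, 2))
bound_curve <- function(values, dt) {
  stopifnot(is.numeric(values), length(values) >= 1, all(values >= 0),
            is.numeric(dt), dt > 0)
  structure(list(values = as.numeric(values), dt = dt,
                 t_max = dt * (length(values) - 1)),
            class = "bound_curve")
}

#' Evaluate a bound curve
#'
#' @param bounds A [bound_curve()].
#' @param t Times (seconds) at which to evaluate the bound.
#' @return Bound heights, linearly interpolated; the last value is held for
#'   `t > t_max` and an error is raised for negative `t`.
#' @export
bound_at <- function(bounds, t) {
  stopifnot(inherits(bounds, "bound_curve"), all(t >= 0))
  v <- bounds$values
  if (length(v) == 1L) return(rep(v, length(t)))
  u <- pmin(t / bounds$dt, length(v) - 1)
  j <- pmin(floor(u), length(v) - 2)
  f <- u - j
  (1 - f) * v[j + 1] + f * v[j + 2]
}

#' @export
print.bound_curve <- function(x, ...) {
  cat(sprintf("Decision bound on [0, %.3f] s (dt = %.4g s, %d nodes)\n",
              x$t_max, x$dt, length(x$values)))
  cat(sprintf("  B(0) = %.3f, min = %.3f, B(t_max) = %.3f\n",
              x$values[1], min(x$values), x$values[length(x$values)]))
  invisible(x)
}

#' @export
plot.bound_curve <- function(x, ..., ylim = NULL) {
  t <- seq(0, x$t_max, by = x$dt)
  if (is.null(ylim)) ylim <- c(0, max(x$values) * 1.05)
  plot(t, x$values, type = "l", xlab = "time (s)", ylab = "bound B(t)",
       ylim = ylim, ...)
  invisible(x)
}
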