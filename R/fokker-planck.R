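# Numerical propagation of the decision-variable density under
# drift-diffusion with time-varying absorbing bounds. The state is carried
# per coherence so that the match step of the bound derivation can aggregate
# exit mass across coherences with arbitrary priors.

#' Initialise a Fokker-Planck state
#'
#' All probability mass starts on the grid node nearest x = 0 (a delta
#' function at the origin), independently for each coherence.
#'
#' @param params A [ddm_params()].
#' @param coh Signed coherences (one density is propagated per value).
#' @param dx Grid spacing in evidence units.
#' @param x_max Half-width of the symmetric grid.
#' @return An object of class `fp_state`: grid `x`, spacing `dx`, a
#'   coherence-by-node matrix `mass` of probability mass per cell, cumulative
#'   absorbed mass per side, and the current time `t`.
#' @export
fp_state <- function(params, coh, dx = 0.01, x_max = 3) {
  stopifnot(inherits(params, "ddm_params"), dx > 0, x_max > dx)
  half <- round(x_max / dx)
  x <- seq(-half, half) * dx
  mass <- matrix(0, nrow = length(coh), ncol = length(x))
  mass[, half + 1] <- 1
  structure(list(x = x, dx = dx, coh = coh, drift = params$kappa * coh,
                 D = 0.5, mass = mass,
                 absorbed_upper = numeric(length(coh)),
                 absorbed_lower = numeric(length(coh)), t = 0),
            class = "fp_state")
}

#' Advance the density one time step
#'
#' One fully implicit (backward-time) Chang-Cooper step of the Fokker-Planck
#' equation for each coherence, with the absorbing boundary imposed at
#' `+/- bound_now` inside the tridiagonal solve (the bound may fall between
#' nodes; the straddled cell is treated by linear interpolation). Mass
#' crossing a bound is transferred to the per-side absorbed tallies.
#'
#' @param state An [fp_state()].
#' @param bound_now Bound height during this step (>= 0).
#' @param dt Time step, seconds.
#' @return The advanced `fp_state`.
#' @export
propagate_step <- function(state, bound_now, dt = 5e-4) {
  stopifnot(inherits(state, "fp_state"), bound_now >= 0, dt > 0)
  if (bound_now > max(state$x) + state$dx / 2)
    stop("grid-extent error: bound ", bound_now,
         " exceeds the grid half-width ", max(state$x))
  res <- cpp_fp_step(state$mass, state$x, state$dx, state$drift, state$D, dt,
                     bound_now)
  state$mass <- res$mass
  state$absorbed_upper <- state$absorbed_upper + res$absorbed_upper
  state$absorbed_lower <- state$absorbed_lower + res$absorbed_lower
  state$t <- state$t + dt
  state
}

#' Coherence-marginal density of the decision variable
#'
#' @param state An [fp_state()].
#' @param priors Prior probabilities over the state's coherences (sum to 1).
#' @return A data frame with the grid `x` and the marginal probability
#'   `density` (mass per cell divided by dx).
#' @export
marginal_density <- function(state, priors) {
  stopifnot(inherits(state, "fp_state"), length(priors) == nrow(state$mass))
  if (abs(sum(priors) - 1) > 1e-8)
    stop("priors must sum to 1 over the coherence set")
  data.frame(x = state$x,
             density = as.numeric(crossprod(state$mass, priors)) / state$dx)
}

#' Exit probability between two consecutive states
#'
#' The probability mass absorbed at either bound during the step(s) between
#' two states, aggregated over coherences with the given priors.
#'
#' @param state_before,state_after Consecutive [fp_state()] objects.
#' @param priors Prior probabilities over the coherences.
#' @return Non-negative scalar exit probability.
#' @export
exit_probability <- function(state_before, state_after, priors) {
  stopifnot(inherits(state_before, "fp_state"), inherits(state_after, "fp_state"))
  if (abs(sum(priors) - 1) > 1e-8)
    stop("priors must sum to 1 over the coherence set")
  d_up <- state_after$absorbed_upper - state_before$absorbed_upper
  d_lo <- state_after$absorbed_lower - state_before$absorbed_lower
  sum(priors * (d_up + d_lo))
}

# Full forward pass under a prescribed bound path; returns per-coherence
# per-step first-passage mass. Internal driver shared by predict_joint and
# the flat-bound validation.
fp_first_passage <- function(params, bounds, coh, dx = 0.01,
                             x_max = max(bounds$values) * 1.05 + 0.1,
                             dt = 5e-4, t_max = 5) {
  stopifnot(inherits(params, "ddm_params"), inherits(bounds, "bound_curve"))
  half <- round(x_max / dx)
  x <- seq(-half, half) * dx
  mass <- matrix(0, nrow = length(coh), ncol = length(x))
  mass[, half + 1] <- 1
  nstep <- round(t_max / dt)
  b_path <- bound_at(bounds, seq_len(nstep) * dt)
  b0 <- bound_at(bounds, 0)
  res <- cpp_fp_evolve(mass, x, dx, params$kappa * coh, 0.5, dt,
                       pmin(b_path, max(x)), min(b0, max(x)))
  list(t = seq_len(nstep) * dt, dt = dt, coh = coh,
       exit_upper = res$exit_upper, exit_lower = res$exit_lower,
       mass = res$mass, x = x)
}
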