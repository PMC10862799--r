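# Forward Monte-Carlo simulation of bounded drift-diffusion decisions and of
# full task sessions with deadlines, scoring and aborts.

#' Draw provisional deadlines
#'
#' Samples from the time-shifted Rayleigh deadline distribution by inversion:
#' t0 + sigma * sqrt(-2 log U).
#'
#' @param spec A [deadline_spec()].
#' @param n Number of samples.
#' @return Deadline times in seconds (all >= `t0`).
#' @export
sample_deadline <- function(spec, n = 1) {
  stopifnot(inherits(spec, "deadline_spec"))
  spec$t0 + spec$sigma_dl * sqrt(-2 * log(runif(n)))
}

#' Moments of the shifted-Rayleigh deadline distribution
#'
#' @param spec A [deadline_spec()].
#' @return A named vector with the closed-form mean `t0 + sigma*sqrt(pi/2)`
#'   and standard deviation `sigma*sqrt((4-pi)/2)`, in seconds.
#' @export
#' @examples
#' rayleigh_moments(deadline_spec(0.6, 0.7))
rayleigh_moments <- function(spec) {
  stopifnot(inherits(spec, "deadline_spec"))
  c(mean_s = spec$t0 + spec$sigma_dl * sqrt(pi / 2),
    sd_s = spec$sigma_dl * sqrt((4 - pi) / 2))
}

#' Simulate bounded drift-diffusion decisions
#'
#' Euler-Maruyama simulation of the decision variable dx = kappa*coh dt + dW
#' until it first reaches the symmetric bounds +/- B(t). The reaction time
#' adds a non-decision time drawn from N(mu_nd, sigma_nd^2) truncated at zero.
#'
#' @param params A [ddm_params()].
#' @param bounds A [bound_curve()].
#' @param coh Signed motion coherence, one value per trial.
#' @param t_max Maximum viewing time; trials not terminated by then have
#'   `choice = "none"` and `NA` times.
#' @param dt Simulation step, seconds.
#' @return A data frame with one row per trial: `coh`, `choice`
#'   ("left"/"right"/"none"), decision time `td_s` and reaction time `rt_s`.
#' @export
simulate_trials <- function(params, bounds, coh, t_max = 5, dt = 5e-4) {
  stopifnot(inherits(params, "ddm_params"), inherits(bounds, "bound_curve"),
            dt > 0)
  if (bounds$values[1] <= 0)
    warning("bound is non-positive at t = 0: decisions terminate immediately")
  res <- cpp_sim_trials(params$kappa * coh, dt, bounds$values, bounds$dt,
                        t_max, -1)
  tnd <- pmax(0, rnorm(length(coh), params$mu_nd, params$sigma_nd))
  choice <- c("left", "none", "right")[res$choice + 2L]
  rt <- ifelse(res$choice == 0L, NA_real_, res$td + tnd)
  data.frame(coh = coh, choice = choice, td_s = res$td, rt_s = rt)
}

#' Simulate a single trial
#'
#' @inheritParams simulate_trials
#' @return A list with `choice`, `decision_time_s` and `rt_s`.
#' @export
simulate_trial <- function(params, bounds, coh, t_max = 5, dt = 5e-4) {
  r <- simulate_trials(params, bounds, coh, t_max = t_max, dt = dt)
  list(choice = r$choice[1], decision_time_s = r$td_s[1], rt_s = r$rt_s[1])
}

#' Simulate a task phase
#'
#' Generates a block of trials under the three-phase task structure: the
#' coherence is drawn from the weighted stimulus set, the correct side follows
#' the coherence sign (drawn uniformly for 0\%), a fraction of trials carries a
#' provisional Rayleigh deadline and is cancelled if the reaction time exceeds
#' it, aborts occur as independent Bernoulli events, trials still undecided at
#' the viewing limit are recorded as aborted, and completed trials score
#' +1/-1 points.
#'
#' @param params A [ddm_params()].
#' @param bounds A [bound_curve()].
#' @param task A [task_config()]; its `deadline_fraction` must match the
#'   phase (0.5 for Phase II, 0 otherwise).
#' @param n_trials Number of trials.
#' @param phase Phase label ("I", "II" or "III").
#' @param participant,session Identifiers stored in the records.
#' @param dt Simulation step, seconds.
#' @return A trial-record data frame (see [validate_trials()]).
#' @export
simulate_phase <- function(params, bounds, task, n_trials, phase = "I",
                           participant = "sim", session = 1L, dt = 5e-4) {
  stopifnot(inherits(task, "task_config"), n_trials >= 0)
  if (phase != "II" && task$deadline_fraction > 0)
    stop("deadline_fraction must be 0 outside Phase II")
  empty <- data.frame(participant = character(), phase = character(),
                      session = integer(), trial_index = integer(),
                      coherence = numeric(), correct_side = character(),
                      has_deadline = logical(), deadline_s = numeric(),
                      choice = character(), rt_s = numeric(),
                      outcome = character(), points_delta = integer(),
                      stringsAsFactors = FALSE)
  if (n_trials == 0) return(empty)

  cs <- task$coherence_set
  idx <- sample.int(nrow(cs), n_trials, replace = TRUE, prob = cs$weight)
  coh <- cs$value[idx]
  correct_side <- ifelse(coh > 0, "right",
                         ifelse(coh < 0, "left",
                                ifelse(runif(n_trials) < 0.5, "left", "right")))
  has_deadline <- runif(n_trials) < task$deadline_fraction
  deadline <- rep(NA_real_, n_trials)
  if (any(has_deadline))
    deadline[has_deadline] <- sample_deadline(task$deadline, sum(has_deadline))
  aborted_pre <- runif(n_trials) < task$abort_rate

  sim <- simulate_trials(params, bounds, coh, t_max = task$max_viewing_s,
                         dt = dt)
  choice <- sim$choice
  rt <- sim$rt_s

  outcome <- rep("aborted", n_trials)
  done <- !aborted_pre & choice != "none"
  canceled <- done & has_deadline & rt > deadline
  completed <- done & !canceled
  outcome[canceled] <- "canceled"
  outcome[completed] <- ifelse(choice[completed] == correct_side[completed],
                               "correct", "error")
  choice[!completed] <- "none"
  rt[!completed] <- NA_real_
  points <- ifelse(outcome == "correct", 1L,
                   ifelse(outcome == "error", -1L, 0L))

  data.frame(participant = participant, phase = phase,
             session = as.integer(session), trial_index = seq_len(n_trials),
             coherence = coh, correct_side = correct_side,
             has_deadline = has_deadline, deadline_s = deadline,
             choice = choice, rt_s = rt, outcome = outcome,
             points_delta = points, stringsAsFactors = FALSE)
}

#' Points earning rate of a session
#'
#' The quantity participants were instructed to maximise: points per minute.
#' Elapsed time per trial is `misc + rt + iti` for completed trials,
#' `misc_cancel + deadline + iti` for cancelled trials and the configured
#' abort cost for aborted trials.
#'
#' @param trials A trial-record data frame.
#' @param task A [task_config()].
#' @return Points per minute.
#' @export
earning_rate <- function(trials, task) {
  stopifnot(inherits(task, "task_config"))
  elapsed <- ifelse(trials$outcome %in% c("correct", "error"),
                    task$misc_s + trials$rt_s + task$iti_s,
                    ifelse(trials$outcome == "canceled",
                           task$misc_cancel_s + trials$deadline_s + task$iti_s,
                           task$abort_cost_s))
  total <- sum(elapsed)
  if (!isTRUE(total > 0)) stop("undefined earning rate: zero elapsed time")
  sum(trials$points_delta) / (total / 60)
}
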