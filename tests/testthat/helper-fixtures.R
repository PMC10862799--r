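# Shared fixtures: small simulated sessions and hand-built trial tables.

fixture_params <- function() ddm_params(16.19, 0.27, 0.02)

fixture_linear_bound <- function(b0 = 1, slope = 0.2, dt = 5e-4, t_max = 5)
  bound_curve(pmax(b0 - slope * seq(0, t_max, dt), 0), dt)

fixture_task <- function(...) task_config(abort_rate = 0, ...)

# a tiny hand-built, valid trial table
fixture_trials_small <- function() {
  data.frame(
    participant = "A", phase = c("I", "I", "II"), session = 1L,
    trial_index = 1:3, coherence = c(0.512, -0.128, 0),
    correct_side = c("right", "left", "right"),
    has_deadline = c(FALSE, FALSE, TRUE),
    deadline_s = c(NA, NA, 1.25),
    choice = c("right", "right", "none"),
    rt_s = c(0.41, 0.93, NA),
    outcome = c("correct", "error", "canceled"),
    points_delta = c(1L, -1L, 0L), stringsAsFactors = FALSE)
}

# simulate a completed-standard-trials session quickly (coarse dt)
fixture_session <- function(n = 500, params = fixture_params(),
                            bounds = fixture_linear_bound(),
                            task = fixture_task(), phase = "I", dt = 1e-3) {
  simulate_phase(params, bounds, task, n, phase = phase, dt = dt)
}
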