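# Phase regressions, time-dependent accuracy, and cancellation-aligned RTs.

make_two_phase <- function(n = 800, shift = 0, seed = 61, bounds2 = NULL) {
  set.seed(seed)
  params <- fixture_params()
  b1 <- fixture_linear_bound()
  if (is.null(bounds2)) bounds2 <- b1
  t1 <- fixture_session(n, params, b1, phase = "I", dt = 2e-3)
  t2 <- fixture_session(n, params, bounds2, phase = "II", dt = 2e-3)
  t2$rt_s <- t2$rt_s + shift
  t2$rt_s <- pmax(t2$rt_s, 0.01)
  rbind(t1, t2)
}

test_that("RT regression coefficients equal the closed-form OLS solution", {
  tr <- make_two_phase(600)
  reg <- rt_phase_regression(tr, "correct")
  d <- filter_standard_trials(tr)
  d <- d[d$outcome == "correct", ]
  X <- cbind(sapply(sort(unique(abs(d$coherence))),
                    function(s) as.integer(abs(d$coherence) == s)),
             as.integer(d$phase == "II"))
  beta <- solve(crossprod(X), crossprod(X, d$rt_s))
  expect_equal(unname(reg$coefficients[, 1]), as.numeric(beta),
               tolerance = 1e-8)
  expect_true(reg$full_rank)
  expect_equal(reg$n, nrow(d))
})

test_that("a known phase shift in RT is recovered by the regression", {
  reg <- rt_phase_regression(make_two_phase(2000, shift = -0.1), "correct")
  expect_lt(abs(reg$beta_phase - (-0.1)), 3 * reg$se + 0.005)
  expect_lt(reg$p_value, 1e-6)
  # identical generators: no phase effect
  reg0 <- rt_phase_regression(make_two_phase(2000, shift = 0, seed = 62),
                              "correct")
  expect_gt(reg0$p_value, 1e-4)
  expect_output(print(reg), "beta_phase")
})

test_that("logistic phase regression detects lower accuracy under lower bounds", {
  tr <- make_two_phase(3000, seed = 63,
                       bounds2 = fixture_linear_bound(0.55, 0.15))
  fit <- accuracy_phase_logistic(tr)
  expect_lt(fit$beta_phase, 0)
  expect_lt(fit$p_value, 0.05)
  # pooled variant with per-participant slopes
  tr$participant <- rep(c("A", "B"), length.out = nrow(tr))
  fitp <- accuracy_phase_logistic(tr, pooled = TRUE)
  expect_lt(fitp$beta_phase, 0)
})

test_that("zero-coherence-only data sit at chance under the intercept-free model", {
  set.seed(64)
  tr <- fixture_session(800, bounds = fixture_linear_bound(0.8, 0.15),
                        dt = 2e-3)
  tr <- tr[tr$coherence == 0 & tr$outcome %in% c("correct", "error"), ]
  tr2 <- tr
  tr2$phase <- "II"
  both <- rbind(tr, tr2)
  fit <- suppressWarnings(accuracy_phase_logistic(both))
  # slope term multiplies |coh| = 0 everywhere: predicted p_correct = 0.5
  # up to the phase term, which here compares identical data
  expect_lt(abs(fit$beta_phase), 0.2)
  p_pred <- 1 / (1 + exp(-fit$beta_phase))
  expect_lt(abs(p_pred - 0.5), 0.06)
})

test_that("windowed accuracy is exact on degenerate inputs", {
  tr <- fixture_trials_small()[1, ][rep(1, 30), ]
  tr$rt_s <- seq(0.3, 3.2, 0.1)
  tda <- time_dependent_accuracy(tr, window_trials = 10)
  expect_true(all(tda$accuracy == 1)) # all-correct data: flat at 1
  # window = n collapses to the overall accuracy
  tr$outcome[1:10] <- "error"
  tda2 <- time_dependent_accuracy(tr, window_trials = 30)
  expect_equal(nrow(tda2), 1L)
  expect_equal(tda2$accuracy, 2 / 3)
  # fewer trials than the window falls back to a single window with warning
  expect_warning(time_dependent_accuracy(tr[1:5, ], window_trials = 100),
                 "single window")
})

test_that("windowed accuracy weighted over disjoint windows recovers the total", {
  set.seed(65)
  tr <- fixture_session(400, dt = 2e-3)
  tr <- tr[abs(tr$coherence) == 0.128 & tr$outcome %in% c("correct", "error"), ]
  w <- 10
  n <- (nrow(tr) %/% w) * w
  tr <- tr[1:n, ]
  tda <- time_dependent_accuracy(tr, window_trials = w)
  disjoint <- tda[tda$window %in% seq(1, n - w + 1, w), ]
  expect_equal(mean(disjoint$accuracy), mean(tr$outcome == "correct"),
               tolerance = 1e-12)
})

test_that("z-scored RTs are standard within each motion strength", {
  set.seed(66)
  tr <- fixture_session(1500, dt = 2e-3)
  for (s in unique(abs(tr$coherence))) {
    i <- abs(tr$coherence) == s & !is.na(tr$rt_s)
    z <- (tr$rt_s[i] - mean(tr$rt_s[i])) / sd(tr$rt_s[i])
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
})

test_that("cancellation-aligned RTs are flat without post-cancellation adjustment", {
  set.seed(67)
  task2 <- fixture_task(deadline_fraction = 0.5,
                        deadline = deadline_spec(0.45, 0.5))
  tr <- simulate_phase(fixture_params(), fixture_linear_bound(), task2, 4000,
                       phase = "II", dt = 2e-3)
  al <- cancellation_aligned_rt(tr, lags = 5)
  expect_equal(nrow(al), 10L)
  # the generator adjusts nothing after a cancellation: post-lag means near 0
  post <- al[al$lag > 0, ]
  expect_true(all(abs(post$mean_z) < 4 * post$se + 0.05))
})

test_that("a constructed post-cancellation speed-up appears at positive lags", {
  set.seed(68)
  task2 <- fixture_task(deadline_fraction = 0.5,
                        deadline = deadline_spec(0.45, 0.5))
  tr <- simulate_phase(fixture_params(), fixture_linear_bound(), task2, 6000,
                       phase = "II", dt = 2e-3)
  # speed up the three trials after each cancellation by 30%
  canc <- which(tr$outcome == "canceled")
  idx <- unique(pmin(rep(canc, each = 3) + 1:3, nrow(tr)))
  tr$rt_s[idx] <- tr$rt_s[idx] * 0.7
  al <- cancellation_aligned_rt(tr, lags = 5)
  early_post <- al$mean_z[al$lag %in% 1:3]
  pre <- al$mean_z[al$lag %in% -5:-1]
  expect_lt(mean(early_post), mean(pre) - 0.1)
  # recovery toward baseline at later lags
  expect_gt(al$mean_z[al$lag == 5], mean(early_post))
})

test_that("cancellation alignment handles boundaries and empty input", {
  tr <- fixture_trials_small()
  tr <- rbind(tr[3, ], tr[1:2, ]) # cancellation at session start
  tr$trial_index <- 1:3
  tr$coherence[3] <- -0.512 # same motion strength so z-scores exist
  al <- cancellation_aligned_rt(tr, lags = 2)
  expect_equal(al$n[al$lag < 0], c(0L, 0L))
  expect_true(all(al$n[al$lag > 0] >= 1L))
  expect_warning(out <- cancellation_aligned_rt(tr[2:3, ], lags = 2),
                 "no cancelled trials")
  expect_equal(nrow(out), 0L)
})
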