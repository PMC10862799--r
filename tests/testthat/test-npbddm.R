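# Nonparametric bound derivation, the joint predictive, and the fit surface.

test_that("derive_bounds recovers a known flat bound from its exact density", {
  params <- ddm_params(16, 0.27, 0)
  cs <- coherence_set()
  B0 <- 0.8
  true_b <- bound_curve(rep(B0, 2), dt = 5)
  fp <- npbddm:::fp_first_passage(params, true_b, cs$value, dx = 0.01,
                                  x_max = 1.5, dt = 5e-4, t_max = 5)
  g <- as.numeric(cs$weight %*% (fp$exit_upper + fp$exit_lower))
  dens <- structure(list(t = fp$t, density = g / (sum(g) * 5e-4), dt = 5e-4,
                         n_trials = 1e6), class = "td_density")
  bh <- derive_bounds(dens, params, priors = cs, x_max = 1.5)
  cdf <- cumsum(g) / sum(g)
  q <- fp$t[c(which(cdf >= 0.05)[1], which(cdf >= 0.95)[1])]
  tt <- seq(q[1], q[2], 0.01)
  expect_lt(max(abs(bound_at(bh, tt) - B0)) / B0, 0.05)
})

test_that("derive_bounds recovers a linear collapse slope from its exact density", {
  params <- ddm_params(16, 0.27, 0)
  cs <- coherence_set()
  true_b <- fixture_linear_bound(1, 0.2)
  fp <- npbddm:::fp_first_passage(params, true_b, cs$value, dx = 0.01,
                                  x_max = 1.5, dt = 5e-4, t_max = 5)
  g <- as.numeric(cs$weight %*% (fp$exit_upper + fp$exit_lower))
  dens <- structure(list(t = fp$t, density = g / (sum(g) * 5e-4), dt = 5e-4,
                         n_trials = 1e6), class = "td_density")
  bh <- derive_bounds(dens, params, priors = cs, x_max = 1.5)
  cdf <- cumsum(g) / sum(g)
  q <- fp$t[c(which(cdf >= 0.1)[1], which(cdf >= 0.9)[1])]
  tt <- seq(q[1], q[2], 0.01)
  slope <- -coef(lm(bound_at(bh, tt) ~ tt))[[2]]
  expect_lt(abs(slope - 0.2) / 0.2, 0.1)
})

test_that("the bound stays at the bracket ceiling while no exit mass is demanded", {
  set.seed(21)
  params <- fixture_params()
  rts <- runif(300, 1.0, 1.6) # all decision mass well after t = 0
  dens <- decision_time_density(rts, params$mu_nd, dt = 1e-3)
  bh <- derive_bounds(dens, params, x_max = 2)
  early <- bound_at(bh, seq(0, 0.3, 0.01))
  expect_true(all(early == 2))
})

test_that("demanding more exit mass in a step lowers the matched bound", {
  cs <- coherence_set()
  x_max <- 1.5
  half <- round(x_max / 0.01)
  x <- seq(-half, half) * 0.01
  run <- function(m) {
    target <- c(rep(0, 200), m, numeric(100))
    r <- npbddm:::cpp_npb_derive(x, 0.01, 16 * cs$value, cs$weight, 0.5,
                                 5e-4, target, x_max, 1 - 1e-4)
    r$bounds[201]
  }
  b <- sapply(c(1e-4, 1e-3, 5e-3, 2e-2), run)
  expect_true(all(diff(b) < 0))
})

test_that("predictive RT densities normalise and shift correctly", {
  params <- ddm_params(16, 0.3, 0)
  cs <- coherence_set()
  b <- fixture_linear_bound()
  jp <- predict_joint(params, b, cs, dt = 1e-3)
  # integral over RT and choice per coherence is 1 (bounded by non-termination)
  tot <- rowSums(jp$upper + jp$lower) * jp$dt
  expect_true(all(abs(tot - 1) < 1e-3))
  # sigma_nd = 0 is a pure shift of the decision-time density by mu_nd
  fp <- npbddm:::fp_first_passage(params, b, cs$value, dx = 0.01,
                                  x_max = 1.2, dt = 1e-3, t_max = 5)
  k <- which(cs$value == 0.512)
  g <- fp$exit_upper[k, ] / 1e-3
  shift <- round(params$mu_nd / 1e-3)
  expect_lt(max(abs(jp$upper[k, (shift + 1):4000] - g[1:(4000 - shift)])), 1e-6)
  # with sigma_nd > 0 the mass is preserved under the convolution
  params2 <- ddm_params(16, 0.3, 0.05)
  jp2 <- predict_joint(params2, b, cs, dt = 1e-3)
  expect_true(all(abs(rowSums(jp2$upper + jp2$lower) * jp2$dt - 1) < 2e-3))
})

test_that("predicted choice probabilities match Monte-Carlo simulation", {
  set.seed(22)
  params <- ddm_params(16, 0.3, 0.05)
  cs <- coherence_set()
  b <- fixture_linear_bound()
  jp <- predict_joint(params, b, cs, dt = 1e-3)
  k <- which(cs$value == 0.512)
  n <- 3e4
  sim <- simulate_trials(params, b, rep(0.512, n), dt = 1e-3)
  p_hat <- mean(sim$choice == "right")
  p_pred <- jp$p_upper[k] / (jp$p_upper[k] + jp$p_lower[k])
  expect_lt(abs(p_hat - p_pred), 3 * sqrt(p_pred * (1 - p_pred) / n) + 2e-3)
})

test_that("the joint likelihood doubles when every trial is duplicated", {
  set.seed(23)
  params <- fixture_params()
  cs <- coherence_set()
  b <- fixture_linear_bound()
  jp <- predict_joint(params, b, cs, dt = 2e-3)
  tr <- fixture_session(200, dt = 2e-3)
  tr <- filter_standard_trials(tr)
  ll1 <- npbddm:::trial_loglik(jp, tr$coherence, tr$rt_s, tr$choice == "right")
  tr2 <- rbind(tr, tr)
  ll2 <- npbddm:::trial_loglik(jp, tr2$coherence, tr2$rt_s, tr2$choice == "right")
  expect_equal(ll2, 2 * ll1, tolerance = 1e-12)
})

test_that("forward simulation, derivation and prediction round-trip RT quantiles", {
  set.seed(24)
  params <- fixture_params()
  true_b <- fixture_linear_bound()
  cs <- coherence_set()
  idx <- sample.int(nrow(cs), 1e4, TRUE, cs$weight)
  sim <- simulate_trials(params, true_b, cs$value[idx])
  dens <- decision_time_density(sim$rt_s, params$mu_nd)
  bh <- derive_bounds(dens, params, cs, x_max = 2)
  jp <- npbddm:::joint_from_exits(attr(bh, "exit_upper"), attr(bh, "exit_lower"),
                                  5e-4, params, cs)
  # the match step is exact: aggregated exit mass reproduces the empirical
  # decision-time density step by step
  ex <- as.numeric(cs$weight %*% (attr(bh, "exit_upper") + attr(bh, "exit_lower")))
  expect_lt(max(abs(ex - (dens$density * dens$dt)[seq_along(ex)])), 1e-9)
  # the predictive RT distribution tracks the sample quantiles up to the
  # kernel-smoothing bias of the decision-time density (order of half the
  # kernel s.d. at the quantiles of a skewed distribution)
  mix <- as.numeric(cs$weight %*% (jp$upper + jp$lower)) * jp$dt
  cdf <- cumsum(mix) / sum(mix)
  for (p in seq(0.1, 0.9, 0.2)) {
    q_pred <- jp$t[which(cdf >= p)[1]]
    q_obs <- as.numeric(quantile(sim$rt_s, p))
    expect_lt(abs(q_pred - q_obs), 0.05)
  }
})

test_that("accuracy declines with RT under derived collapsing bounds", {
  set.seed(25)
  params <- fixture_params()
  cs <- coherence_set()
  tr <- fixture_session(6000)
  tda <- time_dependent_accuracy(tr, window_trials = 300)
  mid <- tda[tda$strength == 0.128, ]
  # compare early vs late windows
  n3 <- floor(nrow(mid) / 3)
  expect_gt(mean(mid$accuracy[1:n3]), mean(mid$accuracy[(2 * n3):(3 * n3)]))
})

test_that("a quick fit returns a coherent model object with working methods", {
  set.seed(26)
  tr <- fixture_session(400, dt = 2e-3)
  fit <- suppressWarnings(npbddm(tr, dt = 4e-3, x_max = 1.5, restarts = 1,
                                 maxit = 40))
  expect_s3_class(fit, "npbddm")
  expect_named(coef(fit), c("kappa", "mu_nd", "sigma_nd"))
  expect_true(is.finite(logLik(fit)))
  expect_equal(attr(logLik(fit), "df"), 3L)
  pr <- predict(fit)
  expect_true(all(diff(pr$p_right) >= -1e-9)) # monotone in signed coherence
  expect_s3_class(predict(fit, type = "joint"), "joint_predictive")
  expect_output(print(fit), "kappa")
  expect_output(print(summary(fit)), "choice probabilities")
  r <- residuals(fit)
  expect_length(r, fit$n)
  s <- simulate(fit, nsim = 50)
  expect_equal(nrow(s), 50L)
  grDevices::pdf(NULL); on.exit(grDevices::dev.off())
  plot(fit)
  # likelihood at the optimum beats +/- 20% kappa perturbations
  obj <- function(k) {
    p <- ddm_params(k, fit$params$mu_nd, fit$params$sigma_nd)
    dens <- decision_time_density(fit$data$rt_s, p$mu_nd, dt = 4e-3)
    b <- derive_bounds(dens, p, fit$priors, x_max = 1.5)
    jp <- npbddm:::joint_from_exits(attr(b, "exit_upper"), attr(b, "exit_lower"),
                                    4e-3, p, fit$priors)
    npbddm:::trial_loglik(jp, fit$data$coherence, fit$data$rt_s,
                          fit$data$choice == "right")
  }
  expect_gte(fit$logLik + 1e-6, obj(coef(fit)[["kappa"]] * 1.2) - 0.5)
  expect_gte(fit$logLik + 1e-6, obj(coef(fit)[["kappa"]] * 0.8) - 0.5)
})
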