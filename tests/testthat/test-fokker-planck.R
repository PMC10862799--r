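# Density propagation: conservation, free diffusion, absorption, closed forms.

test_that("free diffusion reproduces the analytic Gaussian", {
  params <- ddm_params(1, 0.1, 0)
  st <- fp_state(params, coh = 0, dx = 0.01, x_max = 3)
  for (i in 1:400) st <- propagate_step(st, bound_now = 3, dt = 5e-4)
  t <- st$t
  dens <- st$mass[1, ] / st$dx
  expect_lt(max(abs(dens - dnorm(st$x, 0, sqrt(t)))), 5e-3)
  # with drift
  st2 <- fp_state(ddm_params(2, 0.1, 0), coh = 1, dx = 0.01, x_max = 3)
  for (i in 1:400) st2 <- propagate_step(st2, bound_now = 3, dt = 5e-4)
  expect_lt(max(abs(st2$mass[1, ] / st2$dx - dnorm(st2$x, 2 * st2$t, sqrt(st2$t)))),
            5e-3)
})

test_that("mass is conserved to solver tolerance and absorption is monotone", {
  params <- ddm_params(16, 0.2, 0)
  st <- fp_state(params, coh = c(-0.256, 0, 0.512), dx = 0.01, x_max = 1.5)
  prev_abs <- 0
  for (i in 1:600) {
    st <- propagate_step(st, bound_now = 0.8 - 2e-4 * i, dt = 5e-4)
    tot <- rowSums(st$mass) + st$absorbed_upper + st$absorbed_lower
    expect_lt(max(abs(tot - 1)), 1e-9)
    expect_true(all(st$mass >= 0))
    cur <- sum(st$absorbed_upper + st$absorbed_lower)
    expect_gte(cur, prev_abs - 1e-12)
    prev_abs <- cur
  }
})

test_that("a zero bound absorbs all remaining mass split by side of origin", {
  st <- fp_state(ddm_params(1, 0.1, 0), coh = 0, dx = 0.01, x_max = 1)
  for (i in 1:200) st <- propagate_step(st, bound_now = 1, dt = 5e-4)
  interior <- rowSums(st$mass)
  st2 <- propagate_step(st, bound_now = 0, dt = 5e-4)
  expect_equal(rowSums(st2$mass), 0)
  expect_equal(st2$absorbed_upper + st2$absorbed_lower,
               st$absorbed_upper + st$absorbed_lower + interior,
               tolerance = 1e-12)
  # symmetric density splits evenly
  expect_equal(st2$absorbed_upper, st2$absorbed_lower, tolerance = 1e-9)
})

test_that("flat-bound exit probability matches the logistic closed form", {
  # P(upper) = 1/(1 + exp(-2 mu B)) for drift mu, diffusion 1
  for (mu in c(0.5, 2)) {
    for (B in c(0.5, 1)) {
      params <- ddm_params(1, 0.1, 0)
      b <- bound_curve(rep(B, 2), dt = 10)
      fp <- npbddm:::fp_first_passage(params, b, coh = mu, dx = 0.01,
                                      x_max = B, dt = 5e-4, t_max = 30)
      p_up <- sum(fp$exit_upper)
      expect_lt(abs(p_up - 1 / (1 + exp(-2 * mu * B))), 1e-3)
    }
  }
})

test_that("halving dx leaves flat-bound exit probability unchanged to 1e-4", {
  params <- ddm_params(1, 0.1, 0)
  b <- bound_curve(rep(1, 2), dt = 10)
  p <- sapply(c(0.01, 0.005), function(dx) {
    fp <- npbddm:::fp_first_passage(params, b, coh = 1, dx = dx, x_max = 1,
                                    dt = 5e-4, t_max = 20)
    sum(fp$exit_upper)
  })
  expect_lt(abs(p[1] - p[2]), 1e-4)
})

test_that("marginal density mixes coherences and keeps symmetry", {
  params <- ddm_params(16, 0.2, 0)
  st <- fp_state(params, coh = c(-0.256, 0.256), dx = 0.01, x_max = 2)
  for (i in 1:200) st <- propagate_step(st, bound_now = 2, dt = 5e-4)
  # single coherence with prior 1 is the identity
  md1 <- marginal_density(st, c(0, 1))
  expect_equal(md1$density, st$mass[2, ] / st$dx)
  # symmetric pair with equal priors gives a symmetric marginal
  md <- marginal_density(st, c(0.5, 0.5))
  expect_equal(md$density, rev(md$density), tolerance = 1e-12)
  expect_error(marginal_density(st, c(0.5, 0.4)), "sum to 1")
})

test_that("marginal density agrees with a Monte-Carlo trajectory histogram", {
  set.seed(8)
  params <- ddm_params(16, 0.2, 0)
  cs <- coherence_set()
  st <- fp_state(params, coh = cs$value, dx = 0.01, x_max = 3)
  t_snap <- 0.3
  for (i in seq_len(t_snap / 1e-3)) st <- propagate_step(st, 3, dt = 1e-3)
  md <- marginal_density(st, cs$weight)
  n <- 2e5
  idx <- sample.int(nrow(cs), n, TRUE, cs$weight)
  sim <- npbddm:::cpp_sim_trials(params$kappa * cs$value[idx], 1e-3, c(3, 3), 10,
                                 t_snap + 0.01, t_snap)
  xs <- sim$x_snapshot[!is.na(sim$x_snapshot)]
  br <- seq(-1.5, 1.5, 0.15)
  hist_p <- hist(xs[abs(xs) < 1.5], breaks = br, plot = FALSE)$counts / n
  cell <- findInterval(md$x, br)
  model_p <- tapply(md$density * st$dx, cell, sum)[as.character(1:(length(br) - 1))]
  se <- sqrt(pmax(model_p, 1e-6) * (1 - model_p) / n)
  expect_lt(max(abs(hist_p - model_p) / (4 * se + 2e-3)), 1)
})

test_that("exit probability equals the weighted absorbed increment", {
  params <- ddm_params(16, 0.2, 0)
  st <- fp_state(params, coh = c(0, 0.512), dx = 0.01, x_max = 1)
  for (i in 1:100) st <- propagate_step(st, 0.5, dt = 5e-4)
  st2 <- propagate_step(st, 0.5, dt = 5e-4)
  ep <- exit_probability(st, st2, c(0.5, 0.5))
  expect_gte(ep, 0)
  expect_equal(ep, 0.5 * sum(st2$absorbed_upper - st$absorbed_upper) +
                   0.5 * sum(st2$absorbed_lower - st$absorbed_lower))
  # far bound, no movement: essentially no exit
  stw <- fp_state(params, coh = c(0, 0.512), dx = 0.01, x_max = 3)
  stw2 <- propagate_step(stw, 3, dt = 5e-4)
  expect_lt(exit_probability(stw, stw2, c(0.5, 0.5)), 1e-12)
})

test_that("a bound beyond the grid extent is an error", {
  st <- fp_state(ddm_params(1, 0.1, 0), coh = 0, dx = 0.01, x_max = 1)
  expect_error(propagate_step(st, bound_now = 1.5), "grid-extent")
})
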