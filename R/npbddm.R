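# The nonparametric-bound drift-diffusion model: derive the time course of
# the symmetric decision bounds from the empirical decision-time distribution
# (alternating Fokker-Planck propagation with an exit-mass match), and fit
# theta = (kappa, mu_nd, sigma_nd) by maximum likelihood with the bounds
# re-derived from the data inside every likelihood evaluation.

#' Derive decision bounds from a decision-time density
#'
#' Inverts the empirical decision-time distribution into the bound time
#' course B(t). At every time step the per-coherence density of the decision
#' variable is propagated forward, then the symmetric bound is placed so
#' that the probability mass absorbed during the step, aggregated across
#' coherences with the prior weights, equals the empirical termination
#' probability `p_Td(t) * dt`. When the density demands no exit mass the
#' bound stays at the bracket ceiling (the grid half-width); if it demands
#' more than the remaining interior mass the bound is clamped to zero from
#' that step on and the result is flagged.
#'
#' @param density A [decision_time_density()] (its grid sets the time step).
#' @param params A [ddm_params()] (only `kappa` enters the derivation).
#' @param priors Data frame of signed coherences and weights, as
#'   [coherence_set()]; defaults to the design mixture.
#' @param dx Evidence-grid spacing.
#' @param x_max Evidence-grid half-width, which is also the ceiling of the
#'   bound bracket.
#' @param stop_mass Derivation stops once this much probability has been
#'   absorbed (or at the end of the density grid).
#' @return A [bound_curve()] with attributes `exit_upper` / `exit_lower`
#'   (coherence-by-step first-passage mass), `coh`, `weight` and `clamped`.
#' @export
derive_bounds <- function(density, params, priors = coherence_set(),
                          dx = 0.01, x_max = 3, stop_mass = 1 - 1e-4) {
  stopifnot(inherits(density, "td_density"), inherits(params, "ddm_params"))
  if (abs(sum(priors$weight) - 1) > 1e-6)
    stop("priors must sum to 1 over the coherence set")
  half <- round(x_max / dx)
  x <- seq(-half, half) * dx
  target <- density$density * density$dt
  res <- cpp_npb_derive(x, dx, params$kappa * priors$value, priors$weight,
                        0.5, density$dt, target, x_max, stop_mass)
  last <- res$last_step
  b <- bound_curve(c(x_max, res$bounds[seq_len(last)]), density$dt)
  attr(b, "exit_upper") <- res$exit_upper[, seq_len(last), drop = FALSE]
  attr(b, "exit_lower") <- res$exit_lower[, seq_len(last), drop = FALSE]
  attr(b, "coh") <- priors$value
  attr(b, "weight") <- priors$weight
  attr(b, "clamped") <- res$clamped
  attr(b, "cum_exit") <- res$cum_exit
  b
}

# Convolve a decision-time density (on a uniform grid starting at dt) with
# the non-decision-time distribution max(0, N(mu, sigma^2)).
nd_convolve <- function(g, dt, mu, sigma) {
  n <- length(g)
  if (sigma <= 0) {
    s <- mu / dt
    j0 <- floor(s)
    fr <- s - j0
    shifted <- numeric(n)
    idx <- seq_len(n) - j0
    lo <- idx - 1
    g0 <- function(i) ifelse(i >= 1 & i <= n, g[pmax(pmin(i, n), 1)], 0)
    shifted <- (1 - fr) * g0(idx) + fr * g0(lo)
    return(shifted)
  }
  w0 <- pnorm(0, mu, sigma) # atom at zero lag from truncation at 0
  L <- min(n, ceiling((mu + 6 * sigma) / dt) + 1)
  k <- dnorm((seq_len(L) - 1) * dt, mu, sigma)
  z <- convolve(g, rev(k), type = "open")[seq_len(n)]
  z[z < 0] <- 0
  w0 * g + dt * z
}

#' Joint predictive distribution of reaction time and choice
#'
#' For each coherence, the first-passage densities at the upper (rightward)
#' and lower (leftward) bound are computed by Fokker-Planck propagation under
#' the supplied bounds and convolved with the non-decision-time distribution
#' (Gaussian, truncated at zero; a pure time shift when `sigma_nd = 0`).
#'
#' @param params A [ddm_params()].
#' @param bounds A [bound_curve()].
#' @param priors Data frame of signed coherences and weights.
#' @param dx,x_max Evidence-grid spacing and half-width.
#' @param dt Time step of the output grid, seconds.
#' @param t_max Upper end of the reaction-time grid, seconds.
#' @return An object of class `joint_predictive`: time grid `t`, coherences
#'   `coh`, matrices `upper` and `lower` (coherence by time) of RT densities,
#'   and per-coherence choice probabilities `p_upper` / `p_lower`.
#' @export
predict_joint <- function(params, bounds, priors = coherence_set(),
                          dx = 0.01, x_max = NULL, dt = 5e-4, t_max = 5) {
  stopifnot(inherits(params, "ddm_params"), inherits(bounds, "bound_curve"))
  if (is.null(x_max)) x_max <- max(bounds$values) * 1.05 + 0.1
  fp <- fp_first_passage(params, bounds, priors$value, dx = dx, x_max = x_max,
                         dt = dt, t_max = t_max)
  joint_from_exits(fp$exit_upper, fp$exit_lower, dt, params, priors)
}

# Build a joint_predictive from per-step first-passage mass matrices.
joint_from_exits <- function(exit_up, exit_lo, dt, params, priors,
                             t_max = 5) {
  n <- round(t_max / dt)
  K <- nrow(exit_up)
  pad <- function(m) {
    out <- matrix(0, K, n)
    take <- min(ncol(m), n)
    out[, seq_len(take)] <- m[, seq_len(take)]
    out
  }
  gu <- pad(exit_up) / dt
  gl <- pad(exit_lo) / dt
  fu <- t(apply(gu, 1, nd_convolve, dt = dt, mu = params$mu_nd,
                sigma = params$sigma_nd))
  fl <- t(apply(gl, 1, nd_convolve, dt = dt, mu = params$mu_nd,
                sigma = params$sigma_nd))
  structure(list(t = seq_len(n) * dt, dt = dt, coh = priors$value,
                 weight = priors$weight, upper = fu, lower = fl,
                 p_upper = rowSums(gu) * dt, p_lower = rowSums(gl) * dt),
            class = "joint_predictive")
}

#' @export
print.joint_predictive <- function(x, ...) {
  cat(sprintf("Joint RT/choice predictive over %d coherences, t in (0, %.2f] s\n",
              length(x$coh), max(x$t)))
  invisible(x)
}

# Per-trial log likelihood of (rt, choice) under a joint predictive.
# choice_upper: logical, TRUE for rightward (upper-bound) choices.
trial_loglik <- function(jp, coh, rt, choice_upper, floor = 1e-10) {
  kidx <- match(coh, jp$coh)
  if (anyNA(kidx)) stop("trial coherence not in the predictive's set")
  n <- length(jp$t)
  u <- rt / jp$dt
  j <- pmin(pmax(floor(u), 1), n - 1)
  fr <- pmin(pmax(u - j, 0), 1)
  dens <- numeric(length(rt))
  for (i in seq_along(rt)) {
    m <- if (choice_upper[i]) jp$upper else jp$lower
    dens[i] <- (1 - fr[i]) * m[kidx[i], j[i]] + fr[i] * m[kidx[i], j[i] + 1]
  }
  sum(log(pmax(dens, floor)))
}

#' Fit the nonparametric-bound drift-diffusion model
#'
#' Maximises the joint likelihood of single-trial reaction times and choices
#' over theta = (kappa, mu_nd, sigma_nd). The decision bounds are not free
#' parameters: inside every likelihood evaluation they are re-derived from
#' the data's decision-time distribution with the candidate `mu_nd` (see
#' [derive_bounds()]), so the three parameters fully determine the model.
#' Optimisation is a derivative-free Nelder-Mead simplex with jittered
#' restarts; `sigma_nd` is floored at 1 ms.
#'
#' @param data A trial-record data frame (only completed standard trials are
#'   used; see [filter_standard_trials()]).
#' @param priors Optional data frame of signed coherences and weights for the
#'   propagation/match aggregation; defaults to the empirical per-coherence
#'   frequencies of the fitted trials.
#' @param dt Time step of the propagation and likelihood grids, seconds.
#' @param dx,x_max Evidence-grid spacing and half-width (the bound bracket
#'   ceiling equals `x_max`).
#' @param t_max Upper end of the time grids, seconds.
#' @param bandwidth_sd Epanechnikov kernel standard deviation, seconds.
#' @param restarts Number of jittered restarts of the simplex search.
#' @param start Optional named start vector `c(kappa, mu_nd, sigma_nd)`.
#' @param maxit Maximum simplex iterations per start.
#' @return An object of class `npbddm` with components `params`
#'   ([ddm_params()]), `bounds` ([bound_curve()]), `logLik`, `n`, `priors`,
#'   `predictive` ([predict_joint()] at the optimum), `data` (the fitted
#'   trials), `convergence` and `call`.
#' @export
npbddm <- function(data, priors = NULL, dt = 5e-4, dx = 0.01, x_max = 3,
                   t_max = 5, bandwidth_sd = 0.1, restarts = 3, start = NULL,
                   maxit = 200) {
  cl <- match.call()
  trials <- filter_standard_trials(data)
  if (nrow(trials) == 0) stop("no completed standard trials to fit")
  rt <- trials$rt_s
  coh <- trials$coherence
  up <- trials$choice == "right"

  if (is.null(priors)) {
    tab <- table(coh)
    priors <- data.frame(value = as.numeric(names(tab)),
                         weight = as.numeric(tab) / length(coh))
  }
  if (!all(coh %in% priors$value))
    stop("trial coherences outside the prior coherence set")

  # the decision-time KDE is a pure shift of the reaction-time KDE, so the
  # reaction-time KDE is computed once and shifted per candidate mu_nd
  h <- bandwidth_sd * sqrt(5)
  s_grid <- seq_len(round((t_max + 1) / dt)) * dt
  kde_rt <- decision_time_density(rt, 0, bandwidth_sd, dt, t_max + 1)$density
  n_t <- round(t_max / dt)
  sigma_floor <- 1e-3

  make_density <- function(mu_nd) {
    f <- approx(s_grid, kde_rt, xout = seq_len(n_t) * dt + mu_nd,
                yleft = 0, yright = 0)$y
    f[f < 0] <- 0
    norm <- sum(f) * dt
    if (norm < 1e-3) return(NULL)
    structure(list(t = seq_len(n_t) * dt, density = f / norm, dt = dt,
                   n_trials = length(rt)), class = "td_density")
  }

  eval_theta <- function(par, keep = FALSE) {
    kappa <- par[1]; mu_nd <- par[2]; sigma_nd <- max(par[3], sigma_floor)
    if (!is.finite(kappa) || kappa <= 0 || kappa > 200 ||
        !is.finite(mu_nd) || mu_nd < 0 || mu_nd > min(2, max(rt)))
      return(if (keep) NULL else 1e10)
    dens <- make_density(mu_nd)
    if (is.null(dens)) return(if (keep) NULL else 1e10)
    params <- ddm_params(kappa, max(mu_nd, 1e-6), sigma_nd)
    b <- derive_bounds(dens, params, priors, dx = dx, x_max = x_max)
    jp <- joint_from_exits(attr(b, "exit_upper"), attr(b, "exit_lower"),
                           dt, params, priors, t_max = t_max)
    ll <- trial_loglik(jp, coh, rt, up)
    if (keep) list(params = params, bounds = b, predictive = jp, logLik = ll)
    else -ll
  }

  if (is.null(start))
    start <- c(kappa = 15,
               mu_nd = max(0.1, 0.8 * as.numeric(quantile(rt, 0.02))),
               sigma_nd = 0.05)
  best <- NULL
  conv <- 1L
  for (r in seq_len(max(1, restarts))) {
    s <- start
    if (r > 1) {
      s[1] <- start[1] * runif(1, 0.7, 1.4)
      s[2] <- max(0.05, start[2] + runif(1, -0.08, 0.08))
      s[3] <- start[3] * runif(1, 0.5, 2)
    }
    fit <- optim(s, eval_theta, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-7))
    if (is.null(best) || fit$value < best$value) { best <- fit; conv <- fit$convergence }
  }
  if (conv != 0L)
    warning("simplex search did not fully converge; reporting best theta found")

  out <- eval_theta(best$par, keep = TRUE)
  structure(list(params = out$params, bounds = out$bounds,
                 logLik = out$logLik, n = length(rt), priors = priors,
                 predictive = out$predictive, data = trials,
                 convergence = conv, settings = list(dt = dt, dx = dx,
                   x_max = x_max, t_max = t_max, bandwidth_sd = bandwidth_sd),
                 call = cl),
            class = "npbddm")
}

#' @export
print.npbddm <- function(x, ...) {
  cat("Nonparametric-bound drift-diffusion model\n")
  cat(sprintf("  %d trials, log-likelihood %.2f\n", x$n, x$logLik))
  print(x$params)
  cat(sprintf("  bounds: B(0+) = %.3f, derived to t = %.3f s%s\n",
              x$bounds$values[2], x$bounds$t_max,
              if (isTRUE(attr(x$bounds, "clamped"))) " (clamped to 0 late)" else ""))
  invisible(x)
}

#' @export
coef.npbddm <- function(object, ...) {
  c(kappa = object$params$kappa, mu_nd = object$params$mu_nd,
    sigma_nd = object$params$sigma_nd)
}

#' @export
logLik.npbddm <- function(object, ...) {
  structure(object$logLik, df = 3L, nobs = object$n, class = "logLik")
}

#' @export
summary.npbddm <- function(object, ...) {
  obs <- tapply(object$data$choice == "right", object$data$coherence, mean)
  pu <- object$predictive$p_upper
  ptot <- pu + object$predictive$p_lower
  pred <- setNames(pu / pmax(ptot, 1e-12), object$predictive$coh)
  tab <- data.frame(coherence = as.numeric(names(obs)),
                    n = as.integer(table(object$data$coherence)),
                    p_right_obs = as.numeric(obs),
                    p_right_pred = as.numeric(pred[names(obs)]))
  out <- list(params = object$params, logLik = object$logLik, n = object$n,
              choice_table = tab, convergence = object$convergence)
  class(out) <- "summary.npbddm"
  out
}

#' @export
print.summary.npbddm <- function(x, ...) {
  cat("Nonparametric-bound drift-diffusion model\n")
  print(x$params)
  cat(sprintf("  n = %d, log-likelihood = %.2f\n", x$n, x$logLik))
  cat("  choice probabilities (observed vs predicted):\n")
  print(format(x$choice_table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
predict.npbddm <- function(object, type = c("response", "joint"), ...) {
  type <- match.arg(type)
  jp <- object$predictive
  if (type == "joint") return(jp)
  ptot <- jp$p_upper + jp$p_lower
  mean_rt <- as.numeric(((jp$upper + jp$lower) %*% jp$t) * jp$dt) / pmax(ptot, 1e-12)
  data.frame(coherence = jp$coh,
             p_right = jp$p_upper / pmax(ptot, 1e-12),
             mean_rt_s = mean_rt)
}

#' @export
plot.npbddm <- function(x, ...) {
  plot(x$bounds, main = "Derived decision bounds", ...)
  invisible(x)
}

#' @export
residuals.npbddm <- function(object, ...) {
  jp <- object$predictive
  kidx <- match(object$data$coherence, jp$coh)
  res <- numeric(nrow(object$data))
  for (i in seq_along(res)) {
    f <- if (object$data$choice[i] == "right") jp$upper[kidx[i], ]
         else jp$lower[kidx[i], ]
    p <- sum(f) * jp$dt
    mu <- if (p > 1e-12) sum(f * jp$t) * jp$dt / p else NA_real_
    res[i] <- object$data$rt_s[i] - mu
  }
  res
}

#' @export
simulate.npbddm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cs <- object$priors
  idx <- sample.int(nrow(cs), nsim, replace = TRUE, prob = cs$weight)
  simulate_trials(object$params, object$bounds, cs$value[idx],
                  t_max = object$settings$t_max)
}
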