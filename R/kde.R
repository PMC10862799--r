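# Epanechnikov kernel density estimation of the decision-time distribution.

epanechnikov <- function(u) ifelse(abs(u) < 1, 0.75 * (1 - u^2), 0)

#' Decision-time density from reaction times
#'
#' Estimates the probability density of decision times by shifting each
#' reaction time by the mean non-decision time (Td = RT - mu_nd) and
#' smoothing with an Epanechnikov (inverted-parabola) kernel. The kernel is
#' parameterised by its standard deviation; its half-width is
#' `bandwidth_sd * sqrt(5)`. The support is truncated to t > 0 and the
#' density renormalised.
#'
#' @param rts Reaction times, seconds.
#' @param mu_nd Mean non-decision time, seconds (>= 0).
#' @param bandwidth_sd Kernel standard deviation, seconds (default 0.1 s).
#' @param dt Grid step of the returned density, seconds.
#' @param t_max Upper end of the grid, seconds.
#' @return An object of class `td_density`: grid `t` (from `dt` to `t_max`),
#'   `density`, `dt` and the number of trials used.
#' @export
decision_time_density <- function(rts, mu_nd, bandwidth_sd = 0.1, dt = 5e-4,
                                  t_max = 5) {
  if (length(rts) == 0) stop("no reaction times supplied")
  stopifnot(mu_nd >= 0, bandwidth_sd > 0, dt > 0)
  td <- rts - mu_nd
  h <- bandwidth_sd * sqrt(5)
  t <- seq_len(round(t_max / dt)) * dt
  f <- numeric(length(t))
  for (d in td) {
    j1 <- max(1L, as.integer(ceiling((d - h) / dt)))
    j2 <- min(length(t), as.integer(floor((d + h) / dt)))
    if (j1 > j2) next
    j <- j1:j2
    f[j] <- f[j] + epanechnikov((t[j] - d) / h) / h
  }
  f <- f / length(td)
  norm <- sum(f) * dt
  if (norm <= 0)
    stop("degenerate decision-time density: no mass at t > 0 ",
         "(is mu_nd larger than every reaction time?)")
  structure(list(t = t, density = f / norm, dt = dt, n_trials = length(td)),
            class = "td_density")
}

#' @export
print.td_density <- function(x, ...) {
  m <- sum(x$t * x$density) * x$dt
  cat(sprintf("Decision-time density: %d trials, grid dt = %.4g s, mean Td = %.3f s\n",
              x$n_trials, x$dt, m))
  invisible(x)
}
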