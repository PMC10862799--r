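# Descriptive and inferential analyses of trial tables: phase regressions,
# time-dependent accuracy, and cancellation-aligned reaction-time dynamics.

#' Linear regression of reaction time on motion strength and phase
#'
#' RT is regressed on indicator variables for each motion strength plus an
#' indicator for the second phase in the comparison; the phase coefficient
#' measures the RT difference between phases at fixed motion strength and is
#' tested against zero by t-test. Fit separately to correct and to error
#' trials; only completed standard trials enter.
#'
#' @param data Trial-record data frame holding exactly two phases.
#' @param outcome_filter "correct" or "error".
#' @return An object of class `ddm_regression` with the coefficient table,
#'   the phase coefficient `beta_phase` with standard error, t statistic and
#'   p-value, and the n used.
#' @export
rt_phase_regression <- function(data, outcome_filter = c("correct", "error")) {
  outcome_filter <- match.arg(outcome_filter)
  trials <- filter_standard_trials(data)
  trials <- trials[trials$outcome == outcome_filter, , drop = FALSE]
  phases <- sort(unique(trials$phase))
  if (length(phases) != 2)
    stop("need trials from exactly two phases (each with trials); got ",
         length(phases))
  strength <- factor(abs(trials$coherence))
  phase2 <- as.integer(trials$phase == phases[2])
  fit <- lm(trials$rt_s ~ 0 + strength + phase2)
  sm <- summary(fit)
  ct <- sm$coefficients
  i <- grep("^phase2$", rownames(ct))
  structure(list(model = "rt ~ motion-strength indicators + phase",
                 phases = phases, coefficients = ct,
                 beta_phase = ct[i, 1], se = ct[i, 2],
                 statistic = ct[i, 3], p_value = ct[i, 4],
                 full_rank = fit$rank == ncol(stats::model.matrix(fit)),
                 n = nrow(trials)),
            class = "ddm_regression")
}

# logistic log-likelihood with optional L2 ridge; used as a fallback under
# perfect separation
penalized_logistic <- function(X, y, lambda = 1e-3) {
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    sum(log1p(exp(-(2 * y - 1) * eta))) + lambda * sum(b^2) / 2
  }
  optim(rep(0, ncol(X)), nll, method = "BFGS")
}

#' Logistic regression of accuracy on motion strength and phase
#'
#' logit(p_correct) = slope * |coh| + beta_phase * I(phase 2), with a
#' separate slope per participant when `pooled = TRUE`. There is no
#' intercept, so accuracy at zero motion strength is anchored at chance. The
#' phase effect is evaluated by a likelihood-ratio test of the nested models
#' with and without the phase term.
#'
#' @param data Trial-record data frame holding exactly two phases.
#' @param pooled Use per-participant motion-strength slopes.
#' @return An object of class `ddm_regression` with `beta_phase`, the LR
#'   statistic (`statistic`, 1 df) and its p-value.
#' @export
accuracy_phase_logistic <- function(data, pooled = FALSE) {
  trials <- filter_standard_trials(data)
  phases <- sort(unique(trials$phase))
  if (length(phases) != 2)
    stop("need trials from exactly two phases (each with trials); got ",
         length(phases))
  correct <- as.integer(trials$outcome == "correct")
  strength <- abs(trials$coherence)
  phase2 <- as.integer(trials$phase == phases[2])
  if (pooled) {
    subj <- factor(trials$participant)
    f1 <- correct ~ 0 + strength:subj + phase2
    f0 <- correct ~ 0 + strength:subj
  } else {
    f1 <- correct ~ 0 + strength + phase2
    f0 <- correct ~ 0 + strength
  }
  separated <- FALSE
  fit1 <- withCallingHandlers(
    glm(f1, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  fit0 <- suppressWarnings(glm(f0, family = binomial()))
  if (separated) {
    X1 <- stats::model.matrix(fit1)
    X0 <- stats::model.matrix(fit0)
    p1 <- penalized_logistic(X1, correct)
    p0 <- penalized_logistic(X0, correct)
    ll1 <- -p1$value; ll0 <- -p0$value
    beta <- p1$par[ncol(X1)]
    ct <- cbind(Estimate = p1$par)
    rownames(ct) <- colnames(X1)
  } else {
    ll1 <- as.numeric(logLik(fit1)); ll0 <- as.numeric(logLik(fit0))
    beta <- coef(fit1)[["phase2"]]
    ct <- summary(fit1)$coefficients
  }
  lr <- max(0, 2 * (ll1 - ll0))
  structure(list(model = "logit(p_correct) ~ |coh| (+ per-participant) + phase",
                 phases = phases, coefficients = ct, beta_phase = beta,
                 statistic = lr, p_value = pchisq(lr, df = 1, lower.tail = FALSE),
                 separated = separated, n = nrow(trials)),
            class = "ddm_regression")
}

#' @export
print.ddm_regression <- function(x, ...) {
  cat(x$model, "\n")
  cat(sprintf("  phases compared: %s vs %s (n = %d)\n",
              x$phases[1], x$phases[2], x$n))
  cat(sprintf("  beta_phase = %.4f, statistic = %.3f, p = %.3g\n",
              x$beta_phase, x$statistic, x$p_value))
  if (isTRUE(x$separated)) cat("  note: perfect separation; penalized fit\n")
  invisible(x)
}

#' Time-dependent accuracy in sliding reaction-time windows
#'
#' For each motion strength, trials are sorted by reaction time and the mean
#' accuracy and mean RT are computed in sliding windows of `window_trials`
#' trials (stride one). Declining curves indicate a stopping criterion that
#' becomes more lax with time (collapsing bounds).
#'
#' @param data Trial-record data frame (completed trials are used).
#' @param window_trials Window size in trials.
#' @return A data frame with `strength`, window `mean_rt_s`, `accuracy`,
#'   standard error `se` and the window size used.
#' @export
time_dependent_accuracy <- function(data, window_trials = 100) {
  trials <- data[data$outcome %in% c("correct", "error"), , drop = FALSE]
  out <- list()
  for (s in sort(unique(abs(trials$coherence)))) {
    d <- trials[abs(trials$coherence) == s, , drop = FALSE]
    d <- d[order(d$rt_s), , drop = FALSE]
    n <- nrow(d)
    w <- window_trials
    if (n < w) {
      warning(sprintf("motion strength %g has %d < %d trials; single window",
                      s, n, w))
      w <- n
    }
    acc <- as.integer(d$outcome == "correct")
    ca <- cumsum(c(0, acc))
    cr <- cumsum(c(0, d$rt_s))
    i <- seq_len(n - w + 1)
    p <- (ca[i + w] - ca[i]) / w
    out[[length(out) + 1]] <- data.frame(
      strength = s, window = i, mean_rt_s = (cr[i + w] - cr[i]) / w,
      accuracy = p, se = sqrt(pmax(p * (1 - p), 0) / w), window_trials = w)
  }
  do.call(rbind, out)
}

#' Reaction-time dynamics around trial cancellations
#'
#' Reaction times are z-scored within each motion strength (over all trials
#' with an RT), then averaged at each lag relative to every cancelled trial,
#' from `-lags` to `+lags` trials away. Session boundaries truncate the
#' window; lags occupied by trials without an RT (cancelled or aborted) are
#' skipped.
#'
#' @param data Phase II trial-record data frame, all trial types included.
#' @param lags Number of trials on each side of a cancellation.
#' @return A data frame with `lag`, `mean_z`, `se` and `n` (contributing
#'   trials); empty (with a warning) if there are no cancellations.
#' @export
cancellation_aligned_rt <- function(data, lags = 5) {
  z <- rep(NA_real_, nrow(data))
  for (s in unique(abs(data$coherence))) {
    i <- which(abs(data$coherence) == s & !is.na(data$rt_s))
    if (length(i) >= 2) z[i] <- (data$rt_s[i] - mean(data$rt_s[i])) / sd(data$rt_s[i])
  }
  cancels <- which(data$outcome == "canceled")
  if (length(cancels) == 0) {
    warning("no cancelled trials in the data")
    return(data.frame(lag = integer(), mean_z = numeric(), se = numeric(),
                      n = integer()))
  }
  key <- paste(data$participant, data$session)
  out <- lapply(setdiff(seq(-lags, lags), 0), function(l) {
    idx <- cancels + l
    ok <- idx >= 1 & idx <= nrow(data)
    ok[ok] <- key[idx[ok]] == key[cancels[ok]] # stay within the session
    v <- z[idx[ok]]
    v <- v[!is.na(v)]
    data.frame(lag = l, mean_z = if (length(v)) mean(v) else NA_real_,
               se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  })
  do.call(rbind, out)
}
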