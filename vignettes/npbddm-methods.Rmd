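---
title: "Time-varying decision bounds from choice and reaction time: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying decision bounds from choice and reaction time: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npbddm)
```

## The decision model

`npbddm` analyses choice-reaction-time data from perceptual decisions — the
motivating case is direction discrimination of random-dot motion — in the
framework of bounded drift-diffusion. A decision variable $x(t)$ accumulates
noisy momentary evidence,

$$dx = \kappa \cdot coh \; dt + dW,$$

where $coh$ is the signed motion coherence (negative leftward, positive
rightward), $\kappa$ is a signal-to-noise scaling, and $W$ is a standard
Wiener process. The diffusion standard deviation is fixed at 1: it is not
identifiable jointly with $\kappa$ and the bound height, so evidence is in
arbitrary units. Deliberation ends when $x(t)$ first reaches symmetric,
possibly time-varying bounds $\pm B(t)$; the sign of the crossed bound gives
the choice, the crossing time is the decision time $T_d$, and the reaction
time adds a non-decision latency $T_{nd} \sim \mathcal{N}(\mu_{nd},
\sigma_{nd}^2)$ (truncated at zero when realised, so RT $\ge T_d$ always).

When trial difficulty is mixed and time is costly, the earning-rate-optimal
$B(t)$ declines with time ("collapsing bounds"): a decision still pending at
a late time is increasingly likely to be driven by a weak stimulus, so
waiting buys less accuracy per second. Two signatures of a collapsing bound
in data are time-dependent accuracy that falls with RT at fixed motion
strength, and slower errors than correct responses.

## The nonparametric bound derivation

The central method inverts the empirical decision-time distribution into the
bound time course without assuming a parametric bound family. The logic: for
a given $\kappa$, the distribution of decision times is uniquely determined
by $B(t)$, so the empirical distribution determines $B(t)$.

1. **Decision-time density.** Each trial's decision time is estimated as
   $T_d^{(i)} = RT^{(i)} - \mu_{nd}$ and the density $p_{T_d}(t)$ is a kernel
   estimate with an Epanechnikov (inverted-parabola) kernel of standard
   deviation 0.1 s. Because the kernel is parameterised by its s.d., its
   half-width is $0.1\sqrt{5} \approx 0.224$ s. The support is truncated to
   $t > 0$ and renormalised (`decision_time_density()`).
2. **Propagation.** The probability density of $x$ is advanced one time step
   per motion coherence by numerically solving the Fokker–Planck equation of
   drift-diffusion (`propagate_step()`).
3. **Match.** The symmetric bound $\pm B(t)$ is placed so that the
   probability mass absorbed beyond it during this step, aggregated over
   coherences with their prior weights, equals $p_{T_d}(t)\,dt$. Because the
   absorbed mass is monotone in the bound height, $B(t)$ is found by
   bracketing; with the piecewise-linear treatment of the straddled grid
   cell the match is exact to machine precision (`derive_bounds()`).

Steps 2–3 alternate in $dt = 0.5$ ms steps until $1 - 10^{-4}$ of the mass
has been absorbed or the 5 s viewing limit is reached. Early on, where the
(compactly supported) kernel estimate demands no exit mass, the bound rests
at the bracket ceiling, which equals the evidence-grid half-width `x_max`.
If the density ever demands more mass than remains unabsorbed, the bound is
clamped to zero from that step on and the curve is flagged; intent for this
corner is not fully determined by the construction, so the clamp is the
conservative choice.

Given derived bounds, `predict_joint()` yields the joint RT/choice
predictive per coherence: first-passage densities at the upper and lower
bound, convolved with the non-decision-time distribution. The fit
`npbddm()` maximises the resulting single-trial likelihood over
$\theta = (\kappa, \mu_{nd}, \sigma_{nd})$ with a Nelder–Mead simplex and
jittered restarts, **re-deriving the bounds inside every likelihood
evaluation** with the candidate $\mu_{nd}$ — the bound is data-determined,
never a free parameter. (The alternative reading, alternating bound
derivation and parameter updates, was rejected as weaker: re-derivation per
evaluation keeps the likelihood a pure function of $\theta$.) Per-trial
likelihoods are floored at $10^{-10}$ so an outlier RT cannot dominate the
objective, and $\sigma_{nd}$ is floored at 1 ms.

### Numerical scheme

The propagation uses a finite-volume discretisation with Chang–Cooper
weighting of the drift term and a fully implicit (backward Euler) step,
solved as one tridiagonal system per coherence per step. This combination
keeps the density non-negative even from the delta initial condition at
$x = 0$ and conserves probability to solver precision (the package's tests
assert conservation to $10^{-9}$ per step).

Two absorption modes are used, deliberately. A bound that *stands still*
over a step is imposed *inside* the implicit solve, as a Dirichlet
condition at the (generally between-node) bound position, with the stencil
of the last interior node shortened to the actual distance to the bound;
this monitors the barrier continuously, and the flat-bound validation
(choice probability $1/(1+e^{-2\mu B})$, mean decision time
$(B/\mu)\tanh(\mu B)$) agrees with the closed forms to better than
$10^{-3}$ — absorbing only once per step would instead shift the effective
bound outward by $\approx 0.583\sqrt{dt} \approx 0.013$ evidence units. A
bound that *moves* during a step follows the derivation's
propagate-then-absorb ordering: the density is advanced with the absorbing
boundary at the bracket ceiling and the mass beyond the newly placed bound
is then absorbed, with linear interpolation inside the straddled cell to
avoid staircase artifacts. Using the identical ordering in the forward
predictive makes `predict_joint()` under a derived bound path reproduce
the derivation's exit stream — and hence the fit's log-likelihood — to
machine precision, and it matches the Euler simulator, which also checks
the bound once per step.

Grid defaults: $dx = 0.01$ evidence units, half-width `x_max = 3` for
propagation (the dynamic-programming state grid uses the coarser
$\delta x = 0.02$, half-width 4). These were fixed by refinement checks:
halving $dx$ moves the flat-bound exit probability by under $10^{-4}$, and
doubling the policy grid resolution moves the optimal earning rate by under
1%.

### What the inversion can and cannot recover

With the *exact* decision-time density, the derivation recovers known flat
and collapsing bounds to within ~2% over the 5th–95th decision-time
percentiles. With a *kernel-estimated* density the recovery inherits the
kernel's smoothing bias: near the leading edge of the first-passage
distribution — which at $\kappa \approx 16$ rises over tens of milliseconds,
much faster than the 0.224 s kernel half-width — the matched bound first
dips and then overshoots, with deterministic errors of 10–20% in that
region regardless of sample size. Away from the leading edge (beyond about
two kernel half-widths) the recovery is again at the few-percent level, and
a linear collapse slope is recovered to within 10%. The same smoothing
shifts the model's predictive RT quantiles by up to ~30 ms relative to raw
sample quantiles on skewed RT distributions. Parameter recovery is robust to
this: on 2,000-trial synthetic sessions the maximum-likelihood fit recovers
$\kappa$ to within 10% and $\mu_{nd}$ to within 30 ms (median over seeds).

## The optimal stopping policy

`optimal_policy()` solves for the stopping policy that maximises the points
earning rate $\rho$ (points per second) by dynamic programming on states
$\langle x, t\rangle$ ($\delta t = 0.5$ ms, $\delta x = 0.02$). Actions are
*left*, *right* (terminate) or *fix* (accumulate another step):

- Terminating pays the expected points of the chosen side under the
  coherence posterior, minus $\rho(\mu_{ITI} + \mu_{misc} + \mu_{nd})$ for
  the latencies a completed trial incurs (defaults 2.0 s, 0.7 s and the
  fitted $\mu_{nd}$). Zero-coherence trials count as correct with
  probability $\tfrac12$, matching the random designation in the task.
- Fixating pays $\rho\,\delta t$ and, on deadline phases, risks cancellation
  with the hazard below, which pays the cancellation reward (0 points) minus
  $\rho(\mu_{ITI} + \mu_{misc}^{cancel} + \mu_{nd})$.

The coherence posterior is $p(coh \mid x, t) \propto \mathcal{N}(x \mid
\kappa\, coh\, t,\, t)\, p(coh)$ with equal priors over the twelve signed
stimulus slots (zero counted twice). This expression is exact whatever the
bound shape and whether or not deadlines are present, because survival of
the bounds and of the deadline multiply the likelihood of a trajectory by
coherence-independent factors that cancel in the normalisation — a property
the test suite checks by comparing surviving-trajectory coherence
frequencies from simulation against the formula.

Provisional deadlines are drawn from a time-shifted Rayleigh distribution
with density $p(t) = ((t - t_0)/\sigma_{dl}^2)\exp(-(t-t_0)^2 /
(2\sigma_{dl}^2))$. The deadline acts on the reaction time, so on the
decision-time axis of the policy the hazard is shifted by $\mu_{nd}$;
because only a fraction of trials (0.5 in Phase II) carries a deadline, the
raw Rayleigh hazard is weighted by the Bayes posterior probability that the
current trial has one given survival to $t$ (`cancel_hazard()`).

$\rho$ enters its own optimality condition, so it is located by bisection on
$V(x{=}0, t{=}0) = 0$ over the bracket $[-0.5, 0.5]$ points/s to a
tolerance of $10^{-6}$. The value function and policy are symmetric under
$x \to -x$ with left/right relabelled; the solver computes one half-grid and
mirrors it, which enforces the symmetry exactly. At the 5 s viewing limit
only the terminal actions are available (the task never lets deliberation
continue past it); the returned frontier therefore ends at zero at the
horizon. Forward-simulating sessions under the returned frontier reproduces
$\rho^*$ within Monte-Carlo error, and adding the Phase-II hazard lowers the
optimal bounds essentially pointwise (up to one $\delta x$ of frontier
quantisation) relative to the no-deadline solution.

## Bound scaling and the idiosyncrasy test

To ask whether a bound *shape* is preserved across task phases (and is
idiosyncratic to a participant), baseline bounds are transformed by
$B'(t) = s_m B(t/s_t)$ and $(s_t, s_m)$ fit by maximum likelihood with the
DDM parameters held fixed at the target phase's values (`fit_scaling()`;
simplex on $(\log s_t, \log s_m)$, initialised from a
$\{0.5, 0.75, 1, 1.25, 1.5\}^2$ factor grid). Beyond the base curve's
support $B(t/s_t)$ holds its last value — the transform must be defined
there and the flat extension adds no shape information. Fit quality is the
per-trial log-likelihood difference against the phase's own nonparametric
fit; scaling a dataset's own derived bounds recovers $(s_t, s_m) \approx
(1, 1)$ with a per-trial difference within $10^{-3}$.

Cross-fitting all participants' baseline bounds to each dataset gives a
rank matrix; under the null that ranks are random, each diagonal entry is
uniform on $\{1..4\}$, the $4^4 = 256$ patterns are equally likely, and
`permutation_rank_pvalue()` enumerates them exactly (observed diagonal
ranks $[1,2,1,1]$, sum 5, give $p = 5/256 \approx 0.020$). Ties in the
continuous likelihoods are a measure-zero event and are treated as an error
rather than broken arbitrarily.

## The task simulator

`simulate_phase()` generates the study conditions the analyses expect:
coherences drawn from $\pm\{0, 3.2, 6.4, 12.8, 25.6, 51.2\}\%$ with equal
slot weights (zero twice, its correct side drawn uniformly per trial);
Euler–Maruyama integration of the decision variable at 0.5 ms; Gaussian
non-decision times truncated at zero; a 5 s viewing limit (trials still
undecided there are recorded as aborted — rare under realistic bounds);
optional provisional deadlines on a configurable fraction of trials
(cancelled if RT exceeds the drawn deadline, worth 0 points); ±1 point
scoring; and independent Bernoulli aborts at a default 3% per trial,
emulating blinks and fixation breaks, whose generating process the task
does not otherwise constrain. The abort time cost defaults to
$\mu_{misc}^{cancel} + \mu_{ITI}$. `earning_rate()` computes points per
minute with per-outcome elapsed times, the quantity the scoring system
displays and the policy maximises.

What the generator does *not* emulate: sequential adjustments (the
simulator's parameters are stationary within a call, so post-cancellation
speed-ups must be injected explicitly, as the tests do), cross-trial drift
variability, asymmetric or biased bounds, and perceptual learning. Passing
tests therefore certify the estimators under stationary DDM assumptions,
not the full richness of behavioural data.

## Descriptive statistics

`rt_phase_regression()` regresses RT on motion-strength indicators plus a
phase indicator (t-test on the phase coefficient);
`accuracy_phase_logistic()` fits $\mathrm{logit}(p_{correct}) =
\beta_1|coh| + \beta_{Phase} I_{Phase}$ — interceptless, so chance accuracy
at zero strength is built in — with per-participant slopes in the pooled
variant, and evaluates $\beta_{Phase}$ by a likelihood-ratio test (penalised
logistic fallback under perfect separation). Under a null of identical
phases the LR test's type-I error calibrates to the nominal 5% in
simulation. `time_dependent_accuracy()` computes accuracy against RT in
100-trial sliding windows (stride one; the window size is the only
documented choice) per motion strength, and `cancellation_aligned_rt()`
z-scores RTs within motion strength and averages them at lags of up to five
trials around each cancellation, truncating at session boundaries. Lags
whose window crosses a second cancellation are included; with cancellation
rates of a few percent the overlap is rare and excluding such lags would
discard most of the far lags.

## Problem sizes used in the shipped checks

The package's tests run the flat-bound validation at the analysis step
$dt = 0.5$ ms; bound-recovery round trips on $10^4$-trial sessions;
parameter recovery on ten 2,000-trial sessions fit at a 2 ms likelihood
grid with a single simplex start (the coarser grid changes the recovered
parameters by far less than their sampling error and keeps a full recovery
study at desk scale); policy solutions at the native
$\delta t = 0.5$ ms, $\delta x = 0.02$ grid; and statistical calibration on
200 replicate null sessions of 600 trials per phase.
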