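---
title: "Models and methods behind foragedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind foragedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foragedyn)
```

## The scientific problem

A freely foraging animal makes two kinds of decisions at once: *when*
to act, and *what* to choose. `foragedyn` analyses timestamped choice
logs — one record per lever press, with the time in seconds and the
identity of the selected option — from long (order of two weeks),
continuous, multi-option foraging sessions under a 12 h/12 h light/dark
cycle. The package characterizes the timing stream and the choice
stream separately, and supplies a generative model for each:

* **Timing.** Foraging is bursty: most inter-choice intervals (ICIs)
  are a few seconds, but long pauses occur intermittently, and pause
  structure follows the circadian cycle. The *dual-state model*
  alternates an active (burst) state, whose intra-burst intervals are
  truncated power law, with an inactive state whose duration is the
  first arrival of a non-homogeneous Poisson process modulated by the
  hour-of-day activity profile.
* **Choice.** Which option is pressed is rank-biased (a log-linear
  decrease of choice percentage with the log of preference rank) and
  persistent (heavy-tailed runs of identical choices). The
  *dual-control model* combines a goal-directed learner over reward
  values with a habit system that leakily integrates choice history;
  both feed a softmax.

## Descriptive temporal statistics

For an interval series $\tau_1,\dots,\tau_n$ the burstiness index is

$$B = \frac{\sigma - m}{\sigma + m},$$

with $m$ the mean and $\sigma$ the *population* standard deviation.
$B = 1$ is maximally bursty, $B = 0$ Poisson-like, $B = -1$ perfectly
periodic. We use the population normalization because $B$ is a plug-in
functional of the empirical distribution; at the series lengths
involved (thousands of intervals) the distinction from the sample
standard deviation is negligible, but the periodic identity $B = -1$
holds exactly only with the population form.

The memory coefficient $M$ is the lag-1 Pearson correlation of
consecutive intervals, computed over the $n-1$ pairs
$(\tau_i, \tau_{i+1})$ with the means and population standard
deviations of the first and last $n-1$ intervals respectively. A zero
variance in either margin is reported as an error, never silently as 0.

Choice entropy is Shannon entropy (bits) over non-overlapping windows
of 100 trials by default; for four options it is bounded by 2 bits.
Comparison against uniformly shuffled sequences (frequency-preserving)
quantifies how much of the structure depends on choice history.

Periodicity is measured on the autocorrelogram of hourly event counts
(mean-subtracted, normalized to 1 at lag 0). Peaks are local maxima
above a white-noise eligibility threshold
($z_{0.975}/\sqrt{n_\text{bins}}$ by default) separated by at least
12 h, selected greedily by height; lag 0, trivially the global maximum,
participates in the separation constraint, which removes the short-lag
correlation shoulder that bursts produce. The period is the mean
spacing of successive peaks. The default maximum lag of 78 h keeps the
third daily harmonic interior to the scanned range, where it can
qualify as a local maximum. With fewer than two qualifying peaks the
period is reported as undefined, with a warning — a homogeneous Poisson
record lands here by design.

An ICI is assigned to the light or dark cycle by the cycle of its
*starting* event, and cycle windows are half-open (an event exactly at
light onset is "light"), so labels partition events with no double
counting. Sessions are treated as one continuous stream over all days,
matching continuous housing in the recording chamber. `B` and `M` are
computed per log over the whole record.

## Heavy-tail machinery

The ICI distribution is bimodal: a power-law head (intra-burst) and a
Weibull tail (inter-burst), crossing at a timescale $\tau_0$.

**Crossover detection.** $\tau_0$ is the local minimum of the interval
density inside a search window of 50–1000 s. The density is estimated
per unit $\log_{10}\tau$ on logarithmically spaced bins (25 per
decade), smoothed with a 3-bin moving average. Working per log-abscissa
(that is, with $\tau f(\tau)$ rather than $f(\tau)$) matters: the
inter-burst Weibull component often has shape below 1, so the raw pdf
has no interior minimum, while the log-density shows the valley-and-
bump shape seen on logarithmic axes. A candidate minimum must be
flanked on both sides by density at least 1.2 times larger
(configurable prominence); unimodal samples such as exponentials are
thereby rejected with a "no crossover" error rather than yielding a
spurious $\tau_0$.

**Power-law fitting.** For a fixed lower bound $\tau_\min$ and no
truncation the maximum-likelihood exponent is the closed form
$\hat\mu = 1 + n / \sum_i \ln(x_i/\tau_\min)$; with an upper truncation
at $\tau_0$ the truncated likelihood is maximized numerically (the two
agree to $10^{-6}$ as the truncation recedes, which is tested). When
$\tau_\min$ is scanned, the bound minimizing the Kolmogorov–Smirnov
distance between fitted and empirical tail CDFs is chosen, ties broken
toward the smaller bound (keeping more data). Goodness of fit uses the
semiparametric bootstrap: simulate from the fitted model at matched
$n$, refit, and report the fraction of bootstrap KS distances at least
as large as the observed one.

**Weibull fitting.** Scale and shape are MLE via `fitdistrplus`. For
the bimodal tail the sample is left-truncated at $\tau_0$ by
construction, so the conditional likelihood given exceedance of
$\tau_0$ is maximized instead; ignoring the truncation biases the shape
upward, which is visible even when only ~15% of the tail mass is cut.
The composite survival mixes the truncated-power-law head (weight
$w_\text{head}$, the fraction of intervals below $\tau_0$) with the
conditional Weibull tail, and is continuous and non-increasing by
construction.

Per-cycle fits reuse the $\tau_0$ detected once on the overall
distribution (configurable), since the crossover is a property of the
burst/gap decomposition rather than of the cycle.

## The dual-state timing model

Parameters: $\tau_\min$, $\tau_0$, $\mu \in (1,3)$ for the intra-burst
truncated power law; $\xi \in (0,1]$, the per-choice probability of
leaving the active state (burst lengths are geometric with mean
$1/\xi$); $\rho_0$, the mean inactive rate; a 24-vector $P_A(h)$ of
bout-start probabilities per clock hour; and shape exponents
$b_\text{light}$, $b_\text{dark}$ applied to $P_A$ in the corresponding
cycle. The period is fixed at 24 h.

The inactivity rate is
$\rho(t) = \rho_0\, P_A(h(t))^{b(h(t))} / Z$ where $Z$ is the 24-hour
time average of $P_A^b$. The normalization is our choice where only
proportionality is dictated: it preserves the interpretation of
$\rho_0$ as the reciprocal mean inactive duration, so the estimator
$\hat\rho_0 = 1/\overline{\text{gap}}$ and the simulator speak the same
units. Gaps are $\tau_0$ plus the first arrival of this process
(sampled by thinning against the peak rate, evaluated at true clock
time), which guarantees every gap is at least $\tau_0$ and keeps
segmentation at $\tau_0$ an exact inverse of simulation. The first
event of a bout is the arrival itself. Simulations start in the
inactive state at the light onset hour by default.

Estimation from data: segment at $\tau_0$ (intervals below $\tau_0$
share a bout), then $\hat\xi = n_\text{bouts}/n_\text{events}$ (the
geometric MLE), $\hat\rho_0$ as above, and $\hat P_A$ as the normalized
histogram of bout-start clock hours. The free parameters
$(\tau_\min, \tau_0, \mu, b_\text{light}, b_\text{dark})$ are estimated
by *least-area*: each candidate is scored by the area between the
empirical ICI survival and the mean survival of simulated replicates,
integrated in log–log coordinates on a common grid (trapezoid rule,
restricted to where both curves are positive). The search is a user-
supplied grid (10 replicates per candidate by default); no gradient
structure is assumed because the objective is a Monte-Carlo surface.

## The dual-control choice model

On trial $t$ with options $i = 1,\dots,K$:

* Goal-directed values update as $Q_c \mathrel{+}= \alpha_c (R_c - Q_c)$
  for the chosen option and $Q_u \mathrel{+}= \alpha_u (0 - Q_u)$ for
  each unchosen option. The unchosen decay makes the prediction error
  larger when a neglected option is finally re-chosen, a documented
  driver of continued exploration.
* Habit values are the leaky integrator
  $H(t+1) = e^{-1/\kappa}(H(t) + c(t))$ with $H(1) = 0$, equivalent to
  the kernel sum $H_i(t) = \sum_{s\ge 1} e^{-s/\kappa} c_i(t-s)$
  (verified against a direct-summation oracle at $10^{-12}$). The
  integrator is left unnormalized; $\beta_H$ absorbs the scale. Note
  the saturation value is $\approx \kappa$, so the product
  $\beta_H \kappa$ bounds the habit drive.
* Choice probability is softmax over
  $\beta_G Q + \beta_H H$, computed with max-subtraction.
* Reward values come from the generalized matching law:
  $R_i \propto \text{rate}_i^{1/a}$, normalized to $\max R = 1$, with
  the whole-session mean choice rates held fixed during fitting and the
  sensitivity $a$ fitted jointly. The $\max R = 1$ normalization
  mitigates, but does not remove, the trade-off between $a$ and
  $\beta_G$; accordingly the package's recovery guarantees cover
  $\beta_G$, $\beta_H$ and $\kappa$, while $a$ should be interpreted
  with caution.

Initial values are $Q_i(1) = H_i(1) = 0$ (neutral start; the first
trial is uniform). Variants switch systems off — `goal_cu` (no habit),
`goal_c` (additionally no unchosen decay), `habit` (no goal system),
`goal_c_habit` (both systems, no unchosen decay) — with free-parameter
counts 6, 4, 3, 2 and 5. Fitting is bounded L-BFGS-B on the negative
log-likelihood with multi-start (20 uniform restarts by default, seeded);
$\kappa$ and $a$ are searched in $\log_{10}$ space because they are
scale parameters. When several variants are fit, use
`fit_variant_suite()`: it fits the hierarchy bottom-up and warm-starts
every fuller model from its nested submodels' optima, which guarantees
in practice that a fuller model never reports a worse likelihood than a
model nested inside it — random restarts alone do not, and the
resulting likelihood inversions silently corrupt BIC comparisons.
Model comparison reports
$\text{BIC} = -2\,\text{LL} + k \ln N$, the pseudo-$r^2$
$(R - L)/R$ against the random-choice baseline $R = N \ln(1/4)$, and
likelihood-ratio tests for declared nestings only (a non-nested request
is refused, not silently computed). The forward-pass likelihood is
implemented in C++ and checked against an independent R re-
implementation at $10^{-10}$.

Two identifiability limits at two-week scale ($N \approx 5000$ trials)
deserve emphasis, because the test suite measures both. First, $a$ and
$\beta_G$ trade off along a shallow likelihood valley, so while
$\beta_H$ and $\kappa$ recover with median relative error well under
20%, $\beta_G$'s median error sits near 20–28%. Second, the habit
integrator and the unchosen-decay mechanism are *near-observationally
equivalent* as sources of persistence: with honestly optimized nested
fits, dropping the habit costs only a few log-likelihood units beyond
what goal-directed decay can absorb, and vice versa — each typically
less than the BIC penalty of its parameters. Consequently the full
dual-control variant does not reliably win BIC selection on data
simulated from itself at this scale; distinguishing the two
persistence mechanisms decisively requires either longer records or
behavioral regimes (e.g. near-deterministic lock-in) that real animals
do not show. The softmax drive ceiling is the root cause: pushing both
systems' contributions up degenerates choice into a single option
before both become individually decisive.

## The synthetic-data generator

`synthetic_config()` composes the two models over one event stream:
timestamps from the dual-state simulator, options assigned
trial-by-trial by the dual-control simulator (the models are
independent modules; no timing–choice coupling is introduced). Defaults
are the study conditions the analysis targets:

* 14 days, four flavored-pellet options, 12 h/12 h cycle with light
  onset at 08:00, session starting at light onset;
* timing: $\tau_\min = 10$ s, $\tau_0 = 500$ s, $\mu = 2$,
  $\xi = 0.053$, $\rho_0 = 2.4\times10^{-4}\,\mathrm{s^{-1}}$ — the
  magnitudes typical of such recordings;
* hourly profile: 85% of bout-start mass uniform over the 12 dark
  hours, 15% over light, reflecting predominantly nocturnal foraging
  with sporadic light-cycle activity;
* choice: long-run rates $(0.50, 0.25, 0.15, 0.10)$, with
  $\alpha_c = 0.27$, $\alpha_u = 0.05$, $\kappa = 3$, $a = 1.3$,
  $\beta_G = 1$, $\beta_H = 1$. These were chosen once so that the
  generated behavior reproduces the headline phenomena — rank-biased
  choice (top option near 60%, log-linear rank slope near $-80$
  percentage points per decade, in the range such experiments show),
  stable mid-range entropy, decreasing run hazard, heavy-tailed runs —
  while keeping the total softmax drive moderate. The combination
  $\beta_H \kappa \gtrsim 5$ together with a strong goal drive locks
  choice into a single option (a degenerate, zero-entropy regime), so
  realistic parameters necessarily live in the moderate-drive region.

What the generator does *not* emulate: satiety/nutrition dynamics,
response latencies or vigor, inter-individual variability, and any
coupling between what is chosen and when. Tests passing on synthetic
data therefore validate the estimators' internal consistency and power
under the stated model, not the model's adequacy for any particular
empirical dataset.

## Numerical choices and degenerate inputs

* Timestamps must be strictly increasing; simultaneous presses are
  rejected at parse time with the offending line number.
* `detect_tau0` requires the sample to span the search window and
  refuses monotone densities (no interior prominent minimum).
* Power-law fits require at least 10 tail points; the KS scan skips
  candidates that leave fewer.
* The Monte-Carlo shuffle test uses the +1-corrected p-value
  ($p \ge 1/(n_\text{shuffles}+1)$); resolving $p < 0.001$ therefore
  needs at least 1999 shuffles. The test statistic is the sup-
  difference between the empirical run survival and the shuffled-
  ensemble mean, with each shuffle scored against the leave-one-out
  ensemble mean; an area alternative reusing the log–log integral is
  available.
* Rank ties are broken by order of first appearance (essentially
  impossible in real data, deterministic in tests).
* Hazard is reported only where survival is positive.

## Problem sizes used by the test-suite experiments

Stochastic-limit checks use $10^5$ intervals; distribution recovery
uses $10^4$ draws; dual-state least-area recovery uses one 14-day
simulation against a 4 × 5 candidate grid with 5 replicates per
candidate; dual-control recovery and model selection use $N = 5000$
trials over 10 seeded replicates, with 4–6 optimizer restarts. These
sizes were chosen as the smallest at which the estimators' sampling
error is comfortably inside the asserted tolerances.

## Known limitations

* The `a`–$\beta_G$ identifiability caveat above; joint confidence
  regions are not computed.
* Period estimation is peak-based, not spectral; with weak circadian
  modulation the peak picker can miss a daily peak. Records shorter
  than three periods are flagged.
* The least-area search is a grid, not an optimizer; refine by nesting
  grids if needed.
* Reward values derive from the same choice rates the model is fit to
  (the matching-law inversion is deliberately deductive, as specified);
  the pseudo-$r^2$ baseline is the uniform random-choice model.
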