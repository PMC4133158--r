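# foragedyn

Temporal and sequential dynamics of free foraging decisions.

`foragedyn` is an R package for analysing timestamped choice logs from
long, continuous, multi-option foraging experiments — the kind of
recording produced when an animal lives in an operant chamber for about
two weeks, on a 12 h/12 h light/dark cycle, and freely presses one of
four levers for differently flavored food pellets. It is written for
behavioral neuroscientists and ethologists who want to go beyond mean
rates: the package quantifies *when* choices happen (bursts, heavy
tails, circadian structure) and *what* is chosen (preference bias,
persistence), and fits a generative model to each axis.

## The models

**Timing — dual-state model.** Activity alternates between an *active*
state, a burst of choices whose inter-choice intervals (ICIs) follow a
truncated power law `p(τ) ∝ τ^(−µ)` on `[τ_min, τ_0]`, and an
*inactive* state. After each choice the burst ends with probability ξ,
so burst lengths are geometric with mean 1/ξ. The inactive gap is
`τ_0` plus the first arrival of a non-homogeneous Poisson process whose
rate follows the hour-of-day profile `P_A(h)` raised to a
cycle-specific shape exponent (`b_light`, `b_dark`), normalized so that
the mean gap is `1/ρ_0`. This reproduces the empirical signature of
such logs: a bimodal ICI distribution (power-law head, Weibull-like
tail) and a 24-hour autocorrelogram period. The composite ICI
distribution is fit piecewise: the crossover `τ_0` is the local minimum
of the log-binned ICI density in 50–1000 s; the head by truncated
power-law MLE with a Kolmogorov–Smirnov scan for `τ_min`; the tail by
left-truncated Weibull MLE. Free parameters are estimated by least-area
between empirical and simulated log–log survival curves.

**Choice — dual-control model.** Two valuation systems run in
parallel. A goal-directed learner updates the chosen option's value by
the reward prediction error, `Q_c ← Q_c + α_c (R_c − Q_c)`, and decays
unchosen values, `Q_u ← (1 − α_u) Q_u`; reward values derive from mean
choice rates through the generalized matching law `R_i ∝ rate_i^(1/a)`.
A habit system leakily integrates choice history,
`H(t+1) = e^(−1/κ) (H(t) + c(t))`. Choice is softmax over
`β_G Q + β_H H`. Nested variants (goal-only, habit-only, no unchosen
decay) are fit by multi-start maximum likelihood and compared by BIC,
pseudo-r² against a random-choice baseline, and likelihood-ratio tests.

A synthetic-data generator composes both models over one event stream
with known ground truth, so the entire pipeline is testable without any
external data.

## Worked example

```r
library(foragedyn)

cfg <- synthetic_config(days = 14, seed = 42)   # 14-day, 4-option session
log <- generate_dataset(cfg)
log
#> <event_log> 4208 events, 4 options, 14.00 days
#>   options: chocolate, banana, coffee, cinnamon

icis <- interchoice_intervals(log)
burstiness(icis)          # 0.72  -> strongly bursty timing (B in [-1, 1])
memory_coefficient(icis)  # ~0    -> consecutive intervals nearly uncorrelated

autocorrelogram_period(log)
#> <autocorrelogram> bin 1 h, 3 peaks, period 23.50 h   # circadian rhythm

fit_bimodal(icis)
#> <bimodal_fit> [overall] tau0 = 695 s | head: mu = 2.04 (tau_min = 15)
#>   | tail: lambda = 2058, gamma = 0.61 | w_head = 0.93

assign_ranks(log)         # consumption-ranked options: 68/16/9/7 %
fit_rank_loglinear(assign_ranks(log))$slope
#> -102.7                  # percent choice lost per decade of rank

shuffle_run_test(log, n_shuffles = 1999, seed = 1)
#> <shuffle_test> scope overall: observed sup-statistic = 0.1016,
#>   p = 5e-04 (1999 shuffles)   # runs far heavier than chance
```

The numbers mean: the log is bursty (`B = 0.72` on a scale where 0 is
Poisson and 1 maximally bursty) but without interval-to-interval memory
(`M ≈ 0`); activity repeats on a daily period; intervals split at
`τ_0 ≈ 700 s` into a power-law burst regime (`µ ≈ 2`) and a
stretched-exponential gap regime (`γ < 1`); choice is strongly
rank-biased (most presses go to this individual's top option, falling
log-linearly with log rank) and persistent (the run-length distribution
is heavier-tailed than any frequency-matched shuffle, Monte-Carlo
`p = 5e-4`).

Model fitting is a one-liner per component:

```r
fit <- fit_choice_model(log, variant = "dual", restarts = 20, seed = 1)
cmp <- compare_models(lapply(c("dual", "goal_cu", "habit"),
                             fit_choice_model, options = log, seed = 1))
```

`run_full_analysis(list(synthetic = cfg, seed = 1), out_dir = "out")`
runs every stage and writes a JSON summary plus TSV tables.

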