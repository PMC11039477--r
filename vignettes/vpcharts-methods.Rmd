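---
title: "Adaptive memory-type profile monitoring: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive memory-type profile monitoring: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpcharts)
```

## The monitored model

Each monitoring epoch $k$ observes a *profile sample*: $n$ units with
responses $Y_k$ ($n \times p$) generated by the multivariate multiple
linear regression

$$Y_k = X B + E_k,$$

where $X$ is a fixed $n\times(q+1)$ design (first column ones), $B$ the
$(q+1)\times p$ coefficient matrix and the rows of $E_k$ i.i.d.
$N_p(0,\Sigma)$.  Phase-II monitoring is assumed: $B$ and $\Sigma$ are
known from an in-control Phase-I analysis.  Out-of-control states are an
additive coefficient shift $B \to B + \Delta$ and/or an elementwise
variance inflation $\Sigma \to \tau\Sigma$.

Per sample the charts consume two sufficient summaries:

* the least-squares estimate $\hat B_k = (X^TX)^{-1}X^TY_k$, vectorized
  response-major into $\hat\beta_k$ with in-control covariance
  $\Sigma_{\hat\beta} = \Sigma \otimes (X^TX)^{-1}$;
* the pooled standardized residual statistic
  $W_k = f_k = \sum_i e_{ik}\Sigma^{-1}e_{ik}^T \sim \chi^2_{np}$ and the
  mean residual vector $\bar e_k$, with residuals against the in-control
  $B$.

All of $\Sigma_{\hat\beta}$, the $\chi^2$ degrees of freedom $np$, and the
mean-residual covariance $\Sigma/n$ depend on the current sample size, so
every update takes the active $n$ explicitly — necessary because the
adaptive scheme alternates between two sample sizes.

## The four charts

Quadratic forms are mapped to the standard normal scale by the
probability-integral transform
$\Phi^{-1}[H_{df}(x)]$ (`normal_chisq_transform()`), with the cumulative
probability clamped to $[\varepsilon, 1-\varepsilon]$,
$\varepsilon = 10^{-12}$, so the result is always finite; the clamp only
matters in the first updates of a fresh state, where an EWMA quadratic
form can be essentially zero.

With smoothing parameter $\lambda$ (default 0.2) and fresh states at zero:

**Max-MEWMA.**
$z_k = \lambda(\hat\beta_k-\beta) + (1-\lambda)z_{k-1}$;
$C_k = \Phi^{-1}[H_{(q+1)p}\{\tfrac{2-\lambda}{\lambda}
z_k^T\Sigma_{\hat\beta}^{-1}z_k\}]$;
$g_k = (1-\lambda)g_{k-1} + \lambda\,\Phi^{-1}[H_{np}\{W_k\}]$;
$S_k = \sqrt{(2-\lambda)/\lambda}\,g_k$;
plot $ME_k = \max\{|C_k|,|S_k|\}$.

**Max-MCUSUM.**
$U_k = \max\{0, U_{k-1} + a(\hat\beta_k-\beta_g)^T - 0.5D\}$ with $a$ the
$\Sigma_{\hat\beta}^{-1}$-metric unit direction from the in-control
$\beta_g$ to a reference out-of-control $\beta_b$ and $D$ its length;
$L_k = \max\{0, L_{k-1} +
(\hat\beta_k-\beta_g)\Sigma_{\hat\beta}^{-1}(\hat\beta_k-\beta_g)^T - v\}$,
$v = \log(\tau)\,\tau/(\tau-1)$ (natural log; $v \approx 1.0484$ at the
default design $\tau = 1.1$); plot $MC_k = \max\{U_k, L_k\}$.

**SS-EWMAe.**
$z_k = \lambda\bar e_k + (1-\lambda)z_{k-1}$;
$T_k = \Phi^{-1}[H_{p}\{z_k^T[\tfrac{\lambda}{2-\lambda}\Sigma/n]^{-1}
z_k\}]$; $P_k = \lambda T_k + (1-\lambda)P_{k-1}$;
$F_k = \Phi^{-1}[H_{np}\{f_k\}]$;
$V_k = \lambda F_k + (1-\lambda)V_{k-1}$; plot $EWe_k = P_k^2 + V_k^2$.

**SS-CUSUMe.**  Two-sided CUSUMs of $T_k$ (reference $k_1 = 1$) and $F_k$
(reference $k_2 = 1.5$):
$M_k = \max\{D^-_k, D^+_k\}$, $N_k = \max\{B^-_k, B^+_k\}$, plot
$CUe_k = M_k^2 + N_k^2$.  The residual EWMA feeding $T_k$ is maintained
inside the chart state.

Two standardization choices deserve note.  First, the mean statistic of
the SS charts standardizes the $p$-vector $z_k$ by its *asymptotic*
in-control covariance $\tfrac{\lambda}{2-\lambda}\Sigma/n$ — the natural
$p$-dimensional analogue of the $\tfrac{2-\lambda}{\lambda}$ factor in
$C_k$.  Second, all EWMA statistics use the asymptotic variance factor
rather than the exact finite-$k$ factor $1-(1-\lambda)^{2k}$.  The
consequence is a transient: for small $k$ the quadratic forms are
stochastically smaller than their reference $\chi^2$, so $C_k$ and $T_k$
are biased toward large negative values and $|C_k|$ is inflated for the
first few updates.  Calibrated limits absorb this early-run behaviour; an
exact-variance variant was evaluated and rejected because it shifts the
whole out-of-control ATS profile away from the established operating
characteristics of these charts.

The Max-MCUSUM variability track deserves a warning: as defined, $L_k$
accumulates a $\chi^2_{p(q+1)}$ quadratic form minus the allowance
$v \approx 1.05$, so it drifts upward even in control ($E[\text{increment}]
= p(q+1) - v$).  Calibration still achieves any target in-control ARL
(the statistic is monotone in its limit), but the resulting run-length
distribution is concentrated rather than geometric-like, and the chart's
out-of-control behaviour is dominated by that drift.  The recursion is
implemented exactly as defined; treat Max-MCUSUM results accordingly.
$\beta_b$ is a required design input with a documented default (in-control
coefficients plus one unit on every intercept).

## The variable-parameters scheme

Two settings — relaxed $(n_1, t_1, UCL_1, UWL_1)$ after safe-zone samples,
tightened $(n_2, t_2, UCL_2, UWL_2)$ after warning-zone samples — are tied
to targets by

$$E(n) = n_1P_0 + n_2(1-P_0),\quad E(t) = t_1P_0 + t_2(1-P_0),\quad
E(\alpha) = \alpha_1P_0 + \alpha_2(1-P_0),$$

solved by `solve_vp_design()` for $P_0$, $t_1$, $\alpha_2$ given the six
free parameters.  Zone boundaries are inclusive exactly as defined: safe
$[0, UWL]$, warning $(UWL, UCL]$, signal $(UCL,\infty)$.

Because the statistics have memory, values accumulated under one region's
sampling setting must not be mixed into the other region's updates — doing
so inflates the false-alarm rate.  The scheme therefore carries two
independent chart states (`dual_track_state()`); only the active region's
track is updated, and the inactive track is *frozen*, resuming from its
last value when its region is re-entered (resetting it instead was
evaluated and gives slightly worse, and harder to reason about,
behaviour).  A fresh monitoring session starts relaxed: region 1, both
tracks at zero.

## Calibration

`calibrate_ucl()` targets the in-control zero-state ARL $1/\alpha$:

1. an initial limit is the $\lceil R(1-\alpha)\rceil$-th order statistic of
   $R$ simulated first-update statistics from fresh states (cheap and
   well-defined for memory charts, though their marginal distribution
   drifts with $k$);
2. a monotone bracketing/bisection search adjusts the limit until the
   simulated ARL is within a relative tolerance (default 0.02, 0.005 in
   the shipped scripts) of target.  Every evaluation reuses one seed
   (common random numbers), so the empirical ARL curve seen by the search
   is effectively monotone; the achieved ARL is re-verified with an
   independent seed.  Run lengths are truncated at $50/\alpha$ and counted
   at the cap (bias negligible; truncations are reported).

`calibrate_uwl()` sets the warning limit in the variable-sampling-interval
view: with $n$ fixed, interval switching does not alter the statistic
stream, so the chart is run in control as an FP chart at its UCL and the
UWL is the $P_0$ order-statistic quantile of the pooled non-signal
statistics.  The in-control safe-zone fraction then equals $P_0$ by
construction, and the implied VSI time to signal
($\approx E(t)/\alpha$) and ARL are re-verified and reported — matching
$P_0$ first and verifying ARL/ATS avoids the over-determination of
adjusting three quantities with one free limit.  For a VP design the four
limits are calibrated pairwise: $(\alpha_1, n_1)$ gives $UCL_1, UWL_1$;
$(\alpha_2, n_2)$ gives $UCL_2, UWL_2$.  For the reference two-response
scenario this yields $UCL \approx 3.01/2.89$ and $UWL \approx 1.02/1.02$,
in line with limits reported for these charts in the stroke-care
monitoring literature.

## Performance measures and simulation semantics

`run_length_fp()`/`run_length_vp()` estimate zero-state performance: the
shift is present from the first monitored sample and all memory starts at
zero.  RL counts samples to the first exceedance of the active UCL; TS
accumulates the sampling intervals, the interval chosen after sample
$k-1$ elapsing before sample $k$.  For FP, $ATS = t\cdot ARL$ exactly; for
VP the two differ because intervals vary.  Replications are vectorized in
blocks; a fixed seed reproduces results bit for bit.

Two semantic choices define the out-of-control model:

* **A coefficient shift moves the process level.**  The mean channels
  ($\hat\beta_k$ deviations, $\bar e_k$) see $\Delta$ additively, while
  the dispersion statistics $W_k, f_k$ remain central $\tau\chi^2_{np}$ —
  they measure spread about the current process level.  (Monitoring *real*
  data, where only the in-control $B$ is known, makes $W_k$ noncentral
  under a sustained coefficient shift; that only adds detection power, so
  the run-length profiles reported here are the conservative reference
  case, and they are the ones a practitioner will find in the literature
  for these charts.)
* **VP runs start at the scheme's stationary region occupancy.**  The
  initial region of each replication is drawn with the in-control
  safe-zone probability $P_0$ (`start_region = "random"`), representing a
  scheme already in operation when the shift arrives.  A deterministic
  region-1 start (`"region1"`, also what `monitor_stream()` uses for a
  fresh session) front-loads one long interval $t_1$ into every run and
  inflates small-ATS entries by roughly $(1-P_0)(t_1-t_2)$.

One structural fact worth knowing: in control, safe-zone visits both
prolong survival and stretch time, so the in-control VP time to signal
satisfies $ATS \approx E(t)/E(\alpha)$ while the in-control VP ARL is
noticeably *below* $1/E(\alpha)$ — run length and time to signal are not
interchangeable for adaptive schemes even when $E(t) = 1$.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `lam` | 0.2 | — | EWMA weight on the newest sample; smaller = longer memory |
| `k1`, `k2` | 1, 1.5 | SD of $T$/$F$ | SS-CUSUMe allowances |
| `tau_design` | 1.1 | — | variance multiplier in the Max-MCUSUM allowance $v$ |
| `beta_b` | $\beta_g$ + 1 per intercept | response units | Max-MCUSUM direction |
| `clamp_eps` | $10^{-12}$ | probability | transform clamp |
| `reps` | 10000 | — | Monte-Carlo replications per calibration evaluation |
| `tol` | 0.02 | relative | ARL convergence tolerance |
| `rl_cap` | $50/\alpha$ | samples | run-length truncation |

## The synthetic data generator

`generate_phase2_stream()` emulates Phase-II sample streams from any
profile specification: fixed-design scenarios replicate the stored $X$;
the stroke scenario draws covariates per sample (age
$\sim N(72, 10^2)$ truncated to $[18, 100]$, sex $\sim$ Bernoulli(0.5),
severity $\sim$ Gamma(shape 2, scale 4) truncated to $[0, 42]$ — chosen as
plausible for a thrombolysis-treated stroke population, and affecting only
synthetic demonstrations, never the chart mathematics) and generates
log10-scale responses with back-transformed convenience columns.  What the
generator does **not** emulate about real registry data: missingness and
erroneous entries, autocorrelation and seasonality in case mix,
hospital-level heterogeneity, and Phase-I estimation error (parameters are
treated as known).  Passing tests on synthetic streams therefore validate
the monitoring mechanics, not robustness to those real-data features.

## Numerical choices and degenerate inputs

Multivariate normal draws use the upper Cholesky factor of $\Sigma$ scaled
by $\sqrt\tau$; design matrices are validated for full column rank and an
all-ones first column; $\Sigma$ must be symmetric positive definite.
Quantile clamping guarantees finite statistics for all inputs.  A VP
design degenerated to $n_1 = n_2$, $t_1 = t_2$, $UWL \to UCL$ reproduces
the FP chart run for run on shared seeds (a test asserts this).  Ties at
the limits follow the inclusive interval rules (a statistic exactly at the
UCL is a warning, not a signal).

## Problem sizes used by the shipped tests and scripts

The test suite calibrates at 2000–8000 replications and evaluates shifts
at 5000 (choices that keep each Monte-Carlo comparison's standard error
well below the differences being tested); `scripts/acceptance.R` uses
10000-replication evaluations with 8000–10000-replication calibrations.
Distributional checks (Kolmogorov–Smirnov at the 1% level) use 4000–10000
draws.

## Known limitations

* Max-MCUSUM's variability track drifts by construction (above); its
  out-of-control profile is not comparable to the EWMA-type charts.
* The six-response fixture ships without design matrices (not published
  for its source case) and with a synthetic equicorrelation covariance;
  supply your own $X$ matrices to use it.
* Steady-state run lengths, economic design, self-starting/estimated-
  parameter variants, and nonlinear or nonparametric profiles are out of
  scope.
* Analytic (Markov-chain) ARL evaluation is not provided; everything is
  Monte Carlo.
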