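---
title: "Modeling binding-site-coupled degradation of nuclear NICD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling binding-site-coupled degradation of nuclear NICD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicddrain)
```

## The model

Nuclear Notch signaling is carried by the Notch intracellular domain
(NICD), which enters the nucleus at a production rate $P_{NICD}$ and, as
part of the NICD/CSL/Mastermind complex, binds Su(H) paired sites (SPS) on
enhancers. DNA-bound NICD can be phosphorylated by the Cdk8 kinase module
at rate $k_p$; phosphorylated NICD, once it unbinds, is degraded at a fast
rate $\Gamma_p$, while unphosphorylated NICD degrades at a much slower
rate $\Gamma_{up}$. Binding sites therefore act as catalytic *drains*:
every occupied site converts slow-degrading NICD into fast-degrading NICD
at rate $k_p$, lowering the nuclear pool without any transcriptional
output being required.

`nicddrain` implements this model with two coupled pools, total
unphosphorylated $N_{up}$ and total phosphorylated $N_p$ NICD
(molecules/nucleus), and $N = N_e + N_s$ binding sites ($N_e$ effective
endogenous SPS-equivalents, $N_s$ synthetic sites). Because binding and
unbinding are much faster than production, phosphorylation and
degradation, site occupancy is slaved to an equilibrium
partition function: a site is empty, bound by unphosphorylated, or bound
by phosphorylated NICD with weights $1$, $\alpha_{up} = N_{up}/k_\alpha$,
$\alpha_p = N_p/k_\alpha$, where $k_\alpha = k_\alpha^-/k_\alpha^+$ is the
dissociation constant. With $Z = 1 + \alpha_{up} + \alpha_p$, the bound
amounts are $N\,\alpha_{up}/Z$ and $N\,\alpha_p/Z$
(`site_occupancy()`). Only *unbound* molecules degrade.

In units of the baseline abundance $NICD_0 = P_{NICD}/\Gamma_{up}$ and the
dimensionless rates $k_p' = k_p/\Gamma_{up}$,
$\Gamma_p' = \Gamma_p/\Gamma_{up}$, the steady state solves

$$0 = NICD_0 - N_{up} - N\frac{N_{up}}{k_\alpha + N_{up} + N_p}(k_p' - 1),
\qquad
0 = N\frac{N_{up}}{k_\alpha + N_{up} + N_p}k_p'
  - \left(N_p - N\frac{N_p}{k_\alpha + N_{up} + N_p}\right)\Gamma_p'.$$

`steady_state()` solves these with a damped Newton iteration (analytic
Jacobian, three starting points, roots accepted at residual
$< 10^{-10} NICD_0$ with non-negative pools); `integrate_dynamics()`
integrates the corresponding dynamic equations with a stiff-capable
solver (`deSolve::ode`, `lsoda`, rtol $10^{-8}$, atol
$10^{-10} NICD_0$). The dynamic equations are dimensionless in time
(units of $1/\Gamma_{up}$); the package works in physical minutes by
scaling the right-hand sides by $\Gamma_{up}$, and a dimensionless mode
is exposed for cross-checks.

**Model assumptions.** (1) Binding dynamics are much faster than NICD
turnover; (2) molecules far outnumber sites, so the statistical weights
use total rather than unbound abundances; (3) sites bind independently;
(4) no dephosphorylation. The stochastic simulator (below) quantifies
what (1) and (2) cost.

## Parameters, units, conventions

All abundances are molecules per nucleus, all times minutes, all rates
min$^{-1}$. **Half-life convention:** half-life $= 1/\Gamma$ (the
relaxation time), not $\ln 2/\Gamma$; $\Gamma_{up} = 1/120$ pairs with "a
120-minute half-life". The central parameter set
(`default_reporter_params()`, presets `titration_*`,
`reporter_inference`, `dynamics_default`):

| parameter | default | meaning |
|---|---|---|
| $NICD_0$ | 2000 | baseline abundance (plausible range $10^2$–$10^4$) |
| $\Gamma_{up}$ | 1/120 | slow degradation (half-lives 0.5–16 h explored) |
| $\Gamma_p$ | 1/8 | fast degradation of phosphorylated NICD |
| $k_p$ | from slope | back-calculated from the measured titration slope |
| $k_\alpha$ | 1 | dissociation constant (strong binding; see below) |
| $N_e$ | 5.4 | effective endogenous SPS-equivalents |
| $N_s$ | 0, 6, 12, 18 | synthetic sites per genotype |

**Choice of $k_\alpha$.** No measured value exists for the NCM–SPS
dissociation constant in vivo, so it is a documented choice. The model is
built for the strong-binding regime $NICD \gg k_\alpha$, where steady
states are insensitive to $k_\alpha$ (the suite verifies < 1% change over
a 100-fold range), and we default to $k_\alpha = 1$ molecule/nucleus
everywhere. We specifically did *not* adopt a large $k_\alpha$ for the
signal-duration analysis: the short-duration protection discussed below
does not require slow occupancy build-up — it arises because the
*phosphorylated pool* (and hence the fast-degradation flux) takes minutes
to build even when sites fill instantly — while a $k_\alpha$ comparable
to $NICD_0$ would push the model out of the strong-binding regime it
assumes and visibly weaken the steady-state drain (at
$k_\alpha = 1000$ the predicted steady-state reduction from 12 added
sites falls below 20%, and almost vanishes for the low-abundance
parameter variant $NICD_0 = 200$).

## The linear regime and what it buys

For low site numbers and $k_p \gg \Gamma_{up}$ the titration curve is
linear (`linear_regime()`):

$$NICD_{tot}(N_s) \simeq NICD_0 - (N_e + N_s)\,k_p'\left(1 - \frac{1}{\Gamma_p'}\right),$$

so the per-site slope is proportional to $k_p$. Two consequences drive
the inference machinery:

* the slope *ratio* between two genotypes equals their
  phosphorylation-rate ratio — a Cdk8-module heterozygote with half the
  phosphorylation activity gives exactly 2;
* the normalized slope can be inverted for $k_p$
  (`estimate_kp_from_slope()`):
  $k_p = NICD_0\,\Gamma_{up} / \left[(N_e - 1/s)(1 - \Gamma_{up}/\Gamma_p)\right]$,
  which round-trips exactly with `linear_regime()` and yields
  $k_p \approx 0.45$ min$^{-1}$ at the central parameters — a modest,
  physiological kinase rate. `kp_grid()` tabulates this inversion over
  the plausible $NICD_0$ and $\Gamma_{up}$ ranges.

The package flags the linear regime as valid while the predicted total
drop stays below 30% of $NICD_0$ (a configurable threshold; the
approximation is derived for $k_p' \gg 1$ and verified to 5% there).
Outside it, added sites saturate: the per-site decrement shrinks
monotonically. The sign of $k_p'(1 - 1/\Gamma_p') - 1$ decides whether
sites deplete NICD at all: below 1, sequestration (bound NICD is shielded
from degradation) wins and total NICD *rises* with added sites — both
branches are exercised in the tests.

## Signal duration

`duration_sensitivity()` compares, on trajectories started from an empty
nucleus, the fractional NICD reduction caused by adding 12 synthetic
sites against that caused by halving production, at a short (10 min) and
a long time (default $24/\Gamma_{up}$, i.e. 24 relaxation times, so the
long read-out is at steady state for every parameter variant). Halving
production scales the whole trajectory from $t = 0$; the site drain only
bites once occupancy *and* the phosphorylated pool have built up, and in
the very first minutes bound-but-unphosphorylated NICD is even
transiently protected. Hence short-duration processes are much less
sensitive to added sites than to production dose, while long-duration
processes are strongly sensitive to both. `robustness_sweep()` repeats
this over single-parameter variants ($NICD_0 \in \{200, 20000\}$,
$\Gamma_{up} \in \{1/30, 1/1000\}$, $\Gamma_p \in \{1/4, 1/30\}$,
presets `dynamics_*`), re-deriving $k_p$ from the fixed measured slope
under each variant's rates; the asymmetry holds across all of them.

## The stochastic oracle

`simulate_ssa()` is an exact event-driven (direct-method) simulation of
the *full* reaction network — production, degradation of unbound pools,
explicit binding/unbinding to discrete sites at rates
$k_\alpha^+, k_\alpha^-$, and on-DNA phosphorylation — implemented in
compiled code with R's seeded RNG stream. It validates the deterministic
reduction rather than re-deriving it: site conservation is asserted at
every event, and the time-averaged total (burn-in $10/\Gamma_{up}$,
batch-means standard error) is compared with `steady_state()`.

The reduction is exact only in the limit of fast binding: phosphorylation
deposits bound-phosphorylated NICD on the DNA directly, so the bound pool
is out of binding equilibrium by a correction of order $k_p/k_\alpha^-$,
and the weights-use-totals approximation adds a correction of order
$N/NICD_0$. `with_binding_rates()` therefore defaults to
$k_\alpha^- = 600$ min$^{-1}$ (0.1 s site residence — fast TF–DNA
binding, with $k_\alpha^+$ set to keep $k_\alpha$ fixed), which puts both
corrections below the stochastic error of the runs used in the tests; the
suite also demonstrates the convergence directly by showing a slow-unbinding
run ($k_\alpha^- = 10$) sits measurably further from the mean-field value
than a fast-unbinding one at the same $k_\alpha$.

## Reporter inference

`analyze_reporter()` mirrors the experimental analysis of per-disc
reporter fluorescence (a proxy assumed proportional to steady-state
NICD): normalize everything by the reference-genotype zero-site mean
(`normalize_reporter()`, one shared constant, so ratios and crossings are
unaffected), fit ordinary least squares through the per-condition *means*
(`fit_reporter_line()`; reference restricted to $N_s \in \{0, 6, 12\}$ by
default, its fourth point being saturated; mutant uses all four; an
SEM-weighted option exists but is off by default), then:

* `slope_ratio()` — reference/mutant orientation, first-order
  delta-method standard error assuming independent fits,
  $ci_{95} = \hat r \pm 1.96\,se$;
* `estimate_ne()` — the fitted lines cross where synthetic sites cancel
  the genotype difference, at $N_s = -N_e$; the crossing abscissa is
  extrapolated and negated, with a delta-method error over all four fit
  parameters using each fit's internal covariance;
* `infer_kp()` — the reference slope pushed through the $k_p$ inversion.

**Statistical caveats, stated plainly.** The covariance of each line fit
comes from the residual variance of a 3–4 point means regression (1–2
degrees of freedom), and the intervals use $z = 1.96$ with no small-sample
t correction. Such intervals are anti-conservative: in simulation their
coverage of the true two-fold ratio is roughly 85% rather than 95%, and
the estimated standard errors themselves fluctuate by factors of 2–3
between datasets. Both `se` and `ci95` are reported so users can apply
their own correction; with only 3–4 conditions per genotype there is no
clean frequentist fix that does not change the prescribed estimator. The
delta-method propagation itself is verified in the tests against
Monte-Carlo propagation through fits with known covariances.

## Half-life fitting

Luminescence decay of tagged NICD does not follow a single exponential;
`fit_hill_decay()` fits the decreasing Hill form
$(t_{0.5}^n + bg\,t^n)/(t_{0.5}^n + t^n)$ — equal to 1 at $t = 0$,
$(1+bg)/2$ at the half-life $t_{0.5}$, and $bg$ at long times — by
pooled nonlinear least squares over replicates
(`minpack.lm`, bounds $t_{0.5} > 0$, $n \in (0, 10]$, $bg \in [0, 1)$;
initialization $bg_0 = \min$, $t_{0.5,0}$ = time nearest $(1+bg_0)/2$,
$n_0 = 2$). Confidence intervals default to a seeded bootstrap over
replicate wells (residual resampling when only one well; 1000 resamples),
with asymptotic-covariance intervals as the alternative.

## Synthetic data

`gen_reporter_dataset()` emulates the reporter experiment's design: two
genotypes (mutant = reference with $k_p/2$, the expected effect of
removing one copy of a limiting Cdk8-module gene), $N_s \in
\{0, 6, 12, 18\}$, 8 discs per condition. Per-disc values are the
steady-state total times a lognormal multiplicative noise with unit mean;
the 15% coefficient of variation is an invented default (no per-disc
variance is tabulated anywhere to calibrate against) chosen as a
realistic imaging-replicate spread, and lognormal noise keeps
fluorescence positive. The generating truth is attached for recovery
tests. `gen_decay_curves()` adds Gaussian noise (sd 0.05) to a Hill curve
on 17 timepoints over 0–480 min in 3 replicates and renormalizes each
replicate to its first reading, mirroring per-well normalization.

What the generator does *not* emulate: disc-to-disc gain differences,
spatial structure within the margin, saturation of the GFP readout (a
saturating-readout option is deliberately out of the default path), or
outliers — so passing recovery tests demonstrate the estimators work
under the model's own assumptions, not robustness to real imaging
artifacts.

## Problem sizes

The shipped test-suite and reproduction script use: steady-state grids of
up to $3^3$ parameter combinations for the dynamics/algebra cross-check
(tolerance $10^{-6}$ relative); 200 seeded datasets for
reporter-recovery and half-life-bias studies; stochastic runs of
$10^4$–$10^5$ simulated minutes ($\sim 10^7$–$10^8$ events); and
1000-resample bootstraps. These sizes were chosen so each study resolves
the quantity it checks (e.g. stochastic standard errors of ~0.1% of the
mean) while the whole suite stays desk-scale.

## Known limitations

* $N_e$ is an *effective* number: many weak endogenous sites are
  collapsed onto the scale of one strong synthetic site.
* No cis-inhibition, no spatial effects, no transcription output model,
  no dephosphorylation; production is a constant.
* The reporter readout is assumed linear in NICD.
* Small-sample intervals are anti-conservative (see above).
* The thermodynamic reduction carries $O(k_p/k_\alpha^-)$ and
  $O(N/NICD_0)$ corrections, quantified by the stochastic oracle.
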