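# nicddrain

Quantitative modeling of **binding-site-coupled degradation of the Notch
intracellular domain (NICD)**.

Enhancers carrying Su(H) paired sites (SPS) can act as catalytic drains
on nuclear Notch signal: NICD bound to such a site (as part of the
NICD/CSL/Mastermind complex) is phosphorylated by the Cdk8 kinase module
at rate $k_p$ and thereby routed to fast degradation ($\Gamma_p$) instead
of the slow basal pathway ($\Gamma_{up}$), independently of
transcription. Adding sites therefore lowers nuclear NICD; at a low site
number the drop is linear with slope $\propto k_p$, and a genotype with
half the Cdk8-module activity shows half the slope. This package is for
systems biologists who want to fit, test, and extend that model against
reporter-titration and protein-decay data.

With total unphosphorylated/phosphorylated pools $N_{up}, N_p$
(molecules/nucleus), $N = N_e + N_s$ sites, dissociation constant
$k_\alpha$, and dimensionless rates $k_p' = k_p/\Gamma_{up}$,
$\Gamma_p' = \Gamma_p/\Gamma_{up}$, the steady state solves

$$0 = NICD_0 - N_{up} - N\,\tfrac{N_{up}}{k_\alpha + N_{up} + N_p}(k_p'-1),
\qquad
0 = N\,\tfrac{N_{up}}{k_\alpha + N_{up} + N_p}k_p'
  - \big(N_p - N\,\tfrac{N_p}{k_\alpha + N_{up} + N_p}\big)\Gamma_p',$$

with site occupancy given by a one-site partition function
$Z = 1 + N_{up}/k_\alpha + N_p/k_\alpha$ (binding is fast, independent
across sites, and strong: $NICD \gg k_\alpha$).

The package provides, in matching module layers:

* **core model** — `site_occupancy()`, `steady_state()` (damped Newton),
  `integrate_dynamics()` (stiff ODE), `titration_curve()`,
  `linear_regime()`, `estimate_kp_from_slope()`, `kp_grid()`,
  `duration_sensitivity()`, `robustness_sweep()`;
* **stochastic oracle** — `simulate_ssa()`, an exact event-driven
  simulation of the full discrete reaction network (compiled core) used
  to validate the mean-field reduction;
* **inference** — `normalize_reporter()`, `fit_reporter_line()`,
  `slope_ratio()`, `estimate_ne()`, `infer_kp()`, `analyze_reporter()`
  for per-disc reporter titration data, with delta-method errors;
* **decay fitting** — `hill_decay()`, `fit_hill_decay()`: half-lives
  from the decreasing Hill form
  $(t_{0.5}^n + bg\,t^n)/(t_{0.5}^n + t^n)$ with bootstrap CIs;
* **synthetic data** — `gen_reporter_dataset()`, `gen_decay_curves()`:
  seeded generators with attached ground truth;
* **pipeline/CLI** — `run_steady()`, `run_dynamics()`, `run_kp_grid()`,
  `run_fit_reporter()`, `run_fit_decay()`, `run_synth()` plus a thin
  `inst/cli/nicddrain` Rscript front end; parameter presets under
  `inst/extdata/presets/` (`nicd_presets()`).

Units are molecules/nucleus and minutes throughout; half-life $=
1/\Gamma$ (so $\Gamma_{up} = 1/120$ min$^{-1}$ means a 120-min
half-life).

## Worked example

```r
library(nicddrain)

# central parameters; k_p back-calculated from the measured normalized
# titration slope of -0.0294 per site
p <- default_reporter_params()
titration_curve(p, c(0, 6, 12, 18))
#>   n_sites   nicd_up   nicd_p  nicd_tot nicd_tot_norm
#> 1       0 1715.1981 19.40293 1734.6011     1.0000000
#> 2       6 1408.9890 40.45699 1449.4460     0.8356077
#> 3      12 1119.8571 60.66910 1180.5262     0.6805751
#> 4      18  858.2899 79.52230  937.8122     0.5406501
```

Each block of 6 synthetic sites knocks ~16% off nuclear NICD, with the
per-site decrement shrinking as the curve saturates.

```r
# a synthetic reporter experiment (mutant = half phosphorylation rate),
# pushed through the full inference chain
ds <- gen_reporter_dataset(reporter_sim_spec(seed = 101))
analyze_reporter(ds)
#> Line fit [reference]: slope -0.0329823 +/- 0.00097 per site, intercept 1.00336 (n = 3)
#> Line fit [mutant]: slope -0.0134186 +/- 0.0029 per site, intercept 1.01974 (n = 4)
#> Slope ratio (reference/mutant): 2.458 +/- 0.537 (95% CI 1.406 - 3.51)
#> Effective endogenous sites N_e = 0.8374 +/- 1.82
#> Implied phosphorylation rate k_p = 0.5731 /min
```

The slope ratio estimates the phosphorylation-rate ratio (truth 2 here;
the interval covers it), the line crossing estimates the effective number
of endogenous SPS-equivalent sites, and the reference slope is inverted
for $k_p$. With only 3–4 conditions per genotype these estimates are
noisy — single datasets scatter widely around the truth (see the
vignette's statistical caveats).

```r
# why tissues needing long signals are hit hardest by extra sites
duration_sensitivity(p)
#>   time reduction_by_sites reduction_by_halved_production
#> 1   10         0.06099049                      0.5164330
#> 2 2880         0.31942495                      0.5740523
```

At 10 min, 12 added sites have cut NICD by only 6% while halved
production has already cut it by 52%; at steady state both perturbations
are strong (32% vs 57%).

```r
# half-life from a noisy luminescence decay
fit_hill_decay(gen_decay_curves(decay_sim_spec(seed = 101)), seed = 101)
#> Hill decay fit: t05 = 128 min (95% CI 118.6 - 142.2, bootstrap)
#> [truth: t05 = 120 min]
```

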