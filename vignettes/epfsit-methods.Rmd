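---
title: "Methods: models, estimators and design choices in epfsit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in epfsit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epfsit)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the defaults and why they
were chosen, what the synthetic-data generators do and do not emulate, and
the numerical decisions that make the fits deterministic and reproducible.

## 1. Time–mortality bioassays and LT50

Cumulative mortality of fungus-exposed flies is modelled as a binomial GLM
of the proportion dead by day $t$ on $t$ itself:

$$\mathrm{link}\,P(\text{dead by } t) = b_0 + b_1 t, \qquad
  \mathrm{LT}_{50} = -b_0/b_1 .$$

The default link is the **logit on untransformed day**. Probit and
log-day variants are offered (`link`, `log_time`), but logit-on-time is
the standard median-lethal-time practice consistent with inverting the
fitted curve via the familiar `dose.p`-style delta method, and the
package's synthetic mortality process is itself logistic in time, so the
default makes estimator and generator coherent. Replicates are **pooled
into the binomial denominators** by default because screening studies
report a single LT50 ± SE per strain; per-replicate fits are available
(`per_replicate = TRUE`).

Two variances are reported:

* `se_naive` — the delta-method SE from the ordinary binomial GLM
  covariance. This is what `MASS::dose.p` reports, and the tests verify
  the two agree to 1e-10.
* `se` (default) — the same delta formula with a **fly-level
  cluster-robust covariance**. Cumulative counts on successive days are
  repeated observations of the same flies, so binomial independence
  understates the variance of the curve's location; empirically the naive
  2-SE interval covers the generating LT50 only ~76% of the time under the
  package's own generator. Deaths are absorbing, so each replicate's
  per-fly death days can be reconstructed exactly from its cumulative
  counts; refitting on the per-fly Bernoulli expansion and clustering on
  the fly (`sandwich::vcovCL`) restores ~96% coverage. When counts are
  non-integer (after Abbott correction) the expansion is impossible and
  `se` falls back to `se_naive`.

Abbott's correction
$100\,(T - C)/(100 - C)$, floored at 0, is applied to the treated
percentages **only when a control series is supplied**; raw mortality is
the default input to the LT50 fit since whether published LT50s use
corrected or raw mortality is generally unstated.

The SIT-compatibility triage classifies a finite LT50 against a
configurable window, default $[10, 20]$ days: faster-killing strains
would kill sterile males before they mate, slower ones barely suppress.
Both boundaries count as compatible.

## 2. Thermal performance curves

Radial growth series (four quadrant radii per plate per day) are reduced
to one absolute growth rate per plate: the OLS slope of the mean radius on
day, in mm/day. Rates are then fitted against temperature at the **plate
level** (4 rates × 6 temperatures = 24 observations per strain) rather
than as per-temperature means — the replication structure is real
information and the choice makes $n$ explicit in the AIC.

Three rate models are available (`eval_tpc`):

* linear $\mu = a + bT$;
* **Lactin-1 in its printed polynomial form**
  $\mu = a (T-T_{min})^2 (T_{max}-T)$ with parameters $(a, T_{min},
  T_{max})$. This is deliberately the equation as printed in the source
  analysis, which its parameter table matches; the classical exponential
  Lactin-1 is provided as a clearly named alternative
  (`"lactin1_classic"`) but is never silently substituted;
* **CTMI** (cardinal temperature model with inflection) with parameters
  $(\mu_{opt}, T_{min}, T_{opt}, T_{max})$, equal to $\mu_{opt}$ at
  $T_{opt}$ and 0 at both cardinal extremes.

Outside $[T_{min}, T_{max}]$ the nonlinear models return 0, and rates are
floored at 0; fitting residuals use this clamped form, so the fitted curve
is the curve the user evaluates. The CTMI denominator is linear in $T$
and has a root inside the thermal range when
$T_{opt} < (T_{min}+T_{max})/2$; evaluation on that root raises a
descriptive degeneracy error, and the property tests draw parameters from
the admissible half-space.

`fit_tpc` minimises (optionally weighted) RSS with Levenberg–Marquardt
steps from a **fixed deterministic multi-start grid**: $T_{min}$ starts at
$\min(T)-\{15,5,0\}$, $T_{max}$ at $\max(T)+\{0,5,15\}$, $T_{opt}$ over
the observed temperatures, and the rate scale at the maximum observed
rate. Starts are ranked by initial RSS and the best `n_local = 6` are
refined; the best final RSS wins. There is no randomness, so refits are
bit-identical. Cardinal ordering $T_{min} < T_{opt} < T_{max}$ is kept by
a smooth penalty that repels the optimiser from inadmissible regions
instead of a hard reparameterisation — simpler, and adequate because every
start is admissible. Weights default to 1; `"inverse_variance"`
per-temperature weights are available since "weighted least squares" in
source analyses rarely states its weights.

Model comparison uses the Gaussian-RSS AIC
$n\ln(\mathrm{RSS}/n) + 2(k+1)$ — the error variance counts as a
parameter — because it is reproducible without a likelihood that rate
tables never state, together with $R^2_{pseudo} = 1-\mathrm{RSS/TSS}$ and
its degrees-of-freedom adjustment. `select_model` ranks by AIC, breaks
ties within 2 AIC units by adjusted $R^2$, and flags exact residual ties
for the **Vuong non-nested test**: per-observation Gaussian log-likelihood
differences $m_i$ (each model's $\sigma^2 = \mathrm{RSS}/n$),
$z = \sum m_i / (\sqrt{n}\,\mathrm{sd}(m_i))$, two-sided normal $p$;
$\mathrm{sd}(m_i) < 10^{-12}$ is reported as indistinguishable with
$z = 0$ rather than a division by almost-zero.

## 3. Survival and transmission

Kaplan–Meier estimation and the Mantel-Cox log-rank test delegate to the
`survival` package (product-limit with Greenwood variance; pooled
hypergeometric treatment of ties, so all events at a tied time share one
risk set), surfaced through small, typed result objects. End-of-study
censoring is `event = 0` at day 15. The donor-vs-receiver comparison uses
the pooled-variance Student t by default — the df reported in such
studies (e.g. $4+4-2 = 6$) implies pooling — with Welch as an option.

Hemocytometer counts convert to concentrations with the standard improved-
Neubauer constant ($10^4$ per large square per mL), exposed as
`volume_factor` since counting formulas are usually unprinted. Retention
decay is the OLS slope of $\ln(\text{load})$ on day, so loads decaying as
$L_0 r^{day}$ return exactly $\ln r$; **zero loads are excluded** from the
log fit (with the excluded count reported) rather than pseudo-counted,
keeping the slope interpretable.

## 4. Shared statistical machinery

ANOVA, Tukey HSD (via `ptukey`'s numerically integrated studentized
range) and binomial/Poisson GLMs (IRLS, tolerance $10^{-8}$, ≤ 100
iterations) are thin, validated wrappers over the standard R routines.
Compact letter displays use the insert-and-absorb algorithm with letters
assigned in input-group order for determinism; the defining invariant —
two groups share a letter iff their comparison is non-significant — is
brute-force verified in the tests over exhaustive significance patterns.
Where source analyses describe their GLM families contradictorily, the
pipeline defaults to binomial-logit for proportions and Poisson-log for
counts, and documents it here.

## 5. The synthetic-data generators

The generators emulate the study designs exactly: 30 flies × 3 replicates
observed daily for 15 days; 100 conidia × 4 coverslips × 4 plates;
{15, 20, 25, 30, 35, 40} °C × 4 plates × 14 days from a 4 mm plug in a
45 mm-radius dish; 3 flies/day/replicate at days 1, 3, 5.

* Fungus-induced mortality is a **logistic cumulative incidence in time**
  (midpoint `lt50_true`, steepness `slope_true`) — matching the LT50
  parameterisation of the analysis stage — combined competing-risk style
  with a geometric background hazard (earliest death wins). Control-group
  mortality defaults to 0.5%/day, a typical colony loss rate; no published
  control level exists to copy. When the midpoint falls on an observation
  day, that day's cumulative probability is exactly 0.5, so a very steep
  curve splits deaths across the midpoint day and the next — recovery
  experiments use a between-day midpoint where a hard step is wanted.
* Radii are truncated, not resampled, at the plug and plate-edge bounds;
  noisy series are therefore not forced monotone, as with a flexible
  ruler.
* Conidia loads use multiplicative log-normal noise (positive,
  right-skewed).
* All generators save and restore the RNG state, so they are bit-
  reproducible by seed and leave the caller's stream untouched.

What the generators do **not** emulate: mycosis confirmation, irradiation-
dose effects, mating dynamics, humidity/UV covariates, between-replicate
overdispersion beyond binomial/geometric sampling, and any fly-level
frailty. Passing recovery tests therefore show the estimators are correct
under the stated designs, not that real assays are free of those
complications.

## 6. Problem sizes and tolerances in the test-suite experiments

The recovery and calibration experiments use: 200 seeds for CTMI cardinal-
temperature recovery (noise at 5% of $\mu_{opt}$; 1.5 °C criterion) and
for AIC selection consistency; 100 seeds for LT50 2-SE coverage (n = 90
flies, background hazard 0 so the fitted model is correctly specified);
2000 seeds for log-rank type-I calibration (two groups of 30, geometric
hazard 0.1/day — the scale of the survival assays — chosen a priori).
These sizes give Monte-Carlo error comfortably below the margins being
checked while keeping the full suite around half a minute. Hand-derived
oracles (closed-form OLS, grid-search ML, product-limit, hypergeometric
log-rank, direct Vuong summation) are kept in the test helpers,
independent of the implementation paths they check.

## 7. Known limitations

* LT50s from pooled cumulative counts remain slightly biased under a
  nonzero background hazard unless a control series is supplied for
  Abbott correction.
* The printed-polynomial Lactin-1 is not the classical exponential
  Lactin-1; cross-study comparisons of its $a$ parameter are not
  meaningful.
* Published cardinal-estimate tables for this strain panel are internally
  inconsistent (adjusted $R^2$ entries above 1; table-vs-narrative
  disagreement on CTMI cardinal values); only the $\mu(T_{opt}) =
  \mu_{opt}$ identity and the narrative $T_{opt}$ values are stable
  anchors, and `published_cardinal_estimates()` exposes each source
  verbatim so the caller chooses.
* `cardinal_summary` reports the literal min/max over strains and leaves
  any exclusion of implausible fitted values (e.g. negative $T_{min}$) to
  the caller.
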