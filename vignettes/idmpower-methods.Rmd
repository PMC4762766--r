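---
title: "Simulation-based power for illness-death cohort studies: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based power for illness-death cohort studies: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idmpower)
```

## The problem

Closed-form sample-size formulas for survival outcomes — Schoenfeld's
proportional-hazards formula being the standard — assume that event times
are observed exactly, covariates are measured without error, and all
relevant heterogeneity is in the model.  Long-running population cohorts
that recruit across a wide age span and revisit participants every few
years violate all three assumptions: participants enter at different ages
(delayed entry), disease onset is only detected at scheduled visits,
exposures are misclassified, death competes with disease onset, and
unmeasured etiological determinants disperse individual risk.  Each of
these erodes power, so the closed forms are systematically optimistic.

`idmpower` quantifies that erosion by brute force: it simulates the whole
cohort under an irreversible illness-death model, analyses each simulated
dataset exactly as a practitioner would, and reports the rejection
proportion.  The minimum detectable hazard ratio (MDHR) — the smallest
true hazard ratio detectable with 80% power at a given significance level
and cohort size — is found by bisection on top of the power engine.

## The illness-death model

Three states: healthy (1), diseased (2), dead (3), with no recovery from
disease.  Interest lies in the 1→2 transition; the 1→3 transition is a
competing risk.  Time is measured in years since age 45, the conventional
onset of the aging process, so a participant recruited at age `45 + l`
contributes a left-truncated observation: both latent transition times
are drawn conditional on exceeding `l`.

Cause-specific hazards are Weibull with shape above 1 (risk rising with
age).  For a Weibull with scale $\lambda$ and shape $\rho$, left
truncation at $l$ leaves the hazard unchanged — conditioning on survival
to $l$ affects only the normalization — and event times are simulated by
the conditional-survival inversion
$$t = \lambda\left[(l/\lambda)^\rho - \log(1-u)\right]^{1/\rho}, \qquad
u \sim \mathrm{U}(0,1),$$
which inverts the truncated distribution function exactly
(`qltweibull()`).  State-occupancy probabilities follow from the standard
transition-probability identities; the ever-diseased probability is an
adaptive-quadrature integral of $p_{11}(t_1,t)\,q_{12}(t)$
(`occupancy_probs()`, absolute tolerance $10^{-8}$, configurable).

## The generator

Per subject $i$ the simulator draws, in this fixed order: entry offset
$l_i$, environmental and genetic exposures $x_{iE}, x_{iG}$ (independent
Bernoulli), frailty $f_i \sim N(0, \sigma^2)$, the onset time, the death
time, and an exponential loss-to-follow-up time.  The fixed order means
that two scenarios differing only in effect sizes consume identical
random numbers under a common seed, which is what makes common random
numbers work across the MDHR bisection.

The onset hazard of subject $i$ is the baseline Weibull hazard times
$$m_i = \exp(\beta_E x_{iE} + \beta_G x_{iG} +
\beta_{G\times E} x_{iE} x_{iG} + f_i),$$
with the $\beta$s interpreted as log hazard ratios (proportional-hazards
semantics).  Under a Weibull baseline a hazard multiplier $m$ is again
Weibull with scale $\lambda m^{-1/\rho}$, which is how the
subject-specific scale is formed.  The baseline is divided by the closed
form population mean
$E[m] = e^{\sigma^2/2}\sum_{(x_E,x_G)} P(x_E,x_G)\,e^{\beta^\top x}$
(`calibrate_baseline_multiplier()`), so the population-average multiplier
is 1 and the marginal onset hazard stays anchored at the preset
regardless of effect sizes.

Key defaults, with units and provenance:

| Parameter | Default | Meaning |
|---|---|---|
| `n_subjects` | 30,000 | reference comprehensive-cohort size |
| entry ages | uniform 45–85 | recruitment window; see below |
| `followup_years` | 21 | study horizon |
| `visit_interval` | 3 y | panel ascertainment cadence |
| `ltfu_rate` | 0.005 / y | exponential loss to follow-up |
| `frailty_sd` | 0.585 | log-hazard SD; $e^{2 \times 1.96 \times 0.585} \approx 10$, a 10-fold risk ratio between the 97.5th and 2.5th percentiles |
| disease presets | 65/2.0, 48/5.6, 130/3.3 | onset Weibull scale/shape for diabetes, dementia, Parkinson's |
| death | 42/4.3 | 1→3 Weibull, shared by presets |
| misclassification | 0.1 (env), 0.01 (gen) | conventional non-differential rates |
| `alpha` | 0.05 / $10^{-4}$ / $5\times 10^{-8}$ | env / candidate-gene / genome-wide |

The entry-age distribution is the one genuinely open choice: the design
only fixes the 45–85 recruitment window.  We default to uniform, which is
simple, symmetric and documented as an assumption.  It matters: the
number of incident cases a cohort yields in 21 years depends strongly on
how entry ages weight the rising hazard, especially for late-onset
diseases.  Under the uniform default the simulator's 21-year incident
yields differ noticeably from the census-table-derived counts that
motivated the presets (diabetes lower, dementia slightly higher,
Parkinson's lower), and power in rare-disease scenarios shifts
accordingly.  Users matching a specific cohort should set the window —
or supply their own transition parameters — to match its age pyramid.

### Observation schemes

Under continuous monitoring the onset time is recorded exactly whenever
it precedes death, loss to follow-up and the end of follow-up.  Under
panel observation, disease status is ascertained at visits
$l + k\Delta$: an onset is recorded as an event at the first visit at or
after it, provided the subject is alive and under observation then; the
final visit at $l + $ follow-up counts, since the closing wave of the
study is still a wave.  Onsets the subject does not survive to report are
censored at the usual censoring time: no retrospective diagnosis.  Death
and loss to follow-up are treated as exactly observed (registry-style
ascertainment) — the analysis likelihood uses a single censoring time,
and interval-censoring deaths would change the estimand without changing
the question.

### Misclassification

Observed exposures are the true ones flipped independently with fixed
probability, once per subject per dataset, independent of outcome
(non-differential).  True exposures drive event times; observed exposures
enter the analysis.  Rates at or above 0.5 are rejected — beyond that the
observed variable is a better measure of the complement.

## The analysis model

Each simulated dataset is fitted by maximum likelihood under a Weibull
proportional-hazards model with left truncation and right censoring:
events contribute the truncated log density
$\log f_W(t) - \log(1 - F_W(l))$, censored records the truncated log
survival.  The frailty is deliberately omitted from the analysis model —
it plays the unmeasured etiological determinant, and the resulting
attenuation of the estimated hazard ratios is part of what the
simulation is designed to capture.  Consequently the fitted baseline and
effects are allowed to be biased relative to the generator; only the
test's rejection behaviour is asserted, and the type-I error under the
null remains calibrated because exposure and frailty are independent.

Numerical choices: unconstrained BFGS in $(\log\lambda, \log\rho,
\beta)$ with an analytic gradient, initialized from the closed-form
exponential fit (shape 1, scale = total risk time / events, betas 0);
relative tolerance $10^{-12}$; if the per-record gradient remains above
$10^{-5}$ the optimizer is restarted and then polished with Newton steps
using the exact observed information; the covariance is the inverse
Hessian obtained by central finite differences of the analytic gradient.
Convergence, positive-definiteness and identifiability (an exposure
level with zero events) are flagged, never silently absorbed.  Records
with zero risk time ($t \le l$) are data errors, not droppable rows.
The shape parameter is estimated, not fixed: the likelihood is maximized
over the full Weibull family.

The reported test is the two-sided Wald test $z = \hat\beta/\mathrm{SE}$,
with strict inequality at the critical value; a likelihood-ratio test is
provided as a cross-check utility and agrees with the Wald decision in
essentially all replicates at the reference sample sizes.

For main-effect power scans the fitted model contains only the scanned
exposure.  The full three-term model is the estimand for interaction
scans; but in main-effect scans the other terms have hazard ratio 1 by
convention, and with exposure prevalence 0.01 the double-exposed cell
frequently contains no events at all, which would make every such
replicate non-identifiable for no inferential gain.  The `covariates`
argument restores the full model when wanted.

## Power engine and MDHR search

Power is a binomial proportion over replicate datasets, reported with a
Clopper–Pearson 95% interval.  Replicate $r$ uses
`replicate_seed(master_seed, r)`; fit failures are counted and excluded
only within a configurable budget (default 1%), beyond which the cell
errors out.  The MDHR search bisects the hazard-ratio bracket (default
(1, 3]) on the 80%-power crossing, sharing replicate seeds across bracket
points; monotonicity of power in the hazard ratio is assumed, and an
optional coarse pre-scan (a quarter of the replicates per point) warns
when the trace is non-monotone beyond twice its Monte-Carlo standard
error.  If power at the upper bracket end is below target the sentinel
`">3.00"` is returned.  MDHRs are reported to 2 decimals and classified
as small (1, 1.5], moderate (1.5, 2], large (2, 3] or substantial (>3).

The conventional comparator is Schoenfeld's closed form
$d = (z_{1-\alpha/2} + z_{\mathrm{power}})^2 / \{p(1-p)\log^2 \mathrm{HR}\}$
and its inverse
$\mathrm{MDHR} = \exp\{(z_{1-\alpha/2} + z_{\mathrm{power}})/\sqrt{d\,p(1-p)}\}$,
with normal quantiles at double precision.  The event counts $d$ fed to
the comparator are a user choice; the reporting tables default to the
21-year expected incident cases of the three presets (approximately
6100, 4400 and 420 for diabetes, dementia and Parkinson's under the
reference design).  Because the comparator ignores panel detection,
misclassification and frailty, its MDHR bounds the simulation MDHR from
below on matched scenarios.

## Problem sizes

The reference profile is 1000 replicates of 30,000 subjects per power
estimate, matching the precision a production run would use.  The
package's own test suite and the bundled acceptance script run a
desk-scale profile — 200–400 replicates for power estimates, 60
replicates per bisection point with a 0.02 bracket resolution for MDHR
searches, and reduced cohorts where the property under test is
size-invariant (type-I error, ordering properties) — chosen so the whole
suite completes
on a single CPU in well under half an hour while keeping Monte-Carlo
standard errors small relative to the tolerances being checked
(at 200 replicates the SE of a power near 0.5 is 0.035; near 0.99 it is
0.007).  Monte-Carlo intervals are always reported alongside point
estimates.

## What the generator does and does not emulate

It emulates: delayed entry on the age scale, rising Weibull hazards,
competing death, exponential attrition, visit-based onset detection,
non-differential exposure misclassification, and log-normal unmeasured
heterogeneity.  It does not emulate: time-varying exposures, reversible
or recurrent disease, informative censoring, diagnostic error in the
outcome, stratified or weighted sampling designs, or the 2→3
(diseased→dead) transition, which affects neither incident-case counting
nor the analysis likelihood under the no-recovery assumption.  Passing
tests therefore demonstrate correctness of the simulator and estimator
under these stated conditions, not that any real cohort follows them —
in particular, results for late-onset rare diseases are sensitive to the
entry-age assumption discussed above.

## Known limitations

* The entry-age default (uniform 45–85) is an assumption, not an
  estimate; incident-case yields and rare-disease power move with it.
* Panel detection feeds recorded visit times into a likelihood for exact
  event times, mirroring standard practice rather than an
  interval-censored likelihood; the resulting slight bias is part of the
  design being evaluated, not a defect of the fitter.
* The bisection assumes power monotone in the hazard ratio; gross
  violations are only warned about.
* With exposure prevalence 0.01 and a rare disease, single-digit exposed
  event counts make the Wald test's normal reference approximate; the
  likelihood-ratio cross-check is provided for exactly that situation.
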