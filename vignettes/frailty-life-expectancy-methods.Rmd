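---
title: "Frailty-free life expectancy from multi-state models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frailty-free life expectancy from multi-state models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailspan)
```

# The scientific problem

Frailty — the age-related accumulation of health deficits — is strongly
patterned by socio-economic position. A policy-relevant way to express that
patterning is through *frailty-free* and *frail life expectancies*: the
expected remaining years a person of a given age, gender and socio-economic
profile will spend without and with frailty. `frailspan` estimates these
quantities from interval-censored longitudinal panel data of the kind
ageing cohorts produce: subjects interviewed roughly every two years, a
deficit-based frailty state recorded at each interview, and deaths reported
between interviews.

# The frailty index and states

Each subject-wave record carries up to 60 health-deficit items, each coded
in $[0,1]$. The frailty index is the mean of the non-missing items — the
proportion of deficits accumulated. Records with fewer than a configurable
fraction of items observed (default 0.8, i.e. at least 48 of 60) have an
undefined index and contribute no state at that wave; the subject is not
dropped, and the Markov property lets the likelihood simply span the longer
interval between their remaining observations. The index is categorised
with the established cut-points: *robust* when the index is at most 0.08,
*frail* when at least 0.25, *pre-frail* strictly in between. The boundary
values belong to robust and frail respectively, and the three categories
partition $[0,1]$.

# The four-state model

States are robust (1), pre-frail (2), frail (3) and dead (4). Instantaneous
transitions are allowed only between adjacent frailty states and from any
living state to death:

$$1 \leftrightarrow 2 \leftrightarrow 3, \qquad 1,2,3 \rightarrow 4.$$

Direct robust–frail jumps are excluded; an observed robust-to-frail change
over a two-year interval is attributed to an unobserved passage through
pre-frailty, which the matrix exponential accounts for automatically. The
process is Markov: transition risk depends only on the current state, age
and covariates.

Each allowed transition $r \to s$ has intensity

$$q_{rs}(z) = q^{(0)}_{rs} \exp\left(\sum_k \beta_{rs,k}\, z_k\right),$$

a proportional-intensities (log-linear) form, so every coefficient
exponentiates to a hazard ratio. Covariates are: age (continuous, centred
at 70 years, giving each transition a Gompertz-type log-linear age trend);
wealth and area-deprivation quintiles coded as scores 0–4 so that a
coefficient is a per-quintile log-hazard increment (factor coding of
specific transitions can be had by restricting `per_transition` designs);
education as two dummies against a less-than-high-school reference; and a
married indicator. Gender is a stratifier — separate models are fitted for
women and men — not a regression covariate. Models are compared with
BIC $= -2\ell + p\ln n$, with $n$ the number of subjects by default
(configurable, since the effective information in panel data lies between
subjects and observations).

## Likelihood for interval-censored panels

Within a subject, consecutive observation pairs are conditionally
independent given the Markov property. Over an interval of length $t$ with
covariate vector $z$, intensities are held constant (the
piecewise-homogeneous approximation) and $P(t) = \exp(Q(z)t)$:

* living $r$ → living $s$: contributes $P_{rs}(t)$;
* living $r$ → death at an exactly known time: the living state occupied
  just before death is unobserved, so the contribution is
  $\sum_{k \in \{1,2,3\}} P_{rk}(t)\, q_{k4}$, with the terminal hazard
  evaluated at the death age;
* living $r$ → death known only to lie in the interval: $P_{r4}(t)$.

Two numerical choices matter here. First, the age covariate attached to an
interval is evaluated at the interval *midpoint* by default. With
interval-start ages (the other convention, available via
`age_at = "start"`), smoothly increasing hazards produce a first-order bias
of order (age slope × half the interval) in the log baselines — roughly
0.09 on death intensities with biennial waves and Gompertz slopes near
0.09/year, which is comparable to the standard errors in cohorts of a few
thousand subjects. Midpoint evaluation cancels that first-order term, and
our synthetic-truth recovery experiments confirm near-nominal Wald
coverage under it. Non-age time-varying covariates (wealth, deprivation,
marital status) take their interval-start values, because that is when
they are measured. Second, the terminal death hazard is a density at the
interval's end, not an interval average, so it is evaluated at the death
age itself; evaluating it at the midpoint too re-introduces a bias of
order (slope × mean death-interval half-length) in the death baselines.

Transition probabilities are computed on the $3\times 3$ transient block
(death is absorbing, so $\exp(Qt)$ restricted to living states equals
$\exp(Q_{TT}t)$) by uniformization with scaling and squaring: for a
(sub)generator $A$ with $\lambda = \max_r |A_{rr}|$, the series in
$M = I + A/\lambda$ has non-negative terms, so there is no cancellation,
and pre-scaling by $2^s$ keeps the effective $\lambda$ at 5 or below
(about 40 terms for ~$10^{-12}$ accuracy). Unlike inverse-based Padé
routines this cannot fail on the extreme generators an optimiser's line
search visits; log intensities are additionally capped at 20 (about
$5\times 10^8$ events/year) purely to keep those excursions finite. The
user-facing `transition_probability()` for full $4 \times 4$ generators
uses Padé scaling-and-squaring.

## Estimation

The likelihood is maximised by BFGS on the unconstrained parameters (log
baselines and betas) with relative tolerance $10^{-8}$, starting from log
crude rates — events over person-years at risk, with a half-event
continuity correction — and zero betas. The covariance is the inverse of
the numerically differentiated observed information; an indefinite or
singular information matrix is reported as an unavailable covariance, not
silently repaired. Non-convergence sets a flag rather than raising. Tied
observation ages within a subject are an error: they usually indicate a
merge fault in the input, and silently perturbing them would hide it.

# Life expectancies

State-specific life expectancies from age $a_0$,

$$e_{rs}(a_0) = \int_{a_0}^{\omega} P(a_0, u)_{rs}\, du,$$

are computed by deterministic product integration: $P(a_0, u)$ is advanced
as an ordered product of per-step matrix exponentials with the age
covariate refreshed at each step midpoint (other covariates fixed), and
the integral accumulates by the trapezoidal rule. Defaults are a step of
$h = 0.5$ years and a horizon $\omega = 115$ years, beyond plausible
survival; the integrator warns when residual survival at the horizon
exceeds $10^{-3}$. Against the closed-form fundamental matrix
$(-Q_{TT})^{-1}$ of a time-homogeneous model, the integrator at $h = 0.1$
agrees entrywise to better than 0.5%, and the error shrinks as $O(h)$
under step halving. A microsimulation utility (`microsim_les()`) provides
an independent Monte-Carlo cross-check of the same integrals and is used
in the test suite.

The marginal frailty-free, frail and total life expectancies weight the
rows of $e_{rs}$ by the distribution over living states at $a_0$,
estimated by a multinomial logistic regression of each subject's baseline
state on age (with an empirical-proportion fallback when that regression
is degenerate). "Simulating" life expectancies here means drawing
parameters, not individuals: uncertainty is propagated by 1000 draws from
the multivariate normal at the MLE with the estimated covariance,
recomputing every quantity per draw, and taking 2.5/97.5 percentile
limits. The initial-state distribution is held fixed across draws; its
multinomial sampling error is an order of magnitude below the intensity
parameters' contribution at these cohort sizes. Frailty-free plus frail
time equals total time identically in every draw, and percentages are
computed from unrounded years and rounded once at formatting
(round-half-even, one decimal).

Group contrasts subtract per-draw values. Within a stratum, calling
`bootstrap_les()` with the same fit and seed yields identical draw
streams, so contrasts are paired and shared parameter noise cancels;
across separately fitted strata (women vs men) the streams are
independent and the per-draw differences simply convolve the two
uncertainties. The data release convention this package anticipates
degrades birth and death dates to calendar years; `jitter_dates()` draws
exact dates uniformly inside those windows subject to ordering constraints
(birth before first interview, death after last), and the sensitivity
protocol repeats the whole analysis over several jitter seeds, comparing
the spread of point estimates with the bootstrap interval half-width.

# The synthetic cohort generator

Because the motivating data are access-restricted, every stage is
validated on synthetic cohorts with known truth. The generator emulates
the study design rather than any published estimate: subjects aged 50+
with a right-skewed baseline age distribution ($50 + 40\cdot
\mathrm{Beta}(1.2, 3.4)$), 54.5% women, nine biennial waves, baseline
states drawn from an age-dependent multinomial logit calibrated to
realistic robust/pre-frail/frail proportions at ages 50–85, wealth and
deprivation quintiles coupled by a Gaussian copula (rank correlation 0.5),
education frequencies 37/17.5/45.5%, and 69.7% married. Default
transition truths use Gompertz-type age slopes (+0.05/year on frailty
onset, −0.03 on recovery, +0.09 to +0.10 on death) and a protective
wealth gradient (−0.15 per quintile on onset transitions; −0.16 on death
from pre-frailty for women, −0.21 on death from robustness for men, so
the two strata differ qualitatively as real cohorts do). These values are
calibrated *qualitatively* — women accumulate more frail years than men,
wealth extends frailty-free life — and are used for direction and
recovery tests only.

Latent trajectories are simulated exactly under the truth,
piecewise-homogeneous over 1-year age bands with competing exponential
clocks; intensities within a band are evaluated at the band *midpoint*
age, which makes the generation scheme agree with the midpoint-age
likelihood to second order (band-start evaluation would re-introduce the
first-order gap discussed above — the generation bands and the
inference's interval approximation are different discretisations, and the
residual gap is measured by the recovery tests, not assumed zero). Wealth
and marital status drift at wave boundaries (2% per wave each by
default), exercising the time-variant covariate path while keeping
covariates exact within observation intervals. Attrition is per-wave
(5% default) and ends a subject's observation window at the first missed
wave; deaths before that window's end are recorded at their exact age,
later ones are not, so attrition censors death and survival symmetrically
and remains non-informative — the informative attrition real cohorts
suffer is deliberately out of scope. Deaths after a subject's last
*scheduled* wave are likewise unobserved.

What passing tests on these cohorts do show: the likelihood, optimiser,
uncertainty and life-expectancy machinery recover known truths at study
scale (95% Wald intervals cover each true parameter at nominal rate
across 20 replicate cohorts of 2,000 subjects). What they cannot show:
robustness to informative attrition, to misclassification of the frailty
state, to cohort effects in covariates, or to non-Markov dependence —
none of which the generator produces.

# Problem sizes and defaults

| Parameter | Default | Why |
|---|---|---|
| completeness threshold | 0.8 | common frailty-index practice; configurable |
| frailty cut-points | 0.08, 0.25 | established categorical thresholds |
| age centring | 70 years | mid-range of an ageing cohort; numerics only |
| integration step $h$ | 0.5 years | $O(h)$ error well below bootstrap noise |
| horizon | 115 years | residual survival $< 10^{-3}$ |
| bootstrap draws | 1000 | matches standard practice for percentile CIs |
| BIC $n$ | subjects | documented choice; observations available |
| presets | 200 / 2,000 / 15,003 subjects | smoke / routine validation / full study scale |

Routine validation (tests, worked examples) uses the 2,000-subject preset:
estimates there carry roughly the standard errors a reader will see in the
worked example, while a fit completes in tens of seconds. The full-scale
preset exists for users who want study-sized runs.

# Known limitations

* Attrition is treated as non-informative right censoring; real ageing
  cohorts show health-dependent dropout, which biases toward healthier
  survivors.
* Missing covariates are handled by complete-case analysis (the fitter
  stops on missing values); an imputation hook would slot in before
  `fit_msm()`.
* The piecewise-homogeneous approximation evaluates age once per interval;
  with biennial waves and Gompertz slopes near 0.1/year the residual
  second-order error is negligible, but much sparser panels would need
  interval splitting.
* Quintile scores impose a log-linear per-quintile effect; genuinely
  non-monotone gradients need factor coding.
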