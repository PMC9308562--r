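---
title: "Multistage models of age-related disease incidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistage models of age-related disease incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multistage)
```

## The models

Many common diseases behave as if several slow, rate-limiting processes must
all complete before onset is observed — the picture long used for
carcinogenesis, and increasingly plausible for non-malignant disease given
the ubiquity of somatic mutation and other slow tissue-level changes.  This
package fits two minimal parametric embodiments of that picture to
age-at-first-hospital-admission data.

**Sequential (Weibull proportional-hazards) model.**  When $m$ steps must
occur in order, each at a slow constant rate, the onset-age distribution is
approximately Weibull over the ages where disease remains rare.  We
parameterize it by its cumulative hazard

$$H(t \mid X) \;=\; e^{\eta_X}\left(\frac{t}{L}\right)^{m}
\;=\; \left(\frac{t\,e^{\eta_X/m}}{L}\right)^{m},
\qquad \eta_X = \sum_j \beta_j X_j ,$$

with survival $S = e^{-H}$, hazard $h = (m/t)e^{\eta_X}(t/L)^m$, and density
$f = hS$.  $m$ is the *effective number of steps* — real-valued, because
time-varying stage rates blur the classical integer — and $L$ is a timescale
in years.  On log–log axes $\log H$ is exactly linear in $\log t$ with slope
$m$, and covariates displace the line vertically by $\eta_X$ without
changing its slope.  Ratios such as $H(100)/H(50) = 2^m$ depend on $m$
alone, which also makes them insensitive to proportional differences in
unmeasured risk factors between cohorts.

**Non-sequential model (NSM).**  When the $m$ rate-limiting events can occur
in *any* order, each at approximately constant rate $1/L$, onset is the age
at which the last of them completes:

$$S(t) \;=\; 1 - \left(1 - e^{-t/L}\right)^{m}.$$

For integer $m$ this is exactly the maximum of $m$ iid exponential waits —
the brute-force simulator `simulate_parallel_stages()` reproduces it
draw-for-draw and serves as the model's independent oracle in the tests.
Within a non-sequential picture all rate-limiting steps must have similar
(slow) rates, or the faster ones would not be rate-limiting; constant equal
rates are therefore an adequate approximation in the regime where the model
is used.  The NSM carries no covariates by default (nothing in its
derivation supplies a proportional-hazards structure); an optional hazard
multiplier can be attached for experimentation, but every shipped analysis
path fits it unadjusted.

The two models embody very different biology yet both typically describe
incidence data well; a good fit to either is **not** evidence of a
multistage mechanism, and the package deliberately offers no formal
family-selection statistic.

### Effective age and relative aging rates

Rearranging $H$ shows that a risk profile multiplies *age* rather than
hazard: a person with linear predictor $\eta_X$ has the baseline risk of
someone aged $t\,e^{\eta_X/m}$.  We call $e^{\eta_X/m}$ the **relative aging
rate** (RAR), next to the familiar relative risk $e^{\eta_X}$; always
$\mathrm{RAR}^m = \mathrm{RR}$, so risk factors move the effective age only
by the $m$-th root of their hazard ratio — diseases with few effective steps
are the most age-modifiable.  `effective_age()`,
`equivalent_screening_age()` and `expected_first_disease_age()` implement
the resulting arithmetic, e.g. a RAR of 1.1 turns age 50 into effective age
55, and turns 25 expected disease-free years at age 40 into
$(40+25)/1.1 \approx 59$ years of age at first disease (19 disease-free
years).

## Data preparation

The observational unit is the first primary-diagnosis hospital admission per
subject and ICD-10 chapter, on an **age** timescale: subjects enter
observation disease-free at their study entry age (left truncation) and are
right-censored at study end or at a first cancer other than non-melanoma
skin cancer (C00–C97 except C44).  Subjects with such a cancer *before*
entry are excluded outright.  `icd10_chapter()` embeds the WHO chapter
table as a versioned constant (note: chapter IX is circulatory and XI
digestive in the WHO scheme; texts occasionally misnumber these).  Design
choices where the convention is genuinely open:

* A first event for a *different* disease in the same chapter censors the
  subject for the disease under study (rather than removing them): until
  that age they were genuinely at risk under the first-per-chapter design,
  and deleting them would distort the risk sets.
* Same-age ties within a chapter are broken by code sort order,
  deterministically, and logged via `attr(, "ties")`.
* Disease code-sets match as prefixes of dot-stripped codes ("I25.1" covers
  I25.1x; "I21" covers all of I21) and must stay within one chapter.

## Likelihood, initial values, and numerics

Fitting maximizes the left-truncated, right-censored log-likelihood

$$\ell = \sum_i \big[\delta_i \log f(t_i\mid x_i) +
(1-\delta_i)\log S(t_i \mid x_i) - \log S(t_{0i}\mid x_i)\big],$$

over $(\log m, \log L, \beta)$ — the log transform enforces positivity and
makes the optimization unconstrained — with BFGS, a relative
log-likelihood tolerance of $10^{-10}$, and standard errors from the
inverse observed information mapped to the natural scale by the delta
method ($\mathrm{se}(m) = m\,\mathrm{se}(\log m)$).  Coefficients start at
a semi-parametric Cox fit; $(m_0, L_0)$ start from least squares of the log
Kaplan–Meier cumulative hazard on log age.  Under delayed entry that slope
*overstates* $m$ (the step estimator is blind to pre-entry hazard), so
starts are clamped to $m_0 \in [0.3, 25]$, $L_0 \in [1, 10^6]$; the
optimizer reliably descends from there.  The NSM reuses the Weibull start:
for rare diseases $t \ll L$ and its onset CDF reduces to the Weibull form.
Degenerate designs (a covariate level with no events, a failed Cox fit)
fall back to zero coefficients with a message.  Parameter proposals with
$|\log m| > 10$ or $\log L \notin (-10, 30)$ are rejected with a large
penalty rather than evaluated, and a non-positive density at an event age
makes $\ell = -\infty$ so the line search retreats.  Non-convergence and a
non-invertible Hessian are reported in the `convergence` field, never
silently.  Missing covariates are handled by complete-case analysis, the
appropriate choice when missingness is well under 1%.

## The Kaplan–Meier offset

The product-limit estimator assumes survival 1 at the start of observation,
but on an age timescale a middle-aged cohort has already accrued cumulative
hazard $H_1 = \int_0^{t_1} h\,\mathrm{d}s$ by the first observed event age
$t_1$.  Writing $H(t) = H_1 + \hat H(t)$ and using the parametric model for
$H$, the offset is estimated by averaging over the $n$ observed event ages,

$$H_1 \simeq \frac{1}{n}\sum_{i=1}^n \big(H(t_i) - \hat H(t_i)\big),$$

introducing no extra free parameters, and the adjusted curve is
$e^{-H_1}\hat S(t)$.  The average runs over event ages only (tied events
counted with multiplicity): those are the ages where $\hat H$ is defined
and where the estimator carries information; censored rows do not enter.
Variances scale by $e^{-2H_1}$ with $H_1$ treated as fixed.  Without the
offset, log–log plots of delayed-entry data are grossly non-linear and the
apparent slope can approach twice the true $m$ — the package's tests
demonstrate both the distortion and its repair.

## Goodness of fit and inclusion

`chisq_gof()` compares the parametric survival with the adjusted
Kaplan–Meier at the event ages, standardized by the Greenwood variance
only — deliberately strict, since using the fit's variance too would make
discrepancies easier to excuse — with df equal to the number of evaluation
points, uncorrected for the two or three estimated parameters (subtract
them yourself if you prefer).  Two caveats are documented rather than
hidden: adjacent Kaplan–Meier points are correlated, which the χ² treats as
independent; and the $H_1$ average recenters the very deviations being
tested.  The net effect is a *conservative* screen — under a correctly
specified model at realistic sizes it essentially never rejects (measured
type-I error ≈ 0 at α = 0.05 over 200 replicates of n = 20,000) — which is
the right failure direction for a filter whose job is to discard only
clearly ill-described diseases.  Screening p-values are
Benjamini–Hochberg-adjusted across the disease ensemble (level 0.05 by
default) and a disease is also excluded when $\hat m < 0.8$, where the
multistage reading is untenable.

## Sporadic versus late-onset classification

For each included disease the fitted model is extrapolated to
$F(50) = 1 - S(50)$ and $F(100)$ at baseline covariates.  The product
$F(50)\times F(50)/F(100)$ — early risk times the probability that a
disease destined to occur by 100 has already occurred by 50 — is largest
for *sporadic* diseases (appreciable, slowly growing early risk) and
smallest for *late-onset* ones (negligible early risk rising steeply).
Diseases are cut at the empirical 1/3 and 2/3 score quantiles; boundary
values go to the lower tertile, and an all-equal ensemble degenerates to
all mid-range with a message.  Classification uses unadjusted
($\eta_X = 0$) fits: it characterizes the disease, not a risk profile.
Both families can be classified; the Weibull is the reporting default and
the NSM typically agrees.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes: entry ages
from a Normal(57, 8) truncated to [49, 69] (the enrolment profile of large
mid-life population cohorts), sampled by inverse CDF for cross-platform
determinism; categorical covariates with set prevalences; onset drawn from
the true model *conditionally on being event-free at entry* by closed-form
inversion (a rejection mode is retained purely to validate that both
routes give the same truncated law); censoring at entry + 10 follow-up
years by default, and optionally at an independent exponential
competing-cancer age.  Ten years is a stand-in for a typical
electronic-records window; the per-disease defaults used in tests ($m$
between 2 and 5, $L$ chosen so a cohort of a few thousand yields a few
hundred to a few thousand cases) match the case counts the analysis is
designed for.  `generate_episode_table()` additionally emits ICD-10 coded
episode tables with known ground truth (pre-entry cancers, later
same-chapter and non-primary episodes that extraction must ignore), so the
preparation stage is tested against construction rather than against
itself.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: correlated comorbidity (onsets are
independent across diseases given covariates), calendar-time and birth-cohort
effects, covariate measurement error, informative censoring, and
model misspecification itself (real incidence curves need not be Weibull or
NSM; the goodness-of-fit screen exists precisely because some are not).

## Problem sizes and test design

The test suite and `scripts/acceptance.R` exercise the pipeline at sizes
where every check is sharp but cheap: single cohorts of 20,000 subjects for
parameter recovery (each true parameter within 3 reported SEs; 95% CI
coverage for $m$ across 100 replicates inside a [0.89, 0.99] binomial
band), 200 replicates for screen calibration, $10^5$ draws for
Kolmogorov–Smirnov agreement between closed forms and brute-force
simulators (threshold $1.36/\sqrt{n}$), and 20 seeded replicates for the
stratified log–log scenarios: a pure rate increase must displace the
exposed stratum's line upward with unchanged slope, and accelerating one
sequential stage 100-fold must reduce the fitted slope — the signature of a
step ceasing to be rate-limiting.

## Known limitations

* The Weibull approximation to the sequential model holds where cumulative
  risk is small; extrapolations like $F(100)$ inherit parametric form, not
  data, beyond the observed age window.
* The χ² screen's independence assumption and conservative df mean its
  p-values are screening devices, not calibrated tail probabilities.
* Greenwood bands on the adjusted curve ignore uncertainty in $H_1$ and in
  the parametric fit; they are exact only for the offset-known case.
* Interval censoring, frailty, time-varying covariates and cure fractions
  are out of scope.
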