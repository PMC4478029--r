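---
title: "Echocardiographic pulmonary hypertension: derivation, classification and cohort analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Echocardiographic pulmonary hypertension: derivation, classification and cohort analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephcohort)
```

## The problem

Right-heart catheterization, the diagnostic standard for pulmonary
hypertension, is too invasive for population studies. Transthoracic Doppler
echocardiography offers a non-invasive surrogate: the peak velocity of the
tricuspid regurgitation jet (TRV, m/s) gives the systolic pressure gradient
across the tricuspid valve through the simplified Bernoulli equation,

$$\Delta P = 4\,\mathrm{TRV}^2 \quad (\text{mmHg}),$$

and adding an estimate of right atrial pressure (RAP) yields the estimated
pulmonary artery systolic pressure,

$$\mathrm{ePASP} = 4\,\mathrm{TRV}^2 + \mathrm{RAP}.$$

`ephcohort` implements this derivation for tabular cohort data, the
rule-based case definitions built on it, the prevalence and regression
analyses an epidemiological study runs downstream, and a synthetic-cohort
generator calibrated so the whole pipeline can be exercised and tested
end to end without individual-level data.

## Derivation rules

**RAP.** Following echocardiographic guidelines, RAP is categorical: 3 mmHg
when the inferior vena cava (IVC) diameter is at most 21 mm *and* collapses
by more than 50% on a sniff test; 15 mmHg when the diameter exceeds 21 mm
*and* the collapse is under 50%; 8 mmHg in every other case. Both
comparisons are strict, so exact boundary values (21 mm, 50%) fall into the
intermediate class by elimination. `estimate_rap()` is total on its input
grid — the tests enumerate a diameter-by-collapse grid and verify that only
\{3, 8, 15\} occur, each cell mapping to exactly one value.

**Left ventricular function.** Ejection fraction is often unavailable in
M-mode protocols, so systolic function is summarized by fractional
shortening, $\mathrm{FS} = (\mathrm{LVEDD} - \mathrm{LVESD}) /
\mathrm{LVEDD} \times 100\%$, with systolic dysfunction defined as
FS < 29% (strict). A record with LVESD > LVEDD is physically inconsistent
and raises an error naming the rows rather than being dropped silently.

**Diastolic staging.** Participants are placed into three ordered
categories — normal or relaxation abnormality (stage 1), pseudonormal
(stage 2), restrictive (stages 3–4) — from the mitral E/A ratio, the E/E′
ratio and the septal annular velocity E′; in atrial fibrillation the A wave
is unusable, so the E-wave deceleration time replaces the E/A ratio and
`a_peak` is never read. The staging literature is not fully standardized on
exact cutoffs, so the decision *table* is fixed but its thresholds are
named and configurable (`diastolic_thresholds()`), with shipped defaults:
E/A below 0.75 → relaxation abnormality (grouped with normal); E/A above
2.0 → restrictive; otherwise pseudonormal when E/E′ > 10 or E′ < 8 cm/s,
normal when neither. The AF branch uses deceleration time < 140 ms
(restrictive) and > 220 ms (relaxation pattern), with the same
filling-pressure indices in between. All package tests reference this
default table explicitly; none depend on any external staging source.

## Case definitions

The primary definition calls a participant a case when ePASP > 40 mmHg.
Ascertainment is hierarchical, and the path taken is recorded per row:

1. ePASP estimable (TRV and RAP both present): case iff ePASP > 40 mmHg.
2. RAP missing, TRV measured: case iff the gradient exceeds 36 mmHg
   (TRV > 3.0 m/s).
3. Jet absent or too small to measure: assumed non-case, on the reasoning
   that an unmeasurable jet usually indicates normal pulmonary pressures.
4. No tricuspid regurgitation data recorded at all: excluded from the
   denominator.

Note the deliberate asymmetry inherited from the study design: with the
minimum RAP of 3 mmHg, ePASP > 40 implies a gradient above 37 mmHg, yet
the stated fallback threshold is 36 mmHg (TRV > 3.0 m/s). The rules are
implemented exactly as stated, not harmonized.

Two sensitivity definitions bracket the primary one. The *RV-augmented*
definition also accepts a dilated right ventricle (basal RVEDD > 42 mm) as
sufficient; participants without TR data but with a dilated RV become
classifiable cases, which is why this denominator can slightly exceed the
primary one, while no-TR-data rows with a normal-size or unmeasured RV
remain excluded. The *stringent* definition raises the thresholds to
50 mmHg / TRV > 3.4 m/s and ignores the right ventricle. On any cohort the
case sets nest: stringent ⊆ primary ⊆ RV-augmented; the suite checks this
on a thousand randomized cohorts.

## Prevalence statistics

Prevalences use the plain Wald interval
$\hat p \pm z_{0.975}\sqrt{\hat p(1-\hat p)/n}$, no continuity correction,
truncated to $[0, 1]$ and reported in percent. Printed values use half-up
rounding to one decimal (`round_half_up()`), because base R's half-to-even
rounding makes printed triples irreproducible. Wald intervals undercover
slightly at small proportions — at $p = 0.026$, $n = 2823$ the exact
coverage is about 94.6% rather than 95% — which the coverage test asserts
as a property rather than hiding.

Subgroup tables use Pearson's chi-square (omnibus over levels, no
continuity correction) for the across-level p-value, and the
included-versus-excluded characteristics table uses Welch's two-sample
t-test for continuous variables and the same chi-square for categorical
ones. These test choices are conventional defaults for cohort description
tables and are isolated behind `subgroup_prevalence()` /
`compare_populations()` so they can be swapped. Subgroup grouping uses the
imputed covariates by default (first completed copy), with a
complete-case switch in `run_eph_pipeline()`.

## Missing covariates and pooled regression

Smoking and COPD are completed by last observation carried forward from
the prior visit (`locf()`), never overwriting observed values. Remaining
covariate missingness — capped at 6% per covariate, enforced with an error
naming the offender — is handled by chained-equations multiple imputation
(default m = 5) with predictive mean matching: each target is regressed on
all other covariates, parameters are drawn from their Bayesian posterior,
and each missing value receives the observed value of one of the five
donors nearest on the linear predictor. PMM works uniformly for
continuous, binary and categorical targets and never invents values
outside the observed support. TRV, RAP and RVEDD serve as predictors in
every imputation model but are never imputed themselves (they enter
zero-filled with a missingness indicator); the outcome ePASP, being their
deterministic sum, is never imputed either, and models are fitted only on
rows where it is estimable.

Associations with ePASP follow a two-stage scheme. *Model A* regresses
ePASP on each candidate factor adjusted for age and sex (age's own fit
adjusts for sex only, and vice versa). *Model B* is the single
multivariable fit containing exactly the factors with model-A p < 0.05 —
strict, on unrounded pooled p-values. Factor covariates are screened on a
pooled multi-parameter Wald (D1) statistic, single-degree terms on the
pooled t-test. Estimates are pooled by Rubin's rules (variance
$W + (1 + 1/m)B$) with Barnard–Rubin degrees of freedom; when the
between-imputation variance is exactly zero the complete-data degrees of
freedom are used, which makes the zero-missingness pipeline reproduce a
single ordinary least-squares fit to machine precision — a property the
suite asserts. Effects are reported on conventional scales (age per
10 years, BMI per 5 kg/m², FS per 10 points) by deterministic rescaling of
raw-scale fits.

## The synthetic-cohort generator

The generator emulates an elderly population-based echocardiography study.
Covariates are drawn from the configured marginals (age from a normal
distribution left-truncated at 65 whose truncated moments are solved to
hit mean 76.4, SD 6.2), with weak Gaussian-copula correlations (age–COPD
0.15, age–diastolic stage 0.25, BMI–hypertension 0.20, age–FS −0.10)
chosen so the expected subgroup gradients — higher prevalence at older
ages, with COPD, with LV dysfunction — emerge qualitatively. True ePASP is
generated *first*, as the configured linear predictor plus a right-skewed
residual (a centred, scaled log-normal; the skew reproduces the
mean-above-median shape of observed ePASP distributions), and the echo
measurements are then back-derived: RAP from its three-point guideline
distribution (0.85/0.13/0.02 over 3/8/15 mmHg, giving mean 3.89 and
SD 2.31), TRV as $\sqrt{(\mathrm{ePASP} - \mathrm{RAP})/4}$, IVC
diameter/collapse consistent with the drawn RAP category, LV diameters
consistent with the assigned FS, and mitral indices consistent with the
assigned diastolic stage. This direction makes the derivation stage an
exact inverse of the generator — a machine-precision round-trip the tests
rely on — and makes parameter-recovery experiments well-posed because the
linear effect structure is exact in truth. Rows whose drawn ePASP would
fall below their RAP (a vanishing fraction) are floored at RAP and
counted.

Three scalar parameters are not printed anywhere and were calibrated once,
then frozen in the default config: the intercept (5.79 mmHg), the residual
SD (6.58 mmHg) and the log-scale skew (tau = 0.12). They were fitted
jointly, by Nelder–Mead on a large common-random-numbers cohort run
through the actual pipeline, so that the estimable-subset mean and SD of
ePASP and the primary-definition prevalence equal 26.3 mmHg, 7.0 mmHg and
2.6% in expectation under default missingness.

**Missingness model.** Masking reproduces the observed pattern: 16.5% of
participants have no TR data at all (completely at random); among the
rest, 23.7% have an unmeasurable jet, with probability decreasing in true
ePASP through a logistic link whose intercept is solved at run time so the
marginal rate is matched exactly — this encodes the clinical assumption
that unmeasurable jets accompany normal pressures, and it is what makes
the "assumed non-case" rule approximately valid. The default steepness
(0.02 per mmHg) was chosen so that the masked-versus-measured contrast in
true ePASP is clearly visible (about −1 mmHg) while complete-case
estimation on the estimable subset remains unbiased within Monte-Carlo
resolution; steeper links induce a selection-on-outcome attenuation that
would contradict the recovery properties the analysis model assumes. RAP
is masked completely at random at 9.7% (so that roughly 7.4% of all
TR-recorded rows are TRV-measured-but-RAP-missing), and covariates at
their observed small rates, with prior-visit smoking/COPD available for
carry-forward 95% of the time.

**What the generator does not emulate.** Real echo cohorts have
measurement error in every index, correlated multi-window Doppler reads,
medication effects, and missingness mechanisms that are at best partially
known. Passing calibration and recovery tests here shows the pipeline is
internally coherent and unbiased under its stated assumptions — not that
those assumptions hold in any particular real cohort.

## Numerical choices and degenerate inputs

* Strict inequalities exactly as the definitions state them; RAP boundary
  cases fall to 8 mmHg by elimination.
* Half-up fixed-point rounding everywhere a percentage is printed, with a
  machine-epsilon guard against representation error just below a tie.
* Missing values are first-class (`NA` plus a TRV reason code), never
  sentinel numbers; a missing TRV without a reason is an error.
* `wald_ci()` rejects $n = 0$ and out-of-range counts; empty subgroup
  levels are dropped with a warning.
* The imputer falls back to a ridge-stabilized Cholesky only if a
  predictor crossproduct is numerically singular.
* Problem sizes in the test-suite: calibration checks run at n = 100,000
  (three Monte-Carlo standard errors of the mean are then ±0.08 mmHg),
  recovery at n = 20,000 with m = 5, unbiasedness at n = 2,000 over 200
  replicates, coverage with 10,000 binomial draws.

## Known limitations

* The diastolic-staging thresholds are a documented default, not a claim
  about any specific cohort's reading protocol.
* Wald intervals are the stated estimator; Clopper–Pearson or score
  intervals are deliberately not offered as defaults.
* The imputation engine is chained-equations PMM; the original
  MCMC-flavoured procedures differ in mechanism, but at ≤6% missingness
  the pooled-coefficient estimand is engine-insensitive, which is the
  contract the tests pin down.
* No catheterization emulation, WHO-group assignment, medication coding
  or longitudinal modelling.
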