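---
title: "Methods: estimating autonomic maturation age and the 34-week delay biomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating autonomic maturation age and the 34-week delay biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In very preterm infants (born before 30 weeks of gestation), the central
autonomic network matures over the weeks after birth, and that maturation
is disturbed by prematurity itself and by neonatal complications. Heart
rate variability (HRV) — the beat-to-beat fluctuation of cardiac cycle
length — indexes autonomic activity and is available continuously and
non-invasively from bedside monitors. `neomat` implements a pipeline that

1. turns beat-interval (RR) recordings into cleaned 30-minute analysis
   segments,
2. computes a bank of time-domain, frequency-domain and non-linear HRV
   features per segment,
3. regresses post-menstrual age (PMA) on those features (plus gestational
   age, GA) with a genetic-algorithm-selected ensemble, yielding a
   *functional maturation age* (FMA),
4. converts FMA to the delay biomarker `delta = PMA − FMA` (positive =
   delayed), models per-infant delay trajectories over 32–36 weeks PMA
   with a covariate-adjusted linear mixed-effects model, and interpolates
   each infant's delay at 34 weeks PMA (`delta34`), and
5. relates `delta34` to perinatal factors and to 2-year ASQ-3
   neurodevelopmental outcomes.

Because monitor recordings from a real cohort cannot be redistributed, a
first-class synthetic-data module generates RR series, cohorts, delay
trajectories and ASQ outcomes with the statistical structure the analysis
assumes; every downstream stage is developed and tested against it.

## The synthetic-data generator

The generator's defaults *are* the study conditions the rest of the
package is validated under.

**RR series** (`generate_rr_series`). Beats are laid down sequentially;
the interval at time $t$ is

$$\mathrm{RR}(t) = \mu + A_{LF}\sin(2\pi f_{LF} t)
  + A_{HF}\sin(2\pi f_{HF} t) + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma^2),$$

with a fraction of beats replaced by ectopic-like artifacts (RR doubled
or halved — simple, and detectable by the cleaning rule). Defaults encode
a maturation law: baseline RR lengthens and variability amplitudes grow
with PMA; the HF (respiratory) modulation sits near 1 Hz because neonates
breathe far faster than adults. Noise is white by design so that
time-domain feature expectations are analytic; real neonatal RR also has
1/f structure, sleep-state switching, and movement artifacts that this
generator does not emulate — passing tests demonstrate correctness of the
estimators, not clinical performance.

**Cohorts** (`generate_cohort`). GA strata (<26, 26–<28, ≥28 weeks) and
binary perinatal covariates are drawn at the prevalences observed in the
multicentre cohort the package models (male 0.515, BPD 0.34, PDA 0.652,
neurological lesions 0.28, tobacco 0.106, growth restriction 0.25). Each
infant carries a latent true delay at 34 weeks, drawn log-normally per
stratum with medians 3.0 / 2.3 / 1.3 weeks and log-sd matched to the
corresponding interquartile ranges ($\sigma = (\log Q_3 - \log
Q_1)/1.349$: 0.391, 0.620, 0.814). The spread's distributional form is a
package choice — the source estimates report only medians and IQRs, and a
log-normal reproduces the right-skewed, positive-support shape. BPD and
PDA add +0.8 weeks each, *centered at their prevalence*, so complicated
infants are more delayed without moving the stratum medians the
calibration pins down. Centering is mean-zero but not exactly median-zero
on a skewed base distribution, which nudges stratum medians upward by
roughly 0.05 weeks; this is visible in the most mature stratum.

**ASQ outcomes.** Each domain's abnormality flag is Bernoulli with
log-odds `intercept + slope·delta34 + covariate terms`. The default
personal-social model uses an odds ratio of 2.05 per week of delay plus
tobacco (OR 9.57) and neurological-lesion (OR 7.72) effects; other
domains are delay-independent with intercepts matched to observed
abnormality rates (23%, 5.8%, 0.5%, 4.6%). One subtlety is deliberate:
reported per-week ORs from cohort studies are *univariate* (marginal)
estimates, but a logistic model's marginal and conditional slopes differ
when other strong effects exist (non-collapsibility). The configured
slope is therefore defined as the marginal effect, and generation
inflates the conditional slope by the standard logit approximation
$\sqrt{1 + 0.346\,\sigma_u^2}$, where $\sigma_u^2$ is the variance of the
omitted covariate contribution. A univariate logistic fit on a generated
cohort then recovers the configured OR, which is exactly how such an
estimate is produced and reported in practice. The personal-social
intercept (−7.072) was solved once, numerically, so the marginal
abnormality rate matches the observed 6.9%.

**Trajectories** (`generate_trajectory`). The delay grows linearly with
postnatal age, equals the latent `delta34` at 34 weeks (slope default
0.3 weeks/week), and observed FMA adds Gaussian noise (default sd 0.3
weeks). Both defaults mirror the magnitudes the mixed model is expected
to recover.

## Ingestion and segmentation

`read_rr` parses two-column beat files (`#` comments allowed) and rejects
non-monotone times with the offending line number. `clean_rr` flags
beats deviating more than 20% from the centered 11-beat running median —
an explicit, testable stand-in for "good-quality traces", since published
screening rules are rarely stated. `segment_series` tiles the recording
with contiguous, non-overlapping, half-open 30-minute windows from the
first beat (no double counting; simplest reproducible tiling) and keeps
windows with ≥ 80% unflagged beats and ≥ 1000 beats. These thresholds
are declared defaults, not reproductions of any specific study's
screening.

## The HRV feature bank

Nineteen features across the canonical families (`hrv_feature_registry()`).
Conventions that matter:

* **Population variance throughout** (divide by $n$), and Poincaré
  $SD1^2 = \tfrac12\,\overline{\Delta RR^2}$ (uncentered), so the
  identities $SD1 = \mathrm{RMSSD}/\sqrt2$ and $SD1^2 + SD2^2 =
  2\,\mathrm{SDNN}^2$ hold exactly, not just asymptotically.
* **Spectral bands are neonatal**: LF 0.04–0.2 Hz, HF 0.2–2.0 Hz
  (configurable). Band powers integrate a hand-implemented Lomb
  periodogram of the unevenly sampled series — no resampling — scaled so
  the full-band integral approximates the series variance. A zero HF
  power yields a missing ratio with a recorded reason, never an infinity.
* **Sample entropy** uses embedding $m = 2$, tolerance $r = 0.2\,\sigma$
  (Chebyshev distance, self-matches excluded, templates at the first
  $n-m$ positions for both lengths); when $\sigma = 0$ the tolerance
  falls back to an absolute $r$ so a constant series scores 0.
* **DFA** is first-order with boxes from both record ends; α1 uses
  scales 4–11 beats, α2 12–64 (a scale is used only when ≥ 4 boxes fit).
  The fluctuation is multiplied by the finite-size factor
  $s^2/(s^2-4)$: the exact white-noise expectation of raw first-order
  DFA is $\propto (s^2-4)/s$, which biases α1 to ≈ 0.62 at these short
  scales; the corrected statistic has expectation $\propto s^{1/2}$ for
  uncorrelated data, and measured exponents centre on 0.5 (white noise)
  and 1.4 (integrated noise).
* **Visibility graphs** are *natural* visibility on (beat time, RR)
  points with strict inequality, so a constant series is a path graph and
  a strictly convex one a complete graph; series beyond 1024 beats are
  subsampled deterministically. Metrics (mean degree, degree sd,
  assortativity) come from igraph; degree assortativity is legitimately
  undefined on degree-regular graphs and is then missing-with-reason.

Every non-linear estimator is verified against an independent brute-force
oracle (naive triple-loop template counting; all-pairs line-of-sight
checks) on short seeded series, where exact agreement is required.

## The maturation-age model

The published description combines "logistic and random forest
regressions" for a *continuous* age target. The package reads the
logistic component as a **generalized-logistic (bounded sigmoid) growth
curve**, the natural interpretation for an age regressor:
$\mathrm{PMA} = L + (U-L)\,\mathrm{logit}^{-1}(\beta_0 + x^\top\beta)$,
with asymptotes fitted within [22, 45] weeks (Levenberg–Marquardt, with a
fixed-asymptote linearized fallback). The second component is a random
forest (`ranger`, 500 trees by default). The ensemble is their
equal-weight mean (configurable; the source is silent on the
combination), so predictions are convex combinations bounded by the
components. Rows are canonically sorted before fitting, making the fit
invariant to input row order despite bootstrap sampling.

Feature selection follows the genetic-algorithm scheme: fixed-size
subsets, tournament selection, union-sampling crossover, single-swap
mutation, elitism. Fitness is the grouped 5-fold cross-validated MAE of
the ensemble (patients never split across folds), with a 50–100-tree
forest inside the loop for tractability; full grouped leave-one-out CV is
reserved for final evaluation. On the benchmark with three informative
features among seventeen noise features, a population of 20 over 15
generations recovers all informative features in ≥ 95% of seeded runs —
smaller budgets (16 × 10) occasionally miss one.

Evaluation is **grouped LOOCV**: one fold per infant, all of whose
segments are predicted by a model trained on everyone else. Per
infant-week FMA is the median of that week's segment predictions, robust
to unequal segment counts.

## The delay trajectory model

`delta = PMA − FMA`, positive meaning delay — the sign convention under
which all calibrations and tables are stated. Before modelling, each
patient's FMA values pass once through Tukey fences
($[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$, type-7
linear-interpolation quartiles — the most common convention, fixed for
reproducibility; fences are frozen from the original values so the pass
is idempotent by construction).

The mixed model uses all retained delta observations with PMA in
[32, 36]:

$$\delta_{ij} = \beta_0 + \beta_1(\mathrm{PMA}_{ij} - 34)
 + \beta_2\,\mathrm{IUGR}_i + \beta_3\,\mathrm{BPD}_i
 + \beta_4\,\mathrm{lesions}_i + \beta_5\,\mathrm{PDA}_i
 + b_i + \varepsilon_{ij},$$

random intercept $b_i$ per patient, REML (lme4). GA is deliberately *not*
a covariate — it already enters the FMA estimator. Random slopes exist
behind a flag but are off by default, matching the random-intercept
reading of "patient as a random effect"; a singular fit falls back to
fixed effects with a warning. `delta34` is the **conditional** (BLUP)
prediction at PMA = 34 with the patient's own covariates — the
patient-specific quantity the downstream analyses need; marginal
predictions are available via `conditional = FALSE`. Conditional
predictions shrink toward the covariate-adjusted population line as a
patient's observation count falls, a property the tests check
monotonically.

## ASQ-3 scoring and cohort analyses

Items score yes = 10 / sometimes = 5 / not yet = 0; six items per domain
(implied by the 0–60 range); domain abnormal below 35 (communication) or
25 (others); with one or two missing items the adjusted score is the mean
of answered items × 6 (the documented behaviour of the standard scoring
tool), more than two missing undefines the domain; total = sum of five
domains, abnormal ≤ 220; records completed outside 21–26 months of
corrected age are flagged non-analyzable.

Group comparisons default to rank tests (Mann–Whitney–Wilcoxon /
Kruskal–Wallis) because the descriptive statistics are medians and
quartiles; parametric equivalents sit behind `parametric = TRUE`.
Contingency tables dispatch to Fisher's exact test whenever any expected
cell count is below 5, else chi-square; the choice is a pure function of
the data and is reported. Univariate logistic regression reports ML odds
ratios with Wald CIs and detects separation instead of diverging
silently. Multivariable adjustment is deliberately not a default:
with the sparse outcome counts this design targets, univariate reporting
is the honest granularity.

## Problem sizes and numerical choices

The validation suite runs at sizes chosen to make Monte-Carlo tolerances
meaningful while staying desk-scale: 200 cohorts × 500 infants for
odds-ratio recovery (tolerance ±0.15 around 2.05); 1000 infants × 5
visits for the trajectory medians (±0.2 weeks around 2.3 and 1.3); 100
replicates of 200 patients × 5 visits for mixed-model CI coverage
(≥ 90%); 40 patients × 3 segments with 0.5-week feature noise for the
LOOCV error floor (≤ 1.0 week); 20 seeded GA runs on the
3-informative/17-noise benchmark. Oracle-equivalence checks use ≤
100-point series where brute force is exact.

Degenerate inputs are handled explicitly rather than by NaN propagation:
constant series (zero variance, absolute entropy tolerance, zero band
power), all-identical outlier sets (zero IQR ⇒ nothing removed), zero HF
power (missing ratio with reason), degree-regular visibility graphs
(missing assortativity with reason), singular mixed fits (fixed-effect
fallback), logistic separation (flagged sentinel).

## Known limitations

* The synthetic RR process is stationary within a recording; it does not
  simulate sleep states, drug effects, sepsis dynamics, or raw ECG
  waveforms, and the pipeline starts at beat intervals (no QRS
  detection).
* The feature set is a ~20-feature superset of the families named in the
  source work; the exact features and trained weights of the original
  estimator are not reproduced — the model is retrained on synthetic
  data, so absolute FMA errors are not comparable to published MAEs.
* The delay spread's log-normal form, the quality thresholds, the
  ensemble weights and the GA budget are package choices, stated above,
  configurable, and fixed once.
* Generated covariates are mutually independent given the configured
  prevalences; real perinatal complications co-occur (e.g. PDA with low
  GA), so confounding structure in real cohorts is not emulated.
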