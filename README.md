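# neomat

Heart-rate-variability maturation age and the 34-week delay biomarker for
very preterm infants.

## What this package does

In infants born before 30 weeks of gestation, the maturation of the
central autonomic network can be tracked non-invasively through heart
rate variability (HRV). `neomat` implements the full analysis pipeline
around that idea:

* **RR ingestion** — read beat-interval files, flag artifacts against a
  centered 11-beat running median (±20%), and cut recordings into
  contiguous 30-minute good-quality segments.
* **HRV features** — a 19-feature bank per segment: time domain (SDNN,
  RMSSD, pNNx, ...), Lomb–Scargle band powers in neonatal bands (LF
  0.04–0.2 Hz, HF 0.2–2.0 Hz), Poincaré SD1/SD2, sample entropy,
  detrended fluctuation exponents and natural-visibility-graph metrics.
* **Functional maturation age (FMA)** — a genetic algorithm selects a
  feature subset; an ensemble of a generalized-logistic (bounded sigmoid)
  regression and a random forest maps features + gestational age to
  post-menstrual age (PMA); evaluation is leave-one-out cross-validation
  grouped by infant.
* **Delay trajectories** — the biomarker is `ΔHRV = PMA − FMA` (weeks;
  positive = delayed). Per-infant FMA outliers are removed by Tukey IQR
  fences, all observations in the 32–36-week PMA window enter a linear
  mixed-effects model (`Δ ~ (PMA−34) + IUGR + BPD + lesions + PDA`,
  random intercept per infant), and each infant's delay is interpolated
  at 34 weeks PMA as a conditional (BLUP) prediction.
* **Cohort analysis** — ASQ-3 questionnaire scoring (10/5/0-point items,
  domain thresholds 35/25, total ≤ 220 abnormal, missing-item
  adjustment), descriptive tables of `delta34` by perinatal factors
  (rank tests, Fisher/chi-square dispatch by expected counts), and
  univariate logistic odds ratios for abnormal outcomes.
* **Synthetic data** — generators for maturing neonatal RR series,
  preterm cohorts with realistic covariate prevalences, latent delay
  distributions calibrated per gestational-age stratum (medians
  3.0/2.3/1.3 weeks), and ASQ outcomes following configured logistic
  effects (personal-social OR 2.05 per week of delay). Everything
  downstream is developed and validated against these generators.

See `vignettes/neomat-methods.Rmd` for the model conventions and every
numerical choice.

## Worked example

```r
library(neomat)

## one synthetic recording -> segment -> features
s <- generate_rr_series(rr_gen_config(pma_weeks = 34, duration_s = 2100,
                                      seed = 1), "demo")
segs <- segment_series(s)
segs[[1]]
#> <rr_segment> patient demo [0, 1800) s: 4458 clean beats, quality 0.980
extract_features(segs[[1]], c("mean_nn", "sdnn", "rmssd", "sampen",
                              "dfa_alpha1", "vg_mean_degree"))
#> <hrv_features> patient demo, PMA 34 wk
#>        mean_nn           sdnn          rmssd         sampen     dfa_alpha1
#>        393.845         11.801         15.048          2.173          0.635
#> vg_mean_degree
#>          5.967

## a 132-infant synthetic cohort through the trajectory stage
co  <- generate_cohort(cohort_gen_config(n_infants = 132, seed = 8))
obs <- generate_trajectories(co, 32:36, seed = 9)
obs <- merge(obs, co[c("patient_id", "iugr", "bpd", "neuro_lesions",
                       "pda")], by = "patient_id")
res <- delta_trajectory(obs)
res$model
#> <delta_model> 645 obs, 132 patients, PMA 32-36 wk
#>            term estimate      se ci_low ci_high
#> 1   (Intercept)    2.206 0.36798  1.485   2.927
#> 2         pma_c    0.311 0.00831  0.295   0.328
#> 3          iugr   -0.515 0.41854 -1.335   0.306
#> 4           bpd    0.427 0.38328 -0.324   1.179
#> 5 neuro_lesions   -0.312 0.41387 -1.123   0.499
#> 6           pda    0.638 0.37095 -0.089   1.365

co$delta34_weeks <- res$delta34$delta34_weeks[
  match(co$patient_id, res$delta34$patient_id)]
build_table1(co, variables = c("ga_stratum", "bpd", "pda"))[, 1:7]
#>     variable category  n percent median    q1   q3
#> 1 ga_stratum     lt26 30    22.7   2.96 2.322 3.95
#> 2 ga_stratum  ga26_28 55    41.7   2.34 1.643 3.67
#> 3 ga_stratum     ge28 47    35.6   1.20 0.790 1.92
#> 4        bpd        0 90    68.2   1.97 1.042 3.38
#> 5        bpd        1 42    31.8   2.47 1.620 3.41
#> 6        pda        0 50    37.9   1.69 0.825 2.94
#> 7        pda        1 82    62.1   2.27 1.601 3.56
```

Reading the output: the mixed model sees the delay growing by ≈ 0.31
weeks per week of PMA; at 34 weeks the least mature stratum (< 26 weeks
GA) sits around 3.0 weeks of delay and the most mature (≥ 28 weeks)
around 1.2. At n = 132 the per-infant ASQ odds-ratio estimate is noisy —
`logistic_or(co, "asq_personal_social_abnormal", "delta34_weeks")` on
this draw gives OR 4.82 [0.86; 26.93] from only 3 events — which is why
the validation suite measures effect-size recovery across 200 cohorts.

The whole pipeline (generate → ingest → features → train → trajectory →
cohort report) also runs end to end from a single config:

```r
manifest <- run_pipeline(run_config(out_dir = "run1", n_infants = 30,
                                    seed = 17))
write_report("run1")   # markdown report with tables + model summaries
```

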