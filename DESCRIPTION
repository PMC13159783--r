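Package: neomat
Title: Heart Rate Variability Maturation Age and Delay Biomarkers for Very
    Preterm Infants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Estimates a functional maturation age (FMA) of the central
    autonomic network in very preterm infants from beat-interval (RR) time
    series. Provides RR ingestion, artifact cleaning and 30-minute
    segmentation; a bank of time-domain, frequency-domain and non-linear
    heart rate variability features (sample entropy, detrended fluctuation
    analysis, Poincare geometry, natural visibility graphs, Lomb-Scargle
    band powers); genetic-algorithm feature selection with a combined
    generalized-logistic and random-forest age regressor evaluated by
    grouped leave-one-out cross-validation; conversion of FMA to the
    maturation-delay biomarker (delta = post-menstrual age minus FMA) with
    interquartile-fence outlier removal, a covariate-adjusted linear
    mixed-effects trajectory model over 32-36 weeks and patient-level
    interpolation at 34 weeks; Ages and Stages Questionnaire (ASQ-3)
    scoring and cohort association analyses; and a synthetic-data module
    that emulates maturing neonatal RR series and preterm cohorts so the
    whole pipeline is testable without access to monitor recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    ranger,
    igraph,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
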