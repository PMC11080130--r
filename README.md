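# semgscreen

Sarcopenia screening from forearm surface electromyography (sEMG), end to
end and fully reproducible: a motor-unit-pool signal simulator, zero-phase
preprocessing, nine-feature extraction with MVC normalization,
nonparametric group statistics, a sensitivity-weighted soft-voting
classifier under subject-level cross-validation, and Shapley feature
impacts.

## The problem

Sarcopenia - age-related loss of muscle mass and function - is screened
with the AWGS 2019 rule from skeletal-muscle index, grip strength and
chair-stand time.  Those measurements are slow and equipment-bound.
Because motor-unit loss, reinnervation and neuromuscular-junction
instability all alter the interference EMG, a short grip protocol with
surface electrodes is an attractive community-level alternative: record
six forearm channels at 2000 Hz during maximal (MVC) and sub-maximal
(20%, 50% MVC) grips, extract features, classify.

This package is aimed at biosignal and rehabilitation researchers who
want that pipeline as tested, reusable R functions - including a
physiologically grounded synthetic cohort so every stage can be exercised
without access to clinical recordings.

## The method

Per 200-ms window (50-ms step, on an automatically selected stationary
3-s segment of each filtered trial) nine features are computed per
channel: the Hudgins time-domain set - RMS, MAV, iEMG, waveform length
(WL), zero crossings (ZC), slope sign changes (SSC) - and three features
of the Morlet continuous wavelet transform

> C(a, b) = a^(-1/2) ∑ₜ x(t) ψ*((t − b)/a),  ψ(t) = e^{iω₀t} e^{−t²/2}, ω₀ = 5,

at scales a ∈ {3.6, 4.6, ..., 62.6}: mean wavelet power, wavelet entropy
WE = −∑ₐ hₐ ln hₐ of the per-scale power distribution, and the
bias-corrected excess kurtosis of the kernel-density estimate of the
pooled coefficient moduli.  Features are normalized channel-wise by the
subject's mean MVC feature values, compared across groups with
Mann-Whitney U tests (Wilcoxon signed-rank between force levels), and fed
to a soft-voting ensemble

> ŷ = argmax_j ∑ᵢ wᵢ P_{i,j},  i ∈ {linear SVM, random forest, GBM},

whose weights wᵢ are grid-searched for maximal training sensitivity.
Evaluation is balanced subject-level 5-fold cross-validation with pooled
ROC/AUC and an optimal operating point constrained to specificity
above 0.65.  Shapley values on the ensemble score attribute the decision
to individual features.

## A worked example

Simulate a 20-subject cohort with the default sarcopenic contrast
(motor-unit count halved, action potentials 1.6x larger, discharge
jitter doubled), run the whole pipeline, and inspect the result:

```r
library(semgscreen)
cfg <- simulation_config(n_healthy = 10, n_sarcopenic = 10, seed = 7)
res <- run_screening_pipeline(cfg)
res$cv
#> Subject-level 5 fold cross-validation
#>   accuracy    1.000 (+/- 0.000)
#>   sensitivity 1.000 (+/- 0.000)
#>   specificity 1.000 (+/- 0.000)
#>   f1          1.000 (+/- 0.000)
#>   AUC         1.000
#>   OOP         sensitivity 1.000 at specificity 1.000
```

The per-fold mean metrics and pooled AUC are all 1 here: at this contrast
the MVC-normalized amplitude features separate the simulated groups
almost completely (real cohorts are far harder).  The statistical report
mirrors that - amplitude features separate at both force levels while
wavelet entropy is the weakest feature:

```r
res$comparisons[res$comparisons$feature %in% c("RMS", "WL", "WE") &
                grepl("group", res$comparisons$comparison), ]
#>  feature comparison           test statistic        p significant
#>      RMS  group@0.2 Mann-Whitney U         0 1.08e-05        TRUE
#>      RMS  group@0.5 Mann-Whitney U         0 1.08e-05        TRUE
#>       WE  group@0.2 Mann-Whitney U        86 5.20e-03        TRUE
#>       WE  group@0.5 Mann-Whitney U        65 2.80e-01       FALSE
#>      WL  group@0.2 Mann-Whitney U          0 1.08e-05        TRUE
#>      WL  group@0.5 Mann-Whitney U          0 1.08e-05        TRUE
```

A Mann-Whitney statistic of 0 means complete separation of the two
groups' subject-level feature values; p ≈ 1.1e-05 is the exact two-sided
permutation p-value at 10 + 10 subjects.

The methods vignette (`vignettes/semg-sarcopenia-screening.Rmd`) explains
the motor-unit model, every tunable parameter and all numerical choices.

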