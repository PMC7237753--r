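# trflab

Analysis pipeline for **time-resolved fluorescence (TRF) optical biopsy**
of tissue: recovering fluorescence decay kinetics per emission wavelength
and classifying tissue types from the resulting lifetime/intensity
signatures.

## The problem and who this is for

Tissue autofluorescence carries biochemical contrast: endogenous
fluorophores (collagen, elastin, NADH, FAD) differ between tissue types
more in their nanosecond decay kinetics than in their broad, overlapping
emission spectra. TRF point spectroscopy therefore records, at each
emission wavelength λ (360–550 nm, 5 nm steps), the decay `y(n)` of
fluorescence after a short excitation pulse `p(n)`:

    y(n) = dt · Σ_m p(m) h(n−m) + ε(n)

where `h(n)` is the tissue's intrinsic fluorescence impulse response.
`trflab` is for spectroscopists and biomedical-optics researchers who
need the full analysis chain behind such measurements:

1. **Laguerre deconvolution** — `h` is expanded on `L` orthonormal
   discrete Laguerre functions `b_j(n; α)` so that deconvolution reduces
   to ordinary least squares on the pulse-convolved basis,
   `min_c ‖y − Vc‖²`, `h = Σ_j c_j b_j`, with a residual-driven,
   tie-robust choice of the scale α per curve.
2. **Moment estimators** — average lifetime
   `τ_avg = dt · Σ_n n·h(n) / Σ_n h(n)` and integrated intensity
   `mean(h)` per wavelength.
3. **Feature screening** — 37 max-normalized intensity + 37 lifetime
   features (370–550 nm); one-way ANOVA (p < 0.05) then Pearson
   de-duplication (|r| ≥ 0.5 keeps the smaller-p feature).
4. **Classification** — greedy forward feature selection wrapped around a
   linear SVM (inverse-frequency class weights), leave-one-out
   cross-validation, sensitivity/specificity, and ROC/AUC from pooled
   LOOCV decision scores (midrank ties, so AUC = Mann–Whitney U/(n₊n₋)).

A **synthetic cohort generator** emulates an upper-GI biopsy study — 78
specimens across duodenum, antrum, stomach body, normal esophagus,
esophagitis and dysplastic Barrett's esophagus, with class-specific
lifetime-vs-wavelength curves, shared 455 nm-peaked spectra, a 0.3 ns
excitation pulse, and sweep-averaged Gaussian noise at 4–20 dB — so the
entire pipeline runs and is tested without any clinical data.

## Worked example

```r
library(trflab)

study <- runStudy(pipelineConfig(seed = 1))
#> [trflab] simulate        5.6 s
#> [trflab] deconvolve      4.6 s
#> [trflab] feature table: 78 specimens x 74 features
#> ...
study$evaluations$duodenum_vs_esophagus
#> ClassifierEvaluation: duodenum vs esophagus_normal
#>   selected features: intensity_375, intensity_490, intensity_410, lifetime_545
#>   sensitivity 1 , specificity 1 , AUC 1
```

What this means: the generator produced the 78-specimen cohort, every
decay was deconvolved (per-wavelength lifetime recovered with ~3% median
relative error against the generator's ground truth at the cohort's 4–20
dB noise), and the duodenum-vs-normal-esophagus task — after screening
and forward selection picked a handful of spectral and lifetime features
— separated the held-out specimens essentially perfectly at this seed.
Class pairs whose lifetime curves overlap within a specimen's spread
(duodenum vs esophagus at other seeds) land nearer sensitivity 0.93 /
specificity 0.88 / AUC 0.98.

Lower-level entry points: `simulateCohort()`, `processCohort()` /
`processSpecimen()`, `buildFeatureTable()`, `screenFeatures()`,
`runTask()`; see the package vignette for the models, conventions and
design choices, and `inst/scripts/trf-pipeline.R` for a thin command-line
wrapper (`simulate` / `run-all` subcommands).

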