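---
title: "Time-resolved fluorescence optical biopsy: models, estimators and design choices"
author: "trflab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved fluorescence optical biopsy: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement and the analysis problem

Time-resolved fluorescence (TRF) point spectroscopy excites tissue with a
short laser pulse (here a 0.3 ns FWHM pulse at 355 nm) and records the
nanosecond-scale decay of autofluorescence at each emission wavelength,
360–550 nm in 5 nm steps. The recorded decay `y(n)` at one wavelength is
the causal discrete convolution of the excitation pulse `p(n)` with the
tissue's intrinsic fluorescence impulse response `h(n)` — the decay that
would be seen under instantaneous excitation — plus detector noise:

    y(n) = dt * sum_m p(m) h(n - m) + e(n).

Endogenous fluorophores (collagen, elastin, NADH, FAD) differ between
upper-GI tissue types more in their decay kinetics than in their emission
spectra, so the analysis recovers `h` per wavelength, summarizes it by two
scalars — the first-moment **average lifetime**

    tau_avg = dt * sum_n n h(n) / sum_n h(n)

and the **integrated intensity** `mean(h)` — and classifies tissue types
from the resulting per-wavelength feature vectors.

`trflab` implements that pipeline end to end, together with a synthetic
cohort generator that emulates the study conditions (cohort of 78 biopsy
specimens: 27 duodenum, 5 antrum, 19 stomach body, 16 normal esophagus,
8 esophagitis, 3 dysplastic Barrett's esophagus) so every stage is
testable without clinical data.

## Laguerre deconvolution

Naive numerical deconvolution amplifies noise; instead `h` is expanded on
`L` orthonormal discrete Laguerre functions `b_j(n; alpha)`, turning
deconvolution into ordinary least squares on the pulse-convolved basis
`v_j = dt * (p * b_j)`:

    min_c || y - V c ||^2,   h = sum_j c_j b_j.

The basis is built by the numerically stable two-term recursion
`b_j(n) = sqrt(a) b_j(n-1) + sqrt(a) b_{j-1}(n) - b_{j-1}(n-1)` seeded by
`b_0(n) = sqrt(1-a) a^(n/2)`; the factorial closed form overflows at
record lengths of a few thousand samples. The functions are orthonormal
on the infinite grid. When `alpha` is large enough that appreciable tail
mass lies beyond the record (at the default grid this begins around
`alpha = 0.96`), a finite-grid QR re-orthonormalization is applied; it
preserves the span — and least-squares fits depend only on the span — and
is an exact no-op for fully decayed bases.

### Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `nSamples`, `dt` | 2000, 0.025 ns | 50 ns record: resolves the 0.3 ns pulse and spans >10 lifetimes of the slowest (~3.5 ns) decay |
| `order` (L) | 12 | low order is the de-facto regularizer of the unconstrained fit |
| `alphaGrid` | 0.80–0.98 step 0.02 | basis time-scale search range |
| `tieBand` | 0.005 | residual-norm band treated as a statistical tie in scale selection |

### Scale selection

The Laguerre scale is chosen per curve by residual norm, but *not* by the
bare minimum. For fixed `L` every candidate scale fits the same number of
parameters, so on noisy data the expected residual differences between
all scales that can represent the decay are zero; the bare minimizer is
decided by noise and drifts toward large `alpha`, where the long-tailed
basis inflates the variance of the first-moment lifetime. Conversely,
scales that are clearly too fast truncate the decay and bias the lifetime
down sharply while costing almost nothing in residual. `selectAlpha()`
therefore treats all scales whose residual norms lie within a relative
band `tieBand` of the minimum as statistically tied — the band
corresponds to roughly three standard deviations of the chi-square
fluctuation of RSS differences between same-order projections,
`3 * sqrt(4L) / N` on the RSS scale — and returns the central scale of
the tied band. On noiseless data the band collapses to the plain
minimizer, so exact-recovery behaviour is unchanged; an exact two-way tie
resolves to the smaller scale.

### Estimator conventions and degenerate input

The lifetime is evaluated over the whole record with `T = dt`, negative
excursions of the unconstrained fit included; no smoothing, no
truncation. A fit whose total `sum(h)` is nonpositive cannot yield a
meaningful lifetime and is flagged `"unfittable"` (error class
`trflab_degenerate_decay`) rather than silently dropped or reported as a
negative lifetime. The integrated intensity is the arithmetic mean of `h`
over the record; the time-integral convention differs only by the fixed
factor `N * dt`, and intensities are max-normalized per specimen before
any downstream use, so the choice is immaterial. No background term is
fitted by default (the generator produces baseline-free data); a
constant-baseline column can be added via the deconvolution settings.

At moderate noise the estimator carries a small negative bias (2–4% at a
10 dB single-sweep SNR with ten-sweep averaging): the selected scale
slightly truncates the tail that the first moment weights most. This is
a property of the moment estimator on an unconstrained fit, visible in
the class-mean lifetimes the acceptance script reports.

## The synthetic cohort generator

The generator defines the study conditions; its defaults are not meant to
be tuned.

* **Excitation pulse** — Gaussian, 0.3 ns FWHM, centered at 2 ns,
  peak-normalized.
* **Class lifetime curves** — each tissue class has an anchor lifetime at
  an anchor wavelength and a terminal lifetime at 520 nm, following the
  published class curves (stomach body 3.13 ns at 380 nm to 2.12 ns at
  520 nm; antrum 3.25 at 385 to 2.58; duodenum falling to 2.79 at 520;
  esophagitis peaking at 3.46 at 390; dysplastic Barrett's flat at 3.09).
  Interpolation between the anchors is linear in wavelength — only the
  endpoints are constrained — with constant extension beyond them. Normal
  esophagus is modelled flat at 3.10 ns (its curve is described only as
  minimally varying); its between-specimen SD, nowhere reported, is set
  to 0.10 ns, a mid-range value among the derived class spreads.
* **Between-specimen spread** — one rigid lifetime-curve offset per
  specimen, Normal(0, SD), with SD = SE * sqrt(n) converting the reported
  standard errors of class means to population spread (e.g. stomach body
  0.03 * sqrt(19) ≈ 0.13 ns). No per-wavelength jitter beyond noise: the
  smallest assumption producing realistic between-specimen variance.
* **Spectra** — a Gaussian emission band peaking at 455 nm (width 55 nm)
  for every class; esophagitis and dysplastic Barrett's add a
  multiplicative short-wavelength enhancement band (Gaussian at 400 nm)
  reflecting their reported 375–450 nm enrichment, sized so the 455 nm
  peak remains the spectral maximum. The kernel peak is scaled to the
  spectrum value; the *measured* steady-state intensity `mean(h)` is
  therefore proportional to amplitude × lifetime, so classes whose
  lifetime falls with wavelength show their intensity-spectrum peak one
  5 nm bin blue of 455 — a physically faithful consequence worth knowing
  when comparing recovered spectra to the amplitude model.
* **Kinetics** — mono-exponential per wavelength by default; kinetic
  order is not reported. A bi-exponential mode (fixed 60/40 amplitude
  split, fast component at 0.6 of the target lifetime, slow component
  solved so the mixture's discrete first moment matches the target) is
  available for robustness checks. The kernel's *discrete* first moment
  equals `dt*r/(1-r)`, `r = exp(-dt/tau)` — the discrete analog of the
  target, about `dt/2` below the continuous value — and the ground-truth
  table records the exact on-grid value so recovery is measured against
  the right quantity.
* **Noise** — additive i.i.d. Gaussian; the SNR convention (nowhere
  defined in the source) is peak-signal/sigma in dB for a single sweep,
  recorded in the dataset metadata. Each returned curve is the mean of
  10 independently noisy sweeps, emulating post-digitization sweep
  averaging (pre- vs post-digitization averaging is indistinguishable
  for this noise model). Per-curve SNR is drawn uniformly from 4–20 dB.

What the generator does **not** emulate: detector nonlinearity and
photon-counting statistics, the acousto-optic filter's transmission
profile, photobleaching, probe-geometry effects, and any wavelength
correlation of noise. Passing tests therefore demonstrate correctness of
the estimators and the pipeline under the stated noise model, not
robustness to every instrumental artifact of real measurements.

## Feature construction and screening

Each specimen contributes 37 normalized-intensity and 37 lifetime
features on 370–550 nm (the two shortest acquisition wavelengths are
dropped at table construction, matching the stated 37-per-kind feature
count). Intensity vectors are divided by their own maximum — the
published spectra are shown normalized, and per-specimen normalization
removes acquisition-geometry scale; lifetimes stay in ns. Specimens with
any unfittable wavelength are excluded with a logged warning.

Screening is two-stage, run per classification task on the two classes
being compared (matching the pairwise reporting of the source; a pooled
mode across all classes is available):

1. **One-way ANOVA** per feature; significant = p < 0.05. Features
   constant across specimens get p = 1 so degenerate inputs never abort
   a run. No multiple-testing correction is applied (none was applied in
   the source).
2. **Pearson de-duplication**: walking the significant features by
   ascending p, a feature is dropped when its absolute correlation with
   an already-retained feature reaches 0.5. The source text's wording on
   the correlation rule inverts itself; the standard redundancy reading
   (high |r| means redundant, keep the smaller p) is implemented.
   Absolute correlation is used: anticorrelated features are equally
   redundant.

A consequence worth stating plainly: when two classes differ only in
lifetime, intensity features still enter the retained set occasionally —
they are p < 0.05 false positives, expected at the 5% rate across 37
null features precisely because no multiplicity correction is applied.
The tests assert the faithful property (lifetime features dominate with
the smallest p-values; intensity retentions stay within the
false-positive budget), not the impossible one (zero intensity
retentions with high probability).

## Classification and evaluation

Each pairwise task trains a linear SVM (cost 1; classes weighted
inversely to training-fold frequency — the cohort is imbalanced, e.g. 3
dysplastic Barrett's vs 16 normal esophagus). Features are z-scored
inside every leave-one-out fold using training-fold statistics only.
Forward selection adds, at each step, the candidate maximizing LOOCV
balanced accuracy (robust to imbalance), stopping at the first
non-improving step or at 6 features; ties break by screening p-value,
then by column order. Selection runs independently within the intensity
and lifetime catalogs and the union is evaluated, mirroring the
per-catalog reporting style of the source (a joint mode is available).
The ROC is built from the pooled LOOCV decision scores with the midrank
convention for ties, so the trapezoidal AUC equals the Mann–Whitney
statistic; sensitivity and specificity come from the held-out hard
predictions.

If screening retains nothing, or selection keeps nothing, the task
reports a **no-signal null model**: majority-class predictions,
all-zero scores, AUC exactly 0.5. Evaluating a feature that failed its
own significance gate would contradict the screening design.

### A known, deliberate limitation: selection optimism

Screening and forward selection run *outside* the LOOCV whose pooled
scores form the reported ROC — that is the pipeline structure being
reimplemented. The consequence is measurable: on label-permuted data the
full pipeline's mean AUC is about 0.65–0.70, not 0.5, because the
max-over-candidates selection step is optimistically biased when it can
see the same folds it is evaluated on. The fixed-subset LOOCV core is
leakage-free (its permutation null sits at chance, as the tests assert);
only the end-to-end figure inherits the optimism. Nesting the entire
selection inside an outer cross-validation loop would remove it, at the
price of no longer implementing the method under study. Reported
near-perfect task metrics on the default synthetic cohort should be read
with this in mind — though for the well-separated class pairs the truth
is genuinely separable, and the duodenum-vs-esophagus pair (whose class
curves overlap within a specimen SD) lands at sensitivity ~0.93,
specificity ~0.88, AUC ~0.98, close to the source's in-vitro figures for
the same pair.

## Numerical choices and degenerate inputs

* Convolutions are FFT-based with zero padding to the next power of two;
  the direct summation agrees to 1e-10 and is kept as a test oracle.
* The least-squares system is solved by QR; a rank-deficient
  pulse-convolved basis (e.g. an all-zero pulse) raises a singular-system
  error naming the cause.
* Exact ties in forward selection and scale selection resolve by fixed,
  documented orders so every run is bit-reproducible; all randomness
  derives from the single top-level seed.
* Problem sizes used by the test-suite and acceptance runs: the full
  78-specimen cohort on the default 2000-sample grid (about 15 s end to
  end on one CPU), 100-replicate Monte-Carlo noise sweeps for the
  recovery properties, and 20 label permutations for the null control.

## Reproducing a study

```{r}
library(trflab)
study <- runStudy(pipelineConfig(seed = 1), outdir = "trflab_out")
study$evaluations$duodenum_vs_esophagus
```

`trflab_out/` then contains the lifetime table, the feature table, one
YAML report per task, the configuration and a manifest (seed, config
hash, versions) sufficient to reproduce the run byte-for-byte.
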