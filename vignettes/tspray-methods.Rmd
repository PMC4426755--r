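---
title: "Methods: simulating and classifying tissue-spray MS fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying tissue-spray MS fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tspray)
```

## The problem

Tissue-spray ionization mass spectrometry (TSI-MS) records a lipid-dominated
positive-ion fingerprint directly from a ~1 mm³ tissue piece in seconds. For
lung squamous cell carcinoma, the fingerprints of tumor tissue and adjacent
normal tissue differ systematically in a handful of m/z channels, most of
them sodium adducts of pulmonary-surfactant phosphatidylcholines (DPPC at
m/z 757.47, POPC 782.52, DOPC 808.49, SAPC 832.43) plus low-mass ions at
m/z 154.03, 170.06, 203.08 and a phospholipid at 798.90. `tspray`
reimplements the downstream chemometric analysis of such data — binning,
relative-abundance matrix construction, PLS-LDA with Monte Carlo sampling
cross-validation, CARS variable selection, and univariate peak statistics —
together with a synthetic cohort generator, because the original patient
spectra are not publicly deposited.

## The synthetic cohort: a stated world

`generate_cohort()` simulates `n_pairs` matched patients, each contributing
one cancer and one normal tissue, with `replicates_per_tissue` spray
replicates per tissue (defaults 38 and 5, i.e. 380 spectra). The model is
hierarchical:

* **Tissue level.** Each of the eight discriminating features has a
  published per-class mean ± SD relative abundance (percent of base peak);
  `default_peak_params()` carries them verbatim. A tissue's latent abundance
  is drawn from a normal with those moments, truncated at zero. The
  truncation matches the mean ± SD reporting convention while keeping
  abundances positive; at the given effect sizes (means 2–3 SDs above zero)
  the induced upward bias on the mean is below 0.07 percentage points.
* **Replicate level.** Each spray replicate multiplies the tissue abundance
  by lognormal noise with unit mean and coefficient of variation
  `replicate_rsd` (default 0.18, the reported replicate reproducibility of
  the tumor-tissue surfactant ions, RSD ≈ 18%). A lognormal is used so
  intensities stay strictly positive under arbitrarily large noise.
* **Background.** 40 uninformative peaks are placed uniformly over
  m/z 100–1000, at least 0.5 Th away from the feature and base-peak
  positions (so 1.0-Th bins keep the diagnostic channels uncontaminated —
  the generator emulates resolved centroids, not chimeric bins), with
  per-tissue abundances uniform in (0, 2]%. They make variable selection
  nontrivial without carrying class information.
* **Spectrum level.** A synthetic anchor peak at m/z 760.59 is fixed at
  100% relative abundance (the printed abundances of 1–7% are far below
  100, consistent with the standard percent-of-base-peak convention); the
  absolute intensity scale varies uniformly by ±`intensity_drift` (default
  0.30, the reported within-spray total-ion variation); every peak position
  is jittered by ±0.005 Th per spectrum so the 0.01-Th and 1.0-Th bin sizes
  genuinely behave differently.

Matched-pair correlation between a patient's two tissues is *not* modelled:
no covariance is published, so tissues are drawn independently. Real data
also contain hundreds of correlated lipid peaks, chemical noise, and
isotope structure that this generator does not emulate; a green test
therefore establishes that the pipeline machinery is correct and calibrated
to the printed class parameters, not that real tissue would classify at the
same accuracy.

Replicate noise enters the *relative* abundances directly (the base peak is
not jittered): `replicate_rsd` is then exactly the population CV of a
feature across replicates, which is what a per-tissue RSD over five sprays
estimates. Note the n = 5 sample SD is biased low (c₄(5) ≈ 0.94), so the
measured mean RSD sits near 16.5–17.5% for a configured 18.17% — the same
small-sample bias the original five-replicate RSDs carry.

## Preprocessing

Spectra are rescaled so the base peak is 100 (`to_relative_abundance`),
then summed into half-open, left-closed bins `[edge, edge + width)`
anchored at the grid's low edge (`bin_spectrum`); an edge tie goes to the
upper bin. Summing (not maxing) conserves total abundance across bin
widths, which the tests assert. The analysis grid defaults to m/z 100–1000
at 1.0 Th — the low-resolution setting; 0.01 Th is the high-resolution
one — although acquisition ranges are wider. Normalisation happens *before*
binning (switchable via `normalize =`); with sum-binning and one base peak
per spectrum the two orders differ only when the base peak shares a bin
with another peak. Zero-variance columns are retained in the matrix but
removed (with a reported count) before PLS, where they are degenerate.

## PLS-LDA

`fit_pls()` implements NIPALS PLS1: the response is the class coded +1/−1,
each weight vector is proportional to the covariance X'y of the deflated
data, and successive score vectors are orthogonal (asserted to 1e-8).
Columns are mean-centered only; relative abundances share a scale, so
autoscaling is off by default (available via `scale = TRUE`). The
projection matrix R = W(P'W)⁻¹ reproduces scores from centered data, which
is what `predict()` uses.

`fit_lda()` runs Fisher LDA on the latent scores: axis S_w⁻¹(μ₁ − μ₂) with
the pooled within-class covariance regularised by λI, λ = 1e-8·tr(S_w)/d,
when near-singular (CV subsets can be ill-conditioned even when the full
data are not; if the scatter is exactly zero λ falls back to a scale set by
the mean separation). Classification uses the linear discriminant
functions with class-proportion priors; exact ties go to the larger prior,
then lexicographic label order. With two classes Fisher LDA yields a
single axis; score plots therefore show the first two *PLS* scores, and the
LDA object carries a second display axis (top within-class-whitened
variance direction) purely for visualisation.

The classifier default is 5 components, the setting reported to give the
best discrimination.

## Monte Carlo cross-validation

`mc_cross_validate()` draws `n_samplings` (default 35, inside the reported
30–40) random 80/20 train/test splits, refits PLS-LDA per split, and
predicts the complement. Two summaries are reported side by side because
the published "best accuracy 94.42%" and "misclassification 6.58%" cannot
be complements of one summary: the *pooled* misclassification over all
held-out predictions (the headline) and the *best* per-sampling accuracy.
The split unit defaults to `tissue` — all five replicates of a tissue move
together — because replicate-level splitting leaks near-copies of test
spectra into training; replicate-level splitting remains available to mimic
a literal reading of "380 data points". The per-split training row indices
are kept on the result so leakage can be audited directly, and the tests
do so. Randomness comes from per-sampling subseeds derived from one master
seed, so results are reproducible and order-independent.

## CARS variable selection

`cars_select()` follows the competitive adaptive reweighted sampling
scheme: at iteration i a PLS model is fitted on a Monte Carlo subsample of
80% of cases, variables are ranked by |PLS regression coefficient|, an
exponentially decreasing schedule a·e^(−k·i) (boundary conditions: all p
variables at i = 1, two at i = N; default N = 50) forces the retention
count, and adaptive reweighted sampling — p draws with replacement,
weighted by normalised |coefficient|, among the forced survivors — thins
the subset competitively. Drawing p times (the original variable count)
keeps the realised subset tracking the schedule instead of collapsing
geometrically; if sampling ever leaves fewer than two variables the top
two by weight are kept, respecting the schedule floor. Iteration 1
evaluates the full variable set, so the selected subset can never score
worse than the full model under the same CV criterion. Each iteration's
subset is scored by `mc_cross_validate()` and the minimiser wins.

## Univariate statistics

`peak_class_stats()` reports per-feature class means ± SD and a two-sided
two-sample t-test over replicate-level rows (the "380 data points"
reading; whether the published mean ± SD are tissue- or replicate-level is
unstated). Welch's unequal-variance t is the default for robustness, with
the classical pooled-variance Student's t behind `var_equal = TRUE`; with
balanced classes the two statistics coincide and only the degrees of
freedom differ. No multiple-testing correction is applied, matching
per-peak P < 0.05 reporting. `select_abundant_peaks()` implements the
abundance-above-threshold screen (the reference analysis tested peaks
above 20%). `replicate_rsd()` computes the per-tissue sample SD/mean × 100
over spray replicates and averages across tissues. Target m/z matching
tolerance defaults to half the bin width.

Note on calibration tests: with multiple replicates per tissue the
replicate-level t-test treats correlated rows as independent and is
anticonservative; the type-I-error calibration test therefore uses
one replicate per tissue, where rows are genuinely i.i.d.

## Numerical and design choices

* JSON (not YAML) is the run-configuration format: the pipeline needs a
  parser available everywhere the package runs, and `jsonlite` is a hard
  dependency anyway.
* mzML reading is built on `xml2` with base64/zlib decoding; CSV and MGF
  are the native, writeable dialects.
* The acceptance checks of class-mean recovery allow the 3-standard-error
  band plus 0.1 percentage points for the truncation-at-zero bias
  described above.
* Degenerate inputs fail loudly: empty spectra, all-zero intensities,
  constant matrices, single-class training draws (retried, bounded),
  coincident LDA class means, unmatched target m/z.

## Limitations

The generator's independence assumptions (between tissues of a patient,
between features, between background peaks) are simplifications; effect
sizes come from eight printed features only, so the synthetic cohort is
*more* separable than real spectra with hundreds of correlated channels —
the simulated best accuracy saturates near 100%, comfortably above the
94.42% reported on real tissue, and should be read as an upper-bound
sanity check, not a clinical claim. Multiclass discrimination, profile-mode
data, peak alignment and MS/MS structure elucidation are out of scope.
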