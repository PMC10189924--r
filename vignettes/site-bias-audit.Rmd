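---
title: "Auditing acquisition-site bias in slide embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing acquisition-site bias in slide embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hospitals that contribute hematoxylin-and-eosin (H&E) whole-slide images
(WSIs) to public cohorts differ systematically: stain formulations and
protocols shift the color spectrum, scanners imprint characteristic noise
textures, and local demographics skew case mix. Patch embeddings extracted
by convolutional networks pick these cues up, so a classifier — or a
content-based image-retrieval engine — can end up recognizing the
*acquisition site* rather than the histomorphology. This package provides
the machinery to measure that leakage:

1. a **synthetic cohort generator** with a single site-effect knob, so
   every downstream claim can be tested against a known ground truth;
2. **mosaic patch sampling** (RGB-histogram clustering at low
   magnification, proportional allocation, a cellularity filter);
3. a pluggable **feature extractor** contract with a deterministic
   handcrafted baseline (no trained weights required);
4. a **site probe**: a small two-hidden-layer classifier trained on frozen
   patch features under a patient-aware repeated-split protocol;
5. **slide retrieval** by the median-of-min set distance; and
6. a **bias audit** comparing observed same-site retrieval counts with an
   analytic expected value and a permutation null.

## The synthetic cohort model

`cohort_config()` describes a cohort of `n_slides` slides from `n_sites`
sites and `n_classes` cancer-type classes. Site shares are apportioned by
largest remainder, so each site's slide count differs from
`share * n_slides` by less than one. A configurable fraction of patients
(default 7%, the order observed in large public cohorts) owns two slides;
a patient never spans sites or classes. The `class_given_site` matrix
allows strongly imbalanced compositions, including sites contributing a
single cancer type.

Two site-effect mechanisms share one knob, `site_effect_alpha`:

* **stain shift** — each site's color-mixing matrix is
  `I + alpha * Delta`, with `Delta` entries drawn once per site from
  U(−0.15, 0.15);
* **noise texture** — a fixed band-limited Gaussian field per site
  (white noise low-pass filtered at 0.15 cycles/pixel), added with
  amplitude `alpha * 0.05` of the dynamic range.

At `alpha = 0` the stain matrix is exactly the identity and the noise
amplitude zero, so all sites draw from one distribution — the calibration
null. `Delta` and the texture seeds never depend on `alpha`, so sweeping
`alpha` moves the same site effects along a common path.

Image mode renders patches (default 128 px; a desk-scale stand-in for
1000 × 1000 production patches — pipeline behavior, not resolution, is
what the package tests) with elliptical dark "nuclei" whose density and
size depend on the class; the ground-truth nucleus mask is attached for
verification. Feature mode bypasses rendering: each patch vector is
`class_mean + alpha * site_shift + noise` with unit isotropic noise,
class-mean norm 6 (morphology dominates, as it should), and site-shift
norm `2 * alpha`. At `alpha = 1` sites are nearly separable; at
`alpha = 0.25` they overlap heavily — a useful dynamic range for
dose-response checks.

What the generator does *not* emulate: realistic tissue texture,
compression artifacts, scanner file formats, demographic covariates, or
label noise. A pipeline that passes the synthetic calibration can still be
confounded on real data by mechanisms outside this model; what passing
does show is that the *measurement machinery* (splits, probe, distances,
EV, permutation null) is unbiased and correctly calibrated.

## Mosaic sampling choices

The sampler clusters low-magnification patches into 9 groups by
concatenated per-channel histograms (16 bins per channel, L1-normalized —
the binning is a package convention, as no standard exists), allocates a
budget of 55 patches proportionally to cluster sizes (largest remainder,
capped at cluster size), and discards patches whose cellularity score is
below 0.1. A pixel counts as nuclear when its luminance is below 0.55 of
the dynamic range and its blue-to-red ratio is at least 1 (regularized so
black pixels qualify); the score is the nuclear-pixel fraction. The
cellularity filter runs *before* clustering and allocation, so budgets are
spent on eligible patches only. Clustering uses k-means with 10 restarts
under a fixed seed; exact duplicate histogram rows are collapsed before
clustering so degenerate slides cannot crash the centroid solver.

## The probe and its protocol

The probe is deliberately small: hidden layers of 500 and 200 ReLU units,
5 epochs of Adam (batch 60, step 1e-3) on softmax cross-entropy, output
width set to the number of sites in scope. It is implemented in
RcppArmadillo with a private `mt19937` stream, so a fixed seed reproduces
weights bit for bit. The protocol is what carries the scientific weight:

* slides split 90/10 with **no patient on both sides**, and every
  multi-slide patient confined to training (a multi-slide patient in the
  test set lets the probe match a patient, not a site);
* splits stratified by site so rare sites appear in test when feasible;
* 30 repeats with derived seeds, reported as mean ± sd.

Both patch-level and slide-level (majority vote, ties broken by the
highest mean class probability) accuracies are computed; slide-level is
the headline because slides are the unit of diagnosis. Whether published
site-classification accuracies are patch- or slide-level is generally
ambiguous, which is exactly why both are reported. Features enter the
probe raw; `zscore_cohort()` provides a standardized variant for
sensitivity checks, off the default path, since deep features are
conventionally consumed unnormalized and the package makes no claim about
which convention published numbers used.

## Retrieval and the bias audit

The slide-to-slide distance is the **median-of-min**: for each query
patch, the minimum Euclidean distance to the other slide's patches; the
slide distance is the median of those minima. It is directional
(query → corpus) and is used as such — no symmetrization. For even patch
counts the lower-middle order statistic is returned, so the value is
always an attained min-distance (a midpoint option exists). A mean-pooled
variant (distance between per-slide mean vectors) is provided for
comparison. Search is restricted to the query's diagnosis, excludes the
query and (by default) its patient's other slides, and breaks distance
ties lexicographically by slide id.

For a site owning `n_i` of the `N` same-diagnosis slides, with `q`
queries returning `k` neighbors each, the no-bias expectation of the
same-site count is

* naive: `q * k * n_i / N` (a site with a 20% share should own 1 in 5
  results);
* self-excluded: `q * k * (n_i - 1) / (N - 1)`, accounting for the query
  never retrieving itself.

The self-excluded form is the default because it is exactly the mean of
the within-diagnosis label-permutation null (holding neighbor lists
fixed), which the test suite verifies to Monte-Carlo precision. The
permutation p-value is two-sided around the null mean with the standard
+1 correction. Significance is assessed per (diagnosis, site) with **no
multiple-testing correction** — the audit is a diagnostic, and the
calibration checks account for the family size explicitly; users
comparing many sites formally should apply `p.adjust` themselves. The
observed/EV ratio is bounded above by roughly `(N - 1) / (n_i - 1)`, so
large enrichment ratios are only observable for sites with modest corpus
shares — with three equal sites the ceiling is about 3, with six about 6.
Audit experiments that look for strong enrichment therefore use six or
more sites.

## Numerical and design choices

* **Determinism.** Every stage is a pure function of its seed: R-side
  randomness runs under a save/restore seed guard, compiled code uses
  private `mt19937` streams, and derived seeds split the stream per
  repeat/site/stage (all below 2^31).
* **Baseline extractor.** Concatenated color histograms,
  gradient-orientation histogram, and a local-variance pyramid (68 raw
  descriptors) under a fixed seeded random projection to 1024 dimensions
  (the conventional last-pooling-layer width). The projection constant is
  versioned (`"v1"`) for bit-reproducibility. This baseline is a *sharp*
  detector of stain shifts — it sees exact histograms — so it saturates at
  much weaker effects than a generic CNN would.
* **Site-aware oracle extractor.** The baseline plus the generating
  stain-deviation block, scaled by `oracle_gain = 25` so the block is not
  numerically negligible after projection. It demonstrates the
  representation-dependence of site leakage: the extractor-contrast
  experiment runs at `alpha = 0.03`, below the baseline's saturation
  point (around 0.05), where the plain baseline is near chance and the
  site-aware representation is near perfect. The regime was chosen from
  an operating-curve characterization; at stronger effects both
  extractors saturate and no contrast is measurable.
* **Degenerate inputs.** Single-site diagnoses are flagged and reported
  without a p-value; sites without two single-slide patients are dropped
  from test scope with a warning; empty mosaics raise an error naming the
  slide; constant channels pass through histogram equalization unchanged.
* **Problem sizes.** The calibration experiments use 5 sites × 200
  slides × 20 patches (probe null), 20 generator seeds for the audit
  null, 10 repeats × 4 amplitudes for the dose-response check, and a
  48-slide rendered cohort for the extractor contrast — sizes chosen so
  the whole suite runs on a laptop-class single core while keeping
  binomial bands tight enough to be meaningful. The null-calibration band
  is the 95% binomial band at the per-repeat test size (400 patches):
  repeats share one cohort, so pooling all repeats into one binomial
  would understate the variance of their mean.

## Known limitations

* The synthetic site effect is linear in color and additive in texture;
  real inter-site variation includes nonlinear stain chemistry,
  compression, and case-mix differences.
* The audit's EV formulas assume every slide of a site is queried once;
  partial query sets are supported but the permutation null is then the
  only exact reference.
* The handcrafted baseline is not a CNN; it demonstrates the pipeline and
  the direction of representation effects, not the magnitude any
  particular network would show.
* Alias normalization of institution names is table-driven and refuses to
  guess; residual naming ambiguity in real metadata remains the user's
  responsibility.
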