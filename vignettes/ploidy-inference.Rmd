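---
title: "Inferring nuclear ploidy from segmented fluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring nuclear ploidy from segmented fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Endopolyploidy — somatic genome duplication without division — is widespread
in plants, insects and the human heart. Because a DNA-binding dye or a
histone-fusion reporter scales with genome content, the **total nuclear
intensity** of a segmented nucleus is a proxy for its C-value, and nuclear
**size** carries the same signal more weakly. `nucploidy` classifies each
segmented nucleus into a ploidy class (2C, 4C, 8C, ...) from these
object-level features alone, without flow cytometry.

The generative assumption is multiplicative: if 2C nuclei have mean total
intensity $2^k$, then 4C nuclei have mean $2^{k+1}$, 8C mean $2^{k+2}$, and
within-class variation is relative (a coefficient of variation), not
additive. After scaling the features by $\log_2$, each ploidy class becomes
(approximately) a Gaussian component whose means sit one unit apart, so the
nucleus population is modelled as a $K$-component Gaussian mixture

$$p(x) = \sum_{k=1}^{K} w_k \, \mathcal{N}(x \mid \mu_k, \Sigma_k),$$

fitted by expectation-maximization in 1 or 2 dimensions (intensity alone,
or intensity + size/volume). Four covariance families are supported —
spherical, diagonal, full, tied — exactly the structural menu used in the
field's standard mixture implementations. The number of components and the
family are chosen by information criteria,

$$\mathrm{AIC} = -2\log\hat L + 2d, \qquad
  \mathrm{BIC} = -2\log\hat L + d\ln n,$$

with $d$ the free-parameter count
($d = (K-1) + KD + \{\text{spherical: } K;\ \text{diagonal: } KD;\
\text{full: } KD(D{+}1)/2;\ \text{tied: } D(D{+}1)/2\}$).

Components are then sorted by the mean of the intensity dimension (the DNA
content proxy; size ordering is configurable but not the default) and named
along a doubling ladder. Three ladder idioms cover the shipped presets: a
junk class `<2C/Unclassified` for the lowest component (dropped from all
summaries), an open-top class `≥16C` when the brightest component plausibly
mixes higher ploidies, and a relative ladder `2αC, 4αC, 8αC` when only fold
relationships, not absolute ploidy, are known (human cardiomyocytes).

## Uncertainty of the classification

Posterior responsibilities $p_m^k$ quantify how confidently nucleus $m$
belongs to component $k$. With $V^k$ the proportion of (non-dropped) nuclei
whose largest posterior points at $k$:

* $C_\mathrm{out}^k$: proportion classified into $k$ with maximum posterior
  **below 0.8** — they could leave the class;
* $C_\mathrm{in}^k$: proportion of all nuclei whose **second-largest**
  posterior exceeds **0.2** and points at $k$ — they could join it;
* the reported interval is $(V^k - C_\mathrm{out}^k,\ V^k + C_\mathrm{in}^k)$.

Both inequalities are strict, and both thresholds are configurable. The
second-largest posterior's *target* component is credited with $C_\mathrm{in}$;
the procedure's original description leaves that attribution implicit, and
this reading is the one implemented (it is also the only one that makes
$C_\mathrm{in}$ a per-class quantity).

Hard argmax ties (measure-zero in practice) break toward the lower-mean
component — the conservative ploidy call.

## Filters, normalization and QC

* **Variance-of-intensity filter.** The per-object population variance
  $\sigma_i^2 = \frac1{n_i}\sum_j (S_j - \mu_i)^2$ (divide by $n_i$, not
  $n_i - 1$ — kept exactly as the source procedure defines it, although
  sample variance would be conventional) separates epidermal from
  sub-epidermal nuclei; the shipped cutoff is $2^{8.3}$, keep-above.
  Ties at any threshold are kept (inclusive on the kept side): the cutoffs
  sit in histogram troughs where ties are measure-zero, so the choice is
  documented rather than consequential.
* **Guard-cell filter.** Flow-cytometry event tables drop total intensity
  below $2^9$ (stomatal guard cells).
* **Haploid-standard normalization.** When 1C reference nuclei (spermatids)
  are imaged on the same slide, sample intensities are divided by the
  reference *median*, placing nuclei on an absolute ladder
  ($2^0 = $ 1C, $2^1 = $ 2C, ...). Three QC gates protect the anchor:
  at least 10 reference nuclei; median intensity within 2000–6000 (a.u.);
  and at least 90% of median-normalized intensities within 0.5–1.5.
  All endpoints are inclusive, and the 90% test uses $\ge$ (the source does
  not specify open/closed; inclusivity is the documented choice).
  A failing experiment aborts the pipeline — an unanchored ladder is worse
  than no result.
* Records with non-positive selected features cannot be log-scaled; they are
  dropped with a warning (zero-intensity objects are segmentation
  artifacts), and an index map of survivors keeps every downstream artifact
  aligned with the input table.

## Fitting choices

Defaults mirror the reference configuration: 1D fits use tolerance $10^{-5}$
(on the per-sample mean log-likelihood improvement — the convention of the
reference implementation), at most 10,000 iterations, 20 restarts; 2D fits
use $10^{-7}$, 5,000 and 500. Initialization is greedy k-means++ seeding
($2 + \lfloor\log k\rfloor$ local trials per center) followed by a hard
nearest-center assignment and an M-step. A diagonal regularizer
(`reg_covar`, default $10^{-6}$ in squared log2 units) prevents singular
covariances; the source procedure is silent on regularization, and this
value is small enough not to shift any reported mean by a visible amount.
A component collapsing to zero responsibility aborts the restart; the fit
fails only if every restart collapses. Seeds are explicit everywhere
(default 0), and a fit is bit-reproducible given (data, K, family, params).

Tests and the acceptance suite run with `n_init` of 2–4 rather than the
production defaults purely for runtime; `fit_params()` makes this an
explicit argument, not a hidden behavior change.

## AIC versus BIC: a measured limitation

On large, well-separated synthetic data (3 classes, log2 means spaced 1.0,
sd 0.12, 300 nuclei/class, 2D), BIC recovers $K = 3$ in 50/50 seeded
replicates. AIC does not: splitting a 300-point Gaussian cluster buys more
log-likelihood than the $2\,\Delta d = 8$ AIC penalty often enough that AIC
overselects in roughly a quarter to a third of replicates — and the *better*
the optimizer (more restarts, tighter tolerance), the more reliably it finds
the overfit optimum. The same behavior reproduces in the field-standard
mixture implementation at matching settings, with per-fit log-likelihoods
agreeing to $\sim 10^{-7}$, so it is a property of the criterion on this
world, not of this implementation. The acceptance suite pins the
"both criteria recover $K$" expectation and is expected to fail for AIC;
the pipeline therefore selects by **BIC by default**, always reports both
optima, and logs a warning when they disagree or when a criterion decreases
monotonically over the scanned range (in which case the chosen $K$ is only
a ceiling assumption — prior knowledge of the tissue's plausible ploidies
should set the scan range, which is why the presets carry their own ranges:
1–8, 1–5 and 1–3).

## The synthetic world

`simulate_feature_table()` draws class labels from configured weights, then
intensity and size from log2-normal laws: the linear-scale CV maps to
$\sigma_{\log_2} = \sqrt{\ln(1 + \mathrm{CV}^2)}/\ln 2$, so a 10% CV gives
$\sigma_{\log_2} \approx 0.145$ and consecutive classes sit $\sim 6.9$ sd
apart — comfortably separable, matching the sharply multimodal histograms
of real endoreduplicating tissue. Defaults are one stated world: fold 2.0
(exact genome doubling) for both features, CV 10%, base intensity 6000 a.u.
chosen so that the 1C reference population (one rung below the 2C base,
median $\approx 3000$) sits mid-way through the 2000–6000 QC gate.
`simulate_label_image()` places non-overlapping disks/spheres (radius
$\propto$ size$^{1/2}$ or size$^{1/3}$), fills them with noisy voxel
intensities, and then *measures* the emitted feature table directly from
the raster, so image and table agree exactly by construction.

What the generator does **not** emulate: segmentation errors (merged or
clipped nuclei), spatially varying background, depth-dependent attenuation,
PSF blur, or spatial clustering of ploidy classes. A green recovery test
therefore establishes the statistical machinery — not robustness to
segmentation failure, which the user-label and variance filters address
upstream.

## I/O and formats

Feature tables are CSV in the ilastik object-classification dialect; both
`"Total Intensity"` and `"Total Intensity_0"` spellings resolve
automatically, `"User Labels"` falls back to `"Predicted Class"`, and every
mapping is overridable. Label images are uncompressed grayscale TIFF
(via a small built-in baseline codec — no TIFF package is assumed —
supporting 8/16/32-bit unsigned and 32-bit float, multi-page for stacks) or
HDF5 (via rhdf5). Floating-point rasters are rejected with a pointer to
export object predictions rather than probability maps. Coordinates are
0-based pixel units; physical units enter only through calibration
metadata. Ploidy maps are written as a 16-bit class-rank TIFF plus an RGB
PNG (3D volumes are max-rank projected so high-ploidy nuclei are never
hidden), with the palette and rank legend in a JSON sidecar; the default
palette is a colorblind-safe ordered ramp.

Every run writes a manifest (config, seed, package version, config hash,
and all warnings raised); `rerun_from_manifest()` reproduces the run
bit-identically, which the test suite asserts.

## Known limitations

* Mixtures struggle with classes of very low abundance; the scan range and
  the monotonic-criterion warning are the guard rails, not a cure.
* The fold statistics use arithmetic means on the linear scale by default
  (geometric means are also computed and reported alongside); the source
  figures do not specify which, and the two differ by
  $e^{\sigma^2/2}$-style factors at 10% CV — below the reporting precision.
* The two-sample Cramér–von Mises comparison (rank form with midranks,
  finite-sample moment normalization, Bessel-series limiting distribution)
  operates by default on class labels encoded as numeric C-levels, the
  reading consistent with comparing classified distributions; raw-intensity
  comparison is a configuration away.
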