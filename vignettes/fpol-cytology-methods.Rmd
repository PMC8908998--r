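---
title: "Methods: quantitative Fpol cytology with fpolcyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative Fpol cytology with fpolcyto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpolcyto)
```

## The measurement model

Fluorescence polarization imaging records two emission channels through a
polarizing beam splitter: `Fco`, polarized parallel to the linearly
polarized excitation, and `Fcross`, perpendicular to it. Because the two
detection arms are never perfectly balanced, the cross channel is weighted
by an instrument calibration factor G before the polarization ratio is
formed:

$$F_{pol} = \frac{F_{co} - G\,F_{cross}}{F_{co} + G\,F_{cross}}.$$

The ratio is dimensionless, bounded in $[-1, 1]$, invariant to any common
rescaling of both channels (so absolute staining intensity and illumination
drift cancel), strictly increasing in `Fco` and decreasing in `Fcross`. It
is undefined when the denominator — the calibrated total signal — is zero;
such pixels are skipped rather than imputed.

G is measured on a reference specimen of known polarization (an isotropic
dye solution, `Fpol = 0`): `estimate_g()` takes the ratio of mean
valid-pixel intensities and scales it by
$(1 - p_{ref}) / (1 + p_{ref})$. The package default is G = 0.75.

### Assumptions

* One Fpol value meaningfully characterizes a cell; intra-cell variation is
  treated as noise around that value. Per-cell aggregation therefore sums
  each channel over the cell's valid pixels and applies the ratio once —
  an intensity-weighted estimate that down-weights dim, noise-dominated
  pixels. The alternative (mean of pixelwise ratios) is available via
  `cell_fpol(..., pixelwise_mean = TRUE)` for sensitivity analysis; the two
  differ under intensity heterogeneity.
* Channels are acquired simultaneously, so no registration between frames
  or channels is attempted; neither are deconvolution, flat-field or
  photobleaching corrections.

## The processing chain and its numerical choices

**Validity masking.** On the 8-bit scale, pixels below 3 counts are
background and pixels above 254 are saturated; both are excluded. Two
choices were open:

* *Scope of exclusion.* A pixel failing either rule in *any* frame of
  *either* channel is excluded everywhere. This is the conservative
  reading: it avoids averaging partially censored pixels and keeps the two
  channels on an identical pixel set, which the ratio requires. Pixels
  failing both rules are counted once, under the background rule.
* *Sentinel.* Invalid pixels carry `NA`, never 0, so censored background
  can never masquerade as signal in sums.

**Frame averaging.** Arithmetic mean over frames (3 per channel by
default), after masking.

**Emission image.** No single convention defines "total emission" for a
polarization-resolved pair. The package uses
$F_{co} + G\,F_{cross}$ — the denominator of the ratio, i.e. the total
detected signal after calibration — because it makes the emission image
and the Fpol map share one internal scale. The uncorrected sum
`co_plus_cross` and the cuvette-fluorimetry total `co_plus_2g_cross`
(which doubles the single measured perpendicular component to stand in for
both) are selectable in `compute_emission()`.

**Reporting precision.** Fpol is carried at full double precision
throughout; rounding to 3 decimals (round-half-even) happens only at
reporting boundaries (`group_mean()`'s `mean_fpol_rounded` column).

## Segmentation

The reference workflow assumes curated (manual or ground-truth) label
masks, imported from 16-bit single-page TIFFs and relabeled to consecutive
integers. `auto_segment()` provides an automated convenience fallback —
Otsu threshold on the emission image, hole filling, distance-transform
watershed, area filter (defaults 20–2000 µm², 8-connectivity) — but
quantitative validation in this package always uses ground-truth masks, so
segmentation quality never confounds the Fpol chain. Cell size is reported
as area (pixel count × pitch²) with equivalent diameter
$2\sqrt{A/\pi}$ as the secondary metric.

## The synthetic generator

`render_sample()` synthesizes what the instrument would record for one
planned sample, and is the package's substitute for undeposited clinical
images. What it emulates:

* 8-bit quantization, a 205 µm × 205 µm field of view, 3 frames per
  channel, and a configurable G (default 0.75), matching the acquisition
  geometry the pipeline targets. Image resolution is not dictated by that
  geometry; the default is 512 × 512 px (0.4 µm/px, comfortably finer than
  a ~0.9 µm lateral optical resolution) and is configurable.
* Cells as non-overlapping ellipses (equivalent diameter uniform in
  8–25 µm, axis ratio 1–1.8, random orientation) with a concentric nucleus
  occupying 35% of the area at 1.8× cytoplasm brightness. This geometry is
  cosmetic: ground-truth Fpol is constant per cell, because the analysis
  reports one value per cell.
* Per-cell true Fpol drawn from Normal(sample mean, sample SD) truncated
  to (0, 1) by resampling, which preserves unimodality near the means of
  interest (~0.2–0.27).
* Channel intensities via the exact algebraic inversion
  `solve_intensities()`: given target polarization p and total signal
  $S = F_{co} + G\,F_{cross}$, then $F_{co} = S(1+p)/2$ and
  $F_{cross} = S(1-p)/(2G)$.
* Noise: Poisson on the photon-scaled signal plus Gaussian read noise
  (SD 1 count), a uniform background of 1 count (below the exclusion
  threshold of 3), then clipping to [0, 255] and integer quantization —
  the minimal physically plausible model for photomultiplier-based
  confocal detection.
* Reproducibility: one master seed; each sample derives a child seed from
  its row index, so any sample can be regenerated alone, bit-identically.

Cells spill into as many fields as needed to keep per-field coverage under
`max_coverage` (default 20% of field area), mirroring how dense samples
are imaged over several fields.

What it does **not** emulate: optical blur and the microscope's point
spread function, depolarization by scattering, uneven staining, cell
debris, overlapping or clumped cells, erythrocyte contamination, and
non-cancerous infiltrates within tumors. Passing tests on synthetic data
therefore validate the *arithmetic and statistical chain* — inversion,
masking, aggregation, grouping, inference — not robustness to real-world
image artifacts, which only curated masks and real acquisitions can probe.

`simulate_cells()` is the fast statistical path: it draws the same
per-cell Fpol distributions without synthesizing images, and is used for
cohort-scale simulation studies where the imaging layer would add cost but
no information.

## The packaged reference cohort

`plan_cohort("default")` returns a fixed 32-sample plan (21 subjects,
3521 cells) spanning 1 MTC, 9 PTC and 3 FTC malignant samples, 3 FTA and
4 MNG benign samples, and 12 normal-tissue samples, with per-sample cell
counts and Fpol mean ± SD, including 12 cytologically indeterminate
(TBSRTC III–V) nodules. It is deterministic and seed-independent, and
anchors the deterministic checks: group bookkeeping, group means, and
threshold classification.

## Group statistics

Three grouping schemes are supported: `diagnostic3`
(malignant / benign / normal), `histo5` (PTC, FTC, FTA, MNG, normal — the
single MTC sample is excluded, since model-based comparison needs at least
two samples per group), and `indeterminate4` (TBSRTC III-benign,
III-malignant, IV-malignant, V-malignant among indeterminate tumor
samples).

Two estimators of group means are emitted and labelled, never conflated:

* the **reporting estimator** (`group_mean()`): unweighted mean of
  per-sample means, SE = SD of sample means / √n. It is fully
  deterministic given sample summaries.
* the **model-based estimator** (`fpol_lmm()`): least-squares means from a
  linear mixed model on per-cell Fpol with group as fixed effect and a
  random intercept per subject. Subjects contributing several samples
  (tumor plus adjacent normal tissue, or repeated nodule samples) share
  one random-effect level. The random-effects structure is this package's
  choice; cells-within-subject is the minimal structure that respects the
  design's non-independence. Degrees of freedom use the Satterthwaite
  approximation; pairwise contrasts are reported unadjusted with a
  Holm-adjusted column alongside, so both conventions are visible.

When a variance component collapses (singular or degenerate fit — e.g.
zero residual variance in constructed data), the model falls back to a
sample-level one-way linear model with an explicit warning rather than
reporting untrustworthy cell-level inference.

## Threshold classification

The discrimination threshold is fixed at Fpol = 0.245 and the comparison
is strict: a cell or sample at exactly 0.245 is called non-malignant. The
threshold is an empirical operating point, not an optimized quantity — no
ROC fitting is performed. For malignant samples the fraction of
sub-threshold cells is reported, since tumors carry non-cancerous
infiltrates that depress the lower tail.

## Viability

Post-imaging viability from a dye-exclusion count is reported in two
labelled forms: the ratio form $(N_{viable}/N_{non\text{-}viable})
\times 100$, which is undefined when no non-viable cells are counted and
can exceed 100, and the conventional fraction of total
$N_{viable}/(N_{viable}+N_{non\text{-}viable}) \times 100$. The two answer
different questions and are never silently substituted for one another.

## Rendering

Rendering is a pure view layer: it never feeds back into any quantitative
output. Digital staining maps foreground emission pixels above a per-field
intensity quantile (default 0.65) onto a blue-purple nuclear ramp and the
rest onto a blue-green cytoplasmic ramp, luminance following intensity —
no published lookup table exists for this, so the two-ramp quantile scheme
is this package's construction, and palettes are swappable (an H&E-like
palette is a `stain_palette()` away). Fpol maps use a linear black→red
ramp on a fixed 0.0–0.40 scale with clamping at the endpoints, and
rendered images can embed a 50 µm scale bar.

## Validation strategy and problem sizes

The test suite checks each stage against an independent oracle: a
double-loop reimplementation of the ratio (to 1e−12), the algebraic
inversion round trip across a parameter grid, noise-free end-to-end
recovery within the 8-bit quantization bound (0.01), G recovery within 1%
on simulated isotropic fields, and the deterministic cohort quantities
exactly. Statistical behaviour is checked by simulation: power of the
mixed model on cohorts drawn from the reference plan (20 seeds) and type-I
error on identically distributed two-group null cohorts (200 seeds of
16 samples × 25 cells), asserted within a 3-SD binomial band around 0.05.
Imaging tests run at reduced resolution (160–256 px) — the chain is
resolution-independent by construction, so small fields exercise the same
code paths the 512 px default does.

## Known limitations

* The synthetic generator's realism gap listed above: optics-free,
  artifact-free images.
* The automated segmentation is a convenience, validated only on
  well-separated synthetic cells; curated masks remain the reference
  route.
* Mixed-model p-values rely on the Satterthwaite approximation, which is
  accurate but not exact at small group counts (2–5 samples per group in
  the indeterminate scheme).
* TIFF float export stores values on [0, 1]; Fpol maps are affinely
  encoded (documented in the JSON sidecar) rather than stored raw.
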