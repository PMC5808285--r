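---
title: "Methods: phantom design, band selection and K-means detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom design, band selection and K-means detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the pipeline

`hsikmeans` models a screening task: given a visible-range hyperspectral
cube of a breast-tissue histology slide (two spatial axes, one spectral
axis of reflectance), decide per pixel whether it belongs to ductal
carcinoma in situ (DCIS) or to non-cancerous tissue. The pipeline has four
stages:

1. **ROI spectral summarization.** Square regions of interest are placed
   at random — inside pathologist-style cancer annotations on DCIS slides,
   anywhere on normal slides — and each region is summarized as a mean ±
   SD reflectance spectrum over repeated measurements.
2. **Band selection.** Each band is scored by the absolute standardized
   mean difference between the cancer and normal measurement pools; the
   argmax wavelength is selected.
3. **K-means training (leave one patient out).** Labeled ROI pixels from
   all training patients are pooled; K-means with `c = 2` alternates
   Euclidean nearest-center assignment and mean updates until no pixel is
   reassigned; clusters are mapped to {cancer, non-cancer} by majority
   ground truth.
4. **Held-out evaluation.** Every pixel of the held-out patient's slides
   is classified, and the confusion matrix yields sensitivity,
   specificity, TNR and FPR.

The assumptions worth stating plainly: reflectance is treated as already
calibrated into [0, 1] (no white/dark-reference correction is modelled);
tissue classes are spectrally homogeneous up to smooth multiplicative
variation and additive noise; and class structure is learnable from
spectra alone, ignoring spatial context.

## The synthetic phantom: a stated world

Real patient slides are not available, so every stage is driven by a
generator whose defaults are fixed once and not revisited:

| parameter | default | meaning |
|---|---|---|
| `n_patients` | 10 | cohort size; each patient contributes {normal, DCIS} × {stained, unstained} cubes |
| `rows × cols × bands` | 443 × 313 × 31 | emulated snapshot-sensor geometry |
| wavelength grid | 461–641 nm, uniform | 6-nm band spacing; centers 461, 467, …, 641 |
| `cancer_area_fraction` | 0.3 | target DCIS pixel fraction; annotated regions are high-density tumor areas |
| `pixel_noise_sd` | 0.02 | per-band additive Gaussian noise (reflectance units), a few percent of signal — typical of a well-exposed microscope sensor |
| `patient_gain_sd` | 0.05 | SD of one multiplicative gain per patient (section thickness, staining intensity, illumination) |
| `patient_tilt_sd` | 2e-4 /nm | SD of one linear spectral tilt per patient (±~2 % at the grid edges) |

Endmember spectra (pure-class reference curves) are smooth sums of 2–3
Gaussian bumps. Their exact values are a design choice — no tabulated
tissue spectra exist to copy — and they are calibrated to reproduce one
qualitative fact: for stained tissue the measured class separation peaks
at the band nearest 550 nm, and stained separation exceeds unstained
separation there. The calibration is asserted at model construction, so an
uncalibrated model cannot be built.

One subtlety drove the final curve shapes. Because per-patient gain and
texture act multiplicatively, the pooled SD in the separation score scales
with the class mean spectrum, so the standardized score behaves like
`(1 − ρ)/√(1 + ρ²)` with `ρ(b) = E_cancer(b)/E_normal(b)`: the argmax sits
where the *ratio* of the class spectra is smallest, not where their raw
difference is largest. The stained-normal curve is therefore nearly flat
around 550 nm while the stained-cancer curve has a narrow, deep absorption
dip centred at 551 nm (the grid center nearest 550). With a broad dip the
measured peak wandered over ±2 bands between cohort draws; the narrow dip
makes the 551-nm peak stable across seeds. This was fixed once, before
freezing, by measuring full-size cohorts at several seeds.

DCIS masks are unions of 2–6 irregular (angularly perturbed) ellipses —
carcinoma spreading outward from ducts — redrawn until the cancer fraction
lands within ±50 % (relative) of target. Normal "duct" structure is
rendered purely as mild ring-shaped multiplicative texture (±6 %) on
normal-class pixels; labels stay binary because the classifier only
distinguishes cancer from non-cancer. Cancer pixels carry no texture, so
with all variance parameters at zero a cancer pixel equals the cancer
endmember exactly — a property the tests rely on.

**What the phantom does not emulate:** optical physics (scattering,
absorption coefficients, dye chemistry), nuclei-scale morphology, spatially
correlated noise, focus and illumination gradients, staining batch
effects, or inter-patient spectral shape differences beyond gain and tilt.
Held-out accuracy on the phantom is therefore an upper bound of sorts: a
green pipeline run establishes that the machinery is correct and leak-free
on data with the stated statistical structure, not that the method reaches
any particular accuracy on real slides.

## Numerical and procedural choices

* **"One measurement"** of an ROI is the mean spectrum of a random 25-pixel
  subsample (without replacement) of the region; ten such measurements
  give the mean ± SD summary. Repeated physical exposures are not
  available to a simulation reading a fixed cube, and spatial subsampling
  gives the SD the same role: variability of a small-sample average. Both
  counts are configurable.
* **ROI side length** defaults to 20 px (a few hundred pixels per region
  on the full-size sensor); unspecified by any source, chosen so four
  disjoint squares fit comfortably inside typical carcinoma blobs.
* **Separation statistic**: absolute standardized mean difference with the
  two-class pooled SD (variance pooled over all measurements, within- plus
  between-region), floored at `1e-9` to avoid division by zero on
  degenerate constant input. It is symmetric in class labels and invariant
  to a common rescaling of all spectra.
* **Ties** resolve deterministically everywhere: nearest-band lookup and
  band selection break toward the lower wavelength; cluster assignment
  breaks toward the lower cluster index.
* **K-means convergence** is the zero-reassignment rule, not an objective
  tolerance; `max_iter = 300` guards pathological cycling. The objective
  is recorded after each assignment and is non-increasing by construction.
* **Initialization** defaults to the deterministic farthest-apart greedy
  (first center at the point nearest the data mean, then max–min
  distance), which places the two starting centers in opposite spectral
  classes on separable data; random sampling of data points is retained.
* **Empty clusters** (possible under random init) are re-seeded at the
  worst-served point — the point farthest from its nearest surviving
  centroid — which cannot increase the objective.
* **Cluster→label ties** (an exact 50/50 majority) go to the cluster whose
  centroid is darker at the selected band; stained carcinoma is modelled
  darker near 550 nm, and the rule is documented as phantom-specific. If
  the majority vote hands both clusters the same label, the cluster with
  the higher cancer fraction keeps the cancer label so that both labels
  are always represented.
* **Feature mode** defaults to the full 31-band spectrum per pixel; a
  single-band mode at the selected wavelength exists because that channel
  is the natural display/detection band.
* **Evaluation** is pixel-level (every pixel of the held-out slides
  against ground truth); a region-level majority-vote table is also
  emitted, since screening decisions are made per region rather than per
  pixel. Pooled training over all training patients is the primary mode;
  per-patient separate fits are tabulated for inspection but never merged
  into the held-out predictor, because there is no principled way to fuse
  nine independent centroid pairs.
* **Training pixels** come from ROIs (the annotated-region analogue), not
  whole slides, so the training distribution matches what a pathologist
  marks; whole-slide training is available via `flatten_pixels()`.
* **ENVI on disk**: `write_envi()` defaults to float64, on which the
  round trip is value-exact; cohort generation writes float32 (reflectance
  in [0, 1] needs ~7 digits at most, and the full cohort halves to
  ~0.7 GB). All three interleaves and both byte orders are read.
* **Indexing** is 1-based (row, col) everywhere, row-major in flattening —
  the R convention.

## Known limitations

* The phantom's class separability at default noise makes held-out
  metrics near-ceiling; the noise-sweep tests, not the headline metrics,
  are what probe degradation behaviour.
* K-means with `c = 2` on raw spectra cannot represent within-class
  multimodality (e.g. stroma vs lumen vs duct wall as distinct spectral
  modes); the phantom deliberately keeps classes unimodal.
* Reflectance calibration, stain normalization and slide-level batch
  effects are out of scope; on real data they would dominate the error
  budget.
* The 550-nm finding is reproduced as a property of the calibrated
  phantom, by design; it is a consistency check of the analysis chain,
  not independent evidence about tissue optics.
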