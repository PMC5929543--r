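---
title: "Effective cell counting: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective cell counting: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effcount)
```

## The counting model

Direct object counting fails on biofilm-embedded or adherent cells because
touching cells segment into single connected components; purely statistical
whole-image measures, conversely, cannot separate sub-populations. The
method implemented here combines both views. For one staining channel
(red = non-viable, green = viable under the usual live/dead protocols):

1. threshold the channel with a rule statistic strictly greater than an
   integer `T` (single channel `I_c > T`, differential `I_R − I_G > T`, or
   mean intensity);
2. label the mask's 8-connected components;
3. take objects with area in the single-cell window `[s_min, s_max]` as
   isolated single cells and compute their mean area `S̄`;
4. report the effective count `N_eff = S / S̄`, where `S` is the *total*
   thresholded area — clumps included.

The ratio `N_Reff / (N_Reff + N_Geff)` estimates the non-viable fraction.
Using effective counts rather than raw areas is the point of the method:
channel-specific size windows and thresholds let a sub-population with
smaller cells (shrunken dead eukaryotic cells, say) be normalized by its own
typical cell size.

A useful consequence tested in the suite: if every object is an identical
single cell inside the window, `N_eff` equals the object count *exactly*,
and an overlapped clump adds exactly `clump_area / S̄` cells.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `T` | detection threshold, intensity units on the 0–255 scale | none (user) | image-dependent; see the balance procedure |
| `mode` | rule family | `single_channel` | channels are analysed separately; the differential rule suits overlapped-channel images |
| `[s_min, s_max]` | single-cell area window, px | none (user) | inclusive at both ends; bounds depend on magnification and morphology |
| `bins` | object-size histogram bins | 1–300, 301–600, 601–1000, 1001–2000, >2000 px | the bins used throughout the balance analysis; 301–600 captures single cocci, 1001–2000 single rods/eukaryotic cells |
| `T_grid` | sweep grid | 5..250 step 5 | fine enough to resolve histogram maxima; configurable |
| `prefilter` | Gaussian/Sobel preprocessing | `none` | fraction estimates are robust without filtering; filters are opt-in |
| `sigma` | Gaussian sigma, px | 1 | kernel radius `ceil(3σ)`, unit-sum, reflect boundaries |

## The threshold / size-window balance

`T` and the size window are coupled: cells are centre-bright, so raising `T`
shrinks apparent object areas. `threshold_sweep()` computes, for every `T`
on the grid, the total thresholded area and the per-size-bin object counts
and areas. Two invariants hold by construction and are tested on arbitrary
images: the total area is non-increasing in `T`, and at every `T` the summed
per-bin area equals the total area.

`suggest_threshold()` formalizes reading the optimum off the histogram: `T*`
is the grid argmax of the isolated-object count in the chosen single-cell
bin. The original procedure picks this maximum visually; the argmax is this
package's formalization, and deliberately does **no** smoothing and no
automatic resolution of multi-modal count curves — a bimodal curve usually
betrays cell clusters sharing the bin, and is surfaced for inspection
instead. Ties break toward the smaller `T`: a lower threshold keeps more of
the dim cell periphery, which the effective-size normalization absorbs.

The argmax rule presumes the regime the procedure was designed for: a
background that merges with cells at low `T`, so the single-cell count peaks
only once the background clears. On images with nearly uncorrelated,
low-amplitude background noise the count curve can plateau from very low
`T`, and the smallest-tie rule then lands below the noise floor; the
suggestion should be read together with `ratio_stability()`, which reports
the relative spread of the red/green total-area ratio over a threshold band
(a small spread certifies that any `T` in the band yields the same
fractions).

## Z-stacks

Confocal stacks are analysed strictly slice-wise in 2D with shared
parameters; per-slice areas are summed and the single-cell selections of all
slices are pooled before the mean is taken. Pooling (rather than averaging
per-slice results) treats the stack as a raw series of 2D images and keeps
the estimator well-defined when individual slices contain no single cells.
A cell spanning several optical sections is counted once per slice; this is
a documented limitation of 2D analysis, shared by the per-slice fractions
the method targets. No 3D connected components are built.

## Validation statistics

`fit_no_intercept()` fits `y = kx` by least squares through the origin,
`k = Σxy / Σx²` — no intercept because zero cells must map to zero counts.
It reports `R² = 1 − Σ(y−f)²/SS_tot` and `L² = 1 − Σ(f−x)²/SS_tot` with
`f = kx` and `SS_tot = Σ(y−ȳ)²`. Two deliberate choices:

* **One `SS_tot` for both.** The denominator is the ordinary total sum of
  squares of the observed `y`. (In the ideal case `y = x` the alternative
  `Σ(f−f̄)²` coincides with it, since `f = y`.)
* **No clamping.** The formulas do not confine either coefficient to
  [0, 1]: on (1,2), (2,4), (3,6) the fit is perfect (`k = 2`, `R² = 1`) yet
  `L² = 1 − 14/8 = −0.75`, correctly flagging that the line is far from
  `y = x`. Raw values are reported; a negative `L²` simply means the fitted
  line explains the identity worse than the mean does.

`L² = 1` holds exactly iff `k = 1` (given positive `SS_tot` and a non-zero
abscissa), which the suite asserts.

## The synthetic generator

`generate_micrograph()` renders a stated world, not a tuned one: cells are
disks (cocci, mean area 450 px), 4:1 capsules (rods, 1400 px) or 1.5:1
ellipses (eukaryotes, 1500 px) with Gaussian area dispersion (relative sd
0.15), Bernoulli red/green channel assignment, per-pixel intensity
`peak · (1 − r)^falloff` with `peak = 220` and `falloff = 0.5`, additive
Gaussian background noise (sd 5) and optional Gaussian blur. The radial
falloff is essential: with flat-intensity cells the threshold would not
interact with apparent size and the balance procedure would have nothing to
balance. `falloff = 0.5` keeps a 450 px coccus inside the 301–600 px window
over the whole analysis band `T ∈ [15, 60]` (apparent area 445 px at
`T = 15`, 386 px at `T = 60`), which is what makes threshold-robust fraction
recovery a property of the world rather than of tuned settings. A fraction
`overlap` of cells (default 0.2) is placed adjacent to an existing cell so
supports merge; the rest are placed with one pixel of clearance so disjoint
cells never become 8-connected by construction. Placement failing 1000
times raises an error rather than silently under-filling the field.

What the generator does *not* emulate: spatially correlated autofluorescent
background (its noise is iid unless `blur_sigma` is set), uneven
illumination, chromatic cross-talk, extracellular-matrix texture, and any
physical PSF or photobleaching. A green test on synthetic data therefore
establishes the estimator's correctness and threshold robustness under the
stated world — not staining-protocol quality on real samples. Where a test
needs a realistic background (the threshold-suggestion recovery property),
it uses `noise_sd = 20` with `blur_sigma = 1`, which mimics correlated
background patches.

`generate_stack()` renders one population per slice with multiplicative
per-slice intensity jitter and fresh noise; `slice_jitter = 0` replicates
one rendering so the degenerate case is bit-identical.
`benchmark_suite()` derives per-image seeds from a master seed
(`(1009·seed + 7919·i) mod 2³¹−1`) so suites reproduce piecewise.

## Numerical and interface choices

* **Strict inequality** in every threshold rule: a statistic equal to `T` is
  not selected, so `T = 0` on an all-zero image selects nothing.
* **Signed differential statistic**, not clipped at zero; a negative
  difference never exceeds a non-negative `T`. The counterpart of red is
  green and vice versa; a (non-default) blue differential subtracts
  `max(R, G)`.
* **Mean intensity rounded half-up** (`floor(x + 0.5)`, computed in integer
  arithmetic) keeps the intensity statistic integral.
* **Inclusive size bounds** at both window ends, and inclusive bin bounds
  with an open last bin.
* **Label order** is deterministic: consecutive ids in raster-scan order of
  each object's first pixel. Histograms and selections depend only on the
  partition.
* **1-based (row, column) pixel coordinates**, the natural indexing of R
  matrices; areas are pixel counts.
* **16-bit inputs** rescale to 8 bits by integer division by 257, mapping
  full scale to full scale; grayscale replicates to three channels; alpha is
  dropped; JPEG is accepted with a lossy-artifact warning.
* **Zero-area channels** yield `N_eff = 0` without a single-cell mean (there
  is nothing to normalize); a channel with stained area but an empty
  single-cell selection fails loudly with re-adjustment advice. A fraction
  with both effective counts zero is reported missing, never 0.
* **Effective counts stay fractional**; `results_table()` adds a rounded
  companion column at report time only.
* **Manual exclusions** (the batch replacement for interactively discarding
  anomalous segments) apply to the single-cell selection only — never to the
  total stained area.
* **Sobel normalization**: gradient magnitude is rescaled so the per-image
  maximum maps to 255; the source procedure leaves this unspecified, so the
  rescaling is a documented choice here.

## Known limitations

* No watershed or shape-model splitting of touching cells — deliberately:
  area normalization replaces it.
* Global thresholds only; strongly non-uniform illumination needs external
  normalization or per-image adaptive choice of `T`.
* The TIFF codec covers uncompressed baseline TIFF (8/16-bit, gray/RGB/RGBA,
  single- and multi-page); compressed or planar variants must be converted
  first.
* Stack pooling counts a cell once per slice it appears in; absolute counts
  from stacks are per-slice-equivalents, while fractions are unaffected.
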