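---
title: "Quantifying retinal degeneration: methods behind retmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal degeneration: methods behind retmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

retmorph quantifies structural and functional retinal phenotypes of the
kind reported for the *Sgcd*-null mouse, a proposed model of retinal
degeneration: thinned retinal layers, frequent full-thickness tissue
ruptures ("solutions of continuity"), denser nuclear layers, and
unchanged scotopic ERG responses.  This vignette documents the models,
the tunable parameters, and the design decisions, in the package's own
terms.

## Histomorphometry model

An H&E-stained retinal cross-section is treated as a long, bowed band of
eight stacked layers (Ch/RPE, photoreceptor outer and inner segments,
ONL, OPL, INL, IPL, GCL).  All measurements are referenced to a fitted
**retinal curve**:

1. **Luminance.** The RGB slide is reduced to the HSV value channel
   (per-pixel channel maximum), following the original workflow's
   HSV-based grayscale conversion.  A Rec.601 luma option exists.
2. **Extraction.** Tissue is everything darker than the
   tissue/background luminance cut.  H&E luminance is trimodal (nuclei
   around 110, eosin around 230, background around 245 on the fixed
   synthetic palette), so a single Otsu split lands between nuclei and
   everything bright; `luminance_classes()` therefore applies a second
   Otsu pass inside the bright class when a distinctly dark class exists
   (class-mean ratio below 0.6).  Morphological closing (radius 3 px)
   bridges staining speckle; tears wider than twice the closing radius
   survive — they are the signal, and they genuinely fragment the band,
   so all components at least 5% of the largest are retained.
3. **Curve fit.** Mask pixels are rotated to their principal-axis frame;
   band mid-points are taken in 2 px bins, bins that do not span the
   full band (rupture edges, band ends, below 60% of the median pixel
   count) are dropped, and a smoothing spline (<= 10 effective df,
   pixel-count weights) is fitted with one robust re-fit pass that
   removes mid-points further than 3 MAD from the curve.  Rupture wedges
   cut the band obliquely and would otherwise bias the midline by tens
   of pixels.
4. **Frailty index.** Luminance is averaged over the curve normal
   (band half-width 0.35 of the estimated band thickness) at ~1 px
   arclength steps.  Positions brighter than the midpoint between the
   tissue median and the image background level are flagged; flagged
   runs closer than `min_width_um` merge (ties merge, conservatively),
   runs narrower than `min_width_um` (default 5 um, about one nucleus
   diameter) are dropped; surviving runs are counted.  The original
   work does not state its threshold; the tissue/background midpoint is
   the package's choice and is overridable.  Without a supplied
   background level the threshold falls back to an Otsu split of the
   profile itself, declared rupture-free when the class means are
   within 8 luminance units.
5. **Thickness.** Sites sit 500 um to each side of the operator-supplied
   optic-nerve landmark (three measurements per side, 25 um apart,
   emulating repeated measurements per eye).  Along each site's normal,
   per-layer thickness is the length of the normal segment covered by
   the layer, averaged over sites; the total is the sum of layers.
   Sites whose normal does not cross every layer (inside a rupture) are
   skipped and logged.  Synthetic images provide per-pixel layer labels;
   real slides fall back to luminance-class transitions, which resolve
   only the band total and the dark-bright-dark ONL/OPL/INL triplet
   (the ONL is the wider nuclear run).  The remaining interfaces are not
   luminance-separable, a documented limitation.

## Nuclei density

Within the band, nuclei are binarized by the nuclear/cytoplasm Otsu cut
(nuclei = 0, the rest = 255, polarity-checked).  The nuclei-pixel
fraction per normal-offset bin (2 px bins, well below the ~11-20 um OPL)
has two maxima — the nuclear layers — separated by a genuine valley (the
OPL, required to dip below half the lower peak).  Of the two bands, the
one holding more nuclei is labelled ONL: the outer nuclear layer is the
thicker, denser one, so labels follow tissue content rather than image
orientation.

Counting is pixel-based: summed nuclear area divided by a calibration
area per nucleus, which tolerates clumping better than
connected-component counting (offered as an option).  Two refinements
were needed beyond the plain pixel rule:

* **Calibration** is the median area of isolated, approximately round
  components, measured on the *sparser* nuclear band — in a packed ONL
  nearly every component is a clump.
* **Overlap correction** (pipeline default): with coverage fraction $p$
  and nucleus area $A$, the underlying intensity is estimated as
  $\hat\lambda = -\log(1-p)/A$ (Boolean-model inversion) rather than
  $p/A$.  Overlapping nuclei share pixels; at ONL-like packing the raw
  pixel sum undercounts by ~15%.  `nuclei_density()` itself defaults to
  the uncorrected rule so that the arithmetic identity (two disjoint
  calibration-area nuclei in 100 um^2 give density 2.0) holds exactly.

## ERG model and feature extraction

Flash responses are modelled as a negative a-lobe followed by a positive
b-lobe, both raised-cosine bumps with disjoint supports, so the analytic
trough depth equals the a-amplitude and the trough-to-peak excursion
equals the b-amplitude exactly — the literature gives no waveform model,
and compact supports make generator truth exact on the sampling grid.
Sixteen repetitions (the standard averaging count) carry i.i.d. Gaussian
noise.  Defaults: 2 kHz sampling, 250 ms records, onset 20 ms, a-wave
150 uV at 15 ms, b-wave 450 uV at 45 ms, noise 20 uV, flash intensities
0.3-1.2 log cd·s/m².

Extraction mirrors standard practice: baseline is the pre-onset mean;
the a-trough is the post-onset minimum within 50 ms; the b-peak is the
post-trough maximum within 150 ms (both windows configurable; typical
rodent scotopic values).  The b-amplitude is measured trough-to-peak —
when no a-trough exceeds the 5 uV detection floor, from baseline
instead.  Deflections below the floor raise quality flags.  Bandpass
filtering (3-300 Hz, matching the amplifier setting) is zero-phase
frequency-domain filtering with raised-cosine transitions; oscillatory
potentials are not removed before peak search.  The c-wave is out of
scope (standard flash windows are too short).

## Statistics

The decision tree follows the study design: parametric statistics
(pooled Student's t — the literature names Student, Welch is an option)
when both groups have at least 30 observations and pass a
Lilliefors-corrected Kolmogorov-Smirnov gate (Monte-Carlo p, seeded);
otherwise the exact Wilcoxon rank-sum test with the Hodges-Lehmann
median difference.

* `wilcoxon_exact()` enumerates all `choose(na+nb, na)` rank
  assignments (midranks under ties) for pooled sizes up to 20 and
  reports `2*min(P(W<=w), P(W>=w))` capped at 1 — two-sided, which the
  printed floor 0.0286 = 2/70 at 4-vs-4 implies.  Null distributions
  are cached per size and tie pattern.
* `hodges_lehmann()` returns the median of all pairwise differences
  with an exact Mann-Whitney order-statistic interval (conservative,
  coverage at least nominal; how the published intervals were computed
  is not stated, this is the standard exact choice).
* Bonferroni family size is caller-specified (8 for the eight layer
  comparisons); the publications do not state theirs.
* `t_from_summary()` reproduces t-tests from printed mean/SD/n so
  published tables can be checked without raw data.

## The synthetic stated world

Generator defaults are the reported group values: layer thicknesses are
the printed per-layer means for wild-type and knockout
(`reference_layer_profile()`), nuclei densities 2.5/1.6 (WT) and
2.7/1.96 (KO) per 100 um^2, a knockout rupture count centred on the
reported median 13, protein-expression shifts equal to the published
median differences (alpha up, beta/gamma/delta/epsilon down, sarcospan
slightly down).  Where the sources are silent the defaults are one-time
field-plausible choices: 1 um/px scale (slides at x5-x40 are not given a
pixel pitch), nucleus radius 2 um (4-5 um photoreceptor somata), rupture
width 20 um (figure-scale tears), arc bow 3% of image width (eyeball
curvature at section scale), pixel noise SD 2 gray levels, measurement
noise SD 0.1 normalized-expression units.  Note the printed per-layer
means sum to ~491 um (WT), exceeding the printed total 252.4 um; the
generator plants the per-layer values and reports totals as their sum,
while the printed totals are still used for the summary-statistic
t-test target.

What a green test establishes — and what it does not: the synthetic
slides have ideal staining contrast, no sectioning artifacts, no
illumination gradients, disk-shaped nuclei and ruptures that are clean
background-colored wedges; recovery there validates the algorithmic
chain, not robustness to real histology.  Similarly the ERG kernel is
smooth and unimodal per lobe; real traces carry oscillatory potentials.

## Numerical choices and degenerate inputs

Seeds propagate explicitly (`with_seed` preserves the caller's RNG
state); identical spec + seed is bit-identical.  Curve fitting requires
a principal-axis aspect ratio of at least 2 (a filled square is a
geometry error).  Rupture placement needs the spans to fit with
three-width separations, else a validation error names the field.
Degenerate statistics error early: constant samples in the KS gate,
zero variance in both t-test groups, empty samples in rank tests.  In
Friedman's test, fully tied blocks give statistic 0 and p = 1 (the tie
correction would otherwise divide by zero).

## Known limitations

* Real-slide thickness resolves total/ONL/OPL/INL only.
* The optic-nerve landmark is a required input, not auto-detected.
* The rupture count's unit of analysis (eye) follows the structural
  table; whether the published 13 is per slide, eye or animal is
  ambiguous in the source.
* The Boolean overlap correction assumes approximately independent
  nucleus placement; strongly regular packing would overcorrect.
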