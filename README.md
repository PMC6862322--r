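# retmorph

Quantitative retinal phenotyping for rodent degeneration studies, built
around the measurements used to characterize the *Sgcd*-null mouse
retina: H&E histomorphometry (per-layer thickness, a rupture-counting
frailty index, nuclei density per 100 µm²), scotopic flash-ERG a-/b-wave
features, and the exact small-sample statistics such studies report.  A
seeded synthetic-data module generates every input — H&E-like slide
images, ERG traces, two-group expression tables — with ground truth
attached, so the full pipeline is testable without any microscope or
electrode data.

## Who it is for

Vision researchers quantifying retinal cross-sections and flash ERGs in
small rodent cohorts, and anyone needing exact rank-based two-group
inference (enumerated Wilcoxon, Hodges–Lehmann intervals) at n of 4–20.

## The measurements

**Frailty index.** The retina band is extracted from the slide's HSV
luminance, a smoothing-spline **retinal curve** is fitted through the
band midline, and luminance is averaged along the curve over the normal
direction.  Full-thickness ruptures ("solutions of continuity") appear
as background-bright plateaus of the profile; runs brighter than the
tissue/background midpoint, wider than 5 µm after merging, are counted:

```
n_discontinuities = #{ maximal runs: value − median(tissue) > θ, width ≥ w_min }
```

**Thickness.** At sites 500 µm to each side of the optic-nerve landmark
(3 measurements per side), per-layer thickness is the length of the
curve-normal segment covered by each layer; the total is the sum over
the 8 layers (Ch/RPE, PR outer/inner segments, ONL, OPL, INL, IPL, GCL).

**Nuclei density.** Nuclei are Otsu-binarized within the band, the OPL
is segmented as the low-density valley between the two nuclear bands,
and density is `100 · count / area` with the count from summed nuclear
pixel area over a per-nucleus calibration area (Boolean-model overlap
correction in the pipeline).

**ERG.** Repetitions are averaged (16 by default), optionally band-passed
3–300 Hz; the a-wave is baseline-to-trough with implicit time from
stimulus onset, the b-wave trough-to-peak.

**Statistics.** n ≥ 30 and a Lilliefors-corrected KS pass → pooled
Student's t; otherwise exact enumerated two-sided Wilcoxon rank-sum
(p = 2·min(P(W≤w), P(W≥w)) over all C(n₁+n₂, n₁) rank assignments) with
the Hodges–Lehmann median difference and exact Mann–Whitney interval.
One-way ANOVA and Friedman tests with Bonferroni-corrected pairwise
comparisons round out the published decision tree.

## Worked example

```r
library(retmorph)

img <- generate_retina_image(retina_spec(n_ruptures = 5L, seed = 42L))
fr  <- frailty_index(img)
fr$frailty$n_discontinuities
#> [1] 5

gt <- img$ground_truth
i  <- which.min(abs(gt$midline_t_um - gt$landmark_t_um))
lm <- gt$midline_xy_um[i, ] / img$pixel_size_um
th <- measure_thickness(fr$curve, labels = gt$labels,
                        landmark_t_um = curve_locate(fr$curve, lm[1], lm[2]))
round(th$per_layer_um, 1)
#>            ChRPE PR_outer_segment PR_inner_segment              ONL
#>             42.8            109.5            135.8             67.0
#>              OPL              INL              IPL              GCL
#>             19.8             49.5             53.6             13.1
round(th$total_um, 1)
#> [1] 491

d <- nuclei_density_pipeline(img)
c(ONL = d$onl$density_per_100um2, INL = d$inl$density_per_100um2)
#>  ONL 2.71  INL 1.72        # planted: 2.5 and 1.6 per 100 µm²

f <- extract_ab_waves(average_responses(generate_erg_trace(erg_spec(seed = 42L))))
#> a: 152.3 uV @ 13.5 ms;  b: 451.7 uV @ 44.5 ms   (planted 150/15, 450/45, noisy)

wilcoxon_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))
#> wilcoxon_exact: estimate NA, -% CI [NA, NA], p = 0.02857
hodges_lehmann(c(0.42, 0.38, 0.45, 0.40), c(1.19, 1.22, 1.18, 1.25))
#> hodges_lehmann: estimate -0.8, 95% CI [-0.87, -0.73], p = 0.02857
```

The five planted ruptures are recovered exactly; layer thicknesses match
the planted wild-type profile to sub-pixel accuracy; 0.02857 = 2/70 is
the exact two-sided floor for fully separated groups of four.

A complete two-genotype synthetic study (images, ERG at four flash
intensities, expression tables, comparison report) is one call:

```r
demo <- run_demo(seed = 1, out_dir = "demo_out", n_per_group = 6)
demo$report   # total + 8 layers + 2 densities + rupture count, with p-values
```

## Not in scope

Automatic optic-nerve detection, GCL cell counting, stain deconvolution,
photopic/flicker ERG protocols, Naka–Rushton fits, and statistics beyond
the published decision tree.
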