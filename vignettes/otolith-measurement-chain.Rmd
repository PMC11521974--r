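---
title: "The otolith measurement chain: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The otolith measurement chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otomorph)
```

# What the package measures

The otolithic organs (utricle and saccule) sense linear acceleration
through a dense mass of calcium-carbonate otoconia overlying the macula.
Their central band — the striola — is thinner and less dense than the
flanking extrastriola, and its integrity degrades with age. `otomorph`
implements four measurements of that system and the statistics used to
compare them across an age-by-sex cohort:

1. **Micro-CT morphometry.** The otolith is segmented inside a hand-drawn
   ROI at the midpoint threshold $T = (\alpha + \beta)/2$, where $\alpha$
   is the CT-number summary of the otolith ROI and $\beta$ that of a
   disjoint surrounding-tissue ROI. Volume (voxel count × voxel volume)
   and mean CT number over the segmented voxels follow.
2. **Striola edge volume.** The band $0.9\,T \le \mathrm{CT} < T$ sits on
   the CT-number slope flanking the striola. Its volume — the voxels
   *newly detected* when the threshold is relaxed by 10% — is small when
   the boundary is steep and grows as the boundary becomes gentle, which
   is the aged phenotype.
3. **Otolith layer angle.** On an electron micrograph, the angle between
   the lateral-extrastriola (LES) otoconial surface and the basal plane
   of the striola, in $[0^\circ, 90^\circ]$. $90^\circ$ means a sharply
   delimited striola; $0^\circ$ means the boundary has collapsed.
4. **Otolith function index (LVOR).** During linear translation in the
   dark, the mouse eye shows a disconjugate vertical shift that follows
   head *acceleration*. Per stimulation cycle the index is half the
   peak-to-peak excursion of the vertical axis-angle component of the
   left eye relative to rest, and the reported index is the mean of the
   three largest of the five cycles.

The study's group comparison — normality screen, two-way age × sex ANOVA
with interaction, Bonferroni post-hoc among the four cells when the
interaction is significant, $p < 0.05$ throughout — is implemented in
`group_stats` functions over per-ear cohort tables.

# The synthetic-data generators

No animal data ship with the package; every stage is exercised on
generated inputs whose statistical structure matches what the analysis
assumes.

## CT phantom (`gen_ct_phantom`)

An ellipsoidal otoconial body (default semi-axes 40 × 60 × 100 µm on a
64³ grid of 5 µm voxels) of CT number `mu_otolith = 200` in a background
of `mu_background = 50`, with a planar low-density channel of width 16 µm
through the center standing in for the striola. Two knobs matter:

* `edge_blur_um` — Gaussian smoothing of the noiseless density field.
  This is **the aging knob** for the edge statistic: it converts the step
  boundary into a ramp, and every micrometer of blur widens the shell of
  voxels falling inside the $[0.9\,T, T)$ band. The default is 0 (a
  steep, young-type boundary).
* `striola_depth = 0.8` — the channel's density is reduced by
  `depth × (mu_otolith − mu_background)`, i.e. to CT 80. The value is
  deliberately below the edge band: the ROI-mean threshold on the default
  phantom computes to about $T \approx 91$ with band floor
  $0.9T \approx 82$, so the striola reads as the low-density central area
  it is on real reconstructions, the segmented otolith excludes it, and
  the segmented mean CT equals `mu_otolith` on a noiseless phantom. A
  shallower channel (depth ≲ 0.6) would straddle the threshold and make
  volume and mean-CT recovery ill-defined — not a regime the morphometry
  is meant for.

The otolith ROI is the ellipsoid dilated by 10 µm (a hand-drawn ROI
includes surrounding fluid; consequently $\alpha$ is a mixture mean and
$T$ adapts per specimen), and the tissue ROI is a disjoint background
shell. Ground truth (masks, voxel volumes, the analytic
$\tfrac{4}{3}\pi abc$) is recorded before blur and noise.

What the phantom does *not* emulate: anatomical macula curvature, the
striola as a surface groove rather than a full channel, otoconia
granularity, beam hardening, scatter. Two practical consequences: the
planar channel bisects the supra-threshold set, so the
`keep_largest` component filter — useful on real noisy volumes — would
discard one cap on the phantom and is off by default; and passing the
phantom-recovery tests shows the *estimator chain* is correct, not that
real otoliths are measured without bias.

## Sled profile (`gen_sled_trace`)

A pure trapezoidal-velocity profile: accelerate at `a_max`, cruise at
`v_max`, decelerate, over 1.8 m, with 0.3 s dwells at both ends and five
round trips, sampled at 240 Hz. The study's two levels are
1.3 G / 3.25 m/s and 0.7 G / 3.06 m/s; both are feasible over 1.8 m
($v^2/a = 0.83$ and 1.36 m). The profile is the minimal one realizing the
two stated maxima — no jerk limiting — and both bounds are *attained
exactly* because velocity and acceleration channels are the analytic
profile sampled at the trace's own instants. Dwells are exactly
`round(0.3 × 240) = 72` zero-velocity samples: the "approximately 0.3 s"
of the protocol is fixed to 0.3 s for determinism. Leg boundaries are
snapped to the sample grid; the sub-sample position residual this leaves
at each arrival is below one sample's travel at the terminal speed and is
invisible to the ±1-sample displacement contract.

## Eye trace (`gen_eye_trace`)

A linear, lag-free response of the vertical component to acceleration:
$y(t) = g \cdot a(t)/g_0 + \text{drift}\cdot t + \varepsilon$, with
torsional and horizontal components noise-only. Real responses have
latency and mild nonlinearity; neither is quantified for this
preparation, so the model is the simplest one with the documented
property that the waveform resembles acceleration, not position. A pure
transport delay is exposed as `lag_s` for sensitivity checks; the
default is 0.

## Layer tracing and cohort

`gen_layer_points` draws two 100 µm point rows meeting at the requested
angle with isotropic jitter (the manual-pointing error model).
`gen_cohort` draws per-ear records from a 2 × 2 cell-means model with
additive age/sex/interaction shifts and homoscedastic Gaussian residuals
— exactly the ANOVA's assumptions, so the calibration tests measure the
test, not a model mismatch. Default effect directions follow the aging
phenotype (old: density −60 CT, edge volume +4 × 10⁴ µm³, angle −15°,
index −0.6°) with residual s.d. of realistic magnitude for n = 10 ears
per cell.

# Numerical and design choices

* **α/β summary.** The arithmetic mean of each ROI (stable on small
  ROIs); a histogram-mode option exists but is fragile when the otolith
  ROI is generously dilated, because the background mode can dominate
  globally. The per-organ "CT number" is the mean over *segmented*
  voxels, not the whole ROI, which contains fluid by construction.
* **Edge set as a set difference.** `seg(0.9T) \ seg(T)`, with the same
  largest-component policy on both sides. Equivalent to the band
  predicate when the policy is off; the difference form is the literal
  "newly detected region" reading and is what the exhaustive-scan oracle
  checks.
* **Connectivity.** 26-neighborhood, the standard choice for bright 3D
  objects; stated to make results reproducible.
* **Segmentation convention.** `CT ≥ T` (ties inside), voxel-center
  geometry, 0-based physical indexing (`coord = index × spacing`), axis
  order (z, y, x) everywhere.
* **Total least squares for tracings.** Ordinary regression of y on x is
  not invariant to image-axis choice; orthogonal regression is, and the
  angle is folded into $[0^\circ,90^\circ]$ by the absolute cosine since
  a traced line has no orientation.
* **Kinematics.** Zero-phase moving average (window 5 ≈ 21 ms) before
  centered differences; one-sided at the ends. Centered differences are
  exact for the profile's quadratic segments.
* **Cycle segmentation.** Dwell = speed ≤ 20 mm/s for ≥ 0.25 s; one
  cycle = one round trip (motion start after dwell $2k$ to motion start
  after dwell $2k+2$), matching "reciprocated five times" to "five
  repetitive eye movement cycles". These defaults were validated on the
  generator across both stimulus levels.
* **Baseline and peak extraction.** Baseline = mean vertical component
  over all detected dwell samples (the rest position's estimator is not
  otherwise specified). The vertical trace is smoothed (window 41 ≈
  0.17 s) before the per-cycle max/min search: the peak response lives on
  constant-acceleration plateaus ≥ 0.25 s long, which a 0.17 s window
  preserves exactly, while unsmoothed extrema of 0.05° sample noise over
  ~120 plateau samples would bias the half-range upward by ~0.15° — an
  unacceptable error at low gains. The window was chosen by validating
  recovered indices against the closed-form amplitude on generated
  traces. The max/min search spans the full cycle window including the
  intermediate dwell, which is conservative for an acceleration-driven
  response (dwell samples sit at baseline).
* **ANOVA.** Type III sums of squares with sum-to-zero contrasts (the
  convention of the commercial package used in the field), Type II by
  flag; ears are independent observations, with no mixed-effects nesting
  within animal — mirroring the per-ear analysis the cohort tables
  encode. A rank-transform fallback is available when the normality
  screen fails; the screen itself warns and proceeds, since the study
  pathway defines no alternative route.
* **Bonferroni family.** All six pairwise comparisons among the four
  cells by default (m = 6); the four interpretable contrasts (sex within
  age, age within sex) are flagged, and `family = "primary"` restricts
  to them with m = 4. Reported near-1 adjusted p values arise naturally
  from the min(1, m·p) cap.
* **KS normality test.** Compared against a normal with the sample's own
  moments (Lilliefors-style); its p value is conservative, which only
  makes the pass criterion stricter in combination with Shapiro–Wilk.
* **Determinism.** Every randomized generator requires an explicit seed
  and the pipeline runner derives per-stage sub-seeds from the config
  seed; outputs carry no timestamps, so identical config + seed gives
  byte-identical outputs.

# Problem sizes

The test and analysis configurations use 64³ phantoms at 5 µm spacing
(40–96³ where convergence is probed), five-round-trip traces at 240 Hz
(~2 700 samples), 50-point tracings, and cohorts of 10 ears per cell;
calibration uses 400 null and 200 powered replicates. These sizes give
sub-percent Monte-Carlo error on every recovered quantity while keeping
the full suite in the low minutes on one CPU.

# Known limitations

* The phantom's striola is a full planar channel, not a surface groove;
  segmentation-side volume truth is therefore the ellipsoid *minus* the
  channel, and component filtering is inappropriate on the phantom.
* The eye model is linear and lag-free; recovered gain equals true gain
  only under that model, and the 5% recovery margin absorbs smoothing
  and noise effects, not physiological nonlinearity.
* Histology is emulated by ground-truth cross-sections, so the
  area-regression stage validates geometry, not staining or shrinkage.
* The mode-based α/β summary should only be used with tight ROIs.
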