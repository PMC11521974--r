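# otomorph

Quantifying age-related change in the otolithic organs of the inner ear:
a tested R implementation of the full measurement chain from micro-CT
voxels and eye-movement traces to cohort statistics.

## The problem

The utricle and saccule sense linear acceleration through a dense mass of
calcium-carbonate otoconia. With age, the otoconial layer loses density
and its central band — the striola — loses its sharp boundary, and
otolith-driven reflexes weaken. Testing those claims requires four very
different measurements, each with its own pitfalls, plus a common
statistical pathway. `otomorph` packages all of them, together with
synthetic-data generators that make every stage testable without animal
data:

| Measurement | Core quantity |
|---|---|
| CT morphometry | segmentation at the midpoint threshold `T = (α + β)/2`; volume, mean CT number |
| Striola edge volume | volume of the band `0.9·T ≤ CT < T` — grows as the striola boundary blurs |
| Otolith layer angle | angle (0–90°) between the lateral-extrastriola surface and the striola basal plane, by total least squares |
| Otolith function index | per stimulation cycle, `(max positive − max negative vertical eye shift)/2`; mean of the three largest of five cycles |
| Cohort statistics | Shapiro–Wilk + KS screen, two-way age × sex ANOVA (Type III), Bonferroni post-hoc among the four cells |

Here `α` and `β` are the CT-number summaries of an otolith ROI and a
disjoint surrounding-tissue ROI, so the threshold adapts to each
specimen's own contrast. The vestibular stimulus is a linear sled:
trapezoidal moves over 1.8 m at 1.3 G / 3.25 m/s or 0.7 G / 3.06 m/s,
0.3 s end dwells, five round trips, sampled at 240 Hz; lateral travel
stimulates the utricle, longitudinal travel the saccule.

## Worked example

```r
library(otomorph)

# a synthetic otolith: ellipsoid + low-density striola channel + noise
ph  <- gen_ct_phantom(phantom_params(seed = 11))
thr <- compute_threshold(ph$volume, ph$rois)
seg <- segment_otolith(ph$volume, ph$rois$otolith_roi, thr$threshold)
q   <- quantify(ph$volume, seg)
c(threshold = thr$threshold, volume_um3 = q$volume_um3, mean_ct = q$mean_ct)
#>  threshold volume_um3    mean_ct
#>    91.1717 858250.0000   199.7687

# the aging readout: edge volume vs boundary blur
ev <- sapply(c(0, 8), function(b) {
  p <- gen_ct_phantom(phantom_params(edge_blur_um = b, seed = 11))
  t <- compute_threshold(p$volume, p$rois)
  striola_edge_volume(p$volume, p$rois$otolith_roi, t)$edge_volume_um3
})
ev   # um^3 at blur 0 vs 8 um
#> [1]  46250 114375

# LVOR: sled -> eye trace -> otolith function index
tr  <- gen_sled_trace(sled_params())         # 1.3 G, 3.25 m/s, 5 round trips
cyc <- segment_cycles(tr)                    # 5 cycles
eye <- gen_eye_trace(tr, eye_model_params(gain_deg_per_G = 2,
                                          noise_sd_deg = 0.05, seed = 3))
otolith_function_index(eye, cyc)$index       # expect ~ 2 deg/G x 1.3 G
#> [1] 2.610653
```

The threshold lands midway between the ROI summaries (the otolith ROI
deliberately includes surrounding fluid, so α ≈ 132, β ≈ 50); the
segmented volume matches the ground-truth supra-threshold volume to
0.3%; the mean CT recovers the generating density 200 to 0.12%; the edge
volume more than doubles when the boundary blurs from 0 to 8 µm; and the
function index recovers gain × peak acceleration (2.6°) to under 1%.

The `analysis/` directory holds five numbered drivers that run the same
chain as small narrative studies (phantom cohort morphometry, edge-blur
sweep, layer-angle recovery, the four LVOR stimulation conditions, and
cohort statistics), writing their tables under `results/`. A
config-driven runner is also available:

```r
run_pipeline("demo.yaml")   # stages, inputs, seed, output_dir; see ?run_pipeline
```

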