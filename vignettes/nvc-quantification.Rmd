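---
title: "Quantifying penetrating-arteriole dilation from cross-section movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying penetrating-arteriole dilation from cross-section movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(lumenpulse)
```

## The measurement problem

Neurovascular coupling (NVC) matches local cerebral blood flow to neuronal
activity. In awake mice it can be measured directly: a penetrating arteriole
(PA) diving into the barrel cortex is imaged in cross-section by two-photon
microscopy while the contralateral whiskers are deflected by air puffs, and
the lumen — bright, because the blood plasma carries a fluorescent dextran —
dilates transiently. `lumenpulse` turns those movies into numbers: a
per-frame lumen diameter, a basal-normalized response trace, and four
response parameters per arteriole and imaging session, which then feed
nested group statistics across mice, groups, sexes and longitudinal
timepoints.

The acquisition protocol the defaults encode is a 25 s trial sampled at
9.45 Hz, with a 5 s whisker stimulation starting at second 10, ten trials
per arteriole, and two to six arterioles per mouse. The basal (pre-stimulus)
window runs from second 3 to stimulus onset and is half-open; the response
window is the closed stimulation interval, so the onset frame belongs to the
response.

## Per-frame diameter measurement

Each frame passes through four steps:

1. **Intensity adjustment** (`adjust_intensity()`): a linear stretch mapping
   the 1st and 99th intensity percentiles to 0 and 1. Percentiles rather
   than extremes make the mapping robust to hot pixels, and any global gain
   (laser power, detector setting) cancels exactly — the basis of the
   pipeline's intensity-scale invariance.
2. **Binarization** (`binarize_frame()`): Otsu's threshold by default — the
   histogram split maximizing between-class variance — with a fixed manual
   threshold as an override. When the two intensity modes are separated by
   an empty histogram gap every cut in the gap is equally optimal; the
   implementation takes the middle of that plateau so the threshold does not
   ride the edge of either mode.
3. **Component selection** (`select_vessel_component()`): holes are filled
   (the lumen may have a dim core when red cells shadow the plasma), 8-connected
   components are labelled, and the component containing — or nearest to —
   the previous frame's centroid is kept, falling back to the largest
   component on the first frame. The area centroid, border contact and an
   `empty_mask` condition are recorded per frame.
4. **Minimum diameter** (`minimum_diameter()`): chords of the mask through
   the centroid are measured on a 1° sweep over [0°, 180°), each delimited
   by sub-pixel sampling (0.25 px steps, bilinear interpolation, the 0.5
   crossing interpolated between samples), and the minimum over angles is
   the diameter. For an elliptical lumen this is the minor axis, which is
   the quantity that tracks vessel caliber when the section plane is
   oblique.

### Sub-pixel accuracy: why a hard mask is not enough

A binary mask quantizes the lumen edge to the pixel grid. Wherever the
boundary runs parallel to a grid axis, its apparent position jumps in whole
pixels as the vessel dilates, and the minimum-over-angles estimator
preferentially picks up the low side of those jumps. Dilation amplitudes of
interest are 5–30 % of a ~20 µm vessel — fractions of a pixel per frame at
realistic zooms — so the pipeline adds three refinements, each testable on
rendered ground truth:

- **Edge smoothing.** Chords are sampled on a lightly Gaussian-smoothed copy
  of the mask (SD 0.8 px). The 0.5 level of a smoothed 0/1 edge sits exactly
  on the edge whatever its orientation, which removes the staircase error of
  interpolating raw binary pixels. The known inward shift of a smoothed
  *curved* edge (σ²/2 × curvature per side) is added back analytically.
- **Elliptical profile regression** (`method = "ellipse"`, the default in
  `extract_diameter_trace()`). Central chords of an ellipse satisfy
  1/D(θ)² = c₀ + c₁ cos 2θ + c₂ sin 2θ, a linear model in the chord
  profile. An iteratively reweighted (Tukey biweight) least-squares fit
  pools all 180 angles, so single corrupted angles — staircase bands, noise
  specks — carry little weight, and the minor axis
  2b = 1/√(c₀ + √(c₁² + c₂²)) is recovered well below the staircase limit.
  The plain sweep minimum (`method = "chord"`) remains available and is the
  definition used for arbitrary, non-elliptical masks; the fit falls back to
  it whenever the profile is degenerate.
- **Half-intensity edge.** When the adjusted frame is available the chords
  are sampled on a normalized *soft* field (interior level → 1, background
  → 0) instead of the hard mask. The anti-aliased intensity ramp across the
  lumen edge then contributes its sub-pixel information, which is what makes
  slow, shallow dilations (5 % over 4 s) resolvable frame by frame. The
  half-maximum edge criterion is the standard convention in vessel
  diametry.

Frames whose mask is empty, touches the frame border, or whose centroid
falls outside the mask are flagged, carry values linearly interpolated in
time from neighboring good frames, and are excluded from basal statistics;
a trial with more than half its frames flagged is rejected outright.

## From traces to response parameters

Each trial's trace is normalized to its own basal mean (basal = 100 %);
the ten trial traces are then averaged pointwise (`average_trials()`), and
`compute_metrics()` reads four parameters off the averaged trace over the
closed stimulation window:

| parameter | definition | units |
|---|---|---|
| `amplitude_pct` | maximum of the averaged normalized trace in the window; ties resolve to the earliest frame | % of basal |
| `t_max_s` | time from stimulus onset to the amplitude frame | s |
| `t_amp50_s` | first crossing of 100 + (amplitude − 100)/2, linearly interpolated between frames | s |
| `auc_pct_s` | trapezoidal integral of (trace − 100) over the window | %·s |

Two conventions deserve a note. The half-maximum time is referenced to the
*dilation* (50 % of amplitude − 100), not to 50 % of the absolute
normalized value — the latter would precede the stimulus for any trace.
And the AUC integrates the trace minus its 100 % baseline, so a null
response integrates to zero and the AUC behaves as a pure response-magnitude
measure. Longitudinal comparisons (`percent_change()`) follow the same
logic: for the amplitude the dilation component is the quantity compared,
so a halved dilation reads as −50 %.

## The synthetic-movie generator

No raw imaging data ship with the package, so `lumenpulse` carries a
first-class generator whose ground truth the recovery tests measure
against. A trial is a bright ellipse (FITC-filled lumen) on a dark
background whose minor axis follows a parametric dilation time course:
constant basal diameter, a rise — linear by default, gamma-variate-like as
an alternative, since the true kinetic form is not prescribed — peaking at
the frame nearest onset + t_max, and an exponential return with a 2 s time
constant. Dilation is isotropic (both axes scale together), so the true
minimum diameter equals the minor axis at every frame. Rasterization uses
area-coverage anti-aliasing (8×8 subsamples per pixel) so that ~0.1 px
diameter changes are representable; frames are then quantized to
non-negative integers like a photon-counting acquisition, which also makes
the 16-bit TIFF round trip bit-exact.

The noise model captures the dominant awake-imaging artifacts: Gaussian
read noise, optional Poisson shot noise, and per-frame rigid translation
jitter. Jitter is translation only — no rotation or shear — because rigid
displacement is the dominant awake artifact and the measurement is
translation-invariant by construction. Defaults used in the recovery tests:
vessel 1000, background 100 (arbitrary units), read-noise SD 180 (a
contrast-to-noise ratio of about 5), jitter SD 1 px.

Default geometry: 0.5 µm/pixel — a typical two-photon zoom for a single PA
cross-section; penetrating arterioles of 15–30 µm then span 30–60 px. The
field of view is configurable and the renderer refuses geometries whose
ellipse (plus a 4 SD jitter margin) would clip the frame border.

`generate_session()` builds the full hierarchy the statistics assume: per
group, mice receive Gaussian mouse-level offsets on amplitude and time to
peak; each mouse contributes 2–6 arterioles with arteriole-level offsets;
basal diameters are uniform on 15–30 µm. Population defaults (amplitude
15 % ± 3 between mice ± 3 between arterioles; t_max 2.5 s ± 0.4 ± 0.4)
were chosen once as representative of awake-mouse PA responses. One global
seed expands deterministically into per-trial substreams, so a session is
reproducible as a whole while its trials stay independent.

What the generator does **not** emulate: capillaries and pial vessels,
slow drift or z-motion, bleaching, red-blood-cell shadows inside the lumen,
and non-elliptical lumen shapes. Passing recovery tests therefore
demonstrates correctness of the measurement chain under the stated imaging
model, not robustness to every artifact of real data.

## Nested statistics

Arterioles are observations nested in mice, the independent units.
`nested_compare()` fits a linear mixed model with a random mouse intercept
(REML, Satterthwaite degrees of freedom); with one two-level factor the
reported contrast is the nested t-test, with more levels an omnibus F plus
Tukey-adjusted pairwise comparisons on model-based marginal means. When
every mouse's arterioles carry identical values the residual level is
unidentifiable and the model reduces *exactly* to the analysis of mouse
means; the implementation detects this case and uses the closed form, which
is what makes the degenerate contract (equality with the mouse-means t-test)
hold to machine precision rather than to optimizer tolerance. Repeated-
measures ANOVA with sphericity corrections is out of scope; longitudinal
contrasts are handled as paired mouse-level comparisons on percent changes.

Calibration is checked by simulation: under the null (two groups drawn from
the same generator, 8 mice per group, 2–6 arterioles per mouse) the
rejection rate at α = 0.05 over 1000 replicates must sit within 3 Monte
Carlo SE of 0.05, and the null p-value distribution must be near-uniform
(Kolmogorov–Smirnov D < 0.06, our stated tolerance at that replicate
count).

## Intrinsic optical signal mapping

Before arteriole imaging, the whisker-responsive cortical region is located
by IOS: 30 trials of 1.5 s whisker stimulation under 630 nm illumination,
20 s apart. `ios_trial_map()` computes the per-pixel fractional reflectance
change ΔR/R between a response window and the pre-stimulus baseline;
`ios_activity_map()` sums the per-trial maps; `locate_peak_region()`
thresholds at a fraction of the extremum and returns the largest connected
region with its magnitude-weighted centroid. Activated tissue absorbs more
red light, so responses are negative-going; the sign is an explicit
parameter rather than an assumption. The response window defaults to the
stimulation period plus 1 s of hemodynamic lag and is configurable. The
activity map itself is never smoothed, but region localization thresholds a
lightly smoothed copy (2 px Gaussian by default): the hemodynamic response
spans tens of pixels, and on low-SNR maps single noisy pixels would
otherwise compete for the extremum.

## Numerical choices and problem sizes

- Coordinates are row/col, 0-based, pixel centers at integer coordinates,
  stated once and used everywhere (including TIFF I/O).
- Angular sweep 1° by default; halving the step changes ellipse-suite
  results by far less than the 0.2 px convergence tolerance the tests
  assert.
- Chord sampling honors a ≤ 0.25 px step near the edge; the deep interior
  is crossed in coarse jumps that cannot skip a (smoothed) crossing.
- Tie-breaks are deterministic everywhere: earliest frame at equal maxima,
  first of equal Otsu plateau candidates after centering.
- The test suite sizes its simulations to what the properties need rather
  than to the full study scale: 27 ground-truth combinations for the
  zero-noise grid, 50 seeded runs of 10 trials for noisy recovery, 20 seed
  sets of 16 trials for the 1/√n averaging law, 1000 replicates for the
  type-I calibration. The synthetic movies in those tests use 64–96 px
  frames at 0.5 µm/px.

## A worked example

```{r example, eval = FALSE}
protocol <- stim_protocol()
truth <- vessel_truth(basal_diameter_um = 20, dilation_amplitude_pct = 15,
                      t_max_s = 2.5)
noise <- noise_model(gaussian_sd = 180, motion_jitter_sd_px = 1)

trace_um <- diameter_timecourse(truth, protocol)
trials <- lapply(1:10, function(k) {
  render_trial(trace_um, truth, noise, protocol, seed = k)
})
metrics <- measure_pa(lapply(trials, `[[`, "stack"), protocol)
metrics

avg <- average_trials(lapply(trials, function(tr) {
  normalize_trace(extract_diameter_trace(tr$stack), protocol)
}))
autoplot(avg)
```

## Known limitations

- The minimum-diameter definition is the minimal chord through the
  centroid; the minimal Feret (caliper) diameter is a plausible alternative
  reading and is not implemented.
- The ellipse-profile estimator assumes an elliptical lumen; strongly
  non-convex masks fall back to the sweep minimum with its staircase-level
  accuracy.
- Whether the original analysis referenced t_Amp50% to the dilation or to
  the absolute normalized value, and whether its AUC included the baseline
  offset, are open conventions; this package's choices are documented above
  and applied consistently.
- Group differences reported in the source study depend on its raw imaging
  data and are not reproducible here; the statistics layer is validated by
  calibration and power simulations on synthetic sessions instead.
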