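---
title: "Quantifying neurovascular coupling in zebrafish lightsheet imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neurovascular coupling in zebrafish lightsheet imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvcflow)
```

## The measurement problem

Neurovascular coupling (NVC) is the local increase in cerebral blood flow that
follows neural activation. In zebrafish larvae it can be measured
non-invasively: a lightsheet microscope images a single sagittal plane of the
optic tectum at 32 frames/s while a red LED delivers an 8 s visual stimulus,
recording an erythrocyte reporter (gata1) and a neuronal calcium reporter
(GCaMP) simultaneously; separate 1 µm-step Z-stacks of an endothelial
reporter (kdrl), optionally with a junctional claudin-5a GFP reporter,
capture the tectal vasculature in 3-D. `nvcflow` turns these recordings into
numbers: erythrocyte (RBC) speed and its stimulus-locked change, ΔF/F calcium
metrics with peak timing, vascular morphometrics, and the period-wise
statistics that compare them within and between animals.

All times are expressed relative to stimulus onset (t = 0). The analysis
windows are half-open intervals — *baseline* [−10, 0) s, *response* [0, 20) s,
*recovery* [20, 30) s — so a frame at exactly t = 0 belongs to the response
and no frame is counted twice:

```{r}
define_periods(stimulus_onset = 29, stimulus_duration = 8)
```

Pixels are assumed square (0.609 µm at the instrument's magnification);
anisotropic in-plane pixels are rejected at construction. Images use a
top-left origin with (y, x) ordering and 0-based pixel coordinates.

## Erythrocyte speed by particle-tracking velocimetry

Per frame, erythrocytes are segmented by a 3×3 median filter (despeckling;
config-exposed) followed by intensity thresholding. The default threshold is
50% of the frame's 99.9th-percentile intensity, which tracks slow brightness
drift; an absolute threshold can be given instead. Connected components with
area in [`min_area`, `max_area`] px² are reduced to intensity-weighted
centroids.

Centroids are linked frame-to-frame by greedy mutual nearest neighbour: a
head–detection pair is linked when each is the other's nearest candidate and
the link is shorter than `max_disp` pixels. The gate is an
acquisition-matched parameter: the default 20 px/frame corresponds to
~390 µm/s at 32 fps and 0.609 µm/px, and should be raised to ~1.5× the
fastest expected per-frame displacement for faster flows. Tracks may bridge
up to `max_gap = 2` missing frames; bridged positions are linearly
interpolated and flagged. Ties on link cost break lexicographically by
(y, x), making the tracker fully deterministic — and small enough instances
can be checked against exhaustive minimum-total-displacement assignment,
which the test suite does on a battery of ≤3-particle cases.

Per track step, speed is `fps × pixel_size × sqrt(Disp_x² + Disp_y²)` µm/s.
The raw trace `v_raw(t)` is the unweighted mean over all track steps landing
in a frame (pooled across vessels by default; a vessel mask can restrict it).
Missing frames are linearly interpolated — gaps longer than 1 s are left
missing, since inventing a second of haemodynamics is not interpolation any
more — and a centred moving average with a 3 s bin (forced to an odd frame
count, shrinking at the edges) yields `v_smooth`. The stimulus-locked change
is

> ΔRBC = mean(v_smooth over response) − mean(v_smooth over baseline),

with per-period means retained for the statistics layer. The 3 s smoothing
bin blurs the window edges, which biases a true +60 µm/s step down by
roughly 5–10%; the validation bound of 15% on the step recovery accounts for
that known smoothing loss.

## Neuronal calcium

The tectal trace F(t) and a background trace B(t) are per-frame means over
two disjoint ROI masks. With F₀, B₀ their means over the 10 s pre-stimulus
window,

> ΔF/F = ((F − B) − (F₀ − B₀)) / (F₀ − B₀).

This normalisation makes the trace invariant under affine intensity
rescaling (F → aF + c, B → aB + c, a > 0), which the tests assert directly.
A baseline with F₀ − B₀ ≤ 0 invalidates the trace.

Peaks are local maxima of ΔF/F above a threshold, separated by at least 1 s
(stronger peaks suppress weaker neighbours). The threshold is
`k_sd = 2` baseline standard deviations with an absolute floor of 0.05 ΔF/F.
The floor matters: in very quiet recordings (and in clean simulations) the
baseline s.d. can be orders of magnitude below any physiological transient,
and a purely statistical threshold would promote numerical ripples to
events. On a noiseless trace the floor is the only active threshold.
Peak amplitude is measured from the preceding local minimum. Per-period peak
counts and rates (count / window length) feed the statistics; for timing, a
peak is attributed to the latest stimulus event (onset at t = 0, offset at
t = stimulus duration) that precedes it, and `t½` is the first time after
that event at which ΔF/F crosses half the peak amplitude, located sub-frame
by linear interpolation.

## Vascular morphometry

Z-stacks are segmented with a single global Otsu threshold over the whole
channel (256-bin histogram), which accommodates variable vessel brightness
better than a fixed cutoff; components smaller than `min_size = 50` voxels
are removed (6-connectivity, largest component always kept). Centerlines are
computed on the 2-D maximum-intensity projection of the binary mask — all
lengths and radii are therefore in-plane quantities — by two-subfield
morphological thinning to a 1-px, 8-connected skeleton.

Raw thinned skeletons are not graphs yet. Two numerical choices make them
one:

* **Reduced pixel graph.** All 4-adjacent skeleton pixels are connected
  (weight 1); a diagonal pair is connected (weight √2) only when no common
  4-neighbour lies on the skeleton. This removes the staircase double-counts
  that otherwise make straight oblique lines look like chains of junctions.
* **Junction complexes.** Pixels of reduced-graph degree ≥ 3 are junction
  pixels; single-linkage clustering merges those closer together than the
  sum of their local radii (never less than 2 px), because one anatomical
  bifurcation of a thick vessel yields several nearby 3-way pixels. Each
  cluster's centroid is one reported branch point. Terminal spurs shorter
  than 5 px are pruned first.

Segment length is the chord-resampled polyline length of each
branch-to-branch path (chords every 5 px; stride 1 recovers the classic
1/√2 step metric, which overestimates oblique vessels by up to ~14% and is
kept available for comparison). Two correction terms remove known thinning
biases, both derived from the exact distance transform rather than fitted:
free tube ends are extended along their local direction to the mask boundary
minus the local radius (thinning retracts centrelines from rounded caps by
about one radius), and one local radius is added per branch point (the two
child tubes of a bifurcation merge into a single throat for about one radius
before their centrelines separate). On rendered test trees these choices
recover total length within 5% at any orientation and branch-point counts
exactly.

The radius at each centreline pixel realises the centreline-to-edge distance
as an exact Euclidean distance transform to the vessel-edge pixel set
(foreground pixels 4-adjacent to background), plus half a pixel because an
edge-pixel centre sits half a pixel inside the physical boundary. The
half-pixel term makes the estimator's worst-case error 0.5 px over all true
radii instead of biased low. Radius histograms use 0.5 px bins — "unique
radius values" of a Euclidean distance transform are half-integer dense, so
binning below that resolution would fragment the distribution. Radii are
reported in µm with the pixel size recorded.

Claudin-5a reporter intensity is the mean GFP intensity over the vessel mask
voxels divided by total vascular centreline length — the density
normalisation that removes bias from treatment-induced differences in
vascular length; a volume-based denominator is a trivial variant.

## Statistics

Within-animal period comparisons are gated on normality: Shapiro–Wilk per
period, all three must pass at α = 0.05 (per-period granularity, the
strictest reading). If they pass, a one-way repeated-measures ANOVA is used,
with the Greenhouse–Geisser correction applied when the sphericity ε falls
below 0.75 (ε computed from the within-subject covariance matrix);
otherwise a Friedman test. A significant omnibus (p < 0.05 — required before
any post hoc) is followed by Sidak-adjusted pairwise comparisons
(`p_adj = 1 − (1 − p)^m`): paired t-tests on the parametric branch, Wilcoxon
signed-rank otherwise. Between-group comparisons for each period use a
parametric two-way ANOVA (group × period) regardless of the gate — per-cell
Shapiro p-values are still reported for inspection — with Sidak-adjusted
unpaired t contrasts within periods. Two-group comparisons are paired or
unpaired t-tests with explicit degenerate-variance guards. All tests are
deterministic given the data; the type-I error of both omnibus routes is
verified by 1000-replicate null simulation in the acceptance suite.

Two trials per animal are averaged before testing by default
(`stats$average_trials`); treating trial as a factor is available but not
default, since the trials are technical replicates of one physiological
state.

## What the synthetic generators emulate — and what they do not

Every downstream stage is validated on seeded synthetic imagery with
analytic ground truth:

* `simulate_rbc_movie()` advects Gaussian blobs (σ = 1.5 px, amplitude well
  above threshold) along planar vessel centrelines, stepping speed from
  `v_base` to `v_resp` inside the response window, over a dim lumen glow
  plus clipped Gaussian camera noise. Cells are placed round-robin over
  segments at equal ring spacing with a common random phase and wrap at
  segment ends, which keeps concurrent detections separated — the regime a
  nearest-neighbour tracker is designed for, and the regime the defaults
  assume in real tectal capillaries.
* `simulate_calcium_movie()` renders a tectal region at
  `background + F₀ (1 + Σ transients)` over a uniform background, each
  transient a double-exponential kernel `(1 − e^{−t/rise}) e^{−t/decay}`
  scaled to unit maximum. With this additive-background model the noiseless
  ΔF/F of the recording equals the transient sum exactly, so the definition
  can be asserted exact to 1e−9.
* `make_vessel_stack()` rasterises tubes of known axes and radii;
  `random_tree_spec()` grows seeded binary trees whose branch-point count,
  segment lengths and radii are known by construction, with rejection
  sampling that keeps non-adjacent tubes a diameter apart so rasterisation
  cannot merge them.

The generators deliberately omit optics (PSF, lightsheet stripe artefacts),
pulsatile and laminar-profile flow, cell shape, motion artefacts, photobleaching
and vessel-brightness heterogeneity beyond a global level. Passing the
validation suite therefore demonstrates that the *quantification* is correct
on data satisfying the stated model — it does not certify segmentation
robustness against every real-world artefact, which is why every threshold
is config-exposed.

Reproducibility is structural: every generator takes a seed, records it in
its truth sidecar, and regenerates bit-for-bit; experiment stages derive
their seeds from one root seed via `derive_seed()`, and `run_nvc_experiment()`
on a fixed config writes byte-identical result tables.

## Problem sizes and runtimes

The validation suite simulates full-length recordings at the acquisition
frame rate (42 s at 32 fps, 128×208 px; ten cells) for the speed-recovery
checks, a 20-seed null battery at 16 fps on a four-vessel field for the
no-modulation bound, 50 seeded calcium recordings for peak recall/precision,
rendered 128×128×40 stacks for morphometry, and 1000-replicate null
simulations for the test-size calibration. These sizes keep the whole suite
in the minutes range on one CPU while leaving every estimator's error well
inside its acceptance band.

## Known limitations

* Lengths and radii are 2-D projected quantities by design (the 3-D skeleton
  mode is an extension point, not a default); steeply out-of-plane vessels
  are foreshortened.
* The tracker is nearest-neighbour, not a global assignment over time;
  dense, fast flows with cell spacing below the per-frame displacement will
  swap identities (speed, the pooled quantity, is robust to same-direction
  swaps, but trajectories are not).
* Radius estimates saturate at the half-pixel resolution of the distance
  transform; sub-pixel vessel walls (1-px masks) report radii below 1 px.
* Heart-rate quantification and kymograph velocimetry are out of scope.
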