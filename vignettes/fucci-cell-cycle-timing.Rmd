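---
title: "Measuring cell-cycle phase durations from FUCCI time-lapse movies"
author: "fuccitrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cell-cycle phase durations from FUCCI time-lapse movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuccitrack)
```

## The measurement problem

The FUCCI reporter pair marks cell-cycle state by color: mKO2-Cdt1 (red)
accumulates in G1 nuclei and is degraded at S entry, while mAG-Geminin
(green) accumulates from S through mitosis and is destroyed at cytokinesis.
In a two-channel time-lapse movie, a cell's G1 duration is the time from its
birth (the mother's division) to the onset of the green reporter — the G1/S
transition — and its S/G2/M duration runs from green onset to its own
division. Two artefacts make this harder than reading off two channel
maxima:

* around the G1/S transition both reporters are present at once (the red
  degron takes time to clear after S entry), and
* for several frames after mitosis *neither* reporter is detectable — the
  dark gap — so naive frame-to-frame tracking loses every cell exactly at
  the most informative moment.

`fuccitrack` implements a headless version of the click-assisted analysis
used for this kind of data: adaptive-threshold segmentation of each channel,
union of the two binary stacks, seeded connected-component selection driven
by a *click script* (a CSV of `frame,x,y,cell_id,parent_id` records standing
in for interactive mouse clicks), nearest-centroid propagation between
clicks with a bounded dark-gap tolerance, and conversion of the per-cell
mean-intensity traces into phase durations with explicit censoring.

Because no raw imaging data are available to ship, the package carries a
first-class synthetic-data module. Every pipeline stage is tested against
movies rendered from lineages with known ground truth.

## The generative model

`cell_cycle_model()` describes one genotype. G1 and S/G2/M durations are
independent lognormals parameterised by their *median* (minutes) and log-sd.
The lognormal was chosen because durations are positive and the published
single-cell distributions are strongly right-skewed (sds comparable to the
medians); `lognormal_logsd()` converts a reported median ± sd pair into the
log-sd, so the presets are calibrated directly to printed cohort statistics:

```{r presets}
npc_model("wt"); npc_model("mut")
hesc_model("wt"); hesc_model("mut")
```

The wild-type and mutant neural-progenitor (NPC) G1 calibrations are
1408 ± 982 and 517 ± 410 min; the embryonic stem cell (hESC) calibrations
are 198 ± 78 and 153 ± 61 min. S/G2/M medians are not printed for NPCs; we
use 982 min for both genotypes (roughly 16 h, consistent with no genotype
effect on S/G2/M), and 900 min for hESCs (which spend at least 10 h
outside G1). These are modelling choices, not published values.

Reporter kinetics are linear ramps (`reporter_params()`). One deliberate
deviation from a naive reading of the reporter biology matters for
identifiability: green onset is placed *exactly at the model's G1 end*, and
the red reporter then decays linearly over `overlap_min` *after* green
onset. This reproduces the transient red+green co-expression at G1/S (the
degron decays after S entry), while keeping the quantity the pipeline
measures — time from birth to green onset — identical to the model's G1
duration. Had green instead switched on `overlap_min` *before* the model's
G1 end, every recovered G1 would be biased short by the overlap and the
generator's parameters would not be recoverable from its own movies.

Other generator choices, in brief:

* **Frame interval**: 15 min by default. The acquisition interval of the
  original experiments is unstated; 15 min resolves a 153-min median G1
  (about 10 frames) while keeping a 70-h movie at 280 frames.
* **Dark gap**: 3 frames by default, within the 5-frame tolerance the
  tracker allows.
* **Motion**: a persistent random walk (AR(1) velocity, step sd 1.2 px per
  frame) with soft pairwise repulsion keeping nucleus centres at least
  3 radii apart, and mirror reflection at the field borders. The repulsion
  is not cosmetic: merged nuclei become single connected components and
  break seeded tracking, and densely packed nuclei break local-window
  thresholding (below).
* **Noise**: per-pixel Poisson shot noise at the configured photon gain
  followed by Gaussian read noise, then quantisation to the configured bit
  depth. No photobleaching, drift, or 3D optics are simulated.
* **Founders**: staggered by default — each founder is born at a uniformly
  random position inside its own first cycle before the movie starts, so
  the simulated culture is asynchronous like a real one, and founder G1
  phases are start-censored exactly as they are in real movies.

## Segmentation: why the default k is 1.5

`adaptive_threshold()` marks a pixel foreground when it exceeds the local
mean plus `k` local standard deviations over a `window_px` square
(reflective padding). The window defaults to `4 * nucleus_radius + 1`. The
offset multiplier deserves a note, because the obvious "3 sigma" choice
fails structurally: a nucleus occupying fraction *f* of its own window
contributes a bimodal intensity distribution whose local sd is roughly
`amplitude * sqrt(f(1-f))`. The object's own pixels only clear the
threshold when `k < (1-f)/sqrt(f(1-f))`, which is about 2.1 for a typical
*f* ≈ 0.18 (a radius-6 nucleus in a 25-px window). The default is therefore
`k = 1.5`: over empty background it still sits 1.5 noise-sds above the
mean, and the residual noise speckle (isolated pixels) is removed by the
25-px minimum object area, so a zero-signal movie stays empty.

## Tracking and the division boundary

`run_click_script()` tracks each scripted cell by nearest-centroid matching
within `search_radius_px` (default three nucleus radii), tolerating up to
`max_dark_frames` (default 5) frames of absence. No component is ever
assigned to two cells in one frame; ties are broken by distance, then
larger area, then lower label, and daughters are ordered by x-centroid at
birth. A mother's propagation window ends just before her earliest-clicked
daughter.

The division *frame* itself is taken from the trace, not from the track
end: the mother's green offset (the falling crossing after her last
sustained above-threshold run). The track end alone overruns the true
division whenever faint daughter pixels drift into the matching radius
during the dark gap; the green collapse is robust to that, and taking the
*last* sustained run (rather than the first falling crossing) makes it
robust to brief mid-track dropouts from claim conflicts. The daughter's G1
then starts on the frame after the mother's green offset, which also
assigns the dark-gap frames to the daughter's G1.

## Onsets, phase segments, censoring

`detect_onsets()` calls an onset at the first frame where the 3-frame
median-smoothed trace exceeds `bg_mean + k_onset * bg_sd` (defaults:
`k_onset = 5` on robust background statistics estimated from the movie by
median/MAD) for at least `min_run = 2` consecutive frames. Red+green
co-expression is assigned to G1 up to green onset, matching how G1/S
transition markers are placed on published traces.

Phase segments use half-open frame intervals: G1 is
`[division_frame(mother) + 1, green_onset)`, S/G2/M is
`[green_onset, division_frame(self) + 1)`, and a duration is
`(end - start) * frame_interval`. With onsets quantised by `ceiling` on
both ends this convention is unbiased to first order; boundary errors on
noiseless renders are almost all 0 or +1 frame.

A phase missing a bounding event is *censored* on that side: founders
already fluorescent at their first frame are start-censored; cells whose
green onset or division falls beyond the movie are end-censored, with the
censoring time (track end) recorded in the audit table. Censored phases are
excluded from the duration statistics — only measured durations are
compared between genotypes — but kept in the audit table.

## Recovering cohort medians: why Kaplan–Meier

A finite movie right-truncates long phases: a daughter born at time *b* can
only contribute a complete G1 if her G1 is shorter than `T - b`. For the
wild-type NPC calibration (median 1408 min in a 4200-min movie) the naive
median of complete G1 phases is biased low by roughly 15–20%. This is a
property of the *study design*, not of the tracking. The cohort analysis
therefore estimates the median by the Kaplan–Meier product-limit curve over
complete *and* end-censored daughter G1 records (`km_median()`), which is
consistent under independent censoring — and censoring time (`T - b`) is
independent of the cell's own G1 draw. Founder phases are excluded (their
birth is unobserved, which would be left-censoring). Because the durations
lie on a 15-min grid, `km_median()` interpolates the survival curve
linearly across the 0.5 crossing rather than returning the next grid point,
removing an up-to-half-frame upward bias that matters at the hESC scale
(half a frame is 4% of a 198-min median).

Genotype comparison (`compare_cohorts()`) follows the published
conventions: two-sided Mann–Whitney U (exact by full enumeration for
samples of at most 8 without ties, midrank normal approximation with tie
and continuity correction otherwise), Bonferroni correction with a default
family of 2 (G1 and S/G2/M), and boxplot summaries with linear-interpolation
quartiles and 1.5 × IQR whiskers.

## Study conditions used by the cohort tests

The end-to-end checks simulate, per genotype, 10 replicate 256 × 256 movies
of 280 frames at 15 min/frame (70 h) — 14 founders per wild-type NPC movie,
8 per mutant movie (faster cycling yields more cells), 6 per hESC movie —
which pools well over 200 complete daughter G1 phases per genotype. These
sizes were chosen so that the Kaplan–Meier median's sampling error
(≈ 50–60 min for wild-type NPCs) sits well inside the 10% recovery bands;
a single movie takes tens of seconds to render and analyse, the full cohort
suite minutes. Significance at the published cohort sizes is checked on a
random subsample of 23 wild-type and 34 mutant cells.

## DNA-content gating and its structural limit

`gate_dna_content()` automates the usual manual PI-histogram gating: the
dominant low-intensity mode of a kernel-smoothed histogram is the G0/G1
(2N) peak, the peak nearest twice that position is G2/M (4N), each peak's
width is estimated from its *outer* flank (away from the S plateau, as a
half-normal), gates span ±2 estimated sds, S is everything strictly between
the gates, and events below half the 2N mode are dropped as debris. Manual
gate coordinates can be supplied to override the peak finder.

Threshold gating has an inherent boundary leak: S-phase events whose
measured content falls inside a peak gate are counted with that peak. With
S uniform between the peaks this leak is ≈ `(2cv + 4cv) * f_S` — about 4.5
points of S at a 5% peak CV — so exact round-trip of generator fractions
within ±2 points is only a low-CV property (≈ 2% peak CV, the regime of a
well-stained PI sample). The G0/G1 fraction itself stays within 2 points up
to 8% CV. The principled fix (modelling S under the peaks, as in
Dean–Jett–Fox fitting) is deliberately out of scope; the tests assert the
round-trip in the regime where plain gating can deliver it.

## Ancillary assays and genotyping

* `ddct_fold_change()` implements relative quantification: technical
  replicates averaged at the Ct level per sample/gene/experiment,
  ΔCt = Ct(target) − Ct(reference), ΔΔCt = ΔCt(mut) − ΔCt(wt), fold =
  2^−ΔΔCt per experiment, mean ± sd across experiments. Reference
  subtraction makes it invariant to per-experiment input differences.
* `quantify_rois()`, `nc_ratio()` and `percent_change()` cover
  immunofluorescence quantification; the percent-decrease sd is defined
  over per-cell percent values relative to the control-group mean (the
  per-cell convention; the per-experiment alternative is not computable
  from a single field).
* `classify_allele()` aligns each single-allele amplicon globally
  (match +1, mismatch −1, gap −2, no affine extension — adequate for clean
  Sanger-derived single indels) and classes it by the net gap length within
  a window of the predicted cut site; `allele_census()` adds an exact
  two-sided binomial test against 0.5 (minimum-likelihood convention), with
  "consistent with heterozygous" meaning p ≥ 0.05; `find_premature_stop()`
  scans codons from the edit site for the first stop absent from the
  reference frame. Amplicon fixtures are synthetic sequences engineered to
  have the published properties, not the real locus.

## What the synthetic movies do and do not establish

The generator reproduces the statistical structure the analysis relies on —
lognormal phase durations per genotype, reporter overlap at G1/S, the
post-mitosis dark window, dividing and migrating nuclei, Poisson + Gaussian
imaging noise — so green tests demonstrate that segmentation, tracking,
phase calling and the statistics recover known parameters through the full
imaging path at realistic SNR. They do not demonstrate robustness to what
the generator omits: uneven illumination, focus drift, photobleaching,
apoptotic debris, nucleus shape change through mitosis beyond an ellipse,
cell-cycle exit, or segmentation of truly overlapping nuclei (the click
workflow disambiguates *touching* cells, and the simulator keeps nuclei
from interpenetrating). Boundary accuracy claims (95% of phase boundaries
within ±1 frame on noiseless renders) are therefore statements about the
algorithmic pipeline, not about any specific microscope.
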