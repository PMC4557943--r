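---
title: "Scoring scotoma occlusion of driving hazards: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring scotoma occlusion of driving hazards: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scotowatch)
```

## The problem

People with binocular central field loss (CFL) fixate with an extra-foveal
preferred retinal locus (PRL), and their scotoma — often above or below the
PRL — travels with gaze. On the road, a pedestrian approaching from the side
normally falls on intact peripheral retina, but ordinary vertical eye
movements (a glance at the speedometer, an attempted "foveal" fixation) can
momentarily place the hazard inside the scotoma and delay its detection.
`scotowatch` turns that mechanism into a measurable pipeline: it represents
perimetry-mapped scotomas as convex polygons in PRL-centred visual-field
coordinates, replays a hazard event sample by sample against recorded gaze,
scores how much of the pedestrian's angular extent is occluded at each
instant, and classifies each horn-press reaction as timely or untimely by
stopping-distance kinematics. The statistics layer then asks whether
occlusion predicts reaction time, and whether untimely reactions concentrate
among occluded events.

## Geometry

**Coordinates.** All angles are degrees, treated as planar (tangent-plane)
coordinates — the convention of perimetric charts. The visual field's origin
is the PRL; the scene's reference direction is the car heading. The two are
linked by the momentary gaze: a target at head-centred azimuth/elevation
$(\alpha, \epsilon)$ viewed with gaze $(g_\alpha, g_\epsilon)$ sits at
$(\alpha - g_\alpha,\; \epsilon - g_\epsilon)$ in visual-field coordinates.
A 12° downward glance therefore lifts an on-road pedestrian 12° into the
upper field, where a superior scotoma can cover it.

**Scotomas.** Each scotoma is a convex polygon of at most 100 vertices,
validated and stored counter-clockwise; a field may hold several polygons
(treated as a union) or none (a normal-vision control). Convexity is what
makes the core primitive exact: a vertical line at azimuth $x$ intersects a
convex polygon in at most one closed interval, computed edge-by-edge by
linear interpolation (`vertical_chord()`). Points exactly on the boundary
count as inside everywhere in the package (closed-set convention).

**Occlusion.** The pedestrian (2 m tall) is a vertical angular segment: its
azimuth is the signed bearing from the car heading, its elevation span runs
from foot to head as seen from the driver's eye height (1.2 m, exposed in
the configuration; the value is a plausible sedan eye height and nothing
downstream is sensitive to it at these ranges). The occluded fraction is the
length of the intersection of the segment with the union of per-polygon
chords, divided by the segment length. A sample is *occluded* when the
fraction is strictly positive ("any part inside"). Scotoma size is reported
as the mean of the horizontal and vertical chord lengths through the
polygon's vertex centroid — the average cardinal diameter. The centroid is
used because "the centre" of an irregular perimetric plot is otherwise
undefined; for a field with several scotomas the largest polygon's size is
the field-level value, with per-polygon sizes available.

**Scene kinematics.** Pedestrians appear at the distance the car covers in
5 s (67 m city at 30 mph, 134 m highway at 60 mph) at one of four signed
eccentricities (±4°, ±14°) and walk perpendicular to the road at
$v_\text{car}\tan|\theta|$. With both speeds constant the bearing is exactly
constant — a collision course — until the pedestrian halts at the lane edge
(1.8 m from the car's path), slightly before the 5 s mark for every default
eccentricity; the 0.5° bearing-drift bound over the first 3 s holds exactly.
A reaction is *timely* when the distance remaining to the pedestrian's
crossing station at the horn press is at least $v^2/2a$ with $a = 5\,
\text{m/s}^2$ (dry road, good tires); braking is assumed to start at the
press, and the boundary case counts as timely. Timeliness is therefore
monotone: delaying a press can never turn untimely into timely at constant
speed.

## Stream alignment and the analysis span

Simulator output is 30 Hz; gaze is 60 Hz. Each simulator sample takes the
nearest gaze sample within half a gaze period (±1/60 s) — exactly the
"every other sample" rule when clocks are locked, and robust to a few
milliseconds of offset. The analysis span of an event runs from appearance
to the horn press, or to disappearance when undetected. Gaze-missing samples
score as not-occluded, deliberately under-estimating occlusion, and an event
is *gaze-usable* when at least half of its span carries valid gaze. The 50%
threshold is a package choice: the source data report only the fraction of
usable appearances, not the rule that produced it, and the
availability-bias check (`gaze_availability_check()`) is the guard that the
rule does not skew hazard locations. Its expected counts are proportional to
per-eccentricity appearance totals by default; a uniform expectation is
exposed as an option because the two conventions give slightly different
statistics (0.139 vs 0.215 on the published counts, which print as 0.13)
and the original choice is not recoverable.

## Statistics

Conventions are pinned once: Pearson chi-squares are uncorrected (the
published 20.8 and 5.84 match only the uncorrected statistic);
the Mann–Whitney U counts ties as 0.5 and reports $\min(U_1, U_2)$
(verified against the published U = 21 on binary driver-status data, and
against brute-force pair enumeration in the tests); reaction times are
log-transformed with the natural log (the base only rescales coefficients);
no multiple-testing adjustment is applied. The regression
(`ols_logrt()`) is ordinary least squares of log RT on occlusion time plus
subject indicators with the alphabetically first participant as reference.
Median intervals are percentile bootstrap, B = 2000, seeded; the interval
method in the source report is unstated, and the percentile bootstrap was
chosen for its lack of distributional assumptions at these skewed RTs (its
coverage is itself simulation-tested).

## The synthetic-study generator

The generator exists so every stage is testable without any recorded data.
It emulates the study design: per participant, one city and one highway
drive whose appearances divide evenly among the four eccentricities and the
two drives (default 104 per participant, 26 per eccentricity), pedestrians
on exact collision courses, gaze at 60 Hz, simulator state at 30 Hz.

**Gaze** is a three-state process: forward fixation with 0.5° Gaussian
jitter; downward dashboard glances (Poisson, 6/min; 0.7 s; −12° elevation);
and hazard pursuit, spliced in just before the press (gaze lands on the
pedestrian ~0.25 s ahead of the horn). Tracker dropout is i.i.d. per sample
(8%) plus long gaps (10/min, mean 5 s, exponential) — calibrated once so the
gaze-usable event rate lands near the 37% reported for real CFL tracking,
which is dominated by exactly such multi-second losses.

**Responses** follow
$\log RT = \beta_0^{(s)} + \beta_e\,[|\theta| = 14°] + \beta_o\,T_\text{occ}
+ \varepsilon$, with defaults $\beta_0 = \log 2.5$ for scotoma participants
and $\log 1.25$ for controls (subject spread SD 0.15), $\beta_e = -0.25$,
$\beta_o = 0.3$ log-s per second occluded, $\varepsilon \sim N(0, 0.35^2)$,
detection probability 0.98. These were set once so the realized group
medians land near the descriptive 2.3 s / 1.1 s and the untimely pattern
(about a quarter of scotoma-group reactions, a few percent of controls)
matches the published direction. Because $T_\text{occ}$ is measured up to
the press, RT and occlusion are coupled; the generator resolves this as a
monotone fixed point (occlusion time is non-decreasing in the analysis end,
so iteration converges in a few steps), and the scored pipeline reproduces
the generated reaction and occlusion times exactly.

**What the generator does not emulate.** Only dashboard glances produce
occlusion; real CFL data also show occlusion from fixational instability
(PRL–fovea switching) and from scotoma shapes wider than the synthetic
hexagon, so the synthetic occluded-event share (~12–17%) sits below the 42%
observed in the study. Curved roads, turns, traffic interactions and speed
variation are out of scope; car speed is constant, which also means
timeliness in synthetic runs depends only on press time. Passing tests on
synthetic data therefore demonstrate the correctness of the geometry,
bookkeeping and statistics — not behavioural realism of gaze.

## Parameter recovery and its pitfalls

`recovery_benchmark()` regenerates a known-truth study (three scotoma
participants, ≈300 usable events, slope 0.3) and refits it through the full
pipeline. Two genuine biases were diagnosed while building it, and both are
properties worth knowing when interpreting the real analysis:

1. *Omitted eccentricity:* the fitted model contains occlusion and subject
   terms only. If the generating process also has an eccentricity effect,
   it is correlated with occlusion (only small-eccentricity pedestrians
   fall inside the scotoma's horizontal extent during a glance), inflating
   the slope. The benchmark therefore generates from the model it fits
   (no eccentricity effect).
2. *Protocol endogeneity:* occlusion accumulated up to the press grows
   mechanically with the press time, so residual noise leaks into the
   covariate. The effect scales with the residual variance; the benchmark
   runs at a modest noise SD (0.25 log-s) where it is negligible, and the
   slope CI covers the truth in every calibration replicate.

Both caveats apply equally to any analysis that regresses reaction time on
occlusion measured up to the reaction — including on real data.

## Numerical choices and degenerate inputs

Chord endpoints are exact at vertices (interpolation weights 0/1); a line
touching a single vertex yields a zero-length chord, which counts as contact
but contributes no occlusion. Zero-area and reflex polygons are rejected
with the offending vertex named; vertex count is capped at 100. Empty traces
give occlusion 0 with a warning; a constant-occlusion design makes the slope
unidentifiable and is refused rather than fitted. Presses are matched to the
earliest unanswered event in their window. Problem sizes in the shipped
tests — polygon-oracle sweeps of 1000 random cases, 20-replicate Monte-Carlo
benchmarks, studies of 1–14 participants at 104 appearances each — were
chosen to exercise every code path at stable statistical resolution while
keeping a full run in a few minutes on one core.
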