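---
title: "Quantifying family development from long-term home-cage tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying family development from long-term home-cage tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homecagedev)
```

## The problem

Continuous overhead tracking of a rodent family — two adult Mongolian
gerbils and a litter of up to four pups — in their home cage produces weeks
of per-frame (x, y) positions for each animal across postnatal days
P15–P30, the window in which pups transition from nest-bound infants to
independent juveniles. Machine-vision identity tracking of the six animals
is imperfect, the animals vanish from open-field tracking whenever they
huddle in the nest, and the recording system loses roughly 10% of each
session to saving. This package implements the downstream analysis that
turns such tracks into developmental statistics:

1. **Track repair** — detecting and undoing identity switches, bridging
   short tracking gaps, substituting cage-cleaning days.
2. **Heuristic behavior classification** — region-of-interest occupancy
   (food hopper, waterspout), open exploration, distance traveled, pairwise
   proximity, group socialization, approach events, huddle attribution.
3. **Developmental statistics** — adult-normalized trajectories,
   Kolmogorov–Smirnov rapid-development detection, convex-hull overlap of
   trajectories in principal-component space, identity-shuffle controls,
   and a Monte-Carlo power utility.
4. **Social-state networks** — transition graphs over a discretized arena.
5. **Circadian analysis** — hourly ethograms, day/night partition, and
   automatic detection of the developmental periods that maximize circadian
   separation.

Because the corresponding laboratory recordings (~1,000 h) are not
shippable, the package includes a **family simulator** that plants known
developmental structure, so every stage can be validated by parameter
recovery rather than by eyeballing.

## Data model

A `trackset` holds per-frame positions (cm) for named animals
(`female`, `male`, `pup1`…`pup4`), a frame rate, a cage geometry
(57.2 cm × 35.6 cm floor, origin in a corner, x along the long axis), a
light schedule (day 08:00–20:00, half-open on the day side), and a time
base in seconds since midnight of the anchor postnatal day. Postnatal-day
boundaries are placed at wall-clock midnight — the data give no better
convention, and midnight keeps calendar arithmetic exact. Intervals are
half-open `[start, end)` throughout; frame indices are 1-based as is usual
in R.

Two on-disk dialects are canonical: an HDF5 layout (`/meta`, `/animals`,
`/tracks`, `/timestamps`, optional `/poses`) and a wide CSV
(`time_s, pnd, <animal>_x, <animal>_y`) with a JSON metadata sidecar. A
best-effort adapter ingests generic pose-analysis HDF5 exports; because
pixel calibration is never encoded in such exports, a `px_to_cm` scale is
mandatory metadata rather than a guessed constant.

When 6-node poses are present, an animal's per-frame location is the
**median centroid** — the per-axis median over available nodes — which a
single mislocated node cannot displace (the median of `{1,2,3,4,5,100}` is
3.5).

**Coverage.** Recording downtime makes raw daily totals incomparable across
days. Every daily rate in the package is divided by that day's coverage,
defined as recorded frames / (fps × 86400). Because the same denominator is
used for every component of the daily time budget, the identity

huddle + open + missing-unattributed = 24 h

holds to floating-point precision for every animal-day, and the test suite
asserts it to one second.

## Track repair

**Identity switches.** The error mode of multi-animal identity tracking at
this scale is segment-level: from some frame onward two animals' tracks are
exchanged. The detector flags frame *f* for pair (A, B) when A's
displacement from *f−1* to *f* exceeds `jump_cm` (default 10 cm/frame —
about 2.5 m/s at 25 fps, beyond gerbil locomotion) and B's position at *f*
continues A's track (lies within `refit_cm` of A's position at *f−1*). By
default the test is required **symmetrically** — A must likewise continue
B's track — which makes false positives essentially impossible even when a
third animal happens to sit near the pre-jump position, at no cost in
sensitivity for genuine exchanges (both tracks jump in a genuine exchange).
The one-directional variant is available via `symmetric = FALSE`.

The refit radius must cover one frame of ordinary motion plus tracking
jitter, so its default scales with the frame period:
`speed_cms / fps + 1.2` cm (≈1.6 cm at 25 fps, 3 cm at the reduced
simulation rate). Frame pairs spanning recording downtime are never flagged
— a jump across a 10-minute gap is not evidence of anything.

**Correction semantics.** Identity errors accumulate forward in time: each
switch permutes the labels of the already-switched state. The exact inverse
of that accumulation is to apply the detected events in **reverse
chronological order**, each exchanging the two animals' tracks from its
frame to the end of the session. For same-pair or pair-disjoint event
streams this coincides with the natural reading "swap until the next event
involving either animal"; for overlapping pairs only the reverse-order form
is an exact inverse (same-order reapplication composes to a 3-cycle). The
simulator's corruption injector uses the same forward semantics, and the
suite verifies that detect-then-correct restores the original tracks
bit-for-bit, and that applying one event twice is the identity.

**Gap interpolation.** A missing run is bridged by linear interpolation in
time iff its flanking tracked positions are less than 3 cm apart — short
occlusions, not nest entries (a nest entry leaves the animal missing with
distant or absent flanks). Bridged runs can therefore never contain a step
larger than 3 cm. Huddle intervals less than 30 s apart whose centroids lie
within 6 cm are merged as one huddle.

**Disturbance days.** Cage cleaning perturbs behavior for a day; the
affected day is replaced by the mean of its two neighbors, per animal
(`substitute_day`), and the operation refuses to run at the range boundary
rather than extrapolate.

## Behavior classification

All classifiers run on median centroids of cleaned tracks and produce
either bout tables (`[start_s, end_s)` per subject) or daily matrices in
absolute units (hrs/day, m/day, count/day), always coverage-rescaled.

* **ROI occupancy** uses closed rectangles (a centroid exactly on the edge
  is inside). The food hopper is 19.50 × 10.50 cm and the waterspout
  8.50 × 8.00 cm; their placement along the walls is configurable since
  only the sizes are standardized. Seeded random control rectangles
  (`random_roi`) support placement controls.
* **Nest region**: the modal (1 cm grid, dwell-weighted) huddle centroid of
  each day, dilated to a 12 cm disc. Open exploration is tracked time
  outside it.
* **Distance traveled** sums consecutive-frame displacements, skipping
  pairs that span missing data or recording gaps.
* **Pairwise proximity**: maximal runs with distance strictly below 5 cm
  lasting strictly longer than 200 ms.
* **Group socialization**: per frame, groups are connected components of
  the graph joining animals closer than 5 cm; daily time is reported for
  group sizes 1, 2, 3+ and for pup-only vs any-adult groups.
* **Approaches** implement the operational definition as a rule: an event
  starts when the initiator's speed (5-frame centered moving average, to
  suppress jitter) reaches 2 cm/s, persists while it stays above 1 cm/s,
  must close at least half of the initial inter-animal distance, and ends
  with the initiator stopping within one gerbil length (10 cm adult, 6 cm
  pup — body lengths, since the definition is "at most one gerbil length
  away") or on contact (2 cm). A trained classifier could replace this
  rule, but its training data is not reproducible from the definition,
  whereas the rule is.
* **Huddle time**: an animal is huddling when a huddle is active and either
  its centroid is within 6 cm of the huddle centroid or its track is
  missing — animals disappear from overhead tracking when they pile in the
  nest, so missing-during-huddle is the dominant signature. Whether
  missing-track attribution is used is switchable
  (`attribute_missing = FALSE` keeps only the proximity route), since
  tracking rigs differ in whether huddled animals remain visible.
* **Nest following** counts (pup exit, adult exit within 10 s) pairs, each
  adult exit matched to at most one pup exit, earliest first.

## Developmental statistics

**Adult normalization.** Each pup's daily value is divided by the mean of
the two adults' values on P29, per cohort, so 1.0 means "at adult level".
Multiplying back by the reference recovers the input exactly.

**Rapid development.** For each day *d*, the cross-animal distribution is
compared by two-sample Kolmogorov–Smirnov test against the pooled values of
days *d−2* and *d−1*; p-values are Benjamini–Hochberg adjusted within the
behavior and days with adjusted p < 0.05 are flagged. The comparison set is
the previous two days only by default: that is the operative definition of
"became different from what it was", and it is the form under which a
genuine step change at day *d* is flagged at *d* (a variant additionally
requiring difference from the following day is available as
`comparison = "both"`, but it can never flag the first day of a sustained
change, because the day after the step resembles the step day). Under a
global null the flag rate stays near the nominal level; the suite verifies
this over simulated null matrices and verifies ≥95% exact detection of a
planted step.

**Convex-hull overlap.** Each animal's multi-day trajectory is one point in
day-space. The two behaviors being compared are stacked and projected with
one common PCA (a joint projection, so both hulls live in the same
coordinate frame), the first 3 components are kept (2 when either point set
is degenerate in 3), and the overlap is reported as
100 × vol(intersection)/vol(union). The Jaccard denominator is chosen
because it makes the metric symmetric and bounded; the denominator is the
only free choice in "% overlap" and is configurable. Volumes are estimated
by seeded uniform rejection sampling (2×10⁵ points over the union bounding
box) against exact half-space representations of the hulls, which for the
point counts involved (one point per animal) are obtained by facet
enumeration. The estimator is validated against the closed form for two
unit cubes sharing half their volume (Jaccard 1/3).

**Identity shuffling** permutes animal labels independently within each day
(per family, adults included), preserving every day's value multiset while
destroying cross-day individuality — precisely what losing identity
tracking would do. On simulated families, shuffling inflates apparent
inter-behavior hull overlap and deflates within-behavior trajectory
correlations, and the suite asserts both directions.

**Power.** `power_at_n` estimates the power of a two-sided unequal-variance
(Welch) comparison by direct Monte-Carlo simulation, vectorized over
replicates; the test suite cross-checks its rejections against
`stats::t.test`. At the early-development design point — 3 animals per
group, means 0 and 1 on the adult-relative scale, SDs 0.10 and 0.20 — power
exceeds 80% at α = 0.05, which is what justifies group sizes as small as
three.

## Social-state networks

The cage floor is discretized into a 5 × 4 grid (cells 11.44 × 8.9 cm,
5 columns along the long axis); a frame's **social state** is the
20-vector counting subset animals per cell (half-open cell edges, far
row/column closed, so the walls belong to the boundary cells). Missing
animals are omitted, so the vector sum always equals the number of tracked
subset animals. Graphs are built per day and per subset family — single
animals, pairs, all pups, all animals — by collapsing consecutive identical
states and adding one unweighted directed edge per ordered pair of states
ever observed consecutively; transitions spanning recording gaps create no
edges.

Metrics: graph **size** (distinct states); **cycles** as the circuit rank
of the undirected simple projection (edges − nodes + components), a
deterministic, polynomial count of independent cycles that never counts a
cycle twice (exhaustive directed simple-cycle enumeration is available for
small graphs as `count_directed_cycles`); **transitivity** as
3 × triangles / connected triples (0 when no triples exist); and **mean
shortest-path length** within the largest connected component. Graph
plumbing is delegated to igraph; every metric is verified against
brute-force triangle/triple and cycle-basis counts on random graphs.

## Circadian analysis

Behavior bouts are accumulated into 24 wall-clock hour bins, split
proportionally across hour boundaries, averaged over a day range, and
divided by per-hour recording coverage; bins with no recording are missing,
not zero. Day/night proportions split the normalized profile at the light
schedule.

The distance between two normalized profiles is the Bhattacharyya distance
D = −ln Σᵢ √(pᵢqᵢ) — the standard form; it is zero iff the profiles agree
and +∞ for disjoint supports. Inside the changepoint objective an
ε-regularized variant (−ln(BC + 10⁻¹²)) keeps the objective finite when a
sparse animal-period has empty bins.

`find_transitions` searches exhaustively over breakpoint pairs (t1, t2)
partitioning the day range into D1 = [first, t1], D2 = (t1, t2],
D3 = (t2, last], each at least 2 days (the boundary convention is fixed
here since no external convention exists). An animal's period profile is
the mean of its daily normalized profiles — equal weight per day, so a
high-activity day cannot dominate a period. The objective is the cumulative
distance: the sum over animals and over all unordered period pairs
(adjacent-pairs-only is available); the argmax is returned with the full
objective surface, ties broken by the lexicographically earliest pair, and
a flat surface is flagged as degenerate rather than silently returning a
corner.

Planted-structure validation: with three planted regimes (uniform /
evening-peaked / dawn-peaked) the search recovers the exact breakpoints in
≥90% of seeded runs; with a single planted change one breakpoint pins to
the true day while the other wanders — the expected behavior when the
model's assumed number of periods exceeds the data's, and the reason
reported developmental windows shift slightly under different priors. On
full simulated families, the behavior-onset transition dominates the
circadian-onset transition when the behavior itself is sparse early in
development (the food-hopper series before weaning onset), so the
breakpoints land on the onset of the behavior; the denser open-field series
exposes the same effect. This is a property of the data regime, not of the
search, and the profile-level recovery tests isolate the search itself.

## The simulator

`simulate_family` generates what the analysis consumes, with the statistical
structure the study design assumes:

* 2 adults + 4 pups, 57.2 × 35.6 cm cage, P15–P30, lights 08:00–20:00,
  10% of each session dropped as a contiguous save block.
* Each animal alternates nest episodes (stationary at the nest, missing
  from open-field tracks) with active bouts: straight-line waypoint
  locomotion (9 cm/s cruise, positional jitter 0.15 cm) with scripted
  visits to the food and water ROIs. Wander legs route around the feeding
  stations — animals do not loiter in or cut through them unless visiting —
  so ROI occupancy reflects visits, not transit.
* Pup activity budgets follow logistic ramps toward a plateau fraction
  (default 0.85) of the constant adult level: flat floor before the onset
  day, logistic rise after. Defaults place the activity onset at P17 and
  food/water onsets at P22/P23, with zero floors for food and water (pups
  do not visit the hopper before weaning onset). Each pup draws an onset
  jitter (SD 0.5 day) and a plateau factor (lognormal CV 0.15) per
  behavior — the individual idiosyncrasy that makes trajectories
  identifiable and gives the shuffle controls something to destroy — plus
  day-level lognormal noise (CV 0.05, matching ~10% relative variance at
  small group sizes).
* Within-day activity is modulated by circadian hour-weight templates:
  adults are diurnal with a crepuscular pre-dark peak throughout; pups are
  uniform until the planted circadian onset (default P26), then
  diurnal-crepuscular with an added pre-dawn peak.
* Fractional per-hour ROI budgets accrue in an accumulator and are emitted
  as visits of at least 3 s once enough budget exists, so small pup budgets
  realize as genuine, arrivable visits instead of sub-travel-time
  fragments.
* Huddle intervals are the spans with ≥2 animals at the nest; the planted
  ground truth records per-animal-day activity/nest/ROI/distance budgets,
  the ramp parameters, the circadian onset, and (from `inject_id_swaps`)
  the corruption log.

What the simulator does **not** emulate: gait or pose-level kinematics
(only centroid statistics are realistic), pose-estimation noise beyond
positional jitter, partial huddles away from the nest, social interaction
dynamics (animals move independently, so proximity and approach rates are
geometric rather than motivated), or bedding-change disturbances. Passing
recovery tests therefore demonstrates that the analysis recovers planted
budget, identity, and rhythm structure from data with realistic geometry,
sampling, and missingness — not that it is robust to every pathology of
real pose tracking.

**Problem sizes.** Simulations default to 5 fps and 120 recorded seconds
per hour (the full recording regime is 25 fps, continuous); all thresholds
are specified in seconds and centimeters, so results are frame-rate
invariant. The test suite uses 30–120 s/hour and 1–16 day spans, chosen so
the whole suite validates every stage in minutes on one CPU; corruption
tests shorten the day span rather than the session length because switch
detection needs within-session motion, not many days.

## Reproducing the analysis

`analysis/01_simulate_family.R` … `06_circadian.R` run the whole workflow
on three simulated cohorts (12 pups), writing tables under
`results/analysis/` and large intermediates under `scratch/`.
`scripts/acceptance.R --seed N --out results/acceptance.json` recomputes
the self-contained power result. `run_pipeline()` packages the same stage
sequence behind one configuration object with per-stage seeds
(`seed + stage index`) and a content-hashed manifest, so identical
configuration and seed reproduce identical artifacts.

## Known limitations

* The hull-overlap Monte-Carlo error grows when hulls are thin slivers;
  2×10⁵ samples bound the absolute error near 1 percentage point for the
  geometries tested, but reported overlaps below ~0.1% are
  indistinguishable from zero.
* `rapid_development_days` requires ≥3 values per side and so cannot test
  the first two days of a range.
* The approach detector's closing-fraction rule conflates "approach" with
  "pursuit" when the target flees; the study's discussion of approach
  behavior classifies initiator intent no further, and neither does the
  rule.
* Huddle membership is attributed, not observed: when two huddles are
  simultaneously active the nearest centroid wins, and missing-track
  attribution assigns all missing time during a huddle to huddling, which
  overcounts if an animal escapes tracking elsewhere.
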