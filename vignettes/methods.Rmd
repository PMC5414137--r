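---
title: "Automated timing of the Modified Jebsen Test: models, detectors and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated timing of the Modified Jebsen Test: models, detectors and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinectMJT)
```

## The measurement problem

The Modified Jebsen Test of Hand Function (MJT) scores gross dexterity by
timing three tabletop tasks: turning five 76x127 mm cards, spooning five
kidney beans into a 100 mm open can, and stacking four 30 mm checkers on a
wooden board. When a therapist operates the stopwatch, both the subject's
reaction to the go-signal and the therapist's reaction to the task's end
enter the measurement, adding bias and variance of several tenths of a
second. This package replaces the stopwatch with an analysis of a top-down
RGB-D recording (8-bit colour plus per-pixel depth in millimetres, 30 fps,
sensor mounted ~1200 mm above the table): start and end times are defined
by the image content itself.

The package has three layers: *scene and event detection* (the computer
vision), *subtest state machines* (the timing rules), and *agreement
statistics* (how such a system is compared against a therapist and a
video-inspection ground truth). A fourth component, the *synthetic scene
simulator*, exists so that every layer can be validated without sensor
hardware against exactly known ground truth.

## Geometry, calibration and conventions

All thresholds in the detection pipeline are physical lengths in
millimetres, while the detectors operate on pixels. With a perpendicular
sensor, a single scale `mm_per_px` at the table plane maps between the two
(`calibration()`); it can be supplied directly or derived from the
detected board ridge, whose physical length (508 mm) is known
(`calibration_from_ridge()`). A planar scale ignores the height of objects
above the table; at a 1200 mm mounting height a 70 mm tall object is
magnified by ~6%, well inside the ±20% acceptance band of the only
length-critical detector (the ridge filter). Per-pixel depth projection is
deliberately out of scope.

Images are `[row, col]` matrices with row 1 at the top; the subject sits
at the image bottom, so *distal* (away from the subject) means a smaller
row index. Frame indices are 0-based and map to time as `index /
frame_rate`; pixel indices follow R's 1-based convention. A group of
pixels means a 4-connected component (neighbours exactly above, below,
left, right) throughout. The *extent* of a group is the largest pairwise
distance between pixel centres plus one pixel — the footprint convention,
under which a straight run of k pixels has extent k, so a 254-pixel ridge
at 2 mm/px measures exactly 508 mm.

## Scene detection

**Table.** The table dominates the view, so its surface depth is the
median of all depth pixels — robust to any object covering under half the
image. A binary split at 300 mm *below* the surface separates the table
side from the floor beyond its front edge; the edge row is detected per
column (first table-to-floor transition, scanning down the bottom half of
the image) and the per-column rows are combined by their median, which
tolerates columns occluded by the subject's arm.

**Board and ridge.** Pixels more than 50 mm above the table are grouped;
a group whose extent is within ±20% of the 508 mm ridge length is the
ridge (the ridge top is nominally 70 mm up: 19 mm board + 51 mm ridge).
If several groups pass, the detector raises an `ambiguous ridge` error
rather than guessing — a silent misdetection would corrupt every
downstream time. The board footprint is reconstructed geometrically
(ridge axis widened by half the 286 mm board width on each side) because
the 19 mm board top is too close to the depth noise floor to segment; the
board's surface depth is still *measured* from the footprint pixels when
they are credibly above the table, falling back to `surface - 19 mm`.

**Open can.** A gradient-voted circle Hough transform runs on the grey
first frame inside a search window (default: a 300 mm square centred
150 mm in front of the ridge midpoint, where the can is placed). Every
strong Sobel edge pixel votes at ±r along its gradient for each candidate
radius (default window 25-75 mm through the calibration). Candidate
circles are deduplicated by centre, and each radius is refined from the
supporting edge pixels: a physical rim images as an annulus with an inner
and an outer wall, so the refined radius is the midline of the two
strongest magnitude-weighted edge-distance clusters, which ignores weaker
stray edges from nearby structures (the board's front edge, the resting
hand). Among the final candidates, the one whose diameter is closest to
the physical 100 mm wins; ties go to the higher vote count.

## Hand tracking

A hand pixel is more than 30 mm above its *local* surface — ridge top,
board top or table, whichever lies under that pixel — and inside the
table region. Groups of at least 50 pixels (inclusive) qualify; the
largest is the hand. When several qualify (a forearm split by occlusion,
or a tall static object such as the can), the choice of the largest is
deterministic and the observation records the candidate count for
diagnostics. Hand absence is a valid per-frame result, not an error.

All timing logic tracks the *distal centroid*: the unweighted centroid of
the hand pixels within 10 mm (along the row axis) of the hand pixel
farthest from the table's front edge. This approximates the fingertips,
which is what crosses the task thresholds; the full-hand centroid would
lag by half a hand length.

## Event detection

**Cards.** Markers are strictly-green pixels (R < G and B < G), cleaned
by a 5x5 median filter (implemented as a box-sum majority with zero
padding, which makes the border behaviour explicit), grouped, and kept at
>= 10 pixels. A marker whose centroid is within 10 mm of any hand pixel is
ignored — it belongs to a card still being handled. Surviving centroids
feed tracks: a centroid joins the nearest track within 5 mm (the track
centroid is the running mean), else opens a new one; a track with 15 or
more supporting frames is a turned card. Tracks are never deleted: the
marker side starts face-down, so a persistent marker implies a completed
turn.

**Beans.** Consecutive grey frames (unweighted channel mean) are
differenced; pixels above 10% of the 0-255 range (strict > 25.5) form the
change mask, *excluding* current hand pixels — a moving hand would
otherwise dwarf any bean. Groups with centroids within 5 mm merge. A drop
is recorded iff the detector is armed, a merged group has 5-50 pixels
(inclusive) with extent under 15 mm, its centroid lies inside the can
rim, and the hand is within 50 mm of the rim. A drop disarms the
detector; returning the hand to within 30 mm of the ridge (the next bean)
re-arms it. At most five drops are ever recorded.

**Checkers.** A per-pixel depth reference is the mean of the first 15
frames (the scene must be static there; the runner warns if it drifts).
Foreground pixels inside the board footprint more than 5 mm above the
board surface relative to the reference are grouped; groups with extent
between 0.5 and 2 checker diameters (15-60 mm, inclusive), centroid on
the board, and more than 30 mm from every hand pixel are logged with
their mean height above the board. A height maps to a stack count n in
1..4 when it falls in the interval (D ± 0.5 D)·n with D = 6 mm per
checker; those intervals overlap for n >= 2, which the source rule leaves
unresolved, so among the containing intervals the count with the nearest
expected height D·n wins, ties to the smaller n. A height in no interval
is ignored.

## Timing rules

All three subtests share one movement-onset rule: find the first frame
where the distance from the distal centroid to a task reference satisfies
the crossing condition, then scan backwards through the contiguous run of
frames whose displacement toward the target is at least 3 mm/frame
(inclusive); the earliest frame of that run is the start. Short
hand-absent gaps (<= 5 frames, configurable) are linearly interpolated;
longer gaps are an error rather than a guess.

* **Card turning**: distance to the table edge, crossing *exceeds 127 mm*
  (the proximal edge of the cards). End: the first frame at which the
  fifth marker track reaches 15 supporting frames. This confirmation adds
  a fixed 14-frame latency relative to the moment the fifth card landed;
  `end_latency_correction` lets users back-date the reported end by any
  fixed number of frames, with 0 as the default so the raw rule is what
  is reported.
* **Simulated feeding**: crossing *exceeds 147 mm* (20 mm past the board's
  proximal edge at 127 mm). End: five drops recorded *and* the hand more
  than 20 mm outside the rim — both conditions, so a hand lingering over
  the can delays the end.
* **Stacking checkers**: distance to a point 15 mm in front of the middle
  of the board's proximal edge, crossing *falls below 63.5 mm*. End: the
  fifth consecutive frame with a fourth-interval detection; a frame with
  no detection (e.g. the hand re-entering the exclusion zone) resets the
  run.

Every runner is deterministic, turns a recording truncated before its
finish into an explicit `subtest incomplete` condition, and converts
frames to seconds with the recording's frame rate rather than a hard-coded
30.

## Agreement statistics

Two timing methods are compared by Bland-Altman limits of agreement on
matched differences d = A − B. Because subjects genuinely improve between
the two repetitions (a practice effect), the variance of d combines two
components estimated by a one-way ANOVA of d on subject: the residual
mean square (within-subject) plus max(0, (MS_subject − MS_residual)/m_h)
(between-subject), with m_h the harmonic mean of per-subject counts;
negative component estimates truncate at zero, standard
components-of-variance practice. LoA = bias ± 1.96·sd, so the LoA width
is identically 3.92·sd. With one observation per subject the estimator
reduces exactly to the classic sample SD of the differences; with a
single subject it falls back to the plain SD with a warning.

Bias is tested by a one-sample t test on per-subject mean differences;
variance equality by the classic (mean-centred) Levene test on pooled
difference sets; test-retest change by a paired Wilcoxon signed rank test
whose p value is exact for up to 25 nonzero differences — zeros dropped,
ties mid-ranked, with the exact null distribution of the positive-rank
sum computed by dynamic programming over doubled ranks, so ties are
handled without resorting to the normal approximation. Above n = 25 a
tie-corrected normal approximation with continuity correction is used.
All three use Bonferroni adjustment; the family size m is an argument
(default 3: three method pairs per comparison family, or three subtests
per retest family) because the convention is not inherent in the data.

## The synthetic scene simulator

`simulate_recording()` renders a top-down scene at the physical layout of
the test kit: cards 51 mm apart and 127 mm from the front edge, the board
127 mm from the edge with its 508 mm ridge, the can in front of the
board, four checkers touching the board. The hand is a rigid ellipse
(default 120x80 mm) with a trailing forearm band — every detector in the
pipeline sees only connected-pixel geometry, so articulation would add
realism without adding coverage. Trajectories are linear interpolations
of scripted waypoints of the distal tip; events flip cards (revealing the
green marker), inject a three-frame moving blob inside the can (a falling
bean), or raise the stack by 6 mm. Noise is iid Gaussian per pixel on
depth (default sigma 2 mm, a typical figure for structured-light depth at
about 1.2 m) and on each RGB channel (default sigma 3), with a script
seed making every rendering bit-reproducible.

Scene colours are warm-tinted (a wooden table, not neutral grey) with an
R−G margin of at least 15: under iid channel noise an exactly neutral
surface would satisfy the strict R<G and B<G marker test on about a
quarter of its pixels, which no real table does. The can interior's grey
level is kept within ~16 of the hand's so that hand-motion ghosts
crossing the can do not exceed the 25.5 frame-difference threshold —
physically, a matte interior of similar brightness.

Ground truth is computed **from the script alone**, never from the
rendering, so recovery tests cannot be circular. The conventions are the
measurement definitions themselves: the onset is the first frame of the
sustained >= 3 mm/frame approach preceding the crossing (applied to the
scripted tip path); the card end is the fifth flip frame plus the
14-frame confirmation latency; the feeding end is the fifth drop frame
(the default script hovers 20-50 mm outside the rim, so the end condition
already holds there); the stacking end is 4 frames (the
five-consecutive rule) after the completed stack first clears the 30 mm
hand-exclusion zone.

Default scripts reproduce realistic pacing (about 7.5 s per subtest at
30 fps, matching observed completion times in stroke cohorts) at a
fixture scale of 320x240 px and 4 mm/px; full 640x480 at 2 mm/px is
supported and is covered by the geometry self-consistency tests.
`random_script()` jitters onset, event schedule and depth noise (sigma
drawn up to 3 mm) for sweep-style validation, and
`simulate_times_panel()` generates timing tables with known bias,
within- and between-subject variance and practice effect for
parameter-recovery tests of the statistics layer.

What the simulator does *not* emulate — articulated fingers, the spoon,
specular highlights, real structured-light noise spectra (which are
depth-dependent and spatially correlated), therapist occlusion, lens
distortion — bounds what passing tests show: they validate the logic and
the thresholds of the pipeline, not its robustness to every artefact of
real Kinect footage.

## Numerical and design choices

* **Edge-row aggregation**: per-column first transition, median across
  columns. Robust to partial occlusion of the edge and consistent with
  treating the edge as a single straight line.
* **Ambiguity is an error**: both the ridge filter (two passing groups)
  and recording loading (missing frame pairs) fail loudly; timing built
  on a guessed scene is worse than no timing.
* **Inclusive thresholds**: >= 50 hand pixels, >= 10 marker pixels,
  >= 15 supporting frames, bean size in [5, 50], checker extent in
  [15, 60] and ridge extent in [0.8, 1.2]x508 are inclusive at both
  ends; strict inequalities are used where the rule says "more than"
  (30 mm elevation, 5 mm checker height, 10% difference threshold).
* **Tie-breaks**: overlapping stack intervals resolve to the nearest
  expected height, then the smaller count; equal Hough diameter errors
  resolve to the higher vote count.
* **Degenerate inputs**: a zero-variance bias test reports t = 0, p = 1
  (all-zero) or a flagged infinite t (nonzero constant); an all-zero
  Wilcoxon difference vector reports p = 1; an empty-events script
  renders a static recording whose ground truth is NA and on which every
  runner reports "incomplete" or "start not detected".
* **Problem sizes in the validation suite**: the end-to-end sweep uses 20
  recordings per subtest at fixture scale (about 200 frames each), the
  labelling oracle 200 random images up to 64x64, the Wilcoxon oracle
  all n <= 12 via full enumeration, and the statistics recovery a
  200-subject panel — sizes chosen so the whole suite gives tight
  evidence while remaining a desk-scale computation.

## Known limitations

The planar calibration ignores object height (a few percent scale error
at 1200 mm); the card end time carries the 15-frame confirmation latency
unless corrected; the largest-component hand rule can momentarily latch
onto a tall static object when the true hand is nearly out of view, which
is why the simulated rest position keeps a substantial hand area on the
table; and the headline agreement numbers of a clinical deployment
(biases and LoA against a therapist) cannot be reproduced here because
they require the original recordings — the statistics layer is instead
validated by parameter recovery on simulated panels.
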