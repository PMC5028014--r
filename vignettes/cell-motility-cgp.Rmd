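---
title: "Tracking, motility features and evolved classifiers for monolayer videos"
author: "CellTrackCGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking, motility features and evolved classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CellTrackCGP)
```

# Scope and model

CellTrackCGP analyses time-lapse videos of sparse adherent monolayer
cultures (the motivating system is normal human urothelial cells imaged by
DIC videomicroscopy at one frame per 5 minutes over 24 h). It implements
three layers — distance-transform point tracking, a ten-feature motility /
contact summary per video, and a Cartesian Genetic Programming (CGP)
classifier over those features — plus a synthetic-scene generator that
provides ground truth for validating each layer. This vignette records the
modelling assumptions, the tunable parameters, the numerical choices, and
what the validation does and does not demonstrate.

# The tracking model

Per frame, the pipeline is: Gaussian blur (noise suppression), fixed-value
threshold, exact Euclidean distance transform. The distance image assigns
each foreground pixel its distance to the nearest background pixel, so a
convex cell of radius r peaks at ~r at its centre. Detection takes the
local maxima (8-neighbourhood, plateaus included) above `minPeakValue`,
visits them from highest to lowest, and discards any candidate within
`suppressionRadius` of an accepted one. Linking maximizes the product of
the distance image and a Gaussian of distance-to-previous-position over a
clipped square window; a track whose weighted maximum falls below
`lostThreshold` is closed and never revived (features average over
whatever tracks exist, so fragmented tracks contribute rather than harm).
Duplicate tracks closer than `duplicateRadius` are pruned, keeping the
longer-lived (lower id on age ties), and full detection re-runs every
`redetectInterval` frames, seeding tracks only away from existing ones.

None of the knobs above have canonical values; all are exposed with
defaults sized for the synthetic scenes (cells of radius ~8 px on a
midpoint-separable intensity scale):

| parameter | default | units | rationale |
|---|---|---|---|
| `blurSigma` | 2 | px | suppresses pixel noise without merging cells |
| `threshold` | 125 | gray | midpoint of generator fg (200) / bg (50) |
| `suppressionRadius` | 8 | px | one expected cell radius |
| `minPeakValue` | 3 | distance | rejects sub-cellular noise peaks |
| `searchHalfwidth` | 16 | px | 2 radii; > max per-frame displacement |
| `gaussianSigma` | 8 | px | one radius; locality of the match |
| `lostThreshold` | 0.5 | distance | below any real cell-interior value |
| `duplicateRadius` | 8 | px | one radius |
| `redetectInterval` | 10 | frames | recovers losses within ~50 min |

An Otsu auto-threshold is available (`autoThreshold = TRUE`) but off by
default: the reference pipeline thresholds against a predetermined fixed
value, and a per-frame adaptive threshold would let detection drift with
density.

Coordinates are 0-based pixel centres, x = column, y = row, origin
top-left; tracks are emitted at integer pixel resolution (sub-pixel
localization is out of scope).

# The ten features

All kinematics pool steps across tracks (not mean-of-track-means): a video
is summarized by one number per feature, and pooling weights each observed
step equally regardless of track fragmentation. Speeds are Euclidean step
lengths in px/frame. Headings are atan2(Δy, Δx); a zero-displacement step
has no heading and is excluded from angular statistics rather than counted
as zero turn, which would otherwise bias persistence upward for jittery
near-stationary cells. Angular velocity is the absolute heading change
wrapped to [0, π].

Contact is a centre-distance criterion (default `contactRadius` = 16 px,
two radii) because point tracks carry no shape. A *clump* is a connected
component of the contact graph with ≥ 5 cells, membership counted
including the cell itself; the reading "in contact with five or more
*other* cells" (component ≥ 6) is available via `sixTotal = TRUE`.
Contact duration means clump-membership duration (maximal runs of
consecutive member frames), not pairwise contact. A step is *in-contact*
iff its start frame is a clump-member frame (a half-open convention that
assigns each step to exactly one regime); a turn — which spans two steps —
is attributed to the start frame of its first step, the same convention.
*Post-contact* covers the `postContactWindow` = 3 frames after leaving a
clump, truncated at track end or clump re-entry so no frame is counted as
both in- and post-contact; the same window serves the post-contact angular
velocity (the reference method states the window only for speed; symmetry
is the simplest consistent reading).

Features whose restriction is empty (no clumps, no post-contact frames,
all-stationary tracks) are undefined and carried as `NA` — written as
empty CSV cells — and imputed to 0 only at classifier input, keeping the
information visible while giving the CGP numeric inputs.

# The CGP classifier

The genome is a single row of 70 nodes with full feed-forward
connectivity (`levelsBack = nColumns`; nothing constrains connectivity
further in single-row CGP), one output gene, and the 14-entry function
set {+, −, ×, ÷, SQR, SQRT, CUBE, CONST0, CONST1, AND, OR, NAND, NOR,
NOT}. Ten inputs feed the ten features in standard order. Every function
is total: division by zero returns 1, SQRT acts on |x|, logical operators
read an operand as true iff > 0 and emit 1/0, and every node output is
clamped to ±1e100 so that chains of SQR/CUBE cannot overflow to infinity —
any valid genome maps finite inputs to finite outputs. Unary functions
read only their first connection gene and constants read none, but the
genes are always present, so the chromosome length is fixed (211 genes)
and mutation is uniform over positions.

Training is a (1 + 9) evolution strategy: per-gene mutation probability
1%, resampling uniformly over the gene's valid range (possibly to the same
value), fitness = training accuracy, up to 10,000 generations with early
stop at accuracy 1. Selection prefers an equal-fitness offspring over the
parent — neutral drift, which lets the search walk across the large
neutral networks characteristic of CGP; without it the search stalls on
plateaus. Offspring whose mutations touch no semantically active gene
inherit the parent's fitness unevaluated (an exact shortcut, since the
active subgraph is unchanged). Features are min/max-normalized to [0, 1]
on the training table (constant features normalize to 0 and are flagged);
classification is *positive iff output > 0*. The output-to-class mapping,
the fitness function and the split protocol are left open by the reference method;
accuracy fitness, threshold 0 and a stratified 75% split are this
package's documented choices, all config-exposed.

The active subgraph exports as a fully parenthesized infix expression over
the feature names, and `evalExpression()` re-evaluates that string under
the identical protected semantics, which the tests use as a round-trip
oracle. The exported used-input set is the classifier's feature selection.

One inconsistency in the reference description is resolved here: its
parameter table gives nine inputs while its worked network uses inputs
(0)–(9) for the ten features; ten is implemented (nine remains available via
`nInputs`).

# The synthetic generator

`generateScene()` emulates what the tracker and features assume: bright
roughly-circular cells (hard-edged disks, per-cell radius ~N(8, 1) px) on
a darker background (gray 200 on 50, additive N(0, 5) pixel noise,
8-bit), moving as persistent random walks — per frame the heading gains a
wrapped-normal increment with sd 1/sqrt(`turnConcentration`) and the cell
advances by a N(`speedMean`, `speedSd`) step truncated at 0. The
concentration knob spans the whole range with one parameter: 0 degenerates
to a uniform turn on (−π, π] (isotropic walk, mean |turn| = π/2), infinity
to ballistic straight lines. Defaults mirror the motivating acquisition:
288 frames (24 h at 5 min), a 512×512 field, 40 cells, control-like speed
3.5 px/frame, concentration 0.4 (mean |turn| ≈ 1.3 rad/frame). Optional
terms: pairwise attraction (drift of magnitude `clumpAttraction` along the
mean unit vector toward neighbours within `attractionRange`) to produce
clumps; `contactSlowdown` to reduce speed while in contact (used to verify
that in-contact speed reads below overall speed); divisions (daughter one
radius away at a uniform angle); cells crossing the field boundary are
removed and their tracks end. Ground truth — float-precision tracks and
centre-distance contacts — is returned alongside the rendered frames, and
identical configurations (including the seed) reproduce scenes bitwise.

Hard-edged disks with anti-aliasing off are deliberate: the distance
transform of a clean disk then peaks at its centre at ≈ the radius, which
makes detector tests analytic. Intensity polarity is standardized to
bright cells on dark background; DIC data of the opposite polarity should
be inverted before tracking (255 − I for 8-bit input).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: DIC optics (shear shadows, halos), cell shape
and deformation, intensity heterogeneity within and between cells, uneven
illumination, focus drift, and true adhesion dynamics (attraction is a
point force, not membrane contact). Validation on these scenes
demonstrates correctness of the algorithms under their stated assumptions,
not performance on any particular microscope's output.

# Numerical choices and degenerate inputs

* Detection ties (equal maxima) break row-major — smaller y, then smaller
  x — so results are independent of traversal order; the same rule breaks
  ties in the weighted linking argmax.
* Duplicate pruning retains by (age, then lower id); the pruned track's
  current-frame point is dropped so no frame holds two tracks within the
  duplicate radius.
* Angular differences below 1e-12 rad are treated as zero: they are below
  the angular resolution of any representable displacement and arise only
  from floating-point accumulation along exact straight lines.
* A frame with no below-threshold pixel would have an undefined distance
  transform; distances are capped at the image diagonal.
* `oneWayAnova` refuses zero within-group variance (the F statistic is
  undefined) rather than returning infinity; single-class tables are legal
  for fitness (accuracy remains defined) but not for the ANOVA.
* Classifier JSON stores doubles at 17 significant digits so a serialized
  classifier reproduces its predictions exactly.
* No multiple-testing correction is applied across the ten per-feature
  ANOVAs; the report says so.

# Problem sizes used in validation

The test-suite and acceptance-script scenes are sized for a laptop-class
single core: tracking recovery uses 20 cells / radius 8 / speed 2 px/frame
/ 100 frames on a 512×512 field; the isotropic-limit check uses 150 cells
× 100 frames (> 10⁴ steps) on a 600×600 field; CGP learning uses 12 + 12
rows with class means following the observed control vs high-dose trends
(speed 3.57 vs 2.03 px/frame, angular velocity 1.35 vs 1.79 rad/frame)
and within-class sd 0, under the reference evolution parameters; the
end-to-end determinism check runs 2 classes × 3 videos of 10 cells × 25
frames. The headline tracker behaviour at these sizes: ~96–99% of truth
positions recovered within 3 px, median localization error ~0.4 px.

# Known limitations

Point tracks only — no segmentation masks, shape descriptors or lineage
linking; lost tracks are never re-linked, so long-lived single cells may
appear as several shorter tracks (the pooled features are insensitive to
this by construction); contact is centre-distance, blind to actual
membrane apposition; the classifier is binary (the multi-class case is
out of scope); and evolved expressions, while exact, are not unique —
different seeds can select different, equally accurate feature subsets.

```{r example}
sc <- generateScene(sceneConfig(nCells = 5, nFrames = 12, fieldWidth = 128,
                                fieldHeight = 128, seed = 3))
tr <- runTracking(frames(sc))
round(extractFeatures(tr), 3)
```
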