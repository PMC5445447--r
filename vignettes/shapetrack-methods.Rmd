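---
title: "Tracking unmarked mice with runtime-learned shape models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking unmarked mice with runtime-learned shape models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pairs of unmarked laboratory mice filmed from above are easy to track while
they are apart — two dark blobs on a bright floor — and hard to track while
they interact: the blobs merge, and nothing in a single frame says which
animal is which or where one body ends and the other begins. Physical
markers (bleach, dye, RFID) solve the identity problem at the cost of
perturbing the very social behavior one wants to measure.

`shapetrack` takes the marker-free route: it *learns what the animals look
like while they are separated* and spends that knowledge during contacts.
The pipeline has three stages:

1. **Preprocessing.** Illumination-normalized grayscale frames, a static
   background estimated as the pixel-wise temporal median, threshold
   segmentation of the difference image, connected-component blobs, and
   morphological removal of the tail (which also localizes the tail base).
2. **Separated animals: shape learning.** Every blob boundary is matched to
   a single user-annotated reference shape with inner-distance shape
   contexts; the correspondence transfers the nose, tail-base and ear
   landmarks and yields the viewing direction. Matches below a cost
   threshold feed a growing *shape catalog*.
3. **Contacts: model-based separation.** An active shape model (ASM)
   trained on the catalog is fitted to each animal with an alternating,
   occlusion-aware search, so pose, shape and identity survive the merge.

From the resulting trajectories and shape coefficients, social conditions
(nose–nose, anogenital sniffing, side-by-side, following, mating posture)
and self-grooming are classified.

## Preprocessing

Each frame is divided by its mean intensity and rescaled to a common target
mean (default 128), which cancels global lighting drift. The background is
the per-pixel median over a uniform subsample of frames (61 by default):
with a static arena and animals that keep moving, each pixel shows the
empty floor more than half the time, and the median recovers it exactly.
Segmentation thresholds the *absolute* difference image — so dark-on-bright
and bright-on-dark scenes both work — either automatically (between-class
variance maximization, via `EBImage`) or with a fixed manual threshold when
a scene defeats the automatic choice. Components smaller than `b_min`
(default 400 px², about a fifth of a mouse at the default scale) are
discarded as noise.

Tails are removed before any shape analysis, for two reasons: thin tails
segment unreliably, and tail posture is nearly independent of body posture,
so leaving tails in would both destabilize matching and inflate the shape
model with irrelevant variance. The body is the morphological opening of
the blob with a disc of radius `r_S` (default 4 px — anything larger than
the tail half-width and smaller than the body half-width works); the tail
is what the opening removed; the tail base is the centroid of the dilated
tail intersected with the body. A missing tail base (tail hidden under the
body) is a normal outcome, not an error.

## Shape matching

Blob boundaries are resampled to `n = 100` points at equal arc length.
Each point gets a log-polar histogram (5 radial × 12 angular bins, the
customary shape-context binning) of the positions of the other 99 points,
with two substitutions that make the descriptor robust to a bending spine:

* the Euclidean distance between two boundary points is replaced by the
  **inner distance** — the length of the shortest path between them that
  stays inside the silhouette (computed over the visibility graph of the
  polygon with Floyd–Warshall);
* the angle is replaced by the **inner angle** — the initial direction of
  that path relative to the local boundary tangent, which also removes
  in-plane rotation.

Radial bins are log-spaced between 0.125 and 2 times the mean inner
distance, and out-of-range distances are clamped into the end bins so every
histogram counts all `n - 1` other points. Scale invariance comes from the
mean-distance normalization; rotation invariance from the tangent-relative
angles.

Point pairs are scored with the chi-squared histogram cost, and the best
one-to-one correspondence is the exact solution of the dense linear
assignment problem (shortest augmenting path solver in C++; brute-force
enumeration and an independent weighted-bipartite-matching routine serve as
oracles in the tests). The total cost `H` of the optimal assignment is the
match quality used everywhere downstream.

**Correspondence smoothing.** An unrestricted optimal assignment is exactly
right globally but occasionally sends single points of featureless boundary
stretches (the blunt rear of a mouse) far from their neighbours. A valid
contour correspondence, however, is a slowly varying cyclic shift of the
index. We therefore smooth the per-point index shifts with a windowed
circular mean (window ±8 positions) before reading off landmarks and
re-ordering the contour. A rigid transform — where the raw assignment is a
constant shift — passes through unchanged; isolated outlier rows are pulled
back to the consensus. In our synthetic experiments this reduced occasional
80-px tail-landmark excursions to below 3 px without touching well-behaved
matches.

**Nose/tail disambiguation.** A mouse silhouette is nearly fore–aft
symmetric, so the matcher can settle on the reversed body axis. The match
is therefore checked against the morphological tail base: if the
transferred tail lands farther from it than the transferred nose does, the
match is redone with the contour traversal order reversed and the better
orientation kept. When no tail base is available (occlusion), the body-axis
orientation of the previous frame breaks the tie instead; the very first
frame of a video must have localizable tails.

## The shape catalog and its acceptance threshold

Only matches with `H` strictly below a threshold `rho_max` enter the
catalog: bad correspondences have high costs, and training an ASM on them
would poison the model. The threshold trades variability (high `rho_max`)
against plausibility (low `rho_max`). Because `H` scales with the point
count and binning, its absolute value is scene-specific; the package
therefore supports both a fixed `rho_max` and — the default — automatic
calibration from a warm-up sample of match costs (first 60 costs) to hit a
target acceptance *ratio* `c_v`, default 0.5. Around that default the
tracking error is flat over a broad range of ratios, so the exact choice is
uncritical; the acceptance tests sweep `c_v` over 0.15–0.83 and verify the
plateau on synthetic data.

Accepted contours are re-ordered into the reference indexing (so landmark
indices are identical across the whole catalog), rotated about their
centroid so the tail-to-nose axis is vertical with the nose pointing down
the image, and centered on the nose/tail midpoint. Removing whole-body
rotation this way concentrates the model's eigenvectors on actual shape
variation — bending and squash/stretch dominate the leading modes. The
catalog is capped (3000 entries, reservoir-thinned under the run seed) to
bound training cost on long videos.

## The active shape model

The catalog shapes, stacked as vectors `(x1, y1, ..., xn, yn)`, yield a
mean shape `x̄` and covariance (with the usual `1/(s-1)` normalization)
whose eigendecomposition gives orthonormal modes `P` and variances
`lambda_i`. Any plausible shape is `x ≈ x̄ + P b`; the retained mode count
`t` is the smallest prefix whose eigenvalues sum to at least `f_v = 98%` of
the total variance (at least one mode is always kept), and coefficients are
clamped to `|b_i| ≤ m * sqrt(lambda_i)` with `m = 3` — the conventional ASM
settings.

The image term is a per-landmark grey-profile model: at every landmark of
every catalog entry, `2k + 1` intensities (`k = 5`) are sampled along the
outward contour normal in the source frame, first-differenced and
normalized by the sum of absolute values (a zero guard returns a zero
vector on flat profiles). Mean profile and covariance are accumulated per
landmark; the covariance gets `1e-6 * trace/dim` added to its diagonal
before inversion, since small or degenerate catalogs otherwise produce
singular matrices. Fit quality at a candidate position is the Mahalanobis
distance of the observed profile under these statistics.

Fitting iterates, for `N_max = 60` iterations per frame (ample for the
small inter-frame motion at 25 fps): (a) each landmark evaluates the
profile distance at `2l + 1` unit-spaced offsets (`l = 7`) along its normal
and proposes the argmin; (b) a least-squares similarity pose maps the
model-frame shape onto the proposals; (c) the residual is projected onto
the modes, clamped, and reconstructed. Landmarks flagged as frozen skip
step (a) and keep their position until the model constraints pull them
along — the mechanism that prevents two models from swallowing each other
during occlusions.

## Tracking through contacts

Each frame is classified from its qualifying blobs: two blobs above a
single-animal area floor mean *separated*; one blob of roughly double area
means *crossing*; anything else is *lost*, and the previous state is
carried forward flagged, never interpolated. The floor is 0.4 times the
running median single-animal area, and the merged-blob threshold 1.3 times
that median; both factors are configuration keys.

During separated frames both blobs are matched to the reference, landmarks
and the viewing direction (ear-midpoint to nose) are updated, the catalog
grows, and identities follow the maximum contour overlap with the previous
frame (with two animals there are only two pairings; ties keep the previous
labels). At the first crossing the ASM is trained — at least 50 catalog
shapes are required, and an earlier contact raises an explicit error rather
than guessing — and thereafter refreshed after every 500 newly accepted
shapes. Crossing frames initialize both instances from the previous frame
and interleave single iterations between the two animals (the animal
iterating first alternates with frame parity, to avoid a systematic
advantage). Before each iteration, landmarks inside the polygon
intersection of the two current contours — or within 2 px of the other
contour — are frozen. On re-separation, identities are re-assigned by
overlap between the last fitted contours and the new blobs.

## Behavior classification

Distances are expressed in body lengths (the median nose-to-tail distance
over separated frames) so thresholds transfer across scales. Defaults,
all configurable: nose–nose contact within 0.25 body lengths (C1);
nose-to-anogenital contact within 0.25 (C2, directional); side-by-side
when body centers are within 0.6 and headings within 30° of parallel or
antiparallel (C3); following when one animal's nose trails the other's
tail base within 0.5 with headings within 45°, sustained for at least
0.5 s (C4, directional); mating posture when silhouette overlap exceeds
40% of the smaller body with headings within 45° and the mounting animal
behind (C5, directional). Conditions are not mutually exclusive, and lost
frames assert nothing. Per-frame flags become events by majority-vote
smoothing over a 5-frame window followed by a minimum duration of 0.2 s;
durations are compared to reference durations by the relative absolute
error, with a never-detected condition scoring exactly 1.

Self-grooming (C6) is not a positional condition: a stooped, compressed
posture shows up in the low-order shape coefficients (squash/stretch mode).
A support-vector machine with an RBF kernel, class weights inversely
proportional to class frequencies, classifies the per-frame coefficient
vectors; validation is interval-wise — each time interval is predicted by a
model trained on all the others — which respects the strong temporal
autocorrelation of behavior. Coefficients come from the ASM fit on crossing
frames and from projecting the aligned matched contour on separated frames,
so grooming is detectable in both regimes.

## Evaluation

Accuracy against labeled ground truth uses per-frame Euclidean nose and
tail-base distances, the absolute viewing-angle deviation wrapped to
[0°, 180°], and a summary error: the per-frame average of nose and tail
deviation, averaged over frames. The per-frame average could equally be
summed rather than averaged; the sum grows with video length and makes
values incomparable across runs, so the mean is the default and the
unnormalized sum is kept behind `literal_sum = TRUE` for comparison.
Identity mapping is resolved per evaluated frame by minimal total nose
distance before distances are computed, and identity switches are counted
as flips of that mapping — so precision and identity are reported
separately. Precision curves report the fraction of frames below each error
threshold.

## The synthetic generator

Real validation footage cannot ship with a package, so every stage is
exercised on synthetic arena videos with exact ground truth. A mouse is a
simple polygon built on a circular-arc spine: a smooth body-width profile,
a narrower head tapering to a sharp nose, two ear bumps (landmarks), a
semicircular rear cap whose apex is the tail base, and a 2–3 px tapering
tail that specifically exercises the tail-removal morphology. The
articulation parameters — bend angle and squash/stretch — were chosen to
produce exactly the deformation families the shape model is meant to learn.
Scenes use a 480×480 px arena, 80 px body length, background grey 200,
mouse grey 40 (120 in the low-contrast variant), multiplicative
illumination drift of ±4%, Gaussian pixel noise with σ = 3, and 25 fps.
Scripts are deterministic given a seed, and scripted sessions cover
separated-only motion, head-on partial-overlap crossings (the two patrol
paths are phased so every pass meets head-on at a 24 px lane offset,
bounding event overlap well below half a body), following, nose–nose,
anogenital, side-by-side, mating-posture and grooming scenarios, each with
behavior labels derived from explicit pixel rules on the analytic geometry
(e.g. "noses within 20 px") — deliberately independent of the classifier's
body-length thresholds.

What the generator does **not** emulate: fur texture and shading, shadows,
wall reflections, limb detail, partial occlusion by enrichment objects,
motion blur, and genuinely erratic rodent kinematics. Passing tests
therefore demonstrate the correctness and internal consistency of the
algorithms under controlled articulation, contrast, drift and noise — not
performance on any particular real video, which additionally depends on
contrast and segmentation quality.

Patrol paths in the crossing scripts are designed so that no pixel is
covered by an animal in half or more of the frames — otherwise the temporal
median background would absorb the animal. This mirrors a real constraint:
an animal that parks on the same spot for most of a recording will corrupt
a median background there too.

## Numerical choices and degenerate inputs

* The catalog gate is strictly `H < rho_max`; `calibrate_rho` places the
  threshold halfway between the order statistics bracketing the target
  ratio, so the achieved ratio is within `1/N` of `c_v` on the calibration
  sample.
* Assignment ties (exactly equal total costs) resolve to the first minimal
  column found by the augmenting-path scan, which favours low indices;
  identical shapes match with the identity permutation because off-diagonal
  costs are strictly positive for distinct points.
* All-zero frames, flat grey profiles, empty masks, single-class grooming
  labels, and contours below 8 points raise errors or documented safe
  returns rather than propagating NaN.
* Self-intersecting polygons are rejected before inner-distance
  computation; the visibility test uses strict proper-crossing predicates
  plus a midpoint-inside check, which is exact for boundaries in general
  position (smooth contours; collinear triples on a chord are a
  measure-zero degeneracy avoided by arc-length resampling of raster
  boundaries).
* Polygon overlap (identity assignment, mating condition, landmark
  freezing) is computed by rasterization at pixel resolution — the same
  resolution the blobs come from — rather than exact polygon clipping.

## Problem sizes in the test-suite

The suite validates oracle equivalence on 20 random 40-vertex polygons and
50 small assignment instances; shape-model recovery on 200 shapes of 100
points from a 2-mode generator; end-to-end tracking on a 300-frame
480×480 session with three contacts and on a 570-frame session with ten
contacts (the latter with a halved per-frame iteration budget); the
calibration sweep on a 120-frame single-contact session; and behavior
recovery on 80–240-frame scripted sessions. These sizes were chosen as the
smallest that still exercise every regime transition and give stable
statistics.

## Known limitations

* Two animals only; the identity logic enumerates both pairings explicitly.
* No texture or appearance model beyond 1-D grey profiles; animals of
  identical appearance that fully occlude each other for long stretches can
  still swap identities, and no post-hoc identity correction is attempted.
* The ASM search is single-resolution; very fast motion (more than the
  search half-range per frame) during a contact can lose the fit.
* Scale is assumed constant within a video (fixed camera); the catalog is
  not scale-normalized.
* The background model is static; a displaced arena or moving enrichment
  objects require re-estimation.
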