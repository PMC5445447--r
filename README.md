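# shapetrack

Marker-free tracking of two interacting mice in a static top-view arena,
with social-behavior classification — built around an **unsupervised,
runtime-learned shape model**.

## The problem

Automated behavioral phenotyping needs long, unattended recordings of
freely interacting animals. Tracking two unmarked mice is trivial while
they are apart (two dark blobs on a bright floor) and hard while they
interact: the blobs merge, and identity and pose become ambiguous exactly
when the behavior of interest happens. Physical markers perturb social
behavior; supervised models need labeled training data per setup.

`shapetrack` learns each scene's shape repertoire *during the run*. While
the animals are separated, every blob outline is matched to a single
user-annotated reference shape; good matches accumulate in a **shape
catalog**. When the animals touch, an **active shape model (ASM)** trained
on that catalog keeps the two bodies, their landmarks (nose, tail base,
ears), viewing directions and identities apart. The only manual input is
one click-annotation of a reference outline.

## The method in brief

* **Matching.** Contours are resampled to *n* = 100 points; each point
  carries a log-polar shape-context histogram `h_i(k)` built on the
  **inner distance** (shortest path inside the silhouette) and the
  **inner angle** (path direction relative to the boundary tangent), which
  makes descriptors insensitive to spine articulation, rotation, and
  scale. Point pairs are scored with the chi-squared cost
  `C(p_i, q_j) = 1/2 * sum_k (h_i(k) - h_j(k))^2 / (h_i(k) + h_j(k))`, and
  the correspondence minimizes the total cost `H = sum_i C(p_i, q_pi(i))`
  over all bijections (exact linear assignment).
* **Catalog.** Matches with `H < rho_max` are accepted; `rho_max` is
  either fixed or auto-calibrated so that a fraction `c_v` (default 0.5)
  of candidates passes. Accepted shapes are rotated so the tail-to-nose
  axis is vertical, which concentrates the learned variation on bending
  and squash/stretch.
* **ASM.** Principal-component shape model `x ≈ x̄ + P b` with
  coefficients clamped to `|b_i| ≤ m √λ_i` (m = 3), modes retained up to
  `f_v` = 98% variance, plus per-landmark grey-profile statistics.
  Fitting minimizes the Mahalanobis profile distance
  `d_M(g) = (g − ḡ)ᵀ S_g⁻¹ (g − ḡ)` along contour normals; during
  contacts the two models are fitted alternately and landmarks inside the
  mutual overlap are frozen, so neither model swallows the other.
* **Behavior.** Nose–nose, anogenital sniffing, side-by-side, following
  and mating posture are classified from positions, viewing angles and
  silhouette overlap (thresholds in body-length units); self-grooming is
  detected from the shape coefficients with a class-weighted RBF-kernel
  SVM under interval-wise cross-validation.

A synthetic-arena generator (articulated mouse silhouettes with bend,
squash/stretch, ears, thin tail, illumination drift, sensor noise, and
scripted contact/behavior events, all with exact ground truth) makes every
stage testable without external data.

## Worked example

Track a synthetic 300-frame session containing three contact events:

```r
library(shapetrack)

ses <- render_session(script_library("crossings_k", k = 3, n_frames = 300),
                      seed = 11)
ref <- reference_from_session(ses)      # stands in for the one-time annotation
res <- track_video(ses, ref, seed = 11)
res
#> <shapetrack_result> 300 frames (crossing 41, separated 259),
#>   catalog 187 shapes, rho_max = 542.3

evaluate_tracking(res$track, ses$truth)
#>    epsilon mean_d_nose mean_d_tail mean_d_phi n_frames identity_switches
#> 1 1.525156    1.721128    1.329184   2.593451      300                 0
```

Mean nose and tail-base errors are ~1.3–1.7 px on an 80 px body, the
viewing direction is accurate to ~2.6°, and both identities survive all
three contacts (`identity_switches = 0`). The calibrated acceptance
threshold (`rho_max = 542.3`) admitted 187 shapes into the catalog —
roughly the configured half (`c_v = 0.5`) of all candidate matches.

The fitted model's spectrum shows the expected structure — the leading
mode (bending) carries about half the shape variance:

```r
tidy(res$model)
#>    mode eigenvalue var_frac cum_var_frac retained
#> 1     1      108.    0.546         0.546 TRUE
#> 2     2       28.3   0.143         0.689 TRUE
#> ...
```

Per-frame results are a tidy tibble (`res$track`): frame, animal, regime,
nose/tail positions, viewing angle `phi_deg` (degrees, counterclockwise
from +x, y up), match cost, silhouette overlap, and shape coefficients.
Behavior events follow with `behavior_events(res$track)`; plots with
`plot_trajectories(res$track)` and `plot_eigenmodes(res$model)`.

A thin command-line front end (`inst/cli/shapetrack.R`) chains the same
steps on frame directories: `synth`, `run`, `behave`, `eval`.

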