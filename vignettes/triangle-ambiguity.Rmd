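---
title: "Counting the 3D interpretations of a triangle's retinal image"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting the 3D interpretations of a triangle's retinal image}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p3ptriangle)
```

## The model

A triangle `ABC` and an eye at `E` form the tetrahedron `EABC`. The
retinal image is reduced to the three visual angles `(θ_BC, θ_CA, θ_AB)`
at `E`; the triangle's shape is reduced to two vertex angles `(ω_A, ω_B)`,
with `ω_C = 180° − ω_A − ω_B` and `‖AB‖ = 1` fixed (any physical size `s`
just rescales the whole tetrahedron). Recovered positions are `A = l_A
V_A`, `B = l_B V_B`, `C = l_C V_C`, where `V` are the unit sight rays and
`l` the unknown distances. The law of cosines in the three faces meeting
at `E` gives the P3P system

$$ l_i^2 + l_j^2 - 2 l_i l_j \cos\theta_{ij} = d_{ij}^2, \qquad
   ij \in \{AB, BC, CA\}, $$

with `d_ij` from the law of sines. Dividing out `l_A` (ratios
`u = l_B/l_A`, `v = l_C/l_A`) turns two equation ratios into two quadratics
in `u` with coefficients polynomial in `v`; their resultant is a quartic in
`v`, which is why the solution count is 0–4. Only strictly positive
distances count: a vertex "behind the eye" is not a percept.

Two assumptions are worth making explicit. First, the eye is a point
(single center of projection); the binocular analysis treats each eye's
image separately and asks only which shapes are projectable to both, with
no epipolar or vergence consistency imposed. Second, the image is exact —
no retinal measurement noise. The counts are therefore properties of the
geometry, not of an observer.

## Numerical design

**Quartic roots.** The monic quartic's companion matrix is passed to an
eigenvalue routine; a root is treated as real when `|Im| < 1e-9 ·
max(1, |Re|)`. Closed-form radical solutions are fragile near repeated
roots, which occur at exactly the configurations of interest (see below).

**Back-substitution and the symmetric-image pitfall.** A resultant root
`v` normally determines `u` linearly (subtracting the two quadratics
cancels `u²`). That elimination degenerates when the two quadratics are
proportional — precisely what happens on symmetry loci, e.g. an isoceles
image (`θ_BC = θ_CA`) paired with an isoceles shape, where a double root
in `v` carries two *distinct* `u` solutions. A solver that back-substitutes
one `u` per `v` silently returns 2 of 4 solutions there. This
implementation therefore collects `u` candidates from the roots of both
quadratics (plus the linear elimination when well-conditioned) and lets
verification decide.

**Newton polish before verification.** Every returned solution must
satisfy the original system with residuals below `1e-8`. Quartic roots,
however, are ill-conditioned when they cluster — and for small
(near-orthographic) images all solutions cluster tightly, so raw
back-substituted candidates carry errors around `1e-7` and would fail an
honest residual gate despite being genuine. Each candidate is therefore
refined by a few Newton steps on the full 3×3 system (to residuals
`~1e-14`) before the gate. The gate then rejects only extraneous roots
(artifacts of the elimination), not conditioning noise.

**Deduplication and positivity.** Two candidate triples are one solution
when their maximum relative component difference is below `1e-6`
(interpretations are counted as geometric objects, not root
multiplicities); distances must exceed `1e-9`. Degenerate inputs — visual
angles on a triangle-inequality boundary, `ω_C → 0` — are rejected by the
validators rather than solved: they are measure-zero and numerically
unstable.

**The independent oracle.** `oracle_count()` shares nothing with the
solver path: it scans `u` on a dense grid (uniform in `atan u`, covering
the whole ray `u > 0`), computes `l_A(u)` in closed form from the `AB`
equation and the two `l_C(u)` branches from the `BC` quadratic, and counts
sign changes of the remaining `CA` residual, refining each bracket by
bisection and polishing tangential near-zero minima. One subtlety: roots
hiding in the grid cell next to the branch junction (where the `BC`
discriminant vanishes) are caught by inserting the junction points, which
solve a quadratic in `u`, as exact evaluation points. Solver and oracle
agree on every random instance tested (the test suite checks 1000+).

## The synthetic world

There is no external data; the Monte-Carlo study *is* the data source. The
generator draws exactly the constrained uniforms of the study design:

* shapes: `ω_A, ω_B` iid uniform on (10°, 170°), accepted iff `ω_C` also
  lies in (10°, 170°) — rejection sampling, so the joint is exactly
  uniform on the constrained region (mean of each angle is 60° by
  symmetry);
* images: the three visual angles iid uniform on `(θ_lo, θ_hi)`, accepted
  under the apex constraints (sum < 360°, all pairwise triangle
  inequalities). The sweep condition `full` uses `(0.1°, θ_max)`, `half`
  uses `(θ_max/2, θ_max)`. Boundary hits (measure zero) are rejected.

For the small box `(0.1°, 2°)` the acceptance probability has the closed
form `1 − (1−2l)³ / (2(1−l)³)` with `l = lo/hi` (≈ 0.575 here; the often
quoted 1/2 is the `lo → 0` limit), which the tests use as an analytic
oracle on the sampler's bookkeeping.

Each `θ_max` condition runs on a private substream derived from the master
seed and the condition's grid index, so single conditions reproduce
independently of the rest of the sweep. Default trials per condition are
`1e5` — desk scale, binomial SE < 0.2 percentage points near the
thresholds of interest — where the original study used `4e8`; the trial
count is a parameter, not a cap.

What the generator does *not* emulate: retinal noise, eccentricity
effects, any observer model, and any non-uniform prior over shapes or
poses. A green Monte-Carlo test establishes a property of the stated
geometric ensemble, nothing about human vision.

## Shape-space maps and the audit conventions

`compute_shape_map()` grids `(ω_A, ω_B)` at `grid_step` (default 0.5°;
no published figure resolution exists to match) with cell centers offset
by half a step, and solves P3P per valid cell for one fixed image.

The valid region defaults to the **full shape simplex** (all three angles
in (0°, 180°)): the published shape-space maps plot the full simplex with
invalid margins, and the printed audit statistics — "about 20%" of shapes
non-projectable for each Watanabe eye, "less than half" projectable for
the large 90°/100°/110° image — reproduce on the full simplex (20.1% and
40.1% at 0.5°) but not on a (10°, 170°)-restricted grid (13.9% and
51.1%). The restriction to (10°, 170°) is the *sampling* constraint of the
Monte-Carlo experiments and remains available via `omega_range = c(10,
170)`. Grid-refinement stability is tested: halving the step moves the
fractions by well under 2 percentage points.

Two variants of the published small-image example ship as fixtures —
`fig3_text_small` (9°, 10°, 11°) from the running text and
`fig3_caption_small` (10°, 15°, 20°) from the figure caption; the source
is internally inconsistent about which produced the figure, so neither is
asserted.

**A deliberate red test.** The audit claim that the small Beck & Gibson
images never admit 3 or 4 interpretations fails on exactly one grid cell
per image: those images are exactly isoceles (`θ_BC = θ_CA`), and on the
isoceles diagonal of shape space a sliver (about 0.3° long, under 0.02°
wide) of shapes genuinely has 4 interpretations — two depth-reversal
pairs — confirmed by the independent oracle at two scan resolutions. The
claim holds off this near-measure-zero set, and 3 is indeed never
observed. The acceptance test asserts the claim verbatim and is left
failing rather than tuned around.

## Depth reversal

For small images the two dominant solutions mirror each other in depth.
The predicate centers each interpretation's distance profile
`(l_A, l_B, l_C)` and reports `‖e₁ + e₂‖ / (‖e₁‖ + ‖e₂‖)` — 0 for an
exact reversal, 1 for identical oblique profiles, and defined as 0 for the
frontoparallel degenerate case (both offsets zero). The acceptance
threshold 0.15 is an implementation choice; at `θ_max = 14°` well over 95%
of two-solution instances fall below it, and the margin grows as images
shrink (perspective → orthographic).

## Reporting and reproducibility

The CLI (`frequency`, `shapemap`, `stimuli-audit`) writes long-format CSV
with numbers at 12 significant digits (byte-identical reruns under a fixed
seed are a tested contract), statistics JSON, optional base-graphics
plots, and a manifest JSON (command, config, seed, package and R versions,
timings). Config files are flat JSON mirroring the flags — JSON rather
than YAML because the deployment environment guarantees `jsonlite` only —
with explicit flags taking precedence.

## Known limitations

* Exactly degenerate inputs are refused, not regularized; callers probing
  boundaries (e.g. `θ` sums of exactly 360°) get validation errors.
* Solution counts on symmetry loci are correct but discontinuous (the
  4-solution sliver above); statistics quoted at a fixed grid step inherit
  a grid-placement sensitivity of order one cell.
* The binocular combination is a conjunction of monocular projectability;
  it deliberately imposes no stereo-geometric consistency, so it
  *overstates* what a binocular observer could accept.
* `4e8`-trial precision is reachable only by raising `trials`; default
  runs trade the third decimal place for minutes-scale runtimes.
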