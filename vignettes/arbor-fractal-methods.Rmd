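---
title: "Methods: fractal and connectivity-cost analysis of dendritic arbors"
author: "arborfractal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractal and connectivity-cost analysis of dendritic arbors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arborfractal)
```

This vignette is the package's account of what it computes, why the
defaults are what they are, and where the methods' limits lie. The
subject is the 3D geometry of dendritic arbors — here, basal arbors of
CA1 pyramidal neurons — represented as rooted trees of conical-frustum
segments (`segment_arbor`), and the question of whether an arbor's
fractal dimension sits near the value that optimizes its connectivity
per unit of dendritic material.

## The arbor model

A reconstruction is a tree of nodes with 3D positions (micrometres) and
radii; every non-root node defines one segment from its parent. SWC
files of any dialect with integer ids, forward references and `#`
comments are normalized on read to contiguous pre-order ids; duplicated
points (zero-length segments, which tracing software commonly emits)
are merged with a warning rather than rejected. Soma nodes (SWC type 1)
are retained as the root attachment, but segments with *both* endpoints
soma-typed carry no dendritic mass: every metric in the package is a
dendritic metric. Coordinates are taken as micrometres, right-handed,
with no registration.

## Arbor radius

The arbor radius is the radius of gyration computed from the
length-weighted double sum over segment midpoints,

$$R_A^2 = \frac{1}{L_T^2}\sum_{i}\sum_{j}\delta l_i\,\delta l_j\,
  (\mathbf r_i-\mathbf r_j)^2 .$$

The representative point $\mathbf r_i$ of a segment is its midpoint:
the double sum then converges to the continuum double integral as
segments shrink (a rod of length $L$ gives $R_A \to L/\sqrt 6$), and
the choice is unbiased for non-uniform segment lengths. The default
implementation is the algebraically identical one-pass moment form
$R_A^2 = 2(\langle r^2\rangle_w - |\langle \mathbf r\rangle_w|^2)$; the
$O(K^2)$ double sum is kept as a cross-check and the two agree to
1e-9 relative in the test suite.

## Convex hull

Hull surface area (the connectivity normalizer) and volume (the
material-cost normalizer) are computed by an incremental 3D convex hull
over the node coordinates, written for this package and validated
against closed-form solids and an independent computational-geometry
reference on random clouds. Tube radii (~0.7 um) are ignored at hull
scale (~100 um). Coplanar inputs degrade to a flagged 2D hull with zero
volume; the connectivity and cost functionals refuse degenerate hulls
rather than return infinities.

## Multi-origin Sholl and cumulative mass

`sholl_profile()` counts intersections $N_I(r)$ of segment centerlines
with spheres of radius $r$, and the dendritic length $L_{in}(r)$ inside
those spheres, averaged over origins sampled on the arbor itself within
$R_A/2$ of the length-weighted center of mass — sampling many local
origins rather than the soma alone reduces the influence of spheres
protruding beyond the arbor. Numerical choices:

- Crossings and clipped lengths are computed *analytically* from the
  quadratic distance function of each segment — no rasterization — so
  $N_I$ is exact (0, 1 or 2 crossings per segment per sphere) and
  $L_{in}$ is exact clipping. A Monte Carlo integration oracle confirms
  the clipping in the tests.
- Origins are drawn uniformly *by arc length* of the in-ball
  centerline, so long segments are not under-weighted; the draw is
  deterministic given a seed, which is stored in the profile.
- The default radius grid is 2 um to $2R_A$ in 2-um steps, matching the
  fine-scale cutoff of the box-counting analysis; the grid can be
  overridden (the oracle fixtures use finer grids to give the window
  search more points).
- Intersections are counted against centerlines, not tube surfaces:
  the scales of interest (>= 2 um) exceed the median tube width
  (1.4 um).

The mass dimension $D_M$ is the slope of $\log L_{in}$ vs $\log r$,
fitted with the same window rule as box counting (below) over radii in
$(2\,\mu m,\ \mathrm{extent}/5]$. With the default 2-um grid this
requires an arbor extent of about 200 um for a decade-spanning window
to exist; smaller arbors raise an informative error, and cohort-scale
runs report $D_M$ for the subset of arbors that admit a window.

## Box-counting dimension

`fit_box_dimension()` overlays cubic grids of side $L_{box}$ anchored
at the bounding-box corner and counts occupied boxes, with occupancy
tested on centerline samples spaced at most $L_{box}/4$. Box sizes form
a geometric series with ratio $10^{1/16}$ (16 per decade) between the
fine cutoff of 2 um — below the median segment length (2.6 um), where
segment shape rather than arborization controls the counts — and a
coarse cutoff of one fifth of the largest axis-aligned extent, above
which counting statistics fail. Among all contiguous windows spanning
at least one order of magnitude, the ordinary least-squares fit of
$\log_{10} N_{box}$ on $\log_{10} L_{box}$ with maximal $R^2$ defines
$-D_A$.

Two properties of this estimator matter in practice and are visible in
the tests:

- **Window-selection noise.** Because real arbors are not perfectly
  scale-invariant, the local log-log slope varies across the window,
  and the max-$R^2$ rule can jump between competing windows under small
  geometry changes. Across repeated stochastic arbors this contributes
  a per-arbor scatter of roughly 0.1 in $D_A$. An optional
  low-discrepancy grid-offset average (`n_offsets`) is exposed for
  sensitivity analysis; the default remains the single corner-anchored
  grid.
- **Finite-size bias.** Fixtures confirm accuracy where scaling is
  clean: a rod gives $D_A = 0.99$, a dense plane patch 1.98, and a
  twisted Koch-type curve at recursion level 5 gives 1.260 against the
  similarity dimension $\log 4/\log 3 \approx 1.262$ — provided the
  smallest construction feature sits near the 2-um cutoff, which the
  fixture's default span guarantees.

## Angle-scaling distortion

`distort_arbor()` multiplies every fork and weave angle by a factor
$\alpha$. A branch is the maximal chain of segments between forks,
terminals, or the root; weave angles are angles between consecutive
segment directions within a branch and a branch's fork angle is its
first weave angle. At each joint the downstream subtree is rotated
rigidly about the normal of the plane spanned by the incoming and
outgoing directions, in pre-order; this is the scheme for which
re-measuring angles on the output returns exactly $\alpha\theta$ at
every joint (to 1e-6 rad in the tests) while conserving each segment
length to machine precision. Collinear joints ($\theta = 0$) have no
defined axis and are left unchanged — $\alpha\cdot 0 = 0$ anyway.
Products $\alpha\theta > \pi$ are clamped at $\pi$ and counted, so the
sweep's output count stays deterministic. Root-emanating segments have
no incoming direction and keep their heading.

The default sweep grid is $\alpha \in \{0.5, 0.75, 1.25, 1.5, 1.75,
2\}$: six distorted copies per arbor, i.e. 1,404 for a 234-arbor
cohort. Below 0.5 adjacent branches overlap near forks; above 2 the
branches become so tortuous that self-intersections are unavoidable —
`self_overlap_check()` counts interpenetrating non-adjacent tube pairs
and its median count grows between $\alpha = 2$ and 2.5 on synthetic
cohorts.

## Connectivity and material cost

Connectivity $C$ is the area of the arbor's planar projection, with
projected tube widths uniformly expanded by 2 um (the spatial reach of
spines around a branch), averaged over viewing directions and
normalized by hull surface area. "Expanded by 2 um" is read as +2 um on
the projected *width* (+1 um per side); the alternative per-side
reading is available as `dilation_mode = "radius"`. Views are a
Fibonacci lattice on a hemisphere (projection area is antipodally
symmetric); the raster covers a pixel when its center lies within the
locally dilated capsule radius of a centerline sample point, a rule
whose strip width is unbiased on average over sub-pixel phase. Two
oracles guard the machinery: a thin rod's mean dilated projection area
matches $(\pi/4)L(w+2)$ within 3% at 256 views, and a closed spiral
shell reproduces Cauchy's mean-projection ratio (projection/hull area
$\to 1/4$) within 5%.

Defaults are 64 views at 0.5-um pixels; cohort-scale stages use 16
views at 1-um pixels, which moves $C$ by under 0.5% on full-size arbors
(a convergence test doubles the view count and requires <1% change).

Material cost $M$ is the summed frustum volume
$V_i = (\pi/3)\,\delta l_i (r_0^2 + r_0 r_1 + r_1^2)$ over dendritic
segments, divided by hull volume. Frustum overlap at joints is not
deducted; with width/length ratios of real dendrites the error is well
under the 5% tolerance noted on the invariant $M \lesssim 1$.

## The optimization statistic

For each category the $(D_A, C, M)$ points of natural plus distorted
arbors are pooled, $C$ and $M$ are normalized by their maxima within
the observed (optionally clipped) $D_A$ range, and each is fitted with
an ordinary least-squares cubic. The connectivity-cost ratio

$$R_{CM}(D_A) = \frac{dC/dD_A}{dM/dD_A}$$

is evaluated from the *fitted polynomials'* derivatives on a 0.001
grid — not from numerically differentiated binned data, which the
derivative structure would render hopelessly noisy. Grid points where
$|M'|$ falls below 1e-6 of its maximum are masked; $D_O$ is the argmax
of the largest finite component containing an interior maximum, and a
monotone ratio is flagged rather than silently reported. Binned
averages (0.02 in $D_A$) accompany the fits as a diagnostic.

The self-similarity exponent comes from the cross-arbor power law
$R_A \sim L_T^{\nu}$: an OLS fit on log-log axes with
$\mu = 1/\nu - 1$ and a first-order delta-method standard error
($SE_\mu = SE_\nu/\nu^2$; the estimation method behind the quantity's
conventional +/- is not standardized, so the label "delta method" is
attached to ours).

## Group statistics

`anova_tukey()` is a classic fixed-effects one-way ANOVA followed by
Tukey-Kramer studentized-range comparisons, which honor unequal group
sizes; stars are assigned at 0.05/0.01/0.001. The per-radius contrast
of Sholl curves between categories uses Welch's t on per-arbor mean
$N_I(r)$ — the unequal-variance choice is deliberate since cohort sizes
and spreads differ — with no multiplicity correction across radii; the
report flags the contrast as exploratory and returns the longest
contiguous significant run with a consistent sign. The arbor, not the
animal, is the unit of analysis, matching how such cohorts are usually
tabulated; per-animal aggregation is a straightforward `tapply` on the
returned tables when independence is a concern.

Type-I calibration is part of the acceptance suite: under the null
(six groups of 40), the omnibus rejection rate over 1,000 simulations
must sit in 5% +/- 1.5%.

## The synthetic cohort generator

No generative parameters for real CA1 basal arbors are available, so
the generator (`make_cohort()`) is calibrated to reproduce printed,
checkable properties of such cohorts — and its defaults are fixed, not
a tuning surface:

- arbor radii $R_A$ within 68–134 um with cohort mean near 97 um
  (rejection sampling on the window keeps internal statistics
  consistent; the achieved mean is ~93 um);
- segment length and width medians of 2.6 um and 1.4 um (lognormal
  proposals, width tapering by 7% per branch order);
- box dimensions spanning roughly 1.2–1.8 with an interior mode.

Growth is a breadth-first cascade: 3–5 primary stems from a point
soma; branches are chains of ~6 segments whose directions weave by
wrapped-normal angles (mean 30 degrees, sd 13) blended with an outward
radial drift (weight 0.08); forks occur with probability decaying in
branch order, at wrapped-normal fork angles (mean 40 degrees, sd 15);
growth stops at a lognormal target length. The weave/drift combination
is the load-bearing calibration: strong local weave sets the fine-scale
box dimension near 1.5, while the outward drift lets paths still reach
~100-um radii. The price is a total length (~8,000 um) larger than real
basal arbors; of the stated calibration targets, radius and segment
medians were prioritized over total length, and the discrepancy is
noted here deliberately.

Group effects are planted by scaling each group's fork and weave angles
with `distort_arbor()` — the same lever the distortion module sweeps —
so planted effects are exactly angle-scaling effects. The default
multiplier (1.15 for the triple-positive SH-ENR-TR group) shifts mean
$D_A$ by only ~0.06, the same order as the box-count window-selection
noise, mirroring how subtle such group differences are in practice; the
parameter-recovery test therefore uses a 1.3 multiplier, whose ~0.15
shift is decisively detectable at n = 40 per group, and treats 1.15 as
the shipped study condition rather than the test condition.

What passing tests on this cohort do *not* show about real data: the
generator reproduces local geometry and size calibrations, not
cross-arbor allometry — its $R_A$ is nearly independent of $L_T$, so
the emergent self-similarity exponent $\mu$ (~2.3) is steeper than
values near 1.4 measured on real cohorts, and the synthetic $C(D_A)$,
$M(D_A)$ curves place the $R_{CM}$ peak below the natural $D_A$ mode
rather than on top of it. Those quantities are reported honestly by the
reproduction script as properties of the stand-in cohort.

### Oracle fixtures

`make_fixture()` builds deterministic geometries with known answers:
`rod` ($D_A = 1$, $R_A = L/\sqrt6$), `star5` ($N_I = 5$ inside the
rays), `plane_carpet` ($D_A = 2$), `koch3d` (similarity dimension
$\log4/\log3$), `htree3d` (clean fork structure), `geodesic_ball`
(Cauchy 1/4 ratio), and `ball_soup` — a density-calibrated confined
random walk whose cumulative mass grows as $r^3$. The soup's step
density (0.8 um of walk per um^3) is set so that the walker's own
linear trace through each origin stays a small fraction of the
enclosed-volume term at the finest fitted radius; the residual bias is
a few hundredths in $D_M$, well inside the 0.1 oracle band.

## Problem sizes and determinism

Cohort-scale runs use 25 Sholl origins per arbor with profiles
evaluated out to 160 um (well past every N_I peak), 16 views at 1-um
pixels for connectivity, 15 natural arbors per category (each with its
six distorted copies) for the C/M fits, and the full 234-arbor cohort
for everything else; these sizes put the complete reproduction run
near ten minutes on a single core while leaving all estimator
accuracies within the tolerances quoted above. Every random draw —
growth, origin sampling, subset selection — derives from explicit
seeds, and identical seeds reproduce outputs byte-for-byte.

## Known limitations

- OBJ input is a vertex cloud only: no reverse skeletonization is
  attempted, so centerline-based metrics (angles, Sholl, distortion)
  require SWC input.
- The max-$R^2$ window rule, taken as given, is the dominant source of
  per-arbor $D_A$ variance on imperfectly scaling geometries.
- $D_M$ requires an extent of ~200 um under the default 2-um grid (see
  above); use a finer radius grid for smaller arbors.
- Strongly curled distortions ($\alpha = 2$ on already-tortuous
  arbors) can shrink the extent below the box-counting decade
  requirement; pipeline stages drop such arbors with a record rather
  than fail.
- The generator's allometry and optimization-peak placement differ
  from real cohorts, as described above.
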