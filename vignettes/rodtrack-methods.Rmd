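---
title: "Methods: level-set segmentation, septum-based division detection and trajectory-energy tracking of rod-shaped bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: level-set segmentation and trajectory-energy tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodtrack)
```

# Scope

`rodtrack` segments and tracks rod-shaped bacteria (typified by
*E. coli* growing in a microfluidic chamber) in 2-D grayscale
time-lapse stacks, detects divisions from the intensity signature of
the septum, maintains identities by minimizing a global trajectory
energy, and reconstructs lineage trees with per-cell growth
statistics. A built-in simulator renders growing, dividing capsule
cells with exact ground-truth masks and lineage so that every part of
the pipeline can be validated quantitatively.

This vignette documents the model, the discretization, the tunable
parameters and their defaults, the design decisions that were
genuinely open, what the simulator does and does not emulate, and the
known limitations. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

# The level-set model

Cell boundaries are extracted with distance-regularized level set
evolution (DRLSE). A scalar field $\phi$ over the image domain
represents each cell: the contour is the zero level set and the
interior is $\phi < 0$. The energy is

$$E(\phi) \;=\; \mu \int_\Omega p(|\nabla\phi|)\,dx
 \;+\; \lambda \int_\Omega g\,\delta(\phi)\,|\nabla\phi|\,dx
 \;+\; \alpha \int_\Omega g\,H(-\phi)\,dx,$$

with the double-well potential

$$p(s) = \begin{cases}
  \frac{1}{(2\pi)^2}\bigl(1 - \cos 2\pi s\bigr), & s \le 1,\\[2pt]
  \tfrac12 (s-1)^2, & s > 1,
\end{cases}$$

whose minima at $s = 0$ and $s = 1$ keep $|\nabla\phi|$ near 1 (a
signed distance function) without reinitialization, and the edge
indicator $g = 1/(1 + |\nabla G_\sigma * I|^2)$, which is close to 1
in flat regions and small at intensity edges. Minimization follows the
gradient flow

$$\frac{\partial\phi}{\partial t} =
  \mu\,\mathrm{div}\!\left(d_p(|\nabla\phi|)\,\nabla\phi\right)
 + \lambda\,\delta(\phi)\,
   \mathrm{div}\!\left(g\,\frac{\nabla\phi}{|\nabla\phi|}\right)
 + \alpha\, g\,\delta(\phi),
 \qquad d_p(s) = p'(s)/s,$$

where $d_p$ is bounded ($|d_p| \le 1$, with the removable singularity
at 0 filled by its limit 1) and a negative $\alpha$ expands the
contour outward until the $g$-weighted terms stop it at the cell edge.

## Discretization and numerical choices

* Central differences in the interior, one-sided differences at image
  borders (so an exact signed distance function has $R_p = 0$), and a
  5-point divergence stencil; Neumann boundary handling throughout.
* Smoothed Dirac
  $\delta_\varepsilon(x) = \tfrac{1}{2\varepsilon}(1 +
  \cos(\pi x/\varepsilon))$ on $|x|\le\varepsilon$ and its integral as
  the smoothed Heaviside, with $\varepsilon = 1.5$ px. The model
  citations leave the smoothing width open; this is the standard
  choice and it is configurable (`drlse_params(eps = )`).
* Initialization is a binary step: $-c_0$ inside the seed, $+c_0$
  outside, $c_0 = 2$ (configurable). DRLSE tolerates such
  non-distance initializations; the regularizer rebuilds the distance
  profile within a few iterations.
* $|\nabla\phi|$ is floored at $10^{-10}$ in the curvature term.
* Stability requires $\mu\,\Delta t < 0.25$; the constructor refuses
  configurations that violate it.
* The hot loop is implemented in C++ (Rcpp); everything else is plain
  R.

## Stopping criterion

Each iteration evaluates the three unweighted energy integrals
$(R_p, L_g, A_g)$ and stops when

$$\Delta^i = \|R_p^i - R_p^{i-1}\|^2 + \|L_g^i - L_g^{i-1}\|^2 +
  \|A_g^i - A_g^{i-1}\|^2 \;\le\; K.$$

Two properties of this scheme are worth documenting honestly:

* The flow has **no exact steady state** on ideal step-edge images:
  $g$ never vanishes, so the expansion force $\alpha g \delta$ keeps
  pushing the contour through the low-$g$ edge band at a vanishing
  rate (and, given unbounded iterations, eventually past it). $K$ is
  therefore not a shortcut but the operative convergence detector; the
  accuracy of the stopped contour is validated directly (a noiseless
  dark disk is recovered within 2 px Hausdorff distance).
* The production step size ($\lambda = 5$, $\Delta t = 1$) trades
  strict per-step energy monotonicity for speed, as is usual for
  explicit curvature flows. The descent property is verified in the
  regime where it holds: $R_p$ alone at $\Delta t = 1$, and
  $\mu R_p + \lambda L_g$ at a CFL-respecting step from an
  SDF-consistent start.

## Defaults

| parameter | default | units | meaning |
|---|---|---|---|
| $\Delta t$ | 1 | – | time step |
| $\mu$ | 0.2 | – | distance regularization weight |
| $\lambda$ | 5 | – | edge (length) weight |
| $\alpha$ | −3 | – | area weight; negative expands |
| $K$ | 0.005 | – | stopping tolerance |
| $\sigma$ | 1 | px | Gaussian for preprocessing and $g$ |
| $\varepsilon$ | 1.5 | px | Dirac/Heaviside half-width |
| $c_0$ | 2 | – | step initialization height |

The first five are the selected configuration of the method this
package implements; $\sigma = 1$ preserves the rod-like membrane and
septum structures while suppressing noise (larger values smooth the
septum away).

# Segmentation

**Seeding.** Rough interiors come from adaptive thresholding: a pixel
seeds a cell when it is darker than the local mean over a 25-px window
minus an offset (default 30 gray levels). For an 8-bit-like image with
a cell-to-background contrast of ~120 gray levels the offset puts the
seed boundary at the 50% edge crossing — the unbiased edge estimate —
so DRLSE only has to refine it. Both numbers are configurable
(`seg_config`).

**Growth and filtering.** Each seed evolves independently, with
already-claimed pixels frozen so masks stay disjoint. Final components
shorter than `r_s` (default 3 µm — the minimum size of a complete
cell) are discarded as debris, and objects touching the image border
are removed. `r_s` is interpreted as a *length* (maximum Feret
diameter of the mask): the value "3 µm" reads as a pole-to-pole extent
for rods about 1 µm wide; it is configurable for users who prefer an
area interpretation. Border removal applies to first-frame
segmentation and new-cell capture only — removing tracked cells that
later touch the border would truncate genealogies.

**Shape descriptors.** Length is the maximum Feret diameter (convex
hull diameter) of the mask plus one pixel of extent; width is
area/length, which is accurate for high-aspect capsules and avoids the
~15% overestimate an ellipse-equivalent minor axis gives on
rectangular cross-sections. Orientation and eccentricity come from
second central moments.

# Tracking

**Overlap region.** A tracked region from frame $t-1$ is split into
windows of side `w` (default 0.6 µm ⇒ 4 px at 0.15 µm/px); windows
whose maximum smoothed-image gradient exceeds an Otsu split of the
per-window maxima are classified as boundary windows and eliminated.
At this calibration cells are barely wider than the window, so the
surviving interior can be very small; the overlap region V is then
recovered as the intersection of the previous region's neighbourhood
(a 4-px dilation, bounding how far a region may reach in one frame)
with the current frame's adaptive-threshold interior — which is
exactly the "intersection of the previous and current cell region"
the window construction approximates. The Otsu rule itself is a design
choice; the underlying method specifies only that boundary windows
carry high gradients.

**Coevolution without merging.** Every live cell's eroded previous
mask is frozen *before* any cell evolves, so a cell processed earlier
can never creep into a touching neighbour that has not yet claimed its
pixels; afterwards, each evolved mask freezes its pixels for the
remaining cells. When V itself falls into two sizable components (a
physically separated, freshly divided pair that still shares one
label), the components are coevolved with a 1-px moat between them:
same-label components must stay disconnected, not merely
non-overlapping, for the separation to be recognized.

**Component filtering.** Evolved components overlapping the previous
mask are kept. Detached components must look like a rod of comparable
size (eccentricity ≥ 0.8 and area ≥ half the previous region's area).
The obvious alternative — an absolute area cutoff of half the squared
`r_s`-equivalent — would reject genuine cells (a 3 µm × 1 µm rod is
~133 px² at 0.15 µm/px, below such a cutoff of 200 px²), which is why
the relative rule is used.

**Division detection.** Cells are dark on a bright background, and the
septum brightens toward the background level as constriction
completes. The detector therefore works on the *inverted* smoothed
image (max − I), where the cell interior is a high plateau and the
septum a local **minimum**; the criterion is then literally "the local
minimum $l_m$ of the major-axis profile lies below
$r_m = \mu_{septum} + \tau\,\sigma_{septum}$", with the statistics
taken over all tracked contours' boundary bands (a 1-px ring on each
side of each contour) in the current frame and $\tau = 1.2$. The
profile is sampled at 1-px arc steps along the region's major axis,
following the mask's transverse centre of mass (the spine) so bent
cells and freshly separated pairs are sampled through their mid-line,
averaged over a 3-px transverse band. A qualifying minimum must be
≥ 2 px from either pole and have a prominence of at least 4% of the
profile's dynamic range on both flanks, which rejects rasterization
ripple without touching real septa. Detection runs only on regions
longer than `min_div_len_factor * r_s` (default 2 × 3 µm), so newborn
cells are never split spuriously. Regions wider than `r_w` (default
1.2 µm, strict inequality) get the same treatment along the minor axis
— two cells lying side by side merged into one object. Regions whose
mask has physically separated into two components are divided directly,
provided both components are at least `r_s` long (a fragment is not a
daughter).

**Trajectory energy.** Identities are maintained by minimizing

$$E(X) = \beta E_{vel} + \gamma E_{exc} + \eta E_{reg}, \qquad
(\beta, \gamma, \eta) = (0.02,\ 0.5,\ 0.5),$$

with the constant-velocity term
$E_{vel} = \sum_n \sum_{t} \|X_n^t - 2X_n^{t+1} + X_n^{t+2}\|^2$, the
exclusion term $E_{exc} = \sum_t \sum_{n, j \ne n} r_w^2 / \|X_n^t -
X_j^t\|^2$ over ordered pairs (the double-index notation reads
naturally as ordered pairs; the choice only scales the term by 2 and
is absorbed by $\gamma$), and the regularizer
$E_{reg} = N + \sum_n 1/F(n)$ that discourages needless track
fragmentation. Positions $X_n^t$ are mask centroids in pixels;
coincident centroids make $E_{exc}$ infinite and the assignment is
rejected rather than propagating infinities.

**Assignment.** Links between candidate regions and live trajectories
come from mask overlap. Unambiguous one-to-one components are accepted
directly. Ambiguous components are resolved by enumerating all
consistent assignments (each region to one overlapping trajectory or
to a new track, each trajectory extended at most once) and choosing
the energy minimum over the affected trajectories; past 64
enumerable assignments the component falls back to greedy maximum
overlap with a logged event. Assignments are resolved online, frame by
frame — a deliberate simplification of a multi-frame lookahead, which
would require holding several alternative segmentations alive per
frame; the `lookahead` knob is retained in the configuration for
forward compatibility. Divisions close the mother at $t-1$ and open
two children with parent links; cells with no propagated candidate end
their trajectory (no gap closing); new cells entering the field are
captured by re-running the first-frame scheme on the unclaimed area.

# Genealogy and growth

The trajectory forest is validated (children exactly 0 or 2, child
birth = mother end + 1) and annotated with generation numbers (root =
0). Newick export uses trajectory durations (frames) as branch
lengths. Per-cell growth records report size at birth and division
(pole-to-pole length, µm), division time $F(n)$ in frames and seconds,
and the elongation rate as the least-squares slope of $\log L$ against
frame — a log-linear fit rather than a nonlinear exponential fit,
which is robust and sufficient for approximately exponential
single-cell growth. Rates are emitted per frame (canonical) and per
hour.

# Evaluation

* **Dice**: $2|A \cap B| / (|A| + |B|)$; two empty masks score 1.
* **Segmentation categories**: a bipartite overlap graph links
  ground-truth and predicted objects when IoU ≥ 0.5 *or* the
  intersection covers at least half of either object; the coverage
  clause is needed because a prediction covering two equal cells has
  IoU ≈ 0.5 against each and a strict IoU rule could represent neither
  under- nor over-segmentation. One-to-one links are true positives,
  one-to-many over-segmentation, many-to-one under-segmentation
  (counted in ground-truth cells), unlinked ground truth a false
  negative. A cell undergoing division that is matched by either one
  or two predictions counts as a true positive — methods legitimately
  differ on when a dividing cell becomes two objects.
* **MOTP**: mean Euclidean distance over matched pairs.
* **MOTA**: reported as $100\,(1 - \sum_t (FN_t + FP_t + MM_t) /
  \sum_t g_t)$, i.e. the *complement* of the error ratio, so that
  higher is better — matching the percentage semantics in which such
  scores are quoted (the raw ratio formula as printed equals the error
  rate). The three error ratios are also reported separately.
* **Track matching**: correspondences persist from frame to frame
  while within the gating distance (default 5 px); the rest is greedy
  nearest-centroid. A mismatch is counted per affected ground-truth
  track per frame (an identity swap costs 2); ground-truth divisions
  start fresh tracks and do not count as mismatches. Both thresholds
  are configurable and recorded in the report.

# The synthetic world

The simulator emulates the acquisition geometry of a microfluidic
growth-chamber experiment: 0.15 µm/px calibration, 69 s frame
interval, 256×256 px default field, dark cells (gray 80) on a bright
background (gray 200), Gaussian blur of 1 px and additive Gaussian
noise (default 3.6 gray levels = 3% of the dynamic range).

* **Shape**: a capsule (rectangle plus semicircular caps) of width
  1 µm — the mask is analytic, so ground truth is exact.
* **Growth**: exponential, default 0.035/frame, i.e. a division time
  of ~20 frames (~23 min at 69 s/frame), typical of fast-growing
  *E. coli*.
* **Division**: at 6.5 µm the cell enters a septum phase whose
  progress ramps linearly over 4 frames. The rendered septum is a
  transverse ridge (half-width 0.08 µm) whose brightness rises with
  progress *squared* to 90% of the background contrast — constriction
  becomes optically apparent late, and the quadratic ramp keeps the
  detector (at the fixed $\tau = 1.2$) from firing while the septum is
  still forming. Ground-truth division is recorded at the frame where
  progress reaches 1: the daughters (each ≈ L/2) appear with a 0.45 µm
  pole gap (3 px — optically resolvable, like the bright septum line
  between real abutting daughters), and sibling pairs keep that gap
  for 3 frames (daughters push apart as they grow) even under
  crowding, where soft-body repulsion otherwise maintains only a
  0.2 µm minimum surface gap between cells.
* **Determinism**: the scene and every rendered frame derive from the
  single seed; identical seeds give bit-identical data.

What the simulator does **not** emulate: phase-contrast optics (halo,
shade-off), illumination gradients, focus drift, cell-shape
irregularity and bending, lysis, and the dense end-stage crowding of a
filled chamber. A green test on this benchmark therefore establishes
the *internal* correctness and self-consistency of the pipeline at
realistic geometry, contrast and noise — not performance on any
particular real microscope's data.

# Known limitations

* Lost cells end their trajectory; there is no gap closing across
  missed detections.
* Assignment ambiguity is resolved per frame (see above), so a
  pathological crossing that only a multi-frame lookahead could
  disentangle may be resolved greedily.
* The septum detector assumes dark cells on a bright background; other
  contrasts require inverting the input.
* Very fast growth (≫ 0.07/frame, division time under ~10 frames) can
  outrun the 4-px per-frame reach of region propagation.
* Stacks are read as directories of PGM frames (plus CSV/JSON tables);
  TIFF support would require an image I/O dependency not available in
  the target environment.
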