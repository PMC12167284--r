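---
title: "Sphere-fiducial scene registration: model, choices, and limits"
author: "sphereg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sphere-fiducial scene registration: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphereg)
```

## The problem

Building a ground-truth dataset for surgical computer vision requires three
ingredients expressed in one coordinate frame: an accurate surface mesh of
the scene (from an optical or CT scan, in its own scan-local frame S), a set
of high-resolution images, and the camera pose of every image (in a world
frame W, from robot forward kinematics or structure-from-motion). The
missing link is the rigid map between S and W. `sphereg` estimates that map
from spherical fiducial markers of precisely known radius that are rigidly
fixed around the specimen: spheres are easy to localize accurately in a
scan, and their projections in an undistorted pinhole image are exactly
ellipses, whatever the viewpoint.

## The model

A sphere with centre $c$ and radius $r$ is the zero set of the quadric

$$Q = \begin{pmatrix} I & -c \\ -c^\top & c^\top c - r^2 \end{pmatrix},$$

and its silhouette under a camera with $3\times4$ projection matrix
$P = K\,[R \mid t]$ is the conic $E$ with $E^{-1} \propto P\,Q^{-1}P^\top$
(the dual quadric maps tangent planes to tangent lines). A point $x$ on the
ellipse outline, in homogeneous pixel coordinates, satisfies the bilinear
identity $x^\top E\,x = 0$. Writing $E_{ij}$ for the conic of marker $j$ in
image $i$ under a candidate scene-to-world transform $T$, and $x_{ijl}$ for
$L$ points sampled on the detected ellipse outline, the registration is

$$\hat T = \arg\min_T \sum_{i=1}^{N}\sum_{j=1}^{M}\sum_{l=1}^{L}
  \left( x_{ijl}^\top E_{ij}(T)\, x_{ijl} \right)^2 ,$$

minimized with Levenberg–Marquardt (`minpack.lm::nls.lm`) using the analytic
Jacobian, which is obtained by the chain rule through the dual quadric, the
$3\times3$ adjugate, and the conic normalization. When camera poses come
from structure-from-motion they are metric only up to scale; a scale $s$ is
then estimated jointly. We attach $s$ to the S-to-W map
($c_W = sRc_S + t$, with marker radii scaled to $sr$ in W), which is
algebraically equivalent to scaling the camera poses but keeps them fixed.

Two choices make this objective well posed:

* **Conic normalization.** $E$ is a scale-equivalence class, and the
  algebraic cost could be driven to zero by shrinking $E$. Every conic is
  normalized to unit Frobenius norm with positive trace of its upper-left
  $2\times2$ block, making residuals comparable across markers and images.
* **Rotation parameterization.** The rotation is updated as
  $R_0\exp([\omega]_\times)$ with a local axis-angle increment $\omega$,
  singularity-free near any estimate; the scale is parameterized as
  $\log s$ to stay positive.

Convergence is declared at a relative cost change below $10^{-10}$ or a
parameter step below $10^{-12}$, capped at 200 iterations. The dual conic
$B = PDP^\top$ is inverted via its adjugate, which is polynomial in the
entries and well behaved even when $B$ drifts toward singularity during
line-search extremes (for a real sphere in front of the camera $B$ is
always invertible).

## Initialization: exhaustive PnP over marker assignments

The refinement needs a starting point inside its convergence basin, and the
markers are visually indistinguishable, so correspondence must be
established too. In one image where all markers are visible, four detected
ellipse centres are selected (largest support first) and every ordered
assignment of 4 of the $M$ sphere centres to them is evaluated: a P3P solve
(Grunert's quartic) on three pairs, the fourth pair to disambiguate the up
to four roots, and the remaining sphere centres projected and gated against
the unassigned detections (gate: 25 px at a 9504 px sensor width, scaled
linearly with width). The best-scoring hypothesis wins; ties break by
summed gated distance, then assignment order. If no hypothesis gates in
every matchable marker, further ranked 4-subsets are tried — a single
acceptable-but-partial hypothesis from a near-collinear subset is not
trusted, which in our experiments was the difference between occasional
10 mm initializations and uniformly sub-2 mm ones.

An ellipse centre is not the projection of the sphere centre (perspective
bias, up to a few pixels here); the bias is tolerated at initialization and
eliminated by the conic refinement, which never uses centres. In similarity
mode the initial scale is the ratio of the camera-centre baseline between
the two best images (each solved by PnP in metric marker units) to the same
baseline in the camera world.

## Marker localization in the mesh

Markers are localized in the scan by fixed-radius sphere fitting from a
manual initialization (a labelled list of approximate centres; no GUI).
Each iteration selects support vertices whose spherical residual
$\bigl|\;\lVert v-c\rVert - r\;\bigr|$ is within a band (default 1.5 mm,
10% of the 15 mm radius — wide enough for scan noise, narrow enough to
exclude the mounting stalk), trims outliers beyond 3 MAD (fringe vertices
at the sphere–mount junction), and applies a Gauss–Newton update of the
centre. The radius is never estimated: it is known by construction, and
fixing it is what makes hemisphere-only coverage (a handheld scanner sees
one side) well conditioned. Only mesh vertices are used, no face sampling.
We use the sphere-distance residual rather than point-to-point ICP pairs;
with a fixed radius the two coincide at the optimum and the former is
smooth.

## Evaluation metrics

* **Radial error** of an outline point: back-project the pixel to a ray and
  report $\lvert d(\mathrm{ray}, c) - r\rvert$, the deviation from
  tangency to the sphere hull, in mm. Distance to the sphere surface as a
  point set would be zero for every secant ray and could not measure
  tangency. A ray through the centre scores exactly $r$; a tangent ray 0.
  Computed on *control* markers excluded from the registration, and
  divided by $s$ in similarity mode so it is reported in metric mm. Means
  are reported per point, per marker and per image (they differ when
  visibility is uneven).
* **Reprojection error** between the projected and the detected ellipse:
  symmetric mean orthogonal (foot-point) distance, sampled at
  `nSamples = 200` per ellipse by default — geometric, in pixels, not the
  algebraic residual. For concentric circles it is exactly the radius
  difference.
* **Chamfer distance** between meshes: area-uniform surface sampling
  (default $10^5$ points per mesh), exact point-to-triangle nearest
  distance (compiled kernel), symmetric mean by default with median/RMS and
  one-sided variants available so other conventions can be matched.

## The synthetic scene generator

Every stage is testable without external data through `generateScene()`,
whose defaults are the study conditions of the physical rig it emulates:
$M = 10$ registration markers of 30 mm diameter on a ring around the
specimen plus 3 central control markers, $N = 16$ viewpoints at roughly
1 m arranged as two arcs on opposite sides of the table, a
$9504\times6336$ px sensor with $f = 7000$ px (a 30 mm marker at 1 m spans
about 200 px), $L = 20$ outline points, and a simulated scan with 0.05 mm
vertex noise (the point accuracy of a handheld structured-light scanner).
A `"desk"` preset ($1920\times1080$, $f = 1400$ px) keeps rendering tests
fast. Marker placement is jittered (seeded): physical markers are affixed
by hand, and an exactly regular ring would be rotationally symmetric,
making the correspondence between indistinguishable markers genuinely
ambiguous — with ten-fold symmetry no correspondence search can succeed.
All randomness flows from one integer seed; the same config is
byte-identical.

What the generator does *not* emulate: lens distortion (assumed corrected
upstream), specular or low-texture surfaces that defeat real detectors,
occlusion of markers by instruments, soft-tissue deformation between scan
and capture, and SfM pose error structure (poses are exact up to the
injected noise). Passing the synthetic closure tests therefore validates
the geometry and the optimizer, not robustness to real imaging conditions.

## Numerical behaviour and test problem sizes

On noise-free synthetic scenes the objective is exactly zero at the truth,
and the full pipeline (PnP search, matching, refinement) recovers the
transform to about $10^{-11}$ mm and $10^{-8}$ rad, with control-marker
radial error near $3\times10^{-9}$ mm — the numerical noise floor of the
conic chain at this image scale. With 0.5 px outline noise at the
full-resolution preset the mean radial error is a few $\mu$m over 3200
residuals, two orders below the submillimeter regime. The test suite runs
100 noise-free closure scenes, 20 scale-recovery trials, a 5-level noise
sweep with 20 repetitions per level, 100 P3P correspondence searches, 100
hemisphere sphere fits, and 100 random projection-oracle pairs; the
acceptance script reports the same quantities at reduced repetition counts.
Chamfer closed-form checks use UV-spheres subdivided so that facet sag
(about $r\theta^2/8$) stays below 0.01 mm.

## Known limitations

* The ellipse detector (adaptive threshold, connected components,
  sub-pixel threshold-crossing boundary, direct least-squares fit with
  residual gating) is validated against the renderer's analytic conics; on
  real images its residual gate rejects merged silhouettes of overlapping
  markers rather than splitting them.
* Only distortion-free PINHOLE / SIMPLE_PINHOLE models are accepted;
  COLMAP models with distortion must be undistorted first.
* Mesh I/O is text-based (ASCII PLY/OBJ/STL); binary scans must be
  converted.
* Rigid-mode registration of SfM poses whose scale is far from 1 degrades
  by construction; the pipeline warns when detection-to-marker matching
  coverage collapses, and similarity mode is the remedy.
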