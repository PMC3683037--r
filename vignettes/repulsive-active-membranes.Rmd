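---
title: "Tracking many touching objects with mutually repulsive active membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking many touching objects with mutually repulsive active membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(ramtrack)
```

## The model

`ramtrack` tracks a fixed set of moving objects in grayscale time-lapse
movies.  Each object is represented by an **open active contour**: an
ordered chain of control points $v(s)$ with an elastic internal energy

$$E = \int \tfrac{\alpha}{2}\,|v'(s)|^2 + \tfrac{\beta}{2}\,|v''(s)|^2\,
      \mathrm{d}s + \int P(v(s))\,\mathrm{d}s,$$

where $P$ is a smoothed image potential whose minima sit on the objects
(dark bodies on a light background directly; bright-field bacteria after a
classification-based enhancement, below).  Discretizing on $n$ control
points gives the banded operator $A$ with interior row pattern
$(\beta,\,-\alpha-4\beta,\,2\alpha+6\beta,\,-\alpha-4\beta,\,\beta)$
(`build_internal_operator()`); the semi-implicit relaxation step solves

$$(A + \gamma I)\,x_{t+1} = \gamma\,x_t + F_\text{ext}(x_t)$$

per spatial axis.  Open contours model elongated bodies: the endpoint rows
of $A$ are replaced so that the internal force on each tip equals $-1/2$
of the force on its neighbor, leaving the tips free to follow the image.
The body length is controlled externally, by a harmonic tip-stretching
force $k(L_0 - L)/2$ along the outward tip tangents
(`tip_stretch_force()`) or by springs toward anticipated tip positions
(`tip_attraction_force()`).

Three couplings turn per-frame contours into a multi-object tracker:

* **Time** — the contours of one object over a block of frames form a
  *membrane* $X$ ($n$ points $\times$ $T$ frames).  A second banded
  operator $B$ acts along the temporal axis, penalizing inter-frame
  displacement (`temporal_alpha`) and trajectory acceleration
  (`temporal_beta`).  Each iteration solves the Sylvester equation
  $(A+\gamma I)X + XB = \gamma X + F(X)$ (`solve_membrane_block()`), by
  eigendecomposition of the two small operators.  Movies are processed in
  overlapping blocks; already-solved frames are pinned so each block is
  conditioned on the previous one.
* **Objects** — control points of different objects repel within a cutoff
  $r_0$ (the object width): force $\varepsilon(1-d/r_0)^2$ per point pair
  (`repulsion_forces()`).  This keeps two contours from collapsing into
  one merged image well during contact, which is the failure mode of
  independent per-object snakes.
* **Length** — each object's target length is fixed for the whole movie,
  acting as a simple explicit shape prior.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `gamma` | 1/iteration | 1 | step damping; forces are normalized so the peak image force is ~1 px/iteration |
| `tol` | px | 0.01 | convergence threshold on per-iteration displacement |
| `block_size`, `block_overlap` | frames | 5, 1 (flies: 3, 1) | temporal block scheme; smaller blocks correct contact-time misplacements faster |
| `temporal_alpha` | — | 0.005 | drag on inter-frame displacement; kept small because it also drags moving objects backward |
| `temporal_beta` | — | 0.05 | penalty on sharp trajectory turns |
| `r0` | px | object width (cells: 0.7 width) | repulsion cutoff |
| `epsilon` | force | well depth of frame 1 | repulsion magnitude; matching the well depth lets repulsion expel a second contour from an occupied well |
| `k_str` | force/px | 0.25 (cells 0.3) | tip length-constraint stiffness |
| `kappa` | — | 0.2 | inchworm regrowth rate per iteration |
| `shrink_fraction` | — | 0.7 | length fraction at the start of each time step (cells) |

Potentials are normalized per movie by the maximum gradient magnitude of
the first frame.  This makes all force scales (`epsilon`, `k_str`,
`rescue_gain`) movie-independent; without it the balance between image
force, repulsion and tip forces would depend on the camera's contrast.

Two choices deserve explanation because they were genuinely open:

* **Fly target lengths are calibrated to the relaxed equilibrium** on the
  first frame rather than to the blob extent.  A target length above the
  equilibrium leaves the tips under constant outward pressure; whenever a
  neighboring fly softens the potential wall at one end, that tip leaks
  into the gap and drags the contour off its body.  With the calibrated
  length the tip force is zero in isolation and only resists changes.
* **The temporal operator uses natural free ends**, not the spatial
  endpoint rule.  The spatial rule (tip force $= -1/2$ neighbor force,
  opposite sign) is anti-restoring — desired for image-seeking tips, but
  along the time axis it makes the newest slice extrapolate away from its
  past, which destabilizes short blocks.

## Bright-field enhancement for packed rods

Bright-field bacteria appear as dark rods surrounded by bright halos, with
poor contrast where cells pack tightly.  `preprocess_cell_frame()` builds
a potential in four steps:

1. `hessian_features()` — Gaussian-derivative Hessian at scale ~half the
   cell width; the principal eigenvalue is strongly positive across dark
   bodies (valleys) and strongly negative across halos (ridges).
2. `alignment_order()` — a nematic order parameter: the eigenvalue
   anisotropy is treated as a dipole magnitude along the principal
   eigenvector and averaged locally with orientation doubling; the
   returned field is high in unstructured background.
3. `feature_pca()` — the per-pixel triples (eigenvalues, intensity) are
   nearly coplanar; the two leading principal components carry the
   ridge/valley contrast.
4. `em_classify()` — a 3-component full-covariance Gaussian mixture over
   (PC1, PC2, order).  The mixture is *fitted on confident strata only*
   (high-order pixels train the background component; low-order pixels,
   split by PC1, train the two feature lobes) and the transition annulus
   between cells and background is classified by the final E-step.
   Without the stratification the mixture prefers to split the order axis
   into levels instead of separating the two feature lobes whenever
   background dominates the field of view.  Components are labeled by
   rule: background has the highest mean order; among the rest, the lobe
   with the larger responsibility-weighted principal eigenvalue is the
   valley.  `p_valley` is multiplied by 0.8 before renormalization so
   that segmentation errs toward under-segmented valleys, the direction
   the tracker tolerates.

The enhanced image $0\cdot p_\text{valley} + 0.7\cdot p_\text{background}
+ 1\cdot p_\text{ridge}$ is blurred (3 px) into the tracking potential:
cell bodies are minima, halos are barriers, and the elevated background
keeps contours from leaking off cells.  The classifier (PCA transform plus
mixture parameters) is fitted on the first frame and reused for the rest
of the movie; imaging statistics are stationary on these time scales, and
refitting is available via `refit_classifier`.

## Inchworm placement for flexible rods

Cells are tracked as 25-point contours.  At the start of every time step
each contour is shrunk to 70% of its target length about its arc midpoint
and regrown during relaxation: the working growth increment is
$\kappa(L_0 - L)$ per iteration, split between the two tips inversely to
the resistant force each tip faces (a one-dimensional watershed), and
applied as springs toward tip positions extrapolated along the outward
tangents.  A contour that was initialized across a halo ridge between two
cells is thereby freed: the shrink removes the faulty crossing and the
tips regrow along the valley.  Tangential force components are averaged
along the contour each iteration (normal components untouched) and points
are redistributed to uniform arc spacing every 5 iterations; both smooth
the tangential dynamics without changing the normal relaxation.
Contours that end a block below 90% of target length are flagged
`stunted` rather than corrected.

## Jump detection and rescue (flies)

A fly that leaps leaves its contour on empty background.  The mean
potential under the contour is compared with an adaptive threshold (70% of
the trailing-median depth over 30 frames); a failed contour is rescued by
adding a constant-magnitude attraction toward the nearest blob not claimed
by another contour and relaxing normally.  The same rescue is applied when
two contours crowd one body while another blob is unclaimed — the
cohabitation left behind after a missed contact exchange.  Rescues are
checked on every newly solved frame so that corrections land within a
frame or two.

Head/tail orientation is not observable from the oval body image, so it is
decoded afterwards: a two-state hidden Markov model over per-frame
orientation, with logistic emissions on the signed parallel velocity
(flies mostly walk forward) and flip probability `1/(60 fps)` per frame
except at jump frames, where it is 0.5.  `viterbi_head_correction()`
returns the maximum-probability sign path; it changes only orientation
metadata, never positions.

## What the synthetic movies emulate

`simulate_fly_movie()` renders dark anti-aliased ellipses (2.4 mm x 0.9 mm
at 0.1 mm/px) walking in a circular arena at 30 fps: persistent-random-walk
headings, hard arena wall, body-segment soft-core exclusion (bodies touch
but never overlap), occasional teleporting jumps with orientation flips,
1 px camera blur, additive Gaussian noise, 8-bit quantization.  The
default arena density (~3 flies/cm^2) sits between the sparse and crowded
regimes of interest so that close contacts are frequent.

`simulate_cell_movie()` renders worm-like centerlines gliding tangentially
(the tail follows the head's laid path) with Poisson direction reversals
(default rate 1/84 per frame ~ one per 7 min at 12 frames/min), steric
steering away from neighbors, and a bright-field intensity profile: a dark
tube plus a halo ring peaking at 0.75 width from the centerline, then
noise and quantization.  Default speeds (~0.5 px/frame = 0.5 um/min at
0.08 um/px) and geometry follow the imaging regime the tracker targets.

What the generators deliberately do not model: photorealistic texture,
illumination drift, cell growth/division, objects entering the field, and
three-dimensional structure.  Passing the benchmarks therefore
demonstrates the tracking mechanics — identity preservation through
contact, length regulation, reversal detection — not robustness to every
imaging artifact of a real microscope.

## Numerical choices and degenerate inputs

* Sylvester systems are solved by eigendecomposition of the two small
  operators; a shared eigenvalue between $A+\gamma I$ and $-B$ raises an
  error advising a different `gamma` (with the defaults the spectra are
  well separated).
* Arc resampling interpolates along the current polyline; corner cutting
  is second-order in point spacing and is compensated by the length
  constraint forces.
* Coincident points of different objects repel along their
  previous-iteration displacement, or along a deterministic pseudorandom
  direction seeded by the object/point indices, so results are
  reproducible and independent of evaluation order.
* The summed repulsion on a point is softly capped near $\varepsilon$ by
  rescaling pairs (keeping action–reaction exact): in dense pileups the
  uncapped sum over many neighbors could otherwise catapult a contour out
  of its well.
* Per-pixel EM fitting uses a deterministic stride subsample (<= 20k
  pixels) and an mclust covariance prior, which keeps zero-noise synthetic
  frames from producing singular clusters.
* Problem sizes in the test-suite benchmarks: 5 objects x 600 frames at
  256^2 for the walkers; 20 objects x 200 frames at 192^2 for the
  gliders.  These match the density regimes of interest while keeping a
  full run of the suite to minutes.

## Known limitations

* The tracker assumes a fixed object count; newcomers are not detected
  (a correction file can introduce one for the cell pipeline).
* Identity preservation degrades with contact density.  On the synthetic
  arena benchmark a few persistent identity exchanges per several hundred
  frames remain at high densities; each is visible as a crowding rescue in
  the diagnostics.  The residual centroid error is likewise dominated by
  contact episodes, where repulsion holds contours ~1 width apart while
  the bodies touch.
* The EM enhancement expects a reasonably populated field of view.  In
  nearly empty frames the cell/halo clusters are swamped by background and
  classification can fail; the stratified fitting mitigates but does not
  remove this.
* Skeleton initialization merges touching cells and splits cells whose
  poles are classified as ridge; bridging and length-based splitting
  recover most but not all bodies (one cell in twenty may start
  untracked).
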