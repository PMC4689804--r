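---
title: "Structure-tensor orientation analysis and histology-based tractography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-tensor orientation analysis and histology-based tractography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histotract)
```

## The model

A stained histological section images axonal tracts as oriented texture:
bundles of fibers appear (after inversion of a bright-field stain) as
bright striations on a darker background. The local orientation of such a
texture is captured by the **structure tensor**, the Gaussian-windowed
second moment of the intensity gradient,

$$G(\mathbf{p}) = \big(w_\sigma \star \nabla I\,\nabla I^\top\big)(\mathbf{p}) =
\begin{pmatrix} g_{xx} & g_{xy}\\ g_{xy} & g_{yy}\end{pmatrix},$$

a symmetric positive-semidefinite 2×2 matrix per pixel. Intensity varies
*across* fibers and is nearly constant *along* them, so the **major**
eigenvector of $G$ points across fibers and the **minor** eigenvector
along them. All orientation output of this package is therefore the minor
eigenvector direction; this is the only reading under which streamlines
integrated from the tensor field run along bundles rather than across
them. From the eigenvalues $\lambda_1 \ge \lambda_2 \ge 0$ we derive

* coherency $C = (\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$, and
* the two-dimensional fractional anisotropy
  $\mathrm{FA}_{2d} = \sqrt{\dfrac{(\lambda_1-\bar\lambda)^2 +
  (\lambda_2-\bar\lambda)^2}{\lambda_1^2+\lambda_2^2}}$,
  $\bar\lambda = (\lambda_1+\lambda_2)/2$,

which lies in $[0, 1/\sqrt2]$. The quadratic denominator is the package
default; a variant normalized by $(\lambda_1+\lambda_2)$ is available via
`fa2d(..., denominator = "sum")`. The two are monotone transforms of one
another, so thresholded behavior differs only in the cut value; we default
to the quadratic form because it is the standard 2D analogue of the
diffusion-MRI anisotropy index and has the fixed rank-1 limit $1/\sqrt2$.

For tractography the 2D tensor is generalized to three dimensions by
zeroing all z-components ("pseudo-diffusion tensor"). Deterministic
trackers follow the *principal* eigenvector, so the default embedding
eigen-swaps the in-plane block, $T = (\lambda_1+\lambda_2)I - G$: same
eigenvectors, eigenvalues exchanged, principal axis along fibers. The
literal embedding of $G$ is retained (`track_convention = FALSE`) for
completeness; tracking it would run orthogonally to every bundle.

## Conventions

Images are R matrices (row 1 at the top). All angles live in the *display
frame*: $x$ to the right, $y$ pointing up, angles counterclockwise from
$+x$, orientations reduced to $[-90^\circ, 90^\circ)$. Internally the
only consequence is a sign flip of $g_{xy}$ relative to naive row/column
gradient products, applied once when the tensor is assembled; every tensor
in the package can then be read directly in display coordinates.
Orientations are *axial* quantities ($\theta$ and $\theta+180^\circ$ are
the same fiber): summaries of orientation maps should be computed on
wrapped residuals (`wrap_orientation(theta - truth)`), never on raw
angles, which are meaningless near the $\pm 90^\circ$ wrap.

## Preprocessing dialects

Two preprocessing chains are supported by `prep_image()`, reflecting the
two ways stained sections are prepared for orientation analysis:

* **hsb** — luminance grayscale + inversion. Feeds the HSB orientation
  render (hue = orientation on the $[-90, 90)$ wheel mapped to bytes,
  saturation = coherency, brightness = staining intensity).
* **tract** — red-channel extraction (the red channel carries most of the
  contrast of a brown DAB stain), inversion, contrast-limited adaptive
  histogram equalization, and linear normalization to the 8-bit range.
  The nominal "0–256" output range is represented as $[0, 255]$, the
  largest value an 8-bit sample can hold.

Whether inversion should precede or follow equalization is not fixed by
convention; both orders are available (`invert_first`), defaulting to
inversion first so that CLAHE operates on the bright-fiber representation.
CLAHE parameters default to a normalized clip limit of 0.01 on an 8×8
tile grid — standard practice; both are configurable, and a tile grid
smaller than 2×2 falls back to global histogram equalization.

## Numerical choices

* **Gradients.** Default is the derivative of the cubic B-spline
  interpolant (recursive prefilter, then central differences of the
  coefficients), which is exact for locally cubic profiles; plain central
  differences are available and are used by the brute-force test oracles.
  The image mean is subtracted before filtering — derivatives are
  offset-invariant, and this keeps the recursive prefilter exact on flat
  images.
* **Windowing.** "Gaussian window of 5 pix" is interpreted as
  $\sigma = 5$ px (the convention of the standard orientation-analysis
  plugins), truncated at $3\sigma$, with whole-sample mirror boundaries.
* **Eigen-solution.** Closed form for symmetric 2×2 matrices. Pixels with
  eigenvalue gap below $10^{-12}\times\mathrm{trace}$ are treated as
  isotropic: orientation 0 by convention, coherency and FA 0. The
  off-diagonal term is canonicalized with `+ 0` before `atan2` so that a
  negative zero cannot flip an eigenvector by 180°.
* **Percentile.** The seed cut uses the nearest-rank percentile (smallest
  sample value with at least $p\%$ of the sample at or below it), so the
  seed count on an $n$-pixel distinct-valued field is within one pixel of
  $n(100-p)/100$. "Top 95th percentile … high-pass" is read as *keep the
  top 5 %*: seeding the top 95 % instead would start streamlines in
  nearly every brain voxel, which is not a seed mask in any useful sense.
  The percentile is configurable.
* **Brain mask.** The foreground separation is Otsu thresholding,
  morphological closing (disc, radius 5 px), hole filling, and retention
  of the largest connected component; each step is toggleable. This is
  our recipe — the original in-house procedure is unspecified — but each
  ingredient is the field-standard choice for bright tissue on a dark
  slide background.
* **Tensor down-sampling.** Tensors average linearly, so components are
  block-averaged (factor 4 by default) and FA is *recomputed from the
  averaged tensors*. Averaging FA maps directly is upward-biased wherever
  orientations mix within a block. FA for seeding is computed at the
  coarse resolution, on the same grid the tracker sees.

## Tracking

Tracking runs on the coarse pseudo-tensor grid in continuous coordinates
(voxel centers at integers). Tensor lookup uses **probabilistic
nearest-neighbor interpolation**: one of the up-to-four surrounding voxels
is selected with probability equal to its bilinear weight, and its tensor
is used as-is. This keeps every tensor a measured one (no blending of
incompatible orientations) while making the ten repetitions per seed
explore the local orientation distribution; with all randomness drawn from
a single seeded stream, runs are bit-reproducible.

Each launch advances by classical fourth-order Runge–Kutta steps of
length 2 px through the direction field given by the principal eigenvector
of the interpolated tensor. Stage directions are sign-aligned to the
incoming direction (tensor fields are antipodally symmetric); the averaged
direction is normalized so that consecutive points are *exactly* one step
apart — the integrator takes chord steps of fixed length, which is what
the constant-spacing contract of a streamline requires. Launches are
bidirectional by default (two antiparallel half-tracks concatenated
through the seed).

Termination rules: leaving the grid or the brain mask (`mask_exit`,
checked at the nearest voxel of each new point), FA of the interpolated
voxel at or below 0.1 (`low_fa` — the FA check uses the same
probabilistically selected substrate as the direction field, not a
bilinear estimate), a turn of 75° or more (`high_curvature`), 2000 steps
(`max_steps`), or an isotropic tensor (`zero_tensor`). Streamlines
shorter than 5 points are discarded. The step cap and minimum length are
our defaults (nothing is printed for them upstream); both are
configurable.

**Curvature is enforced per stage as well as per step.** The natural
reading of a "curve threshold" is the angle between consecutive step
directions, and that check is applied. It is, however, not sufficient on
its own: with probabilistic nearest-neighbor interpolation, the four RK
stages straddling a sharp orientation interface mix the two sides into an
intermediate step direction, and a discontinuity well above the threshold
(e.g. 80°) can then be crossed in two sub-threshold turns. Terminating
whenever any *stage* direction deviates from the incoming direction by at
least the threshold makes the printed 75° limit actually govern behavior:
interfaces at 75° and above stop tracking deterministically, while a 40°
interface is crossed and followed. For smoothly curving bundles the
per-stage and per-step criteria coincide (stage deviations are
$O(\text{step}/R)$).

"10 iterations" per seed is read as ten stochastic tracking repetitions
(they differ only through the interpolation draws), not ten integration
steps — ten steps would cap every streamline at 20 px, incompatible with
bundle-scale tractography. Each seed gets an RNG substream derived from
(run seed, seed index), so results do not depend on execution order.

## The phantom generator

The phantoms emulate what the pipeline actually consumes — oriented
texture — rather than the full appearance of stained tissue:

* `make_stripe_phantom()` — band-limited (sinusoidal) stripes at an exact
  fiber angle. Sinusoids rather than binary stripes keep gradient
  estimators well-behaved down to the minimum period of 4 px.
* `make_arc_phantom()` — a tangential annulus around a dark "ventricle":
  the C-shaped bundle geometry, for curved-bundle following.
* `make_layered_wall_phantom()` — the four-layer lamination of the fetal
  telencephalic wall: a dim unorganized ventricular zone, a bright
  tangential intermediate zone with a configurable radial crossing
  fraction, a low-contrast crossing subplate, and a radial cortical
  plate. Its testable content is the *ordering* of layer coherencies
  (CP > SP, IZ > SP, IZ > VZ) and VZ < IZ brightness, not absolute
  values.
* `make_perpendicular_phantom()` — a punctate dot field (Poisson-disk
  placed bright blobs) beside in-plane stripes: the appearance of axons
  cut across the section plane, as in the core of a Probst bundle. The
  dots have high intensity but near-zero in-plane coherency, so seeds and
  streamlines concentrate in the stripe region and tracking collapses
  over the dots.
* `make_crossing_phantom()` — two superimposed equal-period stripe
  populations with a mixing weight; equal orthogonal mixes average to
  near-isotropic tensors (the crossing-fiber ambiguity a single tensor
  cannot resolve), while a dominant population is recovered within a few
  degrees.

Phantoms are bit-reproducible under their seeds and restore the caller's
RNG state. What passing phantom tests does *not* show: robustness to
stain inhomogeneity, tissue tears and folds, out-of-plane partial volume
beyond the punctate model, or registration error between section and MRI
— real sections add all of these.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `st.sigma_window` | 5 px | Gaussian window scale of the structure tensor |
| `st.gradient_kernel` | cubic_spline | gradient estimator |
| `tensor.downsample_factor` | 4 | image-to-tracking grid reduction |
| `mask.percentile` | 95 | FA percentile for the seed cut (keep top 5 %) |
| `mask.close_radius` | 5 px | disc radius of the mask closing |
| `track.step_px` | 2 | RK4 step length (coarse pixels) |
| `track.curve_threshold_deg` | 75° | max turning angle per step/stage |
| `track.fa_min` | 0.1 | FA stopping floor |
| `track.iterations_per_seed` | 10 | stochastic repetitions per seed |
| `track.max_steps` | 2000 | step cap per launch |
| `track.min_points` | 5 | minimum points to keep a streamline |

## Problem sizes and verification

The test suite exercises the full pipeline on phantoms of 96–288 px
(coarse tracking grids of 24–72 voxels): large enough for interiors
unaffected by boundary handling and for thousands of streamlines, small
enough that the whole suite runs in well under a minute. Structure-tensor
components are verified against an explicit-loop oracle (1e-6 relative),
eigenpairs against the generic symmetric solver (1e-9), the compiled
tracking stepper bit-for-bit against a pure-R mirror consuming the same
RNG stream, and the integrator against the closed-form chord-advance
solution on an analytic circle field. `scripts/acceptance.R` re-measures
each headline constant operationally — e.g. the curve threshold by
locating, between 66° and 84°, the smallest interface angle that
terminates tracking (75°), and the window scale from the second moment of
the impulse response (4.95 px after correcting for the gradient-stencil
spread).

## Limitations

Single sections only: no serial-section stacking into true 3D volumes, no
section-to-MRI registration, no crossing-fiber models (the tensor reports
the average orientation in crossings), and no native reading of pyramidal
whole-slide formats — sections are expected as ordinary TIFF/PNG/JPEG
tiles, down-sampled from the scanner's native resolution as needed.
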