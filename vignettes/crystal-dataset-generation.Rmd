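---
title: "Synthetic oriented-box datasets of protein crystals: model, renderer, augmentation and evaluation"
author: "pcsgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic oriented-box datasets of protein crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcsgen)
```

## The problem

Monitoring protein crystallization (for example stirred-batch
crystallization of an alcohol dehydrogenase, imaged by bright-field
microscopy) requires detecting large numbers of small, transparent,
elongated crystals in photomicrographs. Training an oriented-object
detector for this task needs far more labeled data than manual annotation
can produce, and crystals are visually dominated by thin intensity
gradients at their edges rather than by texture or color. `pcsgen`
generates fully annotated synthetic grayscale datasets for this detector
family, plus the evaluation metrics (rotated-box average precision with a
size-class breakdown) and the crystal-size-distribution (CSD) analytics
used to interpret detector output on real images.

## The statistical shape model

Each crystal in an image is described by its minimum-area enclosing
rotated rectangle $(r, a, \theta)$: aspect ratio $r = w/h \ge 1$, area
$a = wh$ in px², and angle $\theta$ of the long side. Targets are drawn
as

$$r \sim U[1,\, r_{\max}], \qquad \theta \sim U[-\pi/2,\, \pi/2),$$

with $r_{\max} = 11.4$, a constant taken from prior crystallization
experiments (it is a fixed prior here, never inferred from data). A
uniform area law would visually under-represent small crystals, so the
area instead follows the reciprocal density

$$p(a) = \bigl(a \ln[a_{\max}/a_{\min}]\bigr)^{-1},
  \qquad a \in [a_{\min}, a_{\max}],$$

which makes $a\,p(a)\,da$ constant: every area interval of equal width
contributes the same expected total crystal area, and small crystals are
sampled much more often. Note that this *equal-width* (linear) property
is what the reciprocal law actually delivers; equal totals per
*logarithmic* class would require $p \propto a^{-2}$.
`verify_unbiasedness()` therefore bins total area into equal-width area
classes.

**Defaults and units.** $a_{\min} = 16$ px² (a 4×4 box, near the
practical detection limit) and $a_{\max} = (0.66\,\cdot\,\text{image
side})^2$ are repository defaults — the source experiments did not print
them — and both are configurable in `shape_config()`. Angles use a
half-open support $[-\pi/2, \pi/2)$ so every rectangle has a unique
parameterization.

## Realizing targets with 3D crystals

A target is realized by projecting a convex 3D crystal mesh through

$$M = P\, C\, T\, R_z(\gamma)\, R_y(\beta)\, R_x(\alpha)\,
  S(s_x, s_y, s_z),$$

extracting the convex hull of the projected vertices and its minimum-area
rectangle (rotating calipers: the optimum is aligned with a hull edge),
and accepting the pose once

$$|\sqrt{a'} - \sqrt{a}| < \Delta_a, \quad
  |r' - r| < \Delta_r, \quad
  |\theta' - \theta| < \Delta_\theta,$$

with defaults $\Delta_r = 0.2$, $\Delta_a = 2$ px and
$\Delta_\theta = 2^\circ$ — deviations found sufficient to keep the
realized dataset distributions close to the model. Because meshes keep
their dominant axis along $x$ with nearly equal $y$/$z$ extents, and the
camera's 5° field of view is near-orthographic, the out-of-plane
rotations $\alpha \sim U[0, 2\pi)$ and $\beta \sim U[-\pi/3, \pi/3]$ can
be drawn once, leaving a three-parameter problem in
$(\gamma, s_x, s_y)$ with the closed-form initial guess
$\gamma_0 = \theta$, $s_{x,0} = c\sqrt{ar}$, $s_{y,0} = c\sqrt{a/r}$,
where $c$ is calibrated by projecting the mesh at unit scale after the
initial translation.

Numerical choices worth recording:

* **Solver.** The main solver is a damped fixed-point iteration:
  multiplicative updates of $s_x, s_y$ by the ratios of target to
  achieved sides, additive update of $\gamma$ by the wrapped angle error.
  It typically converges in 3–4 projections; a Nelder–Mead polish of the
  maximum normalized deviation (≤ 200 evaluations) and up to 3 restarts
  with re-drawn $\alpha, \beta$ back it up. $s_z$ is tied to $s_y$
  throughout.
* **Angle for near-squares.** The angle inequality is enforced for *all*
  targets, including near-squares. The minimum-area rectangle of a
  near-square hull still has a well-defined (if sensitive) angle, the
  iteration controls it through $\gamma$, and measured convergence stays
  at 100% over thousands of targets. Skipping the angle check for
  $|r' - 1| < \Delta_r$ (a plausible alternative) would let targets with
  $r$ slightly above 1.2 be realized with uncontrolled angles, which
  both violates the acceptance contract above and distorts the realized
  angle distribution.
* **Angle metric.** Angle differences live on the half-circle (period
  $\pi$, wrap-around at $\pm\pi/2$).
* **Coordinates.** Image coordinates are 0-based, origin top-left, x
  right, y down; $\theta$ is the angle of the long side from +x. Pixel
  $(i, j)$ of the image matrix has center $(j - 0.5,\, i - 0.5)$.

### Procedural meshes

The curated collection of real crystal models that inspired this design
is not redistributable, so `generate_crystal_mesh()` produces convex
prisms and (optionally truncated) bipyramids: a mildly anisotropic
regular polygon cross-section (y/z extent ratio within [0.72, 1.39]),
extruded along x with elongation drawn from [1, 3], normalized to unit
x-extent. Meshes imported from OBJ/ASCII-STL files are validated against
the same invariants (convexity, dominant x axis, y/z ratio in [0.5, 2]).
Extreme elongation is produced by the anisotropic scales of the fit, not
baked into the mesh.

### Scene assembly

`place_crystals()` draws a per-image crystal count (default
$U\{5, 20\}$: with the default area bounds the mean box area is several
thousand px², so substantially denser packing is geometrically infeasible
on a 384 px image), places crystals at uniformly drawn positions, and
rejects any placement whose silhouette touches the border, whose realized
ratio exceeds $r_{\max}$, or whose rotated-box IoU with an accepted
crystal exceeds the overlap cap (default 0.25; the source experiments do
not state a value). Rejected targets are resampled; *all* drawn targets
are recorded (`targets_drawn`) because they — not the surviving
placements — are the unbiased sample from the model. Each crystal gets a
glass material with refractive index $n \sim U[1.1, 1.8]$; a point light
is drawn uniformly on an upper hemisphere (the original light placement
is described only as randomized).

## The stylized renderer

The reference pipeline rendered photorealistic base images with a ray
tracer. `pcsgen` deliberately substitutes a deterministic stylized
renderer with an explicit contract, because the detection-relevant signal
for transparent crystals is the intensity gradient at their visible
edges, not global photorealism:

1. the background is a smooth brightness field tilted toward the light
   position;
2. crystal interiors transmit the background with a weak dimming factor;
3. the projected silhouette and visible crease edges are drawn as
   Gaussian-profile strokes (σ = 1 px default, truncated at 3σ) whose
   contrast grows linearly with $n - 1$, plus a faint bright rim;
4. masks and boxes always come from the exact projected geometry, never
   from pixels.

A scene is fully serializable (mesh + transform + material + camera +
light), so users who need physically correct refraction can re-render
scenes externally without touching the annotations. Output is 8-bit
grayscale PNG; images are processed in float and quantized only at write
time.

## The augmentation pipeline

Real photomicrographs carry spatially correlated noise: cloudy
precipitate and aggregate, thin-film interference bands, skin layers,
scratches, round reactor rims. The pipeline models these with two noise
generators — plane-wave interference textures

$$N_I(x, n, k) = \tfrac12\!\left[\cos(2\pi k^{-1} x\!\cdot\!n + \phi)
  + 1\right]$$

and Perlin (lattice gradient) noise $N_P(k)$ — combined into layers

$$L = \frac1N \sum_{i=1}^{N} H\!\left[N(k_i)\right],
  \qquad N \sim U\{1, 10\},$$

where $H$ is rank-based histogram equalization (so layers from different
generators and scales carry comparable histograms) and the spatial scales
$k_i$ are drawn log-uniformly between 4 px and the image diagonal ("a few
pixels to the image diagonal"; the lower bound 4 px is a repository
choice). A layer is blended into the base image $b$ by the weighted
average

$$A(b, l, w_l) = \frac{w_b\, b + w_l\, l}{w_b + w_l}, \qquad
  w_l = c\, \sigma_b\, l_\alpha\, 2^{-2l + 1},$$

with $w_b = 1$ and $c = 5$ by default: $\sigma_b$ (the standard deviation
of the base image) protects weak signals, the transparency layer
$l_\alpha$ — an independent noise layer of the same kind — randomizes
where the noise bites, and the factor $2^{-2l+1}$ reinforces dark noise
(×2 at $l = 0$) while suppressing bright noise (×1/2 at $l = 1$). A
constant image ($\sigma_b = 0$) passes through unchanged.

Around the noise layers sit object-level brightening/darkening/outlining
(using the exact masks), random cubic splines (scratches), a
rounded-corner overlay (round reactor volumes), row/column displacement
(edge distortions), brightness/contrast, Gaussian blur, additive Gaussian
noise, and exact geometric transforms (flips, 90° rotations) that map
polygons analytically and re-derive each box as the minimum-area
rectangle of its polygon. The published step ordering table for the
reference pipeline is not available; the default order here — geometric →
object-level → interference → Perlin → splines → rounded corners →
displacement → brightness/contrast → blur → noise, each with probability
0.5 — is an explicit repository convention (spatially structured effects
first, pixel-level camera effects last) and is configurable.

## Evaluation and CSD analytics

`evaluate_detections()` implements rotated-box average precision: greedy
per-image matching by rotated IoU (exact convex clipping), pooled
101-point interpolated precision–recall, averaged by default over IoU
thresholds 0.50:0.05:0.95 (single-threshold convention available via
`iou_thresholds = 0.5`; the convention used for the reference numbers is
not stated, so both are exposed). Size classes follow box area with
thresholds $8^2$ and $24^2$ px²; the strict inequalities leave the
boundaries open, which this package resolves upward (64 px² is medium,
576 px² is large). For a size class, ground truth and detections are both
filtered by their own area; out-of-class boxes are ignored.

The CSD side converts detector boxes to physical sizes (long side =
width, short side = height, default calibration 0.84 µm/px), summarizes
with linear-interpolation quantiles (the convention is not stated in the
source; type-7 is documented here), builds ECDFs, and compares
distributions with the two-sided two-sample Kolmogorov–Smirnov test. The
KS p-value is exact (lattice-path counting over all orderings) whenever
$n_1 n_2 \le 10^4$ and there are no cross-sample ties, and otherwise uses
the asymptotic Kolmogorov tail with the Stephens small-sample correction.
At small equal sample sizes the exact null is so discrete that *any*
continuous approximation errs by up to ~0.3, which is why the exact route
is the default there; at the sizes where the asymptotic is actually used
its error at attainable values of $D$ is below 0.05. Photomicrograph
preprocessing mirrors detector-input conditioning: luminance conversion
and quantile mapping of the intensity distribution onto a stored
reference.

## What the generator does and does not establish

The synthetic data emulate: unbiased box-shape statistics, transparent
edge-dominated crystal appearance, correlated noise fields, and the
border/overlap effects of a finite image. They do not emulate:
photorealistic refraction and caustics, crystal clusters or twinning,
non-convex habits, or camera-specific noise spectra. A green test on
synthetic data therefore establishes the mechanics of the generator and
metrics, not detector transfer to any particular microscope. One known,
expected artifact: in *rendered* datasets the largest area classes carry
slightly less total area than the model predicts, because large crystals
are harder to place under the border/overlap constraints;
`verify_unbiasedness()` flags this on achieved annotations without
failing, while raw target draws stay unbiased.

## Worked example

```{r example, eval = FALSE}
library(pcsgen)

out <- tempfile("pcs")
cfg <- dataset_config(n_images = 20, seed = 1)
man <- generate_dataset(cfg, out)
man$n_instances

gt <- annotations_table(read_annotations(file.path(out, "annotations.json")))
rep <- verify_unbiasedness(
  data.frame(r = gt$w / gt$h, a = gt$w * gt$h, theta = gt$theta))
print(rep)

# self-evaluation: perfect detections give AP 100
dets <- cbind(gt, score = stats::runif(nrow(gt), 0.5, 1))
evaluate_detections(dets, gt, iou_thresholds = 0.5)
```

The acceptance script `scripts/acceptance.R` re-runs the placement
tolerance experiment (1,000 targets, fresh procedural meshes) from a
given seed and reports the maximum realized deviations
$|r'-r|$, $|\sqrt{a'}-\sqrt{a}|$ and $|\theta'-\theta|$ (the last in
degrees, over targets with $r \ge 1.2$ where the angle is
well-conditioned).

## Known limitations

* Pure-R rendering: ~1 s per 384×384 image; generating hundreds of
  thousands of images is possible but slow (the defaults generate 1,000).
* The placement optimizer assumes convex meshes with the stated axis
  conventions; wildly anisotropic cross-sections would degrade the
  initial guess (imported meshes are validated).
* Mesh deformation before rendering (hinted at in the source material)
  has no published procedure and is not implemented.
* DOTA export writes box corners at fixed 2-decimal precision; the
  native JSON dialect is lossless and remains the primary format.
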