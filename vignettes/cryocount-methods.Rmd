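---
title: "Counting fluorescent cells in cryo-imaging volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting fluorescent cells in cryo-imaging volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryocount)
```

## The problem

Cryo-imaging alternately sections a frozen specimen and photographs the
block face, producing an aligned 3D volume of brightfield and fluorescence
images. To cover a whole mouse at tractable data volumes, the in-plane
pixel is 8.8–15.6 µm while labeled cells are 10–15 µm across: a cell is
roughly **one pixel** wide. Boundary-based segmentation is impossible at
that scale, so touching cells merge into connected fluorescent *clusters*
and the scientific quantity of interest — how many cells were delivered,
and where — requires estimating the number of cells in each cluster from
its intensity pattern alone.

`cryocount` implements the full analysis chain for red-labeled (e.g.
quantum dot) cells over green-dominant autofluorescence:

1. **Preprocessing** — next-image subtraction of subsurface fluorescence,
   background removal by grayscale morphological reconstruction, and a
   red/green ratio threshold producing a grayscale working volume.
2. **Detection** — hysteresis thresholding, 3D connected-component
   labeling, feature extraction, and knowledge-based false-positive
   rejection.
3. **Counting** — calibration of a single-cell Gaussian template from
   singleton clusters, then per-cluster model selection over the number
   of cells by constrained least squares.
4. **Phantom simulation and evaluation** — synthetic volumes with known
   ground truth, and the agreement statistics used to validate counts.

## The cell model

A cell is modeled as a pixel-integrated isotropic 2D Gaussian: pixel
$(r, c)$ of a cell centred at $(x_c, y_c)$ with total intensity $I_t$ and
width $\sigma$ receives

$$I(r,c) = I_t\,\bigl[\Phi(\tfrac{c+\frac12-x_c}{\sigma})-\Phi(\tfrac{c-\frac12-x_c}{\sigma})\bigr]
               \bigl[\Phi(\tfrac{r+\frac12-y_c}{\sigma})-\Phi(\tfrac{r-\frac12-y_c}{\sigma})\bigr],$$

so the sum over the full support equals $I_t$ for *any* sub-pixel
placement. This is the key property exploited throughout: pixelation
changes a cell's appearance dramatically but not its integrated
intensity. The Gaussian stands in for the physical cell, the imaging
transfer function and tissue scattering jointly; no attempt is made to
separate them.

Because sections (40 µm) are much thicker than cells, a cell usually
lives in one section, but the microtome can cut through a cell. Each
model cell therefore carries a continuous axial coordinate $z_c$: its
home slice is $\lfloor z_c \rfloor$ and the fractional part apportions
$I_t$ between the home slice and the next. We deliberately model the
axial position as continuous rather than fixing a discrete home slice at
initialization — with a frozen home slice the optimizer cannot move mass
across sections, and a sectioned cell seeded in the wrong slice is
unfittable.

## Preprocessing

**Next-image subtraction.** The block face shows fluorescence from
deeper, not-yet-cut sections at roughly 15–20% intensity. Since the next
image in the stack shows those structures at the surface, slice $k$ is
corrected as $\max(0,\, I_k - a\,\mathrm{blur}(I_{k+1}))$. The blur is an
isotropic Gaussian (default 2 px) and the attenuation $a$ a configured
constant (default 0.15); parameter estimation from data is out of scope
and at these resolutions fine-tuning matters little. The clip at zero
also removes the second-order term the subtraction would otherwise leave.

**Background removal.** Autofluorescent background is estimated per slice
and channel by morphological reconstruction: the marker is the image
eroded with a flat disk (default radius 10 px, which must exceed the
largest cluster footprint) and is geodesically dilated under the image
until stable. All local maxima narrower than the disk vanish, leaving a
smooth background that is subtracted and clipped at zero. Reconstruction
is a *lower* envelope: positive noise spikes above a locally low floor
survive at up to several noise SDs, and on a smoothly varying background
it overshoots slightly under clusters (see Limitations).

**Ratio threshold.** Autofluorescence is green-dominant (red/green
$\approx 0.4$) while labeled cells are strongly red (red/green
$\approx 8$). The working volume keeps $I_R$ where
$I_R > T_{R/G}\, I_G$ and is zero elsewhere. The multiplicative form is
algebraically equivalent to thresholding the ratio for positive green and
stays defined at zero green (a zero-green voxel passes when red is
positive), and it preserves monotonicity in the threshold.

The stage order — next-image, then reconstruction, then ratio — follows
the narrative order of the acquisition physics; the alternatives are not
distinguishable on the phantoms and the configuration keeps each stage
independently callable.

## Detection

Hysteresis thresholding retains voxels above a low threshold $T_L$ only
when their $T_L$-connected component contains a voxel above the high
threshold $T_H$. Both comparisons are strict, and connectivity is
26-neighbour in 3D so that a sectioned cell's two halves label as one
cluster. The thresholds come from data:

* $T_H = 0.6 \min_n C_{\max}(n)$ over the per-cluster maxima of an image
  of well-separated cells in culture (no cluster at least as bright as
  the dimmest culture cell can lose all its high-threshold voxels);
  culture components under 5 voxels are ignored as noise speckle.
* $T_L = \mu_{img} + c\,\sigma_{img}$ over **all** voxels of the working
  volume, zeros included, with $c = 1.4$ by default.

Each labeled cluster is measured (volume $C_V$, integrated intensity
$\int C_i$, bounding box, intensity/volume ratio, center of mass, slice
span) and two prior-knowledge rules remove false positives: clusters with
$C_V > T_V$ (large autofluorescent organs), and clusters whose
$\int C_i / C_V$ falls outside a configured band (structures too dim or
too bright to be labeled cells). Every rejection records the rule that
fired, and `threshold_report()` lists, per object, the threshold values
that would include or reject it — the informational content of an
interactive tuning session in a file.

## Counting cells per cluster

Calibration selects *singleton* clusters: single-slice clusters whose
volume and intensity lie near the dominant histogram peak (the two-cell
peak sits at twice the single-cell intensity). The peak is located with a
kernel density whose bandwidth is 0.1× the median intensity — wide
bandwidths can merge the 1- and 2-cell modes when clusters are few. Each
singleton is fit with a free-$(x_c, y_c, \sigma, I_t)$ pixel-integrated
Gaussian (Nelder-Mead by default, Levenberg-Marquardt optional) and the
converged parameters are averaged into the cell template.

For each cluster the initial count is
$N_i = \mathrm{round}(\int C_i / I_t)$ (half-up, floored at 1) and every
integer in $N_i \pm \max(2,\, \mathrm{round}(0.30\,N_i))$ (clipped at 1)
is fit. A fit of $n$ cells minimizes

$$F_{obj} = \sum_m \bigl(I_{Gray} - \sum_n I_{gauss}\bigr)^2$$

over the cluster's bounding box padded by 2 px in $x$ and $y$ (recovering
tail pixels the low threshold missed), with $\sigma$ and $I_t$ fixed at
the calibrated values and $(x_c, y_c, z_c)$ free per cell. Three smooth
quadratic penalties (weight $I_t^2$) keep the problem well-posed for a
derivative-free optimizer:

* $z_c$ confined to $[1, n_{slices}]$;
* centers confined to the patch domain — without this, a surplus cell
  can park its fixed intensity outside the objective's support at zero
  cost and model selection collapses;
* centers of near-coplanar cells (axial distance < 1 section) at least
  $D_{\min}$ apart in-plane, fading linearly with axial separation.

$D_{\min}$ is prior knowledge of the specimen's packing limit —
approximately one cell diameter in tissue. In phantom studies the
harness defaults it to the generator's declared minimum spacing, which
is the same prior stated exactly; a looser value lets a surplus
fixed-intensity cell interleave into clusters of brighter-than-average
cells and biases counts upward.

**Optimization.** Cells are seeded by greedy matching pursuit: each cell
at the maximum of the residual after subtracting the already-seeded
cells' renderings (a merged pair has only one intensity maximum, but the
residual exposes the second). Nelder-Mead runs with relative tolerance
$10^{-6}$ and a 10 000-iteration cap, restarts once from its endpoint
with a fresh simplex, and finishes with a greedy *reseat* pass: each cell
in turn is tentatively moved to the residual maximum and the move kept
only if the objective improves (one objective evaluation per cell when
already converged). With these safeguards, repeated fits from uniformly
random initial placements agree to well under 0.1 px, so results do not
depend on the seed of the initialization. All randomness is seeded
explicitly and derived deterministically from a base seed.

The count with minimal $F_{obj}$ wins; exact ties go to the smaller $n$
(parsimony) and the result is flagged *ambiguous* when the two best
objectives differ by less than 20% of the smaller — the relative form is
assumed, and a cluster whose best objective is exactly zero is ambiguous
only against another exact zero. If no candidate converges the cluster is
reported uncounted.

## The phantom generator

`generate_phantom()` emulates the statistical structure of bead and
labeled-cell validation phantoms:

| parameter | default | rationale |
|---|---|---|
| pixel size / section | 15.6 µm / 40 µm | whole-mouse operating resolution |
| $\sigma$ | 1 px | a 10–15 µm cell blurred to about one pixel |
| intensity CV | 0.15 (cells), 0.05 (microspheres) | measured source variability of each phantom type |
| cluster sizes | pmf (0.45, 0.22, 0.14, 0.11, 0.08) on 1–5 | dispersed sources: mostly singletons, few large clusters |
| min. center spacing | 1.5 px | touching-but-distinct sources at this resolution |
| background | level 40, ±20% smooth field (corr. 12 px) | green-dominant autofluorescence, R/G = 0.4; smooth so reconstruction is actually exercised |
| cell R/G | 8.0 | red-dominant quantum-dot labeling; $I_t$ is defined as the red-channel integral and green receives $I_t/8$ |
| bleed-through | 15% of the next section, blurred 2 px | subsurface fluorescence at 40 µm sections |
| sectioning | 30% of cells split 15–50% into the next slice | exercises the $z_c$ mechanism; cells never span 3+ sections |
| noise | additive Gaussian, SD 3 DN | ≈2% of a single cell's peak pixel; no shot-noise model is claimed |

Clusters are placed by rejection sampling with bounding boxes kept apart
(in-plane, within ±2 slices) and fail explicitly when the volume cannot
hold them. Intensities are Gaussian with the configured CV, truncated at
20% of the mean. The culture variant is a single slice of singletons with
no bleed or sectioning, used to calibrate $T_H$.

What the generator does **not** emulate: tiling/registration artifacts,
tissue-specific autofluorescence spectra (gut, bone), brightfield
anatomy, shot noise, and focus variation. Passing phantom tests therefore
demonstrates the algorithmic chain under its stated model, not
performance on any particular tissue.

## Numerical and design notes

* Half-up rounding is used wherever the procedure rounds (base R rounds
  half-even); the 30% candidate half-width is rounded before the `max`.
* The low-threshold statistic includes zeros and is computed per stack;
  per-slice computation is a configuration choice away but not default.
* Degenerate inputs: single-slice stacks pass through next-image
  subtraction with a warning; an empty working volume yields an empty
  cluster table and a zero-row count table; a culture image with no
  clusters, or a volume with no singletons, raises a named error rather
  than calibrating nonsense.
* Whether the 30% window applies before or after rounding $N_i$ is not
  observable at these cluster sizes; it is applied after.
* Fleiss' kappa is computed with raters = {algorithm, reference} and its
  null-hypothesis asymptotic standard error; Cohen's kappa is reported
  alongside since the two-rater design is its natural home. The two
  differ only in marginal pooling.
* TIFF interchange stores 32-bit floats scaled into [0, 1] with the scale
  recorded in a YAML sidecar (the format's storage contract); round-trips
  are exact to float precision.

## Problem sizes

The test suite and the reproduction script run phantom studies of
200–230 clusters in 8 × 320 × 320 volumes (roughly 450–550 cells), a
200-singleton calibration study, 120-placement pixelation studies, and
oracle cross-checks on ~100 random 16×16×4 volumes — sizes chosen so the
whole suite completes in a few minutes on one core while keeping ≥ 15
clusters in the rarest size class.

## Limitations

* **Sensitivity floor:** $T_H$ from unsectioned culture cells means a
  cell that is both dim (≈3 SD below mean) and heavily sectioned can fall
  below the high threshold and be missed; this is the method's real
  behavior, not an implementation artifact.
* **Background bias:** on tissue-scale background (level 40, ±20%),
  morphological reconstruction overshoots under clusters on curved
  background, biasing per-cluster intensity low by up to ~8% in the worst
  case. Counting absorbs this (model selection, not raw intensity,
  decides), but the 5%-intensity-preservation property should only be
  expected on weak-background (OCT-like) phantoms.
* **Speckle attachment:** with $T_L$ only ~1.3 noise SDs above zero on
  the ratio-thresholded volume, isolated noise voxels occasionally attach
  to a cluster across slices under 26-connectivity, inflating slice span;
  singleton calibration excludes such clusters by the single-slice rule
  and remains unbiased.
* **Fixed-intensity assumption:** clusters whose cells are collectively
  much brighter or dimmer than average can be counted ±1; this is
  inherent to the fixed-$I_t$ model and grows with intensity CV.
* The interactive threshold-selection workflow is replaced by
  configuration plus `threshold_report()`; no GUI is provided.
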