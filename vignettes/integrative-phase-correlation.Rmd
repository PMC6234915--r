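---
title: "Integrative phase correlation for multi-modal plant image alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative phase correlation for multi-modal plant image alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasefuse)
```

## The problem

Phenotyping chambers image each plant in several modalities within seconds:
a high-resolution visible-light (VIS) frame and a lower-resolution
fluorescence (FLU) frame, from cameras that differ in position, orientation
and optics. FLU intensity tracks chlorophyll, so the plant stands out
against a dark, chlorophyll-free background and thresholds cleanly; VIS
backgrounds contain carriers, mats and illumination gradients that defeat
global thresholding. Registering the FLU frame onto the VIS frame transfers
the easy FLU mask to the hard VIS image (segmentation-via-registration).

Two obstacles make this registration unusual. First, the images are
*structurally non-identical*: background structures exist in one modality
only, and intensity relations differ. Second, plants are not rigid — single
leaves keep swaying after the carrier stops, so the FLU→VIS map is not one
affine transform but a family of per-leaf transforms. `phasefuse`
implements a phase-correlation chain plus a scale-space integration scheme
that addresses both.

## Phase correlation and the peak height H

For single-plane images $A, B$ with DFTs $\alpha, \beta$, the normalized
cross-power spectrum is $\mathrm{CPS} = \alpha\beta^*/|\alpha\beta^*|$ and
the phase-correlation surface is its inverse transform. If
$B(x,y) = A(x-\Delta x, y-\Delta y)$ (circularly), the surface is a
Kronecker delta at $(\Delta x, \Delta y)$ — the test suite asserts this
exactly, to $10^{-6}$, for all 1024 integer shifts of a 32×32 fixture. Two
numerical choices matter:

* an $\varepsilon$-guard ($|\alpha\beta^*| < 10^{-12}$ maps to 0) avoids
  division blow-ups at empty frequencies;
* the inverse transform is scaled so that identical images give a peak
  height of exactly 1. The peak height $H$ of the best match is the
  registration's reliability score.

Ties on the maximum resolve to the smallest (row, column) in lexicographic
order, so repeated runs are bit-identical. A 3×3 centre-of-mass sub-pixel
refinement exists but is off by default; all reported results use integer
peaks.

The default gate accepts a registration only when $H > 0.03$ (strict) *and*
the transform is admissible: scale in [0.5, 2], |rotation| ≤ 30°,
centre displacement ≤ 0.5 × the larger image side. The bounds are package
defaults for plausible camera geometry, all configurable.

**The 0.03 threshold is tied to both the normalization and the image
size.** The stochastic floor of a phase-correlation surface between
unrelated images behaves like $\sqrt{2\log(NM)/NM}$: about 0.002 for
2000-px facility frames but about 0.04 at 180 px. With the normalization
above, 0.03 therefore discriminates cleanly on large frames (the gating
test runs at 512 px, where plant-versus-noise registrations fail the gate
in at least 19 of 20 seeded trials while self-registration scores
$H = 1$), whereas on small
desk-scale scenes the transform bounds do most of the gating work. Users
working at unusual resolutions should recalibrate `h_threshold`.

## Rotation and scale: the Fourier-Mellin stage

Rotation and isotropic scaling act on the magnitude spectrum as rotation
and inverse scaling, independent of translation. `logpolar_magnitude()`
therefore windows the image (Hann), takes the centred FFT magnitude,
applies the high-emphasis filter $(1-X)(2-X)$ with
$X = \cos\pi\xi\,\cos\pi\eta$ to suppress the low-frequency core, and
resamples onto a log-polar grid: angle over $[0°, 180°)$ (the magnitude is
point-symmetric) and log-radius spanning $[1, \min(N,M)/2]$. Rotation
becomes a circular shift along the angle axis, scaling a shift along the
log-radius axis, and a second phase correlation measures both.

Grid resolution is a real accuracy lever: the package defaults to
$2\max(N,M)$ angle bins and $\max(N,M)$ radius bins. Coarser grids (e.g.
one bin per degree at 128 px) visibly quantize small rotations; the default
resolves the test grid (rotations −10°…17°, scales 0.8…1.25) to within one
bin, which the registration tests assert via sub-2-px corner error of the
composed transform.

Two ambiguities remain. The half-plane angle axis confounds θ with θ+180°;
and for structurally non-identical images the log-polar correlation has
several near-equal local maxima, each a *locally* optimal
orientation hypothesis (often driven by background structure such as
carrier edges). `register_affine()` therefore expands the top 5 log-polar
peaks × both rotation candidates, completes each hypothesis with its own
translation correlation, and keeps the highest-$H$ candidate whose
composed transform passes the admissibility bounds (falling back to the
global best if none does). This candidate search is what makes the
per-scale registrations of cluttered scenes usable; with a single-peak
chain, spurious 90°/180° orientations win at many scales and are then
discarded by the gate.

Images entering the chain are zero-padded (top-left anchored, so pixel
coordinates are preserved) to a common FFT-friendly size with factors
2/3/5.

## The scale sweep and mask integration

Downscaling smooths images and reweights their spectra; on partially
similar pairs, different downscaling factors let different plant parts
dominate the correlation. `sweep_scales()` registers the pair at every
factor of the inclusive grid 0.1, 0.12, …, 1.0 (46 scales; `scale_max` is
always included), mapping each recovered transform back to full-resolution
coordinates (linear part unchanged, translation divided by the realized
factor). Scales at which an image would fall below 16 px per side are
recorded as skipped failure results rather than errors, keeping one result
per grid scale.

`integrate_masks()` warps the FLU plant mask (Otsu-thresholded from the
pre-scaled FLU grayscale, or user-supplied) into the VIS frame by every
*valid* transform — nearest-neighbour, so masks stay binary — and unions
the results. Union is the default integration rule because coverage of the
reference plant region is the target quantity; a majority-vote rule is
available behind an argument for conservative masks. Invalid (gated-out)
registrations are excluded and logged in the per-scale diagnostics; the
full-size s = 1 registration participates like any other scale. Union
makes the integrated area monotonically non-decreasing in the number of
contributing registrations, and the integrated OR can never fall below the
best single-scale OR — both asserted as properties in the test suite.

The pre-scaling step (FLU resampled to the VIS height before any
registration, width rounded to preserve aspect ratio) runs *after*
background filtering when the blue-mat filter is enabled; the order is
fixed and documented here because filtering is cheaper and cleaner at the
native FLU resolution.

## Preprocessing variants

Eight registration-input variants cross three axes: features (`gray`:
Rec. 601 luminance 0.299/0.587/0.114; `edge`: per-channel Sobel magnitude,
per-pixel maximum over channels, min-max rescaled — phase correlation
leans on edge information, and edge images suppress modality-specific
intensity differences), frame (`full`, or `cropped` to the padded bounding
box of a plant mask), and background (`raw`, or `filtered` = blue-dominant
pixels zeroed, where blue-dominant means $B > R + \delta$ and
$B > G + \delta$ with $\delta = 0.05$). The cited colour-edge literature
does not fix an operator; the Sobel-maximum construction is this package's
deterministic stand-in and equivalence with any specific published
operator is not claimed. Manual segmentation is likewise out of scope:
global (Otsu) thresholding plus externally supplied masks stand in for it.

## The synthetic scene generator

The generator is the package's benchmark instrument, not a renderer of
botanical realism. A scene is a rosette of filled elliptical leaves
attached to a common base (optionally a thin stem rectangle), laid out in
the VIS frame; the FLU frame is the same geometry mapped through the
inverse of the ground-truth similarity transform onto a canvas 0.6× the
VIS linear size, echoing the FLU/VIS camera resolution gap. Defaults: VIS
canvas 180×180 (desk-scale; chosen so a full 46-scale sweep of a pair runs
in a few seconds), five leaves 40–58 px long, residual transform scale
0.96–1.04, rotation ±3°, shift ±8 px, additive Gaussian noise σ = 0.05 on
both modalities. VIS-only structure comprises 2–6 full-width carrier-edge
lines, a low-frequency illumination gradient and optionally a blue mat;
FLU is bright plant on dark background. All randomness flows from the
scene seed through an isolated RNG scope, so regeneration is bit-identical
and the caller's RNG stream is untouched.

Because leaves are ellipses, the ground truth is exact: a VIS-only leaf
rotation about its base maps the ellipse analytically, and the
ground-truth masks are rendered from geometry, not resampled. The named
presets span the difficulty axes seen in real facilities:
`adult_structured`, `rosette_selfsimilar` (near-identical leaves →
ambiguous correlation peaks), `young_thin_line` (a ≤ 5-px-wide shoot of
non-specific shape — the hard case, and the reason batch success rates
order adult ≥ young in the acceptance suite), `nonuniform_motion` (two of
five leaves rotated 5–10°), and `cluttered_vis`.

What the generator does *not* emulate — occlusion, specular highlights,
soil texture, perspective, growth between frames — bounds what passing
tests prove: they validate the registration mathematics and the
integration logic under controlled structural mismatch, not performance on
any particular facility's imagery.

## Known limitations and numerical notes

* The transform model is a similarity (isotropic scale, rotation,
  translation) — what Fourier-Mellin can observe. Shear and non-rigid
  deformation are out of scope; non-uniform motion is handled only through
  mask integration.
* Integrated-mask coverage of strongly moved leaves is high but not
  guaranteed complete: over the standard 20-scene benchmark the integrated
  OR is exactly 1.0 on 18 scenes and ≥ 0.992 on all, the residual being a
  sliver of the most-rotated leaf when no swept scale locks onto that
  leaf's alignment. The acceptance suite asserts full coverage and
  therefore documents this residual as a visible failure rather than
  hiding it.
* Rotation/scale estimation needs edge-rich content; on smooth, blob-like
  images the log-polar correlation peak collapses toward zero shift.
* The ground-truth self-consistency of the generator (warping the FLU mask
  by the true transform against the VIS mask) reaches a Jaccard index of
  about 0.93–0.96, limited by nearest-neighbour resampling of a 0.6×
  canvas; tests assert 0.93.
* Degenerate inputs (all-zero images, singular transforms) yield failure
  results with diagnostics, not exceptions, so batch runs never abort on a
  single bad pair; the one deliberate exception is mask integration with
  zero valid registrations, which raises a typed condition carrying the
  per-scale reasons.
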