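# phasefuse

Automated alignment of multi-modal plant images by integrative
Fourier-Mellin phase correlation.

High-throughput phenotyping platforms photograph every plant with several
cameras: a visible-light (VIS) image and a fluorescence (FLU) image taken
seconds apart, at different resolutions, positions and orientations.
Chlorophyll fluorescence gives FLU images a near-perfect plant/background
contrast, so a FLU image is trivial to segment — while the VIS image, with
its carriers, mats, shadows and reflections, is not. If the FLU image can be
*registered* onto the VIS image, its binary plant mask segments the VIS
image for free (segmentation-via-registration). The catch is that the two
modalities are structurally different images of the same plant, and plants
move: individual leaves sway between the two exposures, which no single
affine transform can compensate.

`phasefuse` implements the frequency-domain registration chain for this
problem, for image analysts building phenotyping pipelines:

* **Phase correlation (PC).** For images *A*, *B* with Fourier transforms
  α = F(A), β = F(B), the normalized cross-power spectrum is
  CPS = αβ\*/|αβ\*| and PC = F⁻¹(CPS). For two structurally identical
  images displaced by (Δx, Δy), PC(x, y) = δ(x − Δx, y − Δy): the global
  maximum localizes the translation, and its height *H* (scaled so that
  identical images give *H* = 1) scores the reliability of the match.
* **Fourier-Mellin extension.** Rotation and isotropic scale become
  translations after log-polar resampling of the (windowed, high-pass
  filtered) spectral magnitudes, so a second phase correlation recovers
  them; the recovered similarity transform maps FLU pixels into the VIS
  frame.
* **Validity gating.** A registration is accepted only if *H* > 0.03 and
  the transform stays within admissible bounds on scale, rotation and
  translation; low peaks indicate a failed correlation between
  structurally unrelated content.
* **Scale-space integration.** Single-step PC on structurally non-identical
  images locks onto *locally* optimal alignments — different ones at
  different downscaling factors. The sweep registers the pair at every
  factor in [0.1, 1.0] (step 0.02, 46 scales) and unions the FLU plant
  masks warped by all valid transforms into a single integrated mask (IM)
  that covers non-uniformly moving leaves no single transform captures.
* **Evaluation.** Success rate SR = ns/n (registrations passing the gate)
  and overlap ratio OR = ar/a (reference plant area covered by the
  registered mask), plus batch/grouped reporting.
* **Synthetic benchmark scenes.** A seeded generator renders FLU/VIS pairs
  of an elliptical rosette with exact ground truth: global similarity
  transform, per-leaf motion, VIS-only clutter (carrier edges,
  illumination gradients, optional blue mat), modality-specific contrast
  and additive noise.

## Worked example

```r
library(phasefuse)

spec <- scene_preset("nonuniform_motion", seed = 7)  # 2 of 5 leaves move
pair <- generate_pair(spec)
pair
#> <synthetic_pair> FLU 108x108 / VIS 180x180  5 leaves  seed=7

out <- register_integrative(pair$flu, pair$vis)
glance(out)
#> # A tibble: 1 × 4
#>   n_scales n_valid success mask_area
#>      <int>   <int> <lgl>       <dbl>
#> 1       46      42 TRUE        15287

overlap_ratio(out$integrated_mask, pair$vis_mask)
#> [1] 0.9996676
```

42 of the 46 per-scale registrations pass the *H* > 0.03 gate and the
transform bounds; their union covers 99.97 % of the ground-truth VIS plant
region. The best *single* scale covers only 70.8 % on this pair — the two
moved leaves sit outside any one similarity transform, which is exactly
what the integration compensates. `tidy(out)` exposes the per-scale table
(scale, H, valid, and the transform components T11, T12, T31, T32);
`autoplot(out)` plots their variation across the sweep, and
`segment_via_mask(pair$vis, out$integrated_mask)` performs the final VIS
segmentation.

A command-line interface wrapping the same functions ships in
`inst/cli/phasefuse.R` with `register`, `sweep`, `evaluate` and `simulate`
subcommands.

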