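---
title: "Methods: multi-offset AO-SLO vessel wall morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-offset AO-SLO vessel wall morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Retinal arteriole walls are nearly transparent phase objects: their refractive
index differs only slightly from the surrounding tissue, so a reflective
confocal scanning laser ophthalmoscope sees the nerve fiber texture above them
but not the wall itself. An offset-aperture detection scheme collects
multiply/forward-scattered photons instead, and a *split-detector* image --
the difference of two opposed offset images divided by their sum -- behaves
like a directional derivative of the tissue phase. One split direction,
however, is blind to edges running parallel to it. With four offset fibers
arranged as two orthogonal pairs around a central confocal fiber, all
directions are covered simultaneously, and the wall becomes measurable:

* **Splits.** With offset channels \(I_1..I_4\) (fibers at 45°, 135°, 225°,
  315°), the package computes the two diagonal splits
  \((I_1-I_3)/(I_1+I_3)\) and \((I_2-I_4)/(I_2+I_4)\) and the
  adjacent-sum splits \((I_1-I_2-I_3+I_4)/\Sigma\) (near-horizontal) and
  \((I_1+I_2-I_3-I_4)/\Sigma\) (near-vertical), \(\Sigma\) the four-offset
  ring sum.
* **MPG.** The magnitude of the phase gradient is
  \(\sqrt{D_h^2 + D_v^2}\) over an orthogonal split pair: an isotropic edge
  map whose maxima sit on refractive-index boundaries -- the wall edges.
* **STD (motion contrast).** Temporal standard deviation of each split over
  the registered stack, averaged over the four splits. Moving blood cells
  make it large inside the lumen and small elsewhere, so its edge is the
  lumen boundary.
* **Morphometry.** The outer wall boundary can only come from the MPG (there
  is no flow there); the inner boundary comes from the STD flow edge,
  cross-checked against the inner MPG ridge. From the two boundary pairs the
  package measures the vessel diameter VD, lumen diameter LD, wall thickness
  \((VD-LD)/2\) and the wall-to-lumen ratio
  \(\mathrm{WLR} = 0.5\,(VD-LD)/LD\) as functions of arclength position.

## Pipeline and parameter choices

**Registration.** A stack of co-acquired frames (typically 100-200 in
clinical use) is aligned with *one alignment function per frame*, estimated
on the confocal channel (strongest static texture) and applied identically to
all five channels -- the central benefit of simultaneous acquisition. The
default transform is a global translation from the cross-correlation peak
with parabolic subpixel refinement; an optional strip mode (`stripCount > 1`)
estimates one translation per horizontal band and interpolates linearly
between band centers, the standard raster-scan distortion model. The
reference frame is the member of a seeded 10-frame subsample with the highest
mean pairwise post-alignment correlation, which avoids anchoring on a
motion-distorted frame and is deterministic given the seed. Frame quality is
the normalized cross-correlation with the reference after alignment; frames
below `rejectionThreshold` (default 0.5) are rejected. The source method
publications give neither the rejection criterion nor the reference policy,
so both are explicit configuration here rather than claims about the original
software.

**Derived images.** Splits are guarded ratios: where the denominator does not
exceed `epsilon` the pixel is invalid (`NA`), never silently zero -- this
matters at registration borders, which must not fake low motion contrast.
The default guard is scale-free, `1e-6 x mean(ring sum)`, so it adapts to
intensity units. Invalidity propagates through every derived image, and
temporal statistics require at least two valid frames per pixel. MPG is
computed from the *temporal-mean* splits (mean first suppresses speckle; one
MPG image per stack), from the near-horizontal/vertical pair by default
(`derivativePair = "axis"`; the diagonal pair is equivalent up to a 45°
rotation of the derivative basis and is selectable). The four-offset SD uses
the population formula (divide by 4) -- sample vs population changes only a
constant factor, and the choice is fixed and documented.

**Segmentation.** The flow region is found by hysteresis: an Otsu threshold
of the valid STD pixels defines the flow core, which is grown to a lower
threshold (0.6 x Otsu, still roughly 8 standard deviations above the
motion-contrast noise floor) over connected pixels -- the flow signal tapers
over the last cell radius inside the lumen, and a single global threshold
cuts into that taper, biasing the mask inward by several pixels on wide
vessels. The grown region is morphologically closed (radius 2 px),
hole-filled, and the largest connected component is kept. MPG ridges are non-maximum-suppressed along the cross-ridge
direction (dominant eigenvector of the structure tensor, smoothing
`ridgeSigma = 2` px), then kept by hysteresis (defaults: 90th/70th percentile
of valid MPG) if the component is at least `minRidgeLength = 10` px long --
the length floor removes isolated noise maxima that percentile thresholds
alone cannot, since the percentiles sit inside the background distribution
when the wall occupies a small image fraction. None of these thresholds comes
from the source publication (it reports a semi-automatic Matlab tool with
expert-grader cleanup); they are deliberate, config-exposed defaults. The
inner boundary is the subpixel flow-edge contour, split into the two vessel
sides at the centerline endpoints and snapped (within `snapDistance = 2` px)
to the inner MPG ridge with a parabolic subpixel fit; the snap search runs
mostly *outward* (from -1 px to `+snapDistance` along the centerline-outward
normal) because the thresholded flow edge sits at or slightly inside the true
lumen boundary -- flow coverage tapers at the edge -- while a symmetric
search would let residual in-lumen ridges from imperfect temporal averaging
of the moving-cell field pull the boundary into the lumen. The outer boundary is
found by marching outward along the local normal from each inner point,
starting at `wallStartOffset = 1.5` px (to clear the inner ridge itself) up
to `maxWallThickness = 15` px, and taking the first MPG profile maximum
supported by a ridge pixel; gaps shorter than `bridgeLength = 10` px of
arclength are bridged linearly, longer gaps remain explicit invalid segments
rather than inventions. Manual grader corrections are replaced by replayable
`EditOp`s (`delete_ridge_region`, `bridge_gap`, `move_vertex`) recorded in a
provenance log; no automatic rule is claimed for distinguishing mural-cell
ridges from wall ridges -- that judgement stays with the operator, now in
reproducible form.

**Morphometry.** The centerline is the longest geodesic path through the
Zhang-Suen skeleton of the lumen mask, smoothed by a 5 px moving average and
trimmed by 1.5 mean lumen radii per end (the skeleton reaches end caps
through diagonal thinning forks up to sqrt(2) radii long). Thinning a wide
tube leaves end forks up to about one radius long, so the branch gate
tolerance scales with the radius; genuinely branched (Y-shaped) masks are
refused in single-vessel mode. Diameters are measured along chords
*perpendicular to the local tangent* -- the only rotation-invariant choice --
with LD taken as the full chord between the two inner intersections (robust
to centerline bias). Profiles are not smoothed by default: raw along-vessel
variation is itself a finding of interest, so smoothing is opt-in
(`smoothingWindow`).

## The synthetic scene generator

Every stage is validated against scenes with exact ground truth. The forward
model inverts the split-as-phase-derivative interpretation: offset channel
\(i\) receives \(B + \alpha\,(\nabla\phi \cdot d_i)\) plus noise, where
\(\phi\) is the scene phase map, \(d_i\) the fiber direction and \(B\) the
isotropic multiple-scattering background. The wall is a phase annulus:
\(\phi\) is flat in background and lumen and elevated by `phaseAmplitude`
across the wall, with raised-cosine transitions of width `edgeWidth` (2 px)
*centred on* the true inner and outer edges, so the phase-gradient maxima sit
exactly on the boundaries being measured. Blood cells are moving phase bumps
(raised-cosine, radius 3 µm, ~2 rad) advected along the centerline and
clipped smoothly to the lumen; their directional gradients make the splits
fluctuate where blood flows, which is what the STD image detects. A formal
alternative -- adding cell contrast as a plain intensity term equally to all
four offsets -- cancels identically in every split numerator and would make
flow *reduce* split variance; erythrocytes are forward-scattering phase
objects, so the phase-bump model is both the physical one and the one under
which motion contrast exists. The confocal channel sees a static smooth
random texture (the nerve-fiber layer stand-in, used by registration), 10% of
the cell profile, and *no wall term*: the confocal blindness to walls is part
of the model. Per-frame global jitter is Gaussian (σ = 2 px); with
probability 0.05 a frame additionally receives a strong horizontal shear
(0.25 px/px) emulating a saccade-distorted frame, and its index is recorded
as truth for rejection tests. Intensities are clipped at zero and quantized
to integer counts (a digitizer model), which also makes written stacks read
back bit-identically.

Default conditions: 256 x 256 px at 1 µm/px, 64 frames, background 100
counts, α = 25 counts/(rad/px) and wall phase 1 rad (wall-edge split
amplitude ≈ 0.14, about 10x the per-frame split noise at Gaussian noise σ =
2 counts), cell density 50 per 100 µm. Tests keep the 64-frame stack depth
(the stated acquisition regime is 100-200 frames; Otsu flow-mask fidelity
degrades visibly below ~30 frames) while scaling the image to 160 x 160 px
for shared fixtures; orientation sweeps, which do not measure flow-mask
fidelity, use 192 x 192 / 32 frames. These are the package's chosen test
conditions.

**What the generator does not emulate:** partially coherent DPC transfer
functions (the forward model is first order in the phase gradient),
photoreceptor mosaics, true nerve-fiber anisotropy, torsional eye motion,
microaneurysm lesions, and mural-cell texture on the wall. Passing tests
therefore demonstrate correctness of the *analysis chain* under the stated
optical model, not clinical performance on real eyes.

## Numerical conventions

Coordinates are 1-based pixel centers, row = y increasing downward,
column = x increasing rightward; subpixel positions are continuous in this
frame, and one convention is used by every module. Interpolation is bilinear
throughout; out-of-bounds samples are invalid, not extrapolated (the
simulator's sheared frames use replicate boundary, as they model corrupted
acquisitions). Subpixel refinement (registration peak, ridge crossings,
boundary snapping) is a three-point parabolic fit, declined when the
curvature is not negative. Ties in non-maximum suppression are broken by
keeping `>=` on one side and `>` on the other, which keeps ridges one pixel
wide through plateaus. Channel stacks are written as 16-bit integer
multi-page TIFFs of raw counts (the package never rescales on read); derived
images are exported as 16-bit TIFFs with an affine scale sidecar for viewing,
while exact stage chaining uses lossless RDS intermediates.

## Known limitations

* The outer-boundary march assumes the wall is locally the *first* supported
  MPG maximum beyond 1.5 px; a bright structure hugging the wall closer than
  that (e.g. a mural cell) lures the boundary until removed with a
  `delete_ridge_region` edit -- mirroring the manual cleanup step of the
  clinical workflow.
* Walls thinner than about 1.5 px of separation between inner and outer
  ridge cannot be resolved by construction (`wallStartOffset`).
* Strip-mode registration models within-frame motion as per-band horizontal
  translation; rotation and torsion are out of scope.
* Single-vessel mode refuses branched lumens rather than measuring them; the
  multi-vessel flag only relaxes component selection, not branch-aware
  centerlines.
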