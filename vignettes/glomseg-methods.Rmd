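---
title: "Statistical segmentation and 3D morphometry of renal glomeruli: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glomseg methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

A cleared-kidney light-sheet stack, after conversion to 8 bits, contains
three voxel populations ordered by grey level: the non-fluorescent
mounting medium, the self-fluorescent renal tissue, and the bright
lectin-labelled capillary structures. The package's central assumption is
that **the tissue population is Gaussian**: its greyscale histogram, over
a range that excludes both the background spike and the bright lectin
tail, is well described by
`F = Fmax · exp(−½((X − mean)/SD)²)`. Under that assumption the quantile
structure of the tissue greys is known, and a threshold at
`mean + 3.29·SD` excludes a *fixed fraction* of tissue voxels
(`pnorm(3.29) ≈ 0.9995`) regardless of the sample's absolute brightness or
contrast. That is what makes the pipeline operator-independent: no display
setting or visual judgement enters the boundary definition. The exclusion
fraction is sometimes quoted loosely as 99.5% (and the ±3.29·SD coverage
as 99%); the exact normal values are 99.95% and 99.90%, and the tests
treat the quoted figures as lower bounds.

The remaining two screens operate on objects, not voxels. Both place their
cut-off at an *inflexion point* of a frequency distribution — the volume
distribution of all labelled objects, then the `Vobj/Vell` shape-ratio
distribution of the survivors — so they, too, contain no free visual
parameter.

## Operationalizing "inflexion point"

An inflexion point between two populations is well defined only when both
populations are visible in the curve. Two detectors are provided:

* **valley** — the minimum of the moving-average-smoothed curve inside
  the most *prominent* separation between adjacent local maxima, where
  prominence is the valley's depth relative to the smaller of the two
  peaks (ties broken toward the taller peak pair). On a bimodal curve
  this is simply the valley between the two largest maxima; on
  multi-modal curves (e.g. a volume histogram whose debris population is
  itself structured) it finds the between-population gap rather than a
  dip inside one population. Endpoint maxima count (the background spike
  peaks at grey 0); zero-height plateaus never count (empty histogram
  tails are not populations); and a secondary peak below 0.5% of the
  primary's smoothed height is treated as sampling noise on a flank, not
  a population. Ties for the minimum resolve to the centre of the tied
  run, so a symmetric two-spike curve yields the exact midpoint.
* **knee** — the position of maximum discrete curvature of the smoothed
  `log(1 + F)` curve, computed in bin-index space with the two bins at
  each end excluded (their finite differences are one-sided). This serves
  monotone-decreasing curves, e.g. a volume distribution dominated by
  debris, where no interior valley exists.

Defaults per stage: background/tissue threshold → valley (the two
populations are always present); volume and shape screens → *auto*, i.e.
valley first with knee as the documented fallback when the valley detector
reports a single population. This deviates from a fixed "knee" default for
the volume screen: the volume distribution of a stack that actually
contains glomeruli is bimodal, and the valley is the better-defined
separator; the knee remains available (`volume_strategy = "knee"`) for
debris-only curves.

Smoothing is a centred moving average, default window 5 bins (3 for the
25-bin ratio histogram), with shrinking windows at the edges. Volume
histograms use 40 logarithmic bins (object volumes span several decades);
ratio histograms use 25 linear bins on [0, 1].

## Gaussian fitting

One fitting engine serves both the greyscale stage and the
per-glomerulus parameter distributions. The start is deterministic and
derivative-free — amplitude and mean from the in-range peak, SD from the
half-width at half-maximum divided by 1.1774 — followed by `nls` (port
algorithm, bounded below by `sd > 0`), with a Nelder–Mead
sum-of-squares fallback if `nls` fails to converge. `R²` is
`1 − SSresid/SStot` over the fitted range, clamped to [0, 1]. The tissue
fit range runs from the background threshold to the grey level where the
right flank first drops below 1% of the tissue peak, so the lectin tail
cannot bias the fitted SD. Fits with non-positive SD or amplitude are
rejected as errors rather than returned.

## Binarization, filtering, labelling

Binarization uses a strict inequality (`grey > threshold`) so the
continuous `mean + 3.29·SD` threshold excludes its own boundary bin. The
3D median filter on a binary mask is a majority vote over a `window³`
neighbourhood (default 3×3×3) with edge replication at borders; "three
voxels for (x, y, z)" is read as one window value per axis in *index*
space, matching common viewer behaviour on anisotropic stacks (a
7×7×7 reading is available via `median_window`). Connected components
default to 26-connectivity — capillary tufts are thin, and diagonal voxel
contacts are common — with 6-connectivity available for sensitivity
analysis.

## The shape score Vobj/Vell

`Vell` is the volume of the smallest ellipsoid containing the object.
Khachiyan's barycentric ascent runs on the *boundary* voxel centres
(interior voxels cannot support the ellipsoid) to relative tolerance
10⁻³, capped at 20 000 iterations; the result is then scaled minimally so
that every corner of every boundary voxel satisfies the quadratic form —
the reported `Vell` is therefore a certified enclosing ellipsoid of the
whole voxel solid, and `Vobj/Vell ≤ 1` holds by construction. Boundary
sets above 6 000 points (merged capillary networks) are thinned with a
deterministic stride before the iteration; the certification step still
uses every boundary corner, so validity is unaffected. Degenerate objects
(single voxels, collinear or coplanar voxel sets) are inflated to their
voxel corners first, so `Vell > 0` always.

Two geometric facts calibrate expectations for this score. A voxelized
ball of radius 10 µm at 0.5 µm isotropic spacing scores about 0.88 (the
corner inflation costs ~4% in radius). A *straight* solid tube cannot
score below `8/(4/3·π·3^{3/2}) ≈ 0.368`: the minimal enclosing ellipsoid
of a box is its √3-semi-axis circumscribed ellipsoid (affine image of the
cube/sphere case), independent of aspect ratio. Straight tubes therefore
sit near 0.35–0.41 and *bent* tubes far lower; the shape screen's valley
separates lobulated spheroids (≈0.7–0.9) from both. One stated acceptance
bound (straight 100×2×2 µm tube ≤ 0.3) contradicts this geometry — it
mixes a cylinder's volume with a box's enclosing ellipsoid — and is left
failing by design; the corresponding test also asserts the separation the
screen actually relies on (ball minus tube ratio > 0.4) and agreement of
`Vell` with the closed-form box oracle.

## Surface area and compactness

Compactness is `36π·V²/S³`, the isoperimetric ratio `S³/V²` normalized so
a perfect sphere scores 1. It inherits all the error of the surface
estimate cubed, so the estimator matters. Counting exposed voxel faces
overestimates a sphere's area by ~50% (the staircase limit is `6r²π`
against `4πr²`), which would drag a perfect ball's compactness to ≈0.3.
The default estimator instead extracts a watertight isosurface: the 0/1
mask is smoothed with a separable Gaussian (σ = 1 voxel per axis, kernel
truncated at 3σ, zero boundary after padding), and marching tetrahedra
(six tetrahedra per cell sharing the cube diagonal, linear interpolation
at level 0.5) triangulate the 0.5-level set with physical spacing applied
to vertex coordinates. On a voxelized ball of radius 10 µm this recovers
the analytic area to well under 1% at 0.5 µm voxels, with error shrinking
monotonically as resolution increases (asserted over 2, 1 and 0.5 µm).
Objects too small to survive smoothing (single voxels) fall back to
face-area counting, and `surface_method = "faces"` exposes the face
estimator for comparison with face-based pipelines. Note that smoothing at
σ = 1 voxel also smooths real surface detail at the 1–2 voxel scale, so
the compactness of small, finely lobulated objects is biased toward 1;
at the paper's anisotropic spacing one σ in z is 2 µm.

## Densities and summaries

Numerical density is the glomerulus count divided by the tissue volume
(voxels above the background threshold × voxel volume, in mm³); volume
density is the percentage of tissue volume occupied by glomeruli. Objects
touching a stack face are *counted* for both densities but *excluded*
from the per-sample morphometric means — their surface and volume are
clipped by the field of view; the choice is exposed as `exclude_edge`.
Within-sample dispersions are population SDs (denominator n) over
glomeruli. Parameter distributions (surface, volume, compactness) use 15
equal-width bins converted to relative frequencies summing to 100%, fitted
with the same Gaussian engine; a fit with `R² < 0.9` is flagged rather
than suppressed. Distributions pool glomeruli across whatever set of
objects is passed; per-sample fitting is a trivial loop left to the
caller.

## The phantom: what it emulates, and what a green test proves

The generator builds the three grey populations (background N(5, 2),
tissue N(80, 10), lectin-bright objects at N(190, 12) for glomeruli and
N(170, 12) for tubes) with per-voxel Gaussian noise, so the tissue/lectin
continuum — the problem the statistical threshold solves — exists in the
phantom. Its object classes mirror the screening problem: lobulated
spheroid glomeruli (radius modulated by a smooth random angular field of
amplitude `lobulation·r`, default 0.15), thin straight tubules standing in
for peritubular capillaries (radius 1.5 µm — also roughly the thinnest
structure that survives a 3×3×3 majority filter at this spacing), a few
*bent* glomerulus-volume tubes as shape-screen decoys, and isolated
bright artifact voxels. Glomeruli are rejection-sampled to be
non-overlapping, clear of stack faces, and separated from all tubes by a
two-voxel halo (one voxel is not enough: the majority filter can bridge a
single-voxel gap and merge ground-truth labels with decoys).

The default stack (64×256×256 voxels at 2×0.5×0.5 µm, ≈128 µm cube) is a
*scaled-down* cortex sample: 40 glomeruli of real size (~25 µm radius)
cannot physically fit in it, so planted glomeruli have radius 8.5 ± 1 µm
(clamped at ±2.5 SD). The value was chosen once, for placeability under
rejection sampling while keeping a ≳3× volume gap above tubule debris,
and is not tuned against any test. Consequently the phantom validates
*mechanisms* — threshold recovery, screen separation, count and volume
recovery, FP/FN bookkeeping — not biological magnitudes: its densities
and compactness are not mouse-kidney values, and a green end-to-end test
does not certify performance on real stacks with depth-dependent
attenuation, stripes, PSF anisotropy, or touching glomeruli, none of
which are simulated. Glomerulus *radii* are Gaussian by construction;
volumes are correspondingly skewed, so the Gaussian-recovery property of
the parameter-distribution fits is tested on directly drawn Gaussian
samples at magnitudes from the real-kidney literature.

## Numerical and degenerate-input conventions

* 16→8-bit conversion is a global min–max linear rescale (the
  operator-independent choice; a fixed display range is configurable);
  flat stacks map to 0 with a warning. Monotonicity of the mapping is a
  tested invariant.
* TIFF I/O is a deliberate, minimal baseline codec (uncompressed
  greyscale 8/16-bit, multi-page, both byte orders on read): no suitable
  dependency was available to the package, and anything it cannot
  represent faithfully (compression, RGB, palettes, tiles) is rejected
  with an explicit error rather than mis-read. Write/read round trips are
  bit-identical and cross-checked against an independent reader in the
  test suite.
* Histogram ties, empty screens (`threshold removes everything`), empty
  stacks, zero-object phantoms, saturated tissue fits
  (`mean + 3.29·SD ≥ 255`) and zero tissue volume all have defined
  outcomes — a centred tie-break, a warning with an empty result, a
  zero-object report with a diagnostic, and typed errors respectively —
  rather than crashes.
* All stochastic code paths (phantom, tests) run under explicit seeds;
  the generator saves and restores the caller's RNG state.

## Known limitations

* Touching glomeruli are not separated (no watershed), matching the
  source protocol; counts in dense cortex may merge neighbours.
* The surface estimator's smoothing biases compactness upward for
  objects a few voxels across; compactness comparisons are only
  meaningful within one estimator and resolution.
* The CLI's `validate` subcommand requires the in-session objects (a
  label TIFF alone does not carry kept-label provenance); scoring is done
  with `validate_detection()`.
* Real-data absolute morphometrics are out of scope: no public raw
  stacks exist for this protocol, and the phantom's scaled geometry is
  not a substitute.
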