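---
title: "Methods: reference-patch normalization and nail color measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-patch normalization and nail color measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nailsense)
```

## The measurement model

nailsense measures per-finger nail plate color from hand images acquired
under a guided convention: the hand rests in a light box, one finger per
vertical guidance band; black reference squares sit at the four image
corners and white reference squares at 25/50/75 % of the width along the
top band. The radiometric core is the per-channel linear normalization

$$\eta_x = \frac{I_x - \mathrm{Black}_x}{\mathrm{White}_x - \mathrm{Black}_x},
\qquad x \in \{R, G, B\},$$

clipped to $[0, 1]$. Its assumption is an affine illumination model per
channel, $I = g_x r + o_x$ for reflectance $r$: the black patches ($r=0$)
are imaged at $o_x$, the white patches ($r=1$) at $g_x + o_x$, so $\eta$
estimates reflectance with both gain and offset cancelled. The assumption
holds to the extent the box illuminates patches and nails equally; strong
spatial illumination gradients, specular highlights on the nail plate,
and any nonlinearity of the sensor response violate it and are not
modelled. Out-of-range values are clipped — the model says nothing about
pixels darker than the black patch or brighter than the white patch, and
clipping is the least surprising choice.

References are taken per channel (black = combine over the four corner
patches, white = combine over the three central patches), because the
gains being cancelled are per-channel quantities. Two combining statistics
are available:

* `minmax` (default): the plain minimum/maximum over the union of patch
  pixels — the literal extraction rule the acquisition convention states.
* `patchmean`: mean per patch, then min/max across patches. Under
  zero-mean sensor noise of SD $\sigma$, the minimum over the ~6400 corner
  pixels of an 800 px frame sits about $3.5\sigma$ below the true level
  (the expected extreme of that many Gaussians), which propagates into a
  bias of several grey levels at low gains; the patch mean has SD
  $\sigma/40$ per patch and is effectively unbiased. `patchmean` is
  therefore the right choice whenever noise is non-negligible, and is
  what the package's own accuracy checks use; `minmax` remains the
  default out of fidelity to the stated rule.

Degenerate references (white $\le$ black on any channel — patches missing,
occluded, or the image is flat) raise a dedicated error rather than
producing meaningless normalizations.

## Segmentation and post-processing

Segmentation is a backend contract: anything producing a per-pixel nail
probability map plugs in. The package ships (a) a loader for mask files
written by any external model, and (b) a classical baseline that operates
on the *normalized* image: a pixel is nail iff normalized brightness
$\max(\eta_R,\eta_G,\eta_B) \ge$ `brightness_min` (default 0.6), saturation
$(\max-\min)/\max \le$ `saturation_max` (default 0.35), and the pixel lies
in a finger guidance band. Nail plates are bright and weakly saturated;
skin is strongly saturated; the box background is dark. Because the
predicate sees $\eta$, it inherits the illumination invariance of the
normalization. The defaults were fixed once against the synthetic
fixtures' skin/nail palette; they are not meant to survive contact with
real hands un-retuned, which is exactly why the backend is pluggable.

Post-processing order is fixed: threshold (default 0.5) → majority filter
(binary median, default 3×3, edge-replicated borders) to fill pinholes →
erosion by a square structuring element of side `erode_filter` → extraction
of 8-connected components with area ≥ `min_area` (default 50 px) → one
contour per finger band (largest area wins, ties to the leftmost
centroid). `erode_filter` (stock values 70 and 92) is defined at the
800 px working size and rescales linearly with the working side,
`min_area` by area. Erosion is deliberately aggressive: output survives
only where the full square fits, so a 70×70 element reduces a nail
ellipse to a small core (about 160 px for the default 100×124 px
ellipses) — that core is uniform nail plate, ideal for color measurement,
and two regions joined by a thin bridge can never stay connected. The
even side 70 is honored exactly (anchor at `floor(k/2)`), which is why the
morphology is implemented on an integral-image primitive rather than on a
library that rounds element sizes to odd. Components use 8-connectivity;
labeling is run-based union-find, checked in the tests against an
independent flood-fill oracle.

The GUI-style "size cursor" is `region_scale`: iterated 3×3
erosion/dilation of an assigned contour until its area passes
`factor ×` original (dilation clipped to the finger band, shrink never
below one pixel — when one more 3×3 erosion would empty the contour, the
last non-empty set is kept even if still above target).

## Color measurement and lookup

Per finger, the package reports the arithmetic mean of the raw channels
and of the normalized channels over the contour's pixel set; the
normalized mean is canonical (mean-of-normalized, which equals
normalized-of-mean up to quantization on clip-free regions, by linearity).
A finger with no contour is a *missing* measurement — pixel count 0, empty
color cells in the exported CSV — rather than a fabricated value; this is
the expected outcome for an occluded thumb. Histories are append-only in
blocks of five fingers, timestamped by sequence index (reproducible) or
wall clock, exported as CSV and optionally plotted as per-finger R/G/B
series.

Measured colors (normalized mean × 255) are matched against a six-entry
nail-discoloration palette (yellow/green/brown/red/white/purple with their
classically associated conditions) by Euclidean distance in RGB, all
entries returned in ascending order, with a `confident` flag below
`max_distance` (default 60 — roughly a "just noticeable at arm's length"
radius; the ranking never depends on it). Euclidean RGB was chosen as the
simplest defensible metric; the table is replaceable via CSV, so a
perceptual space can be swapped in by supplying transformed coordinates.
A healthy pink is far from every entry and correctly yields "no strong
indication". None of this is diagnostic.

## Evaluation metrics

IoU $|A\cap B|/|A\cup B|$ (1 for two empty masks) and hard-mask Dice loss
$1 - 2|A\cap B|/(|A|+|B|)$ (0 for two empty masks), per image and averaged
over directory datasets paired by filename stem. For any pair,
IoU $\le$ Dice coefficient with equality only at 0 or 1. Note that a
*soft* (training-time) Dice loss computed on probability maps is a
different quantity and can sit far from the hard-mask value at high IoU;
this package's loss is strictly the set complement above.

## The synthetic fixture generator

`generateHand()` emulates the acquisition convention: dark box background,
five skin-toned finger bars, one nail ellipse of known true color per
finger, reference patches rendered at true black (0,0,0) and true white
(255,255,255) *before* illumination — so the extraction rule genuinely
inverts the applied model — then per-channel affine illumination and
additive Gaussian sensor noise from a single seeded stream (the caller's
RNG state is untouched). Defaults are the package's study conditions,
chosen once: 800 px frames; pinkish nail plates around (226, 188, 178)
(saturation ≈ 0.21, inside the baseline's acceptance region) on more
saturated skin (205, 140, 110); 100×124 px nail ellipses — large enough
that a 70×70 square fits, i.e. the stock erosion leaves one component per
finger; illumination gain 0.9 and offset 12, a mild controlled-box
deviation from identity that keeps the 0/255 patches inside the 8-bit
range; noise SD 2 grey levels, typical of a consumer sensor at fixed
exposure.

Clipping semantics: the generator validates that the *deterministic*
affine map keeps every rendered value inside [0, 255] (error otherwise,
unless clipping is explicitly enabled); the subsequent noise is clamped at
the range ends, as a real sensor saturates. Validating the noise tails
instead would make any spec with patches at the range ends and nonzero
noise invalid — the tail probability never reaches zero — so saturation is
the only self-consistent reading.

What the generator does *not* emulate: nail texture and lunulae, specular
highlights, spatial illumination gradients, pose variation, soft nail/skin
boundaries, chromatic sensor effects. Passing the package's checks on
fixtures therefore demonstrates the pipeline's arithmetic and its
invariances, not real-world segmentation accuracy; the published accuracy
of any CNN backend on real hands must be established on real data through
the mask-file backend and `evaluateDataset()`.

## Numerical choices and problem sizes

* Working size 800×800 (bilinear, aspect stretched); all thresholds are
  defined at this size and rescaled from it.
* Half-open, 0-based rectangles; x = column, y = row, origin top-left.
* Patch side = `round(0.05 × min(width, height))`, configurable in
  (0, 0.2].
* Binarization threshold 0.5; majority kernel 3; `min_area` 50 px;
  assignment tie-breaks: largest area, then leftmost centroid.
* The package's own accuracy checks run on 20 fixtures per property at
  the full 800 px working size with gains sampled in [0.6, (255−o)/255]
  and offsets in [5, 30] — the stated ranges intersected with the
  clip-free constraint the white patches impose; recovery of true nail
  colors is within 3 grey levels per channel (observed ≈ 0.5), and
  normalized images of illuminated vs un-illuminated frames agree within
  2/255 (rounding of the affine map accounts for up to ~1.7/255 at gain
  0.6, which is why the band is where it is).

## Known limitations

* The classical baseline's thresholds are fixture-calibrated; real skin
  tones and glossy nails will need retuning or an external backend.
* Reference patches inside finger bands can, in pathological cases (a
  missing nail *and* no erosion), be picked up as the band's largest
  bright component; the stock erosion removes them, but configurations
  with `erode_filter = 0` should keep `min_area` above the patch area or
  mask the patch rectangles upstream.
* Lunula segmentation is out of scope; measurements average the whole
  detected plate core.
* The disease palette is a coarse lookup, not a classifier; distances in
  raw RGB are not perceptually uniform.
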