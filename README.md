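# nailsense

Fingernail color monitoring from guided hand images: reference-patch
radiometric normalization, pluggable nail segmentation, per-finger color
measurement with history, nail-color/symptom lookup, and segmentation
evaluation — as a batch R library with a thin command-line wrapper.

## The problem

Nail plate color carries clinically suggestive information (pallor,
cyanosis, discolorations), but raw webcam RGB values drift with
illumination, so the tiny color changes worth tracking are swamped by
lighting. Under a guided acquisition convention — the hand placed in a
controlled light box, one finger per vertical guidance band, black
reference squares at the four image corners and white reference squares at
three positions along the top band — each channel can be anchored to known
reflectances. For pixel value `I` in channel `x ∈ {R, G, B}`:

    eta_x = (I_x − Black_x) / (White_x − Black_x)

where `Black_x` is taken over the corner patches and `White_x` over the
central patches. If illumination acts per channel as `I = gain·r + offset`
on reflectance `r`, the black patch (r = 0) estimates `offset`, the white
patch (r = 1) estimates `gain + offset`, and `eta` recovers `r` exactly —
gains and offsets cancel. Measured per-finger mean colors therefore stay
comparable across sessions, and can be matched against a reference palette
of nail discolorations (yellow, green, brown, red, white, purple) with
their classically associated conditions. The match is indicative only; a
diagnosis belongs to a dermatologist.

The pipeline per image: resize to the 800 px working frame → extract
references → normalize → segmentation backend (classical
brightness/saturation baseline, or mask files from any external model) →
threshold → majority-filter hole fill → square-element erosion
(`erode_filter`, stock values 70 and 92) → 8-connected contours → assign
one contour per finger band → per-finger mean raw and normalized RGB →
append to history. Segmentations are scored against ground truth with
IoU and hard-mask Dice loss. A seeded synthetic fixture generator renders
the whole acquisition convention (skin bars, elliptical nails of known
color, reference patches, affine illumination, sensor noise) so every
stage is testable offline with exact ground truth.

## Worked example

```r
library(nailsense)

fx  <- generateHand(syntheticHandSpec(seed = 42))   # 800 px fixture
res <- runSnapshot(fixtureImage(fx),
                   pipelineConfig(reference_stat = "patchmean"))
res$measurements
#>   finger pixel_count missing     R     G     B  eta_R  eta_G  eta_B
#> 1      1         160   FALSE 215.5 181.7 172.3 0.8865 0.7391 0.6980
#> 2      2         160   FALSE 220.0 183.1 174.1 0.9058 0.7454 0.7060
#> 3      3         160   FALSE 213.8 177.6 170.3 0.8792 0.7212 0.6893
#> 4      4         160   FALSE 217.2 184.7 177.6 0.8938 0.7521 0.7211
#> 5      5         160   FALSE 212.1 179.1 172.4 0.8715 0.7280 0.6987
```

All five nails were found (`missing = FALSE`). `pixel_count` is 160
because the stock `erode_filter = 70` keeps only the nail core that a
70×70 square fits into — by design, so touching regions can never merge.
The raw means (`R,G,B`) show the fixture's illumination (gain 0.9, offset
12): finger 2's true color (231, 190, 180) was imaged as (220.0, 183.1,
174.1). The normalized means undo it:

```r
255 * unlist(res$measurements[2, c("eta_R", "eta_G", "eta_B")])
#> 231.0 190.1 180.0     # true color: (231, 190, 180)
```

A healthy pink is far from every pathological palette entry, so the lookup
reports no strong indication:

```r
head(res$matches[[2]], 2)
#>    color distance                            symptoms confident
#> 1  White      102          Protein deficiency, anemia     FALSE
#> 2 Yellow      193 Diabetes or psoriasis, lung disease     FALSE
```

Segmentation quality against the generator's ground truth (run with
`erode_filter = 0` to score the full detected nail):

```r
res0 <- runSnapshot(fixtureImage(fx), pipelineConfig(erode_filter = 0))
maskIoU(res0$mask, fixtureMask(fx))
#> [1] 0.9996
```

The command-line wrapper (`inst/scripts/nailsense`) exposes the same
workflows: `process IMG`, `batch DIR`, `eval --pred-dir --gt-dir`,
`simulate --out DIR`, `classify --rgb R,G,B`.

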