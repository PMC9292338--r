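---
title: "Reading urine test strips from photographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading urine test strips from photographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripreader)
```

## The problem

A urine test strip (dipstick) carries ten chemical indicator pads that
change color after contact with urine; each pad reads one analyte
(glucose, bilirubin, ketone, specific gravity, hemoglobin, pH, protein,
urobilinogen, nitrite, leukocytes). The result is normally read by eye
against a manufacturer's color reference card — a slow, operator-dependent
comparison. `stripreader` automates that reading from an ordinary
photograph showing the strip next to its reference card: it locates and
rectifies the card, finds the strip's pads, extracts each pad's dominant
color, matches it to the card's graded swatches, and classifies each
analyte as negative or positive.

The pipeline is deterministic and training-free. Because real study
photographs cannot be shipped with a package, a seeded synthetic scene
generator stands in for the camera: it renders the card and a dipped strip
under controlled perspective, blur, brightness and noise, with full ground
truth, so that every stage is testable offline.

## Layout as configuration

Everything the pipeline knows about a strip product lives in a declarative
layout (JSON or YAML): the ten parameters in physical order from the
dipped end, their manufacturer read times (30, 40, 45, 60 or 120 s), their
graded levels with values and units, and the card's swatch rectangles in a
canonical pixel frame. Coordinates are 0-based pixels, y downward,
rectangles `(x, y, width, height)`; the canonical frames are defined by
the package's own template renderers. The shipped default is a
Multistix-10-SG-style layout with plausible level labels, values and
colors; **clinical deployments must substitute the actual manufacturer
values and measured card coordinates**. The physical order of the pads
from the dipped end is not standardized across products; the shipped
order is a documented assumption carried by the layout file.

The reference card shipped here is synthetic: it is painted from the
layout (`paint_card_template()`) with the swatch grid surrounded by a
deterministic constellation of high-contrast discs and squares in the card
margins. Real cards are feature-poor for binary descriptors (smooth
swatches, periodic grid); the fiducial art gives the matcher unique,
multi-scale structure the way commercial reference cards carry logos and
text. A deployment photographing a real card would supply that card's
template image instead.

## Card detection and rectification

The card is found by classic binary-feature matching:

1. **Keypoints**: segment-test (FAST-9) corners over a 4-level image
   pyramid (scale factor 1.2), scored by contrast and non-maximum
   suppressed.
2. **Orientation**: the intensity centroid of a radius-15 patch gives each
   keypoint an angle.
3. **Descriptors**: 256 pairwise intensity comparisons on a smoothed
   patch, the pair pattern rotated to the keypoint angle — a rotated
   binary (BRIEF-style) descriptor matched by Hamming distance.
4. **Matching**: exhaustive (brute-force) nearest neighbours, sorted by
   distance; the best 50 matches are kept. No ratio test or cross-check is
   applied, matching the method's published description.
5. **Homography**: a RANSAC consensus (reprojection threshold 5 px, up to
   1000 samples, least-squares refit on the inliers) estimates the
   template-to-scene projective transform; the scene is inverse-warped
   into the canonical card frame.

Two robustness details matter in practice. First, the template feature
bank (`template_feature_bank()`) contains features from both the sharp
template and a defocused (sigma = 1.2 px) rendering: descriptors computed
only on a sharp template stop matching under camera defocus. Second,
because many template keypoints can share one nearest scene neighbour,
only the lowest-distance match per scene keypoint enters the estimation,
and a consensus set whose scene points barely spread beyond the threshold
is rejected as degenerate — otherwise a collapsing homography can
"explain" many-to-one matches.

A detection is accepted with at least 10 kept matches and 8 inliers, a
convex recovered quadrilateral, and an area of at least 1% of the scene.
Failures signal a `detection_failure` condition carrying the match counts.
Strip detection by the same template matching is possible but known to be
unreliable for feature-poor strips; the supported localization path is the
field detector below, run on a user-supplied strip crop or region of
interest.

## Reference fields and test-field localization

Reference swatches are cropped from the rectified card at the layout's
constant coordinates (scaled to the rectified size), keeping the central
50% of each rectangle to avoid borders and bleed.

Test pads on the strip are found without any stored coordinates, since a
photographed strip is never as regular as a rectified card:

1. **Candidate squares.** The strip crop is preprocessed under a grid of
   settings — luma and saturation channels × blur sigmas {0, 1, 1.7, 2.3}
   × binarizations {Otsu, adaptive mean, gradient-magnitude edges,
   quantile thresholds at 0.25/0.5/0.75, both polarities} — and the
   contours of connected components are simplified to quadrilaterals
   (Douglas–Peucker with growing tolerance). A candidate survives if its
   shorter side is at least 20% of the crop's short dimension, its side
   aspect ratio is within 1 ± 0.06, and it fills at least 80% of its
   quadrilateral. The saturation channel is essential: weakly pigmented
   pads (pale cream on a white strip) are nearly invisible in luma.
   Duplicate detections across settings are kept deliberately — they act
   as votes in the clustering. The aspect filter is applied to the fitted
   quadrilateral's sides rather than to a bounding box, so pads sheared
   into parallelograms by perspective still read as squares; when the
   strict filter leaves fewer than 60% of the expected fields, one relaxed
   pass (aspect ≤ 1.25) compensates for stronger foreshortening.
2. **Clustering.** Candidate centers are clustered by k-means (k-means++
   seeding, 10 restarts, deterministic given the seed). The cluster count
   is chosen by an elbow rule on the **log** within-cluster sum of
   squares: k maximizing `log W(k-1) − 2 log W(k) + log W(k+1)`, ties to
   the smaller k. The usual second difference of raw WCSS fails for this
   geometry — for ~10 equally spaced collinear tight clusters, WCSS falls
   like 1/k², whose raw second difference peaks at k = 2; on the log scale
   the drop-to-flattening transition at the true k dominates. A k whose
   WCSS is numerically zero short-circuits the search.
3. **Physical cleanup.** Cluster centers closer than 0.75 pad sides are
   sub-clusters of one pad and are merged; centers far off the common axis
   are background artifacts and are dropped.
4. **Grid completion.** Centers are projected on their principal axis and
   sorted. The pitch is the median consecutive spacing after folding each
   gap by the integer multiple suggested by the pad side (a plain median
   fails when half the gaps span two pitches). Gaps larger than 1.5×
   pitch are filled with `round(gap/pitch) − 1` equally spaced points; if
   the grid is still short, points are extrapolated one pitch beyond the
   ends, alternating ends starting at the dipped end. Extrapolation is
   constrained by the strip's own extent, estimated as the connected
   component of strip-colored pixels (sampled half a pitch to either side
   of each detected center) — without this constraint the completed grid
   can slide one pitch toward the wrong end whenever the outermost pale
   pads go undetected. Needing to extrapolate more than half the fields
   is a hard failure (`grid_completion_failure`).
5. **Patches.** A patch of side 0.5× the median candidate side is cropped
   at each center; patches map to parameters in layout order along the
   axis (dipped end at the low end; the crop is assumed oriented with the
   dipped end left or top).

## Color extraction and similarity

Each patch's dominant color is summarized per HSV channel by the peak of
its histogram — 360 one-degree bins for hue, 256 bins for saturation and
value; ties break toward the lowest bin, and the peak bin's center is
reported. Achromatic colors (saturation 0) report hue 0 by convention.

Three similarity measures compare a test color `a` against a reference
color `b`, with `dH` the circular hue difference:

* **Hue**: `1 − dH/360`, in [0.5, 1] for chromatic colors. Hue carries
  most of the diagnostic information for these chemistries. When either
  color is nearly achromatic (saturation < 0.05) the hue channel is
  meaningless, and the score falls back to the matching factor's
  saturation/value terms (configurable guard, on by default; an extension
  beyond the published formula).
* **Matching factor**: `1 − (α·dH + β·dS + β·dV)/3` with α = 0.6429,
  β = 0.1786, all channel differences on the unit scale (`dH` divided by
  360 before weighting). The weights sum to ~1, which is what keeps the
  score in [0, 1] under unit-normalized channels; a mixed-unit reading of
  the same formula (degrees added to unit fractions) would not produce a
  bounded score, so the normalized form is used.
* **Euclidean**: each color maps to HSV cylinder coordinates
  `(s cos h, s sin h, v)`; the similarity is `1 − d/√5`, where `√5` is
  the cylinder's diameter-diagonal — the maximal possible distance.

The hue wrap-around (circular `dH`) is applied in all three measures; a
linear difference would call hues of 350° and 10° maximally different.

The matched level is the argmax of the chosen similarity over the
parameter's reference levels, ties toward the lowest concentration — the
clinically conservative choice for detection-limit analytes, whose lowest
level means "negative".

## Classification and read times

pH is pathological strictly above 7.0 (7.0 itself is negative); specific
gravity is negative within [1.005, 1.025] g/ml inclusive; urobilinogen is
negative strictly below 1 mg/dl; every other parameter is negative exactly
when the matched level is its lowest (below-detection) level. The
strict/inclusive readings of the published wording are fixed as stated and
covered by boundary tests.

Pads develop at different rates; the manufacturer specifies read times of
30/40/45/60/120 s, with five parameters in the 60 s group. `analyze()`
accepts one photograph per read time (a named list keyed by seconds) and
reads each parameter from its own time point; a single-photo mode reads
everything from one image and records a warning, since timed capture is
the commonest protocol violation in home use.

## The synthetic scene generator

`render_scene()` composites the painted card and strip onto a procedural
background (solid, smooth texture, or photo-like with soft shapes) under
independent random perspective warps, then applies brightness shift,
Gaussian blur and pixel noise **in that fixed order** (reordering changes
the extracted peaks). The warp model displaces each corner independently
and uniformly within `warp_magnitude ×` the object size and passes the
exact homography through the displaced corners. All randomness derives
from the scene seed through a private RNG scope, so identical
configurations give byte-identical images; the ground truth records the
homographies, field quads in scene coordinates, planted levels and their
reference colors.

Default degradations — warp 0.12, blur sigma 0.8 px, noise sigma 0.01,
brightness 0, textured background — represent a plausible handheld indoor
photograph: mild perspective, slight defocus, visible sensor noise. The
generator does **not** model shadows, specular highlights, color casts
from illumination, or camera color pipelines; the package performs no
white-balance correction, so tests passing on synthetic scenes demonstrate
the geometry and the color-matching logic, not robustness to real-world
illumination chromaticity. `render_strip_crop()` renders the
axis-aligned strip crop a user or upstream detector would supply, with the
warp capped at 0.06.

## Problem sizes and numerical choices

The test suite exercises: metric identities on 10⁴ random color pairs;
brute-force oracles for the histogram mode, the argmax matching (100
cases) and optimal k-means assignments (instances up to 12 points,
enumerated exhaustively); card detection on 100 seeded scenes (warp up to
15%, blur up to 1.5 px, brightness ±20%), expecting ≥ 95% success with
mean corner error ≤ 3 px; field placement on 50 strips with up to two
degraded pads, expecting ≥ 95% of centers inside the true pad rectangles;
and end-to-end level recovery on 60 clean scenes cycling through every
level of every parameter, expecting ≥ 90% recovery for each similarity
method. `scripts/acceptance.R` recomputes the same quantities from
scratch (80/40/40 scenes) and writes them as JSON. These sizes were chosen
to give stable rates from a deterministic, seeded run.

Numerical details fixed by design: histogram ties break toward the lowest
bin; k-means is seeded (k-means++) and restarted 10 times under a caller
seed, so clustering is reproducible; homography estimation normalizes
coordinates (Hartley) before the DLT; bilinear sampling clamps at image
borders; the RANSAC sample is rejected if any three of its four points are
collinear. Degenerate inputs raise typed conditions
(`detection_failure`, `field_detection_failure`,
`grid_completion_failure`) rather than generic errors, so callers can
distinguish "no card in view" from a malformed layout.

## Known limitations

* Strip localization needs a crop or ROI in full scenes; whole-scene pad
  search is only reliable when the strip dominates the frame. A learned
  strip detector is out of scope.
* The color comparison inherits the photograph's illumination; without a
  color-constancy step, strong color casts will bias all three measures.
* The shipped layout's level values and colors are plausible but not
  manufacturer-calibrated; clinical use requires substituting measured
  values.
* The synthetic generator's degradations are homogeneous across the
  image; vignetting, mixed lighting and motion blur are not modelled.
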