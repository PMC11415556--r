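---
title: "Positioning quality control of elbow radiographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positioning quality control of elbow radiographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elbowqc)
```

## The problem

Whether an elbow radiograph is usable depends first on positioning: the
joint must be centered, the anteroposterior (AP) projection must show an
open, horizontal joint space with the olecranon fossa centered between the
epicondyles, and the lateral (LAT) projection must be taken at roughly 90
degrees of flexion. `elbowqc` turns landmark annotations — one detection box
plus seven keypoints for AP, one box plus three keypoints for LAT — into
quantitative positioning indices and pass/fail verdicts, evaluates how well
a detector reproduces the landmarks, and quantifies model-human agreement.
Image content (sharpness, contrast, pathology) is deliberately out of
scope: all computations operate on coordinates normalized to the unit
square (origin top-left, x rightward, y downward — the raster convention of
annotation tools).

## The annotation schema

AP keypoints: 1 medial epicondyle, 2 lateral epicondyle, 3/4 medial and
lateral joint space inferior to the humerus, 5/6 medial and lateral joint
space superior to the radius, 7 the center of the coronoid/olecranon fossa.
LAT keypoints: 1 mid-humerus, 2 center of the humeral trochlea, 3
mid-radius. Arity is mandatory; parsers reject anything else.

## The five criteria and their indices

For an AP annotation with box center $(X_A, Y_A)$ and keypoints
$(x_i, y_i)$:

1. **Elbow positioning.** $\max(|X_A - 0.5|, |Y_A - 0.5|) \le$
   `center_tolerance`.
2. **Olecranon fossa.** With
   $S_{17} = \sqrt{(x_1-x_7)^2 + (y_1-y_7)^2}$ and $S_{27}$ defined
   analogously from keypoint 2, the fossa should sit slightly toward the
   ulnar side: the ratio $S_{17}/S_{27}$ must lie in
   (`fossa_ratio_min`, `fossa_ratio_max`]. The lower bound is strict —
   $S_{17}$ must exceed $S_{27}$ — and the upper bound caps "slightly".
3. **Joint space.** The humeral-side points (3, 4) and radial-side points
   (5, 6) must be vertically separated by at least `joint_space_margin` on
   both the medial (3 vs 5) and lateral (4 vs 6) side.

For a LAT annotation:

4. **Elbow positioning.** Keypoint 2 (trochlea center) within
   `center_tolerance` of the image center on both axes.
5. **Flexion angle.**
   $\alpha = \cos^{-1}\!\big(\vec{P_1P_2}\cdot\vec{P_2P_3} /
   (|P_1P_2|\,|P_2P_3|)\big)$ must satisfy
   $|\alpha - 90^\circ| \le$ `angle_tolerance`.

### Default thresholds

The clinical literature states directions ("close to 90 degrees", "slightly
greater") but no numeric cutoffs, so the thresholds are conventions of this
package, chosen once and overridable through `qc_config()` or a YAML file:

| parameter | default | rationale |
|---|---|---|
| `center_tolerance` | 0.1 | accepts the central 20% band per axis — a centered joint with ordinary collimation slack |
| `fossa_ratio_min` | 1.0 (strict) | the minimal literal reading of "greater than" |
| `fossa_ratio_max` | 1.5 | a ratio beyond 1.5 is no longer "slightly" biased |
| `joint_space_margin` | 0.005 | half a percent of image height; separates a truly open space from annotation noise |
| `angle_target`, `angle_tolerance` | 90, 10 degrees | the usual clinical acceptance band around true lateral positioning |

YAML was chosen for the config file because a mature YAML reader is
standard in the R ecosystem, keeping the key-value contract without a
hand-written parser.

### Two open conventions, and how they are resolved

**Angle convention.** The arccos formula above uses the *direction* vectors
$\vec{P_1P_2}$ and $\vec{P_2P_3}$: a straight arm (collinear points) gives
0 degrees, and anatomical flexion of 90 degrees gives exactly 90. The
anatomical vertex convention (rays from $P_2$ to $P_1$ and $P_3$, straight
arm = 180 degrees) is its supplement; both agree at 90. The verbatim vector
formula is the default (`convention = "vector"`), the vertex variant is
available everywhere an angle is computed, and the synthetic generator
honors whichever is active so round trips are exact under both.

**Joint-space direction.** "Y of keypoints 3 and 4 greater than Y of 5 and
6" depends on the y-axis orientation, which annotation tools and displays
disagree on. Under the raster y-down convention used here, the humeral-side
points sit *above* (smaller y than) the radial-side points in a
conventionally displayed AP view, so the default is
`humeral_side_above = TRUE`; setting it `FALSE` applies the literal y-up
reading. The criterion itself — both pairs separated by at least the margin
in the configured direction — is unchanged.

## Image preprocessing

DICOM inputs are read by a minimal built-in parser for single-frame
grayscale objects in the implicit/explicit-VR little-endian transfer
syntaxes (no R DICOM reader is available to the package), rescaled with
RescaleSlope/Intercept, windowed with the stored window (else min-max) to
8-bit, and inverted for MONOCHROME1. Resizing to the 640 x 640 model frame
**letterboxes** by default: uniform scaling to the long side plus symmetric
constant-fill padding. Letterboxing is chosen because the QC indices are
ratios, distances and angles — a non-uniform stretch would corrupt
$\alpha$ and $S_{17}/S_{27}$; a stretch mode exists
(`mode = "stretch"`) for emulating stretch-resizing pipelines. The recorded
transform maps annotations between frames and inverts to within half a
pixel.

## Detection evaluation

Boxes are scored by intersection-over-union; keypoints by object keypoint
similarity,
$\mathrm{OKS} = \frac{1}{K}\sum_i \exp\!\big(-d_i^2 / (2 s^2 \kappa_i^2)\big)$,
with $d_i$ the displacement of keypoint $i$, $s^2$ the ground-truth box
area in normalized units (the common object-scale convention; documented
here because no published value exists for elbow landmarks) and
$\kappa_i = 0.1$ uniformly by default, overridable per keypoint. Matching
is greedy in descending confidence with best-similarity tie-break, then
lowest index — deterministic by construction, one-to-one. Average precision
uses 101-point interpolation over the monotone precision envelope (the
convention YOLO-family tooling reports); an exact all-points integration is
available behind a flag. `mAP50` is AP at similarity 0.50, `mAP50_95` the
mean over 0.50:0.05:0.95; the summary's single precision/recall pair is
taken at the confidence cutoff maximizing F1 on the 0.5-threshold ranking,
with the full precision-recall curve returned alongside, since a fixed
operating point is otherwise arbitrary.

## Agreement statistics

Model-human agreement per quantitative index (eight AP indices, three LAT
indices) uses the intraclass correlation coefficient in the two-way,
absolute-agreement, average-measures form: with subject, rater and residual
mean squares $MS_R$, $MS_C$, $MS_E$ from the crossed two-way ANOVA,

$$\mathrm{ICC}(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}.$$

With raters fixed (mixed model) the point estimate is identical to the
random-raters form; only the interpretation differs. The 95% confidence
interval uses the F-based bounds for the single-measure form with
Satterthwaite denominator degrees of freedom, stepped up to average
measures by the Spearman-Brown relation — the standard route for this ICC
family. Perfect agreement ($MS_E = 0$) degenerates those bounds; the
interval then collapses onto the point estimate. Reliability labels: above
0.9 excellent, above 0.75 good, 0.5-0.75 moderate, below poor. Subjects
missing either rating are dropped and counted, never imputed. ICCs are
computed on normalized coordinates, consistent with the criteria being
defined on the normalized image.

## The synthetic generator

The generator is the closed-form inverse of the metric computations, so
parameter recovery is exact (tested to 1e-9): epicondyles at
`joint_center` $\pm$ (`epicondyle_halfwidth`, 0), keypoint 7 shifted by
`fossa_bias` so $S_{17} =$ halfwidth + bias, joint lines separated by
`joint_gap`, LAT segments constructed to reproduce `flexion_deg` under the
active angle convention. Defaults (center (0.5, 0.5), halfwidth 0.2, bias
0.02 — hence $S_{17} = 0.22$, $S_{27} = 0.18$, ratio 1.22 —, gap 0.04,
flexion 90, segment length 0.3) describe a well-positioned study of a joint
occupying roughly the central half of the frame.

`joint_tilt` is a *relative* tilt between the two joint lines (each line
shears by half the tilt in opposite directions). This is deliberate: a
rigid rotation of both lines about the joint center can never invert the
vertical ordering of the aligned keypoint pairs in this construction, so
the relative tilt is the geometric fault that actually violates the
joint-space criterion — while leaving the box center (by central symmetry
of the layout) and the fossa distances untouched, which is what makes
single-fault specificity testable.

Fault magnitudes are fixed conventions chosen to exceed the default
thresholds decisively: `off_center` offsets one center coordinate by
0.15-0.2, `fossa_shift` draws a negative bias of 0.02-0.04 (making
$S_{17} < S_{27}$), `space_tilt` draws 25-35 degrees of relative tilt
(collapsing the lateral pair below the margin), `wrong_flexion` draws
55-70 degrees. Nominal parameters jitter mildly (center within 0.03,
flexion within 4 degrees) so that nominal records always pass the default
configuration. Detector error is emulated by `perturb()`: isotropic
Gaussian displacement of every keypoint and the box center, clipped to the
unit square, with a confidence that decays exponentially with the realized
mean displacement (so confidence ranks correlate with accuracy, as for a
real detector) or, alternatively, uniform on [0.5, 1].

What the generator does *not* emulate: radiographic texture, anatomical
shape variation, occlusion, per-landmark heteroscedastic detector error,
and annotator disagreement structure. Passing tests therefore demonstrate
the correctness of the geometry, the rules, the evaluators and the
statistics — not clinical-grade detector performance, which requires real
images and a trained network.

## Numerical choices

- The arccos argument is clamped to [-1, 1] before evaluation; angles are
  degrees externally, radians internally.
- Degenerate geometry (zero-length LAT segments, $S_{27} = 0$, zero-area
  boxes) raises an error naming the offending element rather than
  returning a sentinel — a silent 0 degrees would masquerade as a QC
  failure.
- Boxes are stored center-form (cx, cy, w, h), the YOLO-pose convention;
  corner-form input is accepted and clipped to the unit square.
- YOLO-pose text is written at 6 decimal places and round-trips at that
  precision; Labelme JSON round-trips at full double precision. Keypoint
  visibility flags are parsed and preserved but ignored by QC (the schema
  has no occlusion notion).
- JPEG export uses quality 0.95.

## Problem sizes

The test suite and examples run at desk scale by choice: cohorts of 10-60
synthetic records, rating matrices up to n = 2000 for the ICC
parameter-recovery check, and small detection instances (at most six
detections) where evaluators are compared against exhaustive enumeration
oracles. These sizes are where the closed-form expectations are exact or
the oracles tractable; the implementations themselves have no size limits.

## Known limitations

- The five criteria assume single-elbow, single-class annotations; no
  multi-joint frames.
- DICOM support covers uncompressed little-endian single-frame grayscale
  only.
- ICC requires complete pairs; systematic missingness is reported, not
  modeled.
- Threshold defaults are conventions, not clinically validated cutoffs;
  site-specific calibration should go through the configuration file.
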