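# elbowqc

Automated positioning quality control (QC) of elbow-joint radiographs from
keypoint and bounding-box annotations.

Radiographers and radiology QC teams need to decide quickly whether an
elbow study is technically adequate — centered, with an open joint space,
the olecranon fossa between the epicondyles, and (for the lateral view)
roughly 90 degrees of flexion — before it reaches a reader. `elbowqc`
computes that decision from landmark annotations, whether drawn by a human
(Labelme JSON) or predicted by a pose detector (YOLO-pose text), and
provides the surrounding machinery: detector evaluation, model-human
agreement statistics, DICOM preprocessing, and a synthetic annotation
generator so the whole pipeline is testable without clinical images.

## The method

An AP annotation carries one detection box and seven keypoints
(1/2 medial/lateral epicondyle, 3/4 humeral-side and 5/6 radial-side
joint-space points, 7 fossa center); a LAT annotation carries one box and
three keypoints (1 mid-humerus, 2 trochlea center, 3 mid-radius). All
coordinates are normalized to the unit square. Five criteria are evaluated:

- **AP positioning**: box center (X_A, Y_A) within a tolerance of (0.5, 0.5);
- **Olecranon fossa**: S17 = ‖k1 − k7‖ slightly greater than
  S27 = ‖k2 − k7‖ (ratio in a configured band above 1);
- **Joint space**: Y-coordinates of points 3/4 separated from 5/6 by a
  margin, on both the medial and lateral side;
- **LAT positioning**: trochlea center (X_2, Y_2) within the central region;
- **Flexion angle**: α = arccos(P1P2 · P2P3 / (|P1P2| |P2P3|)) within a
  tolerance of 90 degrees.

Detector output is scored with IoU (boxes) and object keypoint similarity
(OKS, exponential falloff of displacement scaled by object size), summarized
as precision, recall, mAP50 and mAP50–95. Model-human agreement per
quantitative index uses the two-way, absolute-agreement, average-measures
intraclass correlation coefficient with F-based 95% confidence intervals
(ICC > 0.75 good, > 0.9 excellent). The methods vignette
(`vignettes/elbowqc-methods.Rmd`) documents every formula, convention and
default.

## Worked example

```r
library(elbowqc)

# a well-positioned synthetic AP study
rec <- generate_ap(synthetic_params(), image_id = "demo_ap")
evaluate_record(rec)
#> QC report (AP view, image demo_ap): PASS
#>   positioning      value=0.00000    threshold=0.1      pass
#>   olecranon_fossa  value=1.22222    threshold=1.5      pass
#>   joint_space      value=0.04000    threshold=0.005    pass

# a lateral study flexed at 65 degrees fails exactly the angle criterion
bad <- generate_lat(synthetic_params(flexion_deg = 65), image_id = "demo_lat")
evaluate_record(bad)
#> QC report (LAT view, image demo_lat): FAIL
#>   positioning      value=0.00000    threshold=0.1      pass
#>   flexion_angle    value=65.00000   threshold=10       FAIL
```

The `positioning` value is the box-center deviation from (0.5, 0.5); the
`olecranon_fossa` value is the S17/S27 ratio (1.22 here: the fossa sits
slightly toward the ulnar side, as it should); `joint_space` is the smaller
of the two vertical pair separations; `flexion_angle` is α in degrees.

Evaluating a jittered detector against ground truth, and the agreement
between two raters:

```r
gts <- generate_cohort(40, c(none = 0.8, wrong_flexion = 0.2), seed = 42)$records
preds <- lapply(seq_along(gts), function(i) perturb(gts[[i]], 0.01, seed = i))
mean_average_precision(Filter(function(r) r$view == "AP", preds),
                       Filter(function(r) r$view == "AP", gts),
                       kind = "keypoints")
#> Keypoint (OKS) evaluation (12 predictions, 12 ground truths)
#>   precision 1.0000  recall 1.0000  mAP50 1.0000  mAP50-95 0.8047

model <- lapply(gts, evaluate_record)
human <- lapply(seq_along(gts), function(i)
  evaluate_record(perturb(gts[[i]], 0.005, seed = 100 + i)))
head(agreement_report(paired_index_table(model, human))$table, 3)
#>   index  n   icc ci_low ci_high     label
#> 1    XA 12 0.973  0.907   0.992 excellent
#> 2    YA 12 0.970  0.900   0.991 excellent
#> 3   S17 12 0.833  0.399   0.952      good
```

With 1% keypoint jitter every detection still matches at OKS 0.5 (mAP50 =
1) but the stricter thresholds bite (mAP50–95 = 0.80); with 0.5% jitter
between "raters" every index keeps good-to-excellent agreement.

## Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "elbowqc", package = "elbowqc"))')
Rscript $CLI simulate --n 50 --seed 7 --output sim
Rscript $CLI qc --input sim/annotations --output qc_out
Rscript $CLI eval --gt gt.csv --pred pred.csv --output eval_out
Rscript $CLI icc --model model.jsonl --human human.jsonl --output icc_out
```

Subcommands: `qc`, `eval`, `icc`, `simulate`, `convert` (dialect
conversion), `preprocess` (DICOM to 640 x 640 PNG/JPEG). Exit codes: 0
success, 1 usage error, 2 data error.

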