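# The five positioning-quality criteria: three for AP projections (elbow
# centering, olecranon-fossa centering, joint-space ordering) and two for LAT
# projections (trochlea centering, flexion angle). Each criterion yields a
# quantitative index plus a pass/fail verdict against a configurable
# threshold; the thresholds are conventions of this package, not published
# values -- the literature states directions ("close to 90 degrees",
# "slightly greater") without cutoffs.

#' QC configuration
#'
#' Thresholds and conventions applied by [evaluate_ap()] and
#' [evaluate_lat()]. All distances are in normalized units (fractions of the
#' image side), angles in degrees.
#'
#' @param center_tolerance Maximum allowed `|coordinate - 0.5|` for the
#'   centering criteria; the default 0.1 accepts the central 20% band per
#'   axis.
#' @param fossa_ratio_min,fossa_ratio_max Allowed range of the fossa distance
#'   ratio S17/S27. The criterion is `fossa_ratio_min < S17/S27 <=
#'   fossa_ratio_max`: S17 must strictly exceed S27 (the fossa sits slightly
#'   toward the ulnar side), but not by much (the cap bounds "slightly").
#' @param joint_space_margin Minimum vertical separation between the
#'   humeral-side (3, 4) and radial-side (5, 6) joint-space keypoints, per
#'   medial and lateral pair.
#' @param angle_target Target flexion angle in degrees (90).
#' @param angle_tolerance Allowed deviation of the flexion angle from
#'   `angle_target`, degrees.
#' @param humeral_side_above Logical. `TRUE` (default) expects the
#'   humeral-side points above the radial-side points under the raster
#'   y-down convention, i.e. `Y3 < Y5` and `Y4 < Y6`; `FALSE` applies the
#'   opposite ordering (the literal "greater than" reading for a y-up axis).
#' @param angle_convention Flexion-angle convention passed to
#'   [flexion_angle()]: `"vector"` or `"vertex"`.
#' @return A list of class `"qc_config"`.
#' @seealso [read_qc_config()] to load overrides from a YAML file.
#' @export
qc_config <- function(center_tolerance = 0.1,
                      fossa_ratio_min = 1.0,
                      fossa_ratio_max = 1.5,
                      joint_space_margin = 0.005,
                      angle_target = 90,
                      angle_tolerance = 10,
                      humeral_side_above = TRUE,
                      angle_convention = c("vector", "vertex")) {
  angle_convention <- match.arg(angle_convention)
  if (center_tolerance <= 0 || joint_space_margin <= 0 || angle_tolerance <= 0)
    stop("all tolerances must be positive", call. = FALSE)
  if (fossa_ratio_min < 1)
    stop("fossa_ratio_min must be >= 1 (S17 must exceed S27)", call. = FALSE)
  if (fossa_ratio_max <= fossa_ratio_min)
    stop("fossa_ratio_max must exceed fossa_ratio_min", call. = FALSE)
  if (angle_target <= 0 || angle_target >= 180)
    stop("angle_target must lie in (0, 180) degrees", call. = FALSE)
  structure(list(center_tolerance = center_tolerance,
                 fossa_ratio_min = fossa_ratio_min,
                 fossa_ratio_max = fossa_ratio_max,
                 joint_space_margin = joint_space_margin,
                 angle_target = angle_target,
                 angle_tolerance = angle_tolerance,
                 humeral_side_above = isTRUE(humeral_side_above),
                 angle_convention = angle_convention),
            class = "qc_config")
}

#' Read QC configuration overrides from a YAML file
#'
#' The file holds any subset of the [qc_config()] fields as top-level keys;
#' unknown keys are an error so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML key-value file, or `NULL` for defaults.
#' @return A `"qc_config"`.
#' @export
read_qc_config <- function(path = NULL) {
  if (is.null(path)) return(qc_config())
  vals <- yaml::read_yaml(path)
  known <- names(formals(qc_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(qc_config, vals)
}

#' Quantitative AP indices
#'
#' Computes the eight AP quantitative indices from a box and its seven
#' keypoints: the box center `(XA, YA)`, the fossa distances `S17` (keypoint
#' 1 to 7) and `S27` (keypoint 2 to 7), and the joint-space y-coordinates
#' `Y3..Y6`.
#'
#' @param box A `"bbox"`.
#' @param kpts An [ap_keypoints()] matrix (or 7-by-2 coercible).
#' @return Named list `XA, YA, S17, S27, Y3, Y4, Y5, Y6`.
#' @export
compute_ap_metrics <- function(box, kpts) {
  kpts <- ap_keypoints(kpts)
  ctr <- box_center(box)
  list(XA = unname(ctr["x"]), YA = unname(ctr["y"]),
       S17 = euclidean_distance(kpts[1L, ], kpts[7L, ]),
       S27 = euclidean_distance(kpts[2L, ], kpts[7L, ]),
       Y3 = unname(kpts[3L, "y"]), Y4 = unname(kpts[4L, "y"]),
       Y5 = unname(kpts[5L, "y"]), Y6 = unname(kpts[6L, "y"]))
}

#' Quantitative LAT indices
#'
#' The trochlea-center coordinates `(X2, Y2)` and the flexion angle `alpha`
#' in degrees.
#'
#' @param kpts A [lat_keypoints()] matrix (or 3-by-2 coercible).
#' @param convention Flexion-angle convention, see [flexion_angle()].
#' @return Named list `X2, Y2, alpha`.
#' @export
compute_lat_metrics <- function(kpts, convention = c("vector", "vertex")) {
  convention <- match.arg(convention)
  kpts <- lat_keypoints(kpts)
  list(X2 = unname(kpts[2L, "x"]), Y2 = unname(kpts[2L, "y"]),
       alpha = flexion_angle(kpts[1L, ], kpts[2L, ], kpts[3L, ],
                             convention = convention))
}

verdict_row <- function(criterion, value, threshold, rule, pass) {
  data.frame(criterion = criterion, value = value, threshold = threshold,
             rule = rule, pass = pass, stringsAsFactors = FALSE)
}

qc_report <- function(view, image_id, metrics, verdicts) {
  structure(list(view = view, image_id = image_id, metrics = metrics,
                 verdicts = verdicts, overall = all(verdicts$pass)),
            class = "qc_report")
}

#' Evaluate the three AP quality criteria
#'
#' Positioning passes when both box-center coordinates are within
#' `center_tolerance` of 0.5. The olecranon-fossa criterion passes when
#' `fossa_ratio_min < S17/S27 <= fossa_ratio_max`. The joint-space criterion
#' passes when both the medial (3 vs 5) and lateral (4 vs 6) keypoint pairs
#' are separated by at least `joint_space_margin` in the direction configured
#' by `humeral_side_above`.
#'
#' @inheritParams compute_ap_metrics
#' @param cfg A [qc_config()].
#' @param image_id Optional identifier carried into the report.
#' @return A `"qc_report"` with three verdicts and an overall pass flag.
#' @export
evaluate_ap <- function(box, kpts, cfg = qc_config(), image_id = NA_character_) {
  stopifnot(inherits(cfg, "qc_config"))
  m <- compute_ap_metrics(box, kpts)
  if (m$S27 == 0)
    stop("degenerate geometry: S27 is zero, fossa ratio undefined", call. = FALSE)

  center_dev <- max(abs(m$XA - 0.5), abs(m$YA - 0.5))
  ratio <- m$S17 / m$S27
  sgn <- if (cfg$humeral_side_above) 1 else -1
  sep_medial <- sgn * (m$Y5 - m$Y3)
  sep_lateral <- sgn * (m$Y6 - m$Y4)

  v <- rbind(
    verdict_row("positioning", center_dev, cfg$center_tolerance,
                "max(|XA-0.5|, |YA-0.5|) <= center_tolerance",
                center_dev <= cfg$center_tolerance),
    verdict_row("olecranon_fossa", ratio, cfg$fossa_ratio_max,
                "fossa_ratio_min < S17/S27 <= fossa_ratio_max",
                ratio > cfg$fossa_ratio_min & ratio <= cfg$fossa_ratio_max),
    verdict_row("joint_space", min(sep_medial, sep_lateral),
                cfg$joint_space_margin,
                "both joint-space pairs separated by >= joint_space_margin",
                min(sep_medial, sep_lateral) >= cfg$joint_space_margin))
  qc_report("AP", image_id, m, v)
}

#' Evaluate the two LAT quality criteria
#'
#' Positioning passes when the trochlea center is within `center_tolerance`
#' of the image center on both axes; the flexion-angle criterion passes when
#' `|alpha - angle_target| <= angle_tolerance`.
#'
#' @inheritParams compute_lat_metrics
#' @inheritParams evaluate_ap
#' @return A `"qc_report"` with two verdicts and an overall pass flag.
#' @export
evaluate_lat <- function(kpts, cfg = qc_config(), image_id = NA_character_) {
  stopifnot(inherits(cfg, "qc_config"))
  m <- compute_lat_metrics(kpts, convention = cfg$angle_convention)
  center_dev <- max(abs(m$X2 - 0.5), abs(m$Y2 - 0.5))
  dev <- abs(m$alpha - cfg$angle_target)
  v <- rbind(
    verdict_row("positioning", center_dev, cfg$center_tolerance,
                "max(|X2-0.5|, |Y2-0.5|) <= center_tolerance",
                center_dev <= cfg$center_tolerance),
    verdict_row("flexion_angle", m$alpha, cfg$angle_tolerance,
                "|alpha - angle_target| <= angle_tolerance",
                dev <= cfg$angle_tolerance))
  qc_report("LAT", image_id, m, v)
}

#' Evaluate any annotation record
#'
#' Dispatches an [annotation_record()] to [evaluate_ap()] or
#' [evaluate_lat()] by its view.
#'
#' @param record An `"elbow_annotation"`.
#' @param cfg A [qc_config()].
#' @return A `"qc_report"`.
#' @export
evaluate_record <- function(record, cfg = qc_config()) {
  stopifnot(inherits(record, "elbow_annotation"))
  if (record$view == "AP")
    evaluate_ap(record$box, record$keypoints, cfg, image_id = record$image_id)
  else
    evaluate_lat(record$keypoints, cfg, image_id = record$image_id)
}

#' Summarize a batch of QC reports
#'
#' @param reports Nonempty list of `"qc_report"` objects.
#' @return List with `n`, `n_pass`, `pass_rate`, `criterion_counts` (per
#'   criterion: evaluated and passed), and `failure_histogram` (failed
#'   criterion -> count).
#' @export
summarize_batch <- function(reports) {
  if (length(reports) == 0L)
    stop("empty input: no QC reports to summarize", call. = FALSE)
  stopifnot(all(vapply(reports, inherits, logical(1L), "qc_report")))
  verdicts <- do.call(rbind, lapply(reports, `[[`, "verdicts"))
  overall <- vapply(reports, `[[`, logical(1L), "overall")
  crit <- split(verdicts$pass, verdicts$criterion)
  counts <- data.frame(criterion = names(crit),
                       evaluated = vapply(crit, length, integer(1L)),
                       passed = vapply(crit, sum, integer(1L)),
                       row.names = NULL, stringsAsFactors = FALSE)
  failed <- verdicts$criterion[!verdicts$pass]
  hist <- if (length(failed)) table(failed) else table(factor(character()))
  list(n = length(reports), n_pass = sum(overall),
       pass_rate = mean(overall), criterion_counts = counts,
       failure_histogram = as.list(hist))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report (%s view, image %s): %s\n", x$view,
              ifelse(is.na(x$image_id), "<unnamed>", x$image_id),
              if (x$overall) "PASS" else "FAIL"))
  v <- x$verdicts
  for (i in seq_len(nrow(v)))
    cat(sprintf("  %-16s value=%-10.5f threshold=%-8.4g %s\n",
                v$criterion[i], v$value[i], v$threshold[i],
                if (v$pass[i]) "pass" else "FAIL"))
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param x A `"qc_report"`.
#' @return A JSON string (one line; suitable for JSON-lines manifests).
#' @seealso [qc_report_from_json()]
#' @export
qc_report_to_json <- function(x) {
  stopifnot(inherits(x, "qc_report"))
  jsonlite::toJSON(list(view = x$view, image_id = x$image_id,
                        metrics = x$metrics, verdicts = x$verdicts,
                        overall = x$overall),
                   auto_unbox = TRUE, digits = NA, na = "null")
}

#' Deserialize a QC report from JSON
#'
#' @param txt A JSON string as produced by [qc_report_to_json()].
#' @return A `"qc_report"`.
#' @export
qc_report_from_json <- function(txt) {
  o <- jsonlite::fromJSON(txt)
  qc_report(o$view, if (is.null(o$image_id)) NA_character_ else o$image_id,
            as.list(o$metrics), o$verdicts)
}
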