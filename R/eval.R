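# Detection evaluation: bounding-box accuracy via intersection-over-union
# (IoU), keypoint accuracy via object keypoint similarity (OKS), and the
# derived precision / recall / mAP50 / mAP50-95 summaries. Matching is the
# standard greedy one-to-one assignment in descending confidence order;
# average precision uses 101-point interpolation with a monotone precision
# envelope (the convention YOLO-family tooling reports), with an all-points
# variant behind a flag.

#' Intersection over union of two boxes
#'
#' @param a,b Center-form boxes (`"bbox"` or length-4 `(cx, cy, w, h)`).
#' @return Overlap area / union area, in `[0, 1]`.
#' @export
iou <- function(a, b) {
  ca <- box_corners(a); cb <- box_corners(b)
  area_a <- (ca["x2"] - ca["x1"]) * (ca["y2"] - ca["y1"])
  area_b <- (cb["x2"] - cb["x1"]) * (cb["y2"] - cb["y1"])
  if (area_a <= 0 || area_b <= 0)
    stop("degenerate geometry: zero-area bounding box", call. = FALSE)
  iw <- max(0, min(ca["x2"], cb["x2"]) - max(ca["x1"], cb["x1"]))
  ih <- max(0, min(ca["y2"], cb["y2"]) - max(ca["y1"], cb["y1"]))
  inter <- iw * ih
  unname(inter / (area_a + area_b - inter))
}

#' Object keypoint similarity
#'
#' `mean_i exp(-d_i^2 / (2 s^2 kappa_i^2))` where `d_i` is the Euclidean
#' displacement of keypoint i between prediction and ground truth, `s^2` the
#' object scale (ground-truth box area in normalized units), and `kappa_i`
#' the per-keypoint falloff constant. Equals 1 iff every displacement is
#' zero and decreases strictly in each displacement.
#'
#' @param pred,gt Keypoint matrices of equal arity (n-by-2).
#' @param scale_sq Object scale s^2 > 0 (normalized box area).
#' @param kappas Per-keypoint falloff constants (> 0), recycled to the
#'   arity. The default 0.1 is a uniform convention; no published
#'   per-landmark constants exist for elbow keypoints.
#' @return Similarity in `[0, 1]`.
#' @export
oks <- function(pred, gt, scale_sq, kappas = 0.1) {
  pred <- as.matrix(pred); gt <- as.matrix(gt)
  if (nrow(pred) != nrow(gt) || ncol(pred) != 2L || ncol(gt) != 2L)
    stop("schema error: keypoint arity mismatch (", nrow(pred), " vs ",
         nrow(gt), ")", call. = FALSE)
  if (!is.finite(scale_sq) || scale_sq <= 0)
    stop("parameter error: scale_sq must be positive", call. = FALSE)
  kappas <- rep_len(kappas, nrow(gt))
  if (any(kappas <= 0))
    stop("parameter error: kappas must be positive", call. = FALSE)
  d2 <- rowSums((pred - gt)^2)
  mean(exp(-d2 / (2 * scale_sq * kappas^2)))
}

# Similarity between one prediction and one ground-truth record.
record_similarity <- function(pred, gt, kind, kappas = 0.1) {
  if (kind == "box") {
    iou(pred$box, gt$box)
  } else {
    b <- as.numeric(gt$box)
    oks(pred$keypoints, gt$keypoints, scale_sq = b[3L] * b[4L], kappas = kappas)
  }
}

#' Greedy one-to-one matching of detections to ground truths
#'
#' Predictions are sorted by confidence (descending, ties by input order);
#' each claims the unmatched ground truth of highest similarity, provided
#' that similarity reaches `threshold`. Each prediction and each ground
#' truth appears in at most one pair.
#'
#' @param preds List of prediction [annotation_record()]s (with confidence).
#' @param gts List of ground-truth [annotation_record()]s.
#' @param threshold Minimum similarity for a match.
#' @param kind `"box"` (IoU) or `"keypoints"` (OKS).
#' @param kappas OKS falloff constants, see [oks()].
#' @return List of class `"match_result"`: `pairs` (data frame `pred`, `gt`,
#'   `similarity`, indices into the input lists), `unmatched_predictions`,
#'   `unmatched_ground_truths`, `threshold`, `kind`.
#' @export
match_detections <- function(preds, gts, threshold = 0.5,
                             kind = c("box", "keypoints"), kappas = 0.1) {
  kind <- match.arg(kind)
  views <- unique(c(vapply(preds, `[[`, character(1L), "view"),
                    vapply(gts, `[[`, character(1L), "view")))
  if (length(views) > 1L)
    stop("schema error: mixed AP/LAT records in one matching problem",
         call. = FALSE)
  conf <- vapply(preds, function(p) p$confidence %||% 1, numeric(1L))
  ord <- order(-conf, seq_along(preds))
  gt_taken <- rep(FALSE, length(gts))
  pairs <- list()
  for (pi in ord) {
    if (!length(gts)) break
    sims <- vapply(seq_along(gts), function(gi) {
      if (gt_taken[gi]) -Inf
      else record_similarity(preds[[pi]], gts[[gi]], kind, kappas)
    }, numeric(1L))
    gi <- which.max(sims)
    if (length(gi) && is.finite(sims[gi]) && sims[gi] >= threshold) {
      gt_taken[gi] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        data.frame(pred = pi, gt = gi, similarity = sims[gi])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(pred = integer(), gt = integer(),
                           similarity = numeric())
  structure(list(pairs = pairs,
                 unmatched_predictions = setdiff(seq_along(preds), pairs$pred),
                 unmatched_ground_truths = which(!gt_taken),
                 threshold = threshold, kind = kind),
            class = "match_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Precision and recall from a match result
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`; with no
#' predictions at all, precision is defined as 0 whenever any ground truth
#' exists (and 1 on an empty problem).
#'
#' @param m A `"match_result"`.
#' @param n_predictions,n_ground_truths Totals in the evaluated set.
#' @return Named numeric `c(precision =, recall =)`.
#' @export
precision_recall <- function(m, n_predictions, n_ground_truths) {
  tp <- nrow(m$pairs)
  if (tp > n_predictions || tp > n_ground_truths)
    stop("match result inconsistent with the stated counts", call. = FALSE)
  precision <- if (n_predictions == 0L) {
    if (n_ground_truths == 0L) 1 else 0
  } else tp / n_predictions
  recall <- if (n_ground_truths == 0L) 1 else tp / n_ground_truths
  c(precision = precision, recall = recall)
}

# Confidence-ranked TP/FP labels at one similarity threshold, across images.
# Returns a data frame ordered by descending confidence with tp flags.
rank_detections <- function(preds, gts, threshold, kind, kappas) {
  gt_ids <- vapply(gts, `[[`, character(1L), "image_id")
  conf <- vapply(preds, function(p) p$confidence %||% 1, numeric(1L))
  ord <- order(-conf, seq_along(preds))
  gt_taken <- rep(FALSE, length(gts))
  tp <- logical(length(preds))
  for (pi in ord) {
    img <- preds[[pi]]$image_id
    cand <- which(gt_ids == img & !gt_taken)
    if (!length(cand)) next
    sims <- vapply(cand, function(gi)
      record_similarity(preds[[pi]], gts[[gi]], kind, kappas), numeric(1L))
    best <- which.max(sims)
    if (sims[best] >= threshold) {
      gt_taken[cand[best]] <- TRUE
      tp[pi] <- TRUE
    }
  }
  data.frame(confidence = conf[ord], tp = tp[ord])
}

#' Average precision at one similarity threshold
#'
#' Builds the precision-recall curve by sweeping the confidence ranking and
#' integrates it. `"coco101"` evaluates the monotone precision envelope at
#' 101 equally spaced recall points; `"all_points"` integrates the envelope
#' exactly over every recall increment.
#'
#' @inheritParams match_detections
#' @param interpolation `"coco101"` or `"all_points"`.
#' @return Average precision in `[0, 1]`.
#' @export
average_precision <- function(preds, gts, threshold = 0.5,
                              kind = c("box", "keypoints"), kappas = 0.1,
                              interpolation = c("coco101", "all_points")) {
  kind <- match.arg(kind)
  interpolation <- match.arg(interpolation)
  if (!length(gts)) stop("empty input: no ground truths", call. = FALSE)
  if (!length(preds)) return(0)
  r <- rank_detections(preds, gts, threshold, kind, kappas)
  tp_cum <- cumsum(r$tp)
  fp_cum <- cumsum(!r$tp)
  rec <- tp_cum / length(gts)
  prec <- tp_cum / (tp_cum + fp_cum)
  # monotone (right-to-left running max) precision envelope
  env <- rev(cummax(rev(prec)))
  if (interpolation == "coco101") {
    qs <- seq(0, 1, length.out = 101L)
    vals <- vapply(qs, function(q) {
      i <- which(rec >= q)
      if (length(i)) env[i[1L]] else 0
    }, numeric(1L))
    mean(vals)
  } else {
    rec0 <- c(0, rec)
    sum((rec0[-1L] - rec0[-length(rec0)]) * env)
  }
}

#' Precision, recall, mAP50 and mAP50-95 over a matched dataset
#'
#' Average precision is computed at each similarity threshold in
#' `thresholds`; `mAP50` is the value at 0.50 and `mAP50_95` the mean over
#' 0.50 to 0.95 in steps of 0.05. The reported precision and recall are
#' taken at the confidence cutoff maximizing F1 on the threshold-0.5
#' ranking, and the full curve is returned for inspection.
#'
#' @inheritParams average_precision
#' @param thresholds Similarity thresholds for the mAP ladder.
#' @return List of class `"eval_summary"`: `precision`, `recall`, `mAP50`,
#'   `mAP50_95`, `ap_by_threshold`, `pr_curve` (data frame `confidence`,
#'   `precision`, `recall`, `f1`), `kind`, `n_predictions`,
#'   `n_ground_truths`.
#' @export
mean_average_precision <- function(preds, gts,
                                   thresholds = seq(0.5, 0.95, by = 0.05),
                                   kind = c("box", "keypoints"), kappas = 0.1,
                                   interpolation = c("coco101", "all_points")) {
  kind <- match.arg(kind)
  interpolation <- match.arg(interpolation)
  if (!length(gts)) stop("empty input: no ground truths", call. = FALSE)
  ap <- vapply(thresholds, function(th)
    average_precision(preds, gts, th, kind, kappas, interpolation), numeric(1L))
  names(ap) <- sprintf("%.2f", thresholds)
  map50 <- if ("0.50" %in% names(ap)) unname(ap["0.50"]) else ap[[1L]]

  if (length(preds)) {
    r <- rank_detections(preds, gts, 0.5, kind, kappas)
    tp_cum <- cumsum(r$tp); fp_cum <- cumsum(!r$tp)
    rec <- tp_cum / length(gts)
    prec <- tp_cum / (tp_cum + fp_cum)
    f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    curve <- data.frame(confidence = r$confidence, precision = prec,
                        recall = rec, f1 = f1)
    best <- which.max(f1)
    p_out <- prec[best]; r_out <- rec[best]
  } else {
    curve <- data.frame(confidence = numeric(), precision = numeric(),
                        recall = numeric(), f1 = numeric())
    p_out <- 0; r_out <- 0
  }
  structure(list(precision = p_out, recall = r_out,
                 mAP50 = map50, mAP50_95 = mean(ap),
                 ap_by_threshold = ap, pr_curve = curve, kind = kind,
                 n_predictions = length(preds), n_ground_truths = length(gts)),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("%s evaluation (%d predictions, %d ground truths)\n",
              if (x$kind == "box") "Box (IoU)" else "Keypoint (OKS)",
              x$n_predictions, x$n_ground_truths))
  cat(sprintf("  precision %.4f  recall %.4f  mAP50 %.4f  mAP50-95 %.4f\n",
              x$precision, x$recall, x$mAP50, x$mAP50_95))
  invisible(x)
}
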