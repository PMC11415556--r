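pred_of <- function(gt, conf, dkpts = 0, dbox = 0) {
  k <- pmin(pmax(gt$keypoints + dkpts, 0), 1)
  b <- as.numeric(gt$box)
  annotation_record(gt$view,
                    bounding_box(min(max(b[1] + dbox, 0), 1), b[2], b[3], b[4]),
                    k, image_id = gt$image_id,
                    source = "prediction", confidence = conf)
}

test_that("iou matches analytic overlaps", {
  b <- bounding_box(0.5, 0.5, 0.4, 0.4)
  expect_equal(iou(b, b), 1)
  expect_equal(iou(bounding_box(0.2, 0.2, 0.2, 0.2),
                   bounding_box(0.8, 0.8, 0.2, 0.2)), 0)
  # squares of side 0.5 offset by half a side: overlap 0.125, union 0.375
  expect_equal(iou(bounding_box(0.25, 0.5, 0.5, 0.5),
                   bounding_box(0.5, 0.5, 0.5, 0.5)), 1 / 3)
  expect_equal(iou(b, bounding_box(0.5, 0.5, 0.2, 0.2)), 0.25)
  expect_error(iou(b, c(0.5, 0.5, 0, 0.2)), "degenerate")
})

test_that("oks follows the exponential falloff term by term", {
  k <- nominal_ap_record()$keypoints
  expect_equal(oks(k, k, scale_sq = 0.1), 1)
  # single keypoint with d^2 = 2 s^2 kappa^2 gives exp(-1)
  s2 <- 0.05; kap <- 0.2
  d <- sqrt(2 * s2 * kap^2)
  expect_equal(oks(matrix(c(0.5 + d, 0.5), 1), matrix(c(0.5, 0.5), 1),
                   scale_sq = s2, kappas = kap), exp(-1))
  # mixed displacements equal the mean of hand-computed per-point terms
  set.seed(41)
  dk <- matrix(stats::rnorm(14, sd = 0.01), 7, 2)
  k2 <- k + dk
  expected <- mean(exp(-rowSums(dk^2) / (2 * 0.06 * 0.1^2)))
  expect_equal(oks(k2, k, scale_sq = 0.06, kappas = 0.1), expected)
  expect_error(oks(k[1:5, ], k, scale_sq = 0.1), "arity")
  expect_error(oks(k, k, scale_sq = 0), "scale_sq")
})

test_that("oks is bounded and strictly decreasing in displacement", {
  k <- nominal_ap_record()$keypoints
  prev <- 1
  for (d in c(0.005, 0.01, 0.02, 0.05, 0.1)) {
    v <- oks(k + d / sqrt(2), k, scale_sq = 0.06)
    expect_true(v >= 0 && v < prev)
    prev <- v
  }
})

test_that("greedy matching is one-to-one and confidence-ordered", {
  gt <- nominal_ap_record("img1")
  p1 <- pred_of(gt, 0.9)
  m <- match_detections(list(p1), list(gt), kind = "box")
  expect_equal(nrow(m$pairs), 1L)
  expect_length(m$unmatched_predictions, 0L)
  expect_length(m$unmatched_ground_truths, 0L)
  expect_gte(m$pairs$similarity, m$threshold)

  # two predictions on one gt: the higher-confidence one wins
  p_low <- pred_of(gt, 0.4, dbox = 0.01)
  m2 <- match_detections(list(p_low, p1), list(gt), kind = "box")
  expect_equal(m2$pairs$pred, 2L)
  expect_equal(m2$unmatched_predictions, 1L)

  expect_error(match_detections(list(p1), list(nominal_lat_record()), kind = "box"),
               "mixed AP/LAT")
})

test_that("greedy matching agrees with an independent brute-force matcher", {
  set.seed(43)
  for (rep in 1:20) {
    n_gt <- sample(2:4, 1); n_pred <- sample(2:5, 1)
    gts <- lapply(seq_len(n_gt), function(i)
      generate_ap(synthetic_params(
        joint_center = c(stats::runif(1, 0.35, 0.65), stats::runif(1, 0.35, 0.65)),
        epicondyle_halfwidth = stats::runif(1, 0.1, 0.2)), image_id = "im"))
    preds <- lapply(seq_len(n_pred), function(i)
      pred_of(gts[[sample(n_gt, 1)]], stats::runif(1),
              dbox = stats::runif(1, 0, 0.05)))
    m <- match_detections(preds, gts, threshold = 0.3, kind = "box")
    pred_df <- data.frame(conf = vapply(preds, `[[`, numeric(1), "confidence"),
                          image = "im")
    gt_df <- data.frame(image = rep("im", n_gt))
    tp <- oracle_rank_labels(pred_df, gt_df, 0.3,
                             function(i, j) iou(preds[[i]]$box, gts[[j]]$box))
    expect_equal(nrow(m$pairs), sum(tp))
  }
})

test_that("precision_recall covers the worked count cases", {
  gt <- nominal_ap_record("img1")
  m <- match_detections(list(pred_of(gt, 0.9)), list(gt), kind = "box")
  expect_equal(precision_recall(m, 1, 1), c(precision = 1, recall = 1))
  # 3 TP out of 4 predictions and 4 ground truths: 0.75 / 0.75
  fake <- structure(list(pairs = data.frame(pred = 1:3, gt = 1:3,
                                            similarity = rep(0.9, 3)),
                         unmatched_predictions = 4L,
                         unmatched_ground_truths = 4L,
                         threshold = 0.5, kind = "box"),
                    class = "match_result")
  expect_equal(precision_recall(fake, 4, 4), c(precision = 0.75, recall = 0.75))
  empty <- match_detections(list(), list(gt), kind = "box")
  expect_equal(precision_recall(empty, 0, 4), c(precision = 0, recall = 0))
})

test_that("perfect predictions give all metrics exactly 1", {
  gts <- generate_cohort(8, c(none = 1), seed = 44, view = "ap")$records
  preds <- lapply(gts, perturb, sigma = 0)
  for (kind in c("box", "keypoints")) {
    s <- mean_average_precision(preds, gts, kind = kind)
    expect_equal(s$precision, 1)
    expect_equal(s$recall, 1)
    expect_equal(s$mAP50, 1)
    expect_equal(s$mAP50_95, 1)
  }
  s0 <- mean_average_precision(list(), gts, kind = "box")
  expect_equal(s0$mAP50, 0)
  expect_equal(s0$precision, 0)
})

test_that("average precision equals the exhaustive all-cutoff oracle", {
  set.seed(45)
  for (rep in 1:15) {
    n_img <- sample(3:6, 1)
    gts <- lapply(seq_len(n_img), function(i)
      generate_ap(synthetic_params(
        joint_center = c(0.5, 0.5) + stats::runif(2, -0.05, 0.05)),
        image_id = paste0("im", i)))
    preds <- unlist(lapply(gts, function(g) {
      k <- sample(0:2, 1)
      lapply(seq_len(k), function(j)
        pred_of(g, stats::runif(1), dbox = stats::runif(1, 0, 0.2)))
    }), recursive = FALSE)
    if (!length(preds)) next
    for (th in c(0.5, 0.75, 0.9)) {
      got <- average_precision(preds, gts, threshold = th, kind = "box")
      pred_df <- data.frame(conf = vapply(preds, `[[`, numeric(1), "confidence"),
                            image = vapply(preds, `[[`, character(1), "image_id"))
      gt_df <- data.frame(image = vapply(gts, `[[`, character(1), "image_id"))
      tp <- oracle_rank_labels(pred_df, gt_df, th, function(i, j)
        iou(preds[[i]]$box, gts[[j]]$box))
      expect_equal(got, oracle_ap_from_labels(tp, length(gts)), tolerance = 1e-12)
    }
  }
})

test_that("mAP50-95 never exceeds mAP50 and degrades with jitter", {
  gts <- generate_cohort(12, c(none = 1), seed = 46, view = "ap")$records
  prev_box <- prev_oks <- Inf
  prev_mean_oks <- Inf
  for (sigma in c(0.002, 0.01, 0.03, 0.08)) {
    preds <- lapply(seq_along(gts), function(i)
      perturb(gts[[i]], sigma, seed = 1000 + i))
    sb <- mean_average_precision(preds, gts, kind = "box")
    sk <- mean_average_precision(preds, gts, kind = "keypoints")
    expect_lte(sb$mAP50_95, sb$mAP50 + 1e-9)
    expect_lte(sk$mAP50_95, sk$mAP50 + 1e-9)
    expect_lte(sb$mAP50_95, prev_box + 1e-9)
    expect_lte(sk$mAP50_95, prev_oks + 1e-9)
    mean_oks <- mean(vapply(seq_along(gts), function(i) {
      b <- as.numeric(gts[[i]]$box)
      oks(preds[[i]]$keypoints, gts[[i]]$keypoints, scale_sq = b[3] * b[4])
    }, numeric(1)))
    expect_lt(mean_oks, prev_mean_oks)
    prev_box <- sb$mAP50_95; prev_oks <- sk$mAP50_95
    prev_mean_oks <- mean_oks
  }
})

test_that("all-points interpolation integrates the envelope exactly", {
  gts <- generate_cohort(6, c(none = 1), seed = 47, view = "ap")$records
  preds <- lapply(seq_along(gts), function(i)
    perturb(gts[[i]], 0.02, seed = 2000 + i))
  a101 <- average_precision(preds, gts, kind = "box")
  aall <- average_precision(preds, gts, kind = "box",
                            interpolation = "all_points")
  expect_true(a101 >= 0 && a101 <= 1 && aall >= 0 && aall <= 1)
  expect_lt(abs(a101 - aall), 0.1)  # same curve, different quadrature
})
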