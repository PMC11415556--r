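test_that("compute_ap_metrics matches hand-computed fossa distances", {
  k <- rbind(c(0.3, 0.4), c(0.7, 0.4), c(0.35, 0.45), c(0.65, 0.45),
             c(0.35, 0.55), c(0.65, 0.55), c(0.52, 0.42))
  m <- compute_ap_metrics(bounding_box(0.5, 0.5, 0.6, 0.4), k)
  expect_equal(m$S17, sqrt(0.22^2 + 0.02^2))
  expect_equal(m$S27, sqrt(0.18^2 + 0.02^2))
  expect_equal(c(m$XA, m$YA), c(0.5, 0.5))
  expect_equal(c(m$Y3, m$Y4, m$Y5, m$Y6), c(0.45, 0.45, 0.55, 0.55))

  # coincident keypoints 1 and 7 give S17 = 0
  k2 <- k; k2[7, ] <- k2[1, ]
  expect_equal(compute_ap_metrics(bounding_box(0.5, 0.5, 0.6, 0.4), k2)$S17, 0)

  # keypoint 7 midway between 1 and 2 gives S17 = S27
  k3 <- k; k3[7, ] <- c(0.5, 0.4)
  m3 <- compute_ap_metrics(bounding_box(0.5, 0.5, 0.6, 0.4), k3)
  expect_equal(m3$S17, m3$S27)
})

test_that("evaluate_ap applies the three criteria with the configured rules", {
  rec <- nominal_ap_record()
  rep <- evaluate_ap(rec$box, rec$keypoints)
  expect_s3_class(rep, "qc_report")
  expect_equal(nrow(rep$verdicts), 3L)
  expect_setequal(rep$verdicts$criterion,
                  c("positioning", "olecranon_fossa", "joint_space"))
  expect_true(all(rep$verdicts$pass))
  expect_true(rep$overall)

  # off-center box fails positioning only
  p <- synthetic_params(joint_center = c(0.7, 0.5))
  r2 <- generate_ap(p)
  rep2 <- evaluate_ap(r2$box, r2$keypoints)
  expect_false(rep2$verdicts$pass[rep2$verdicts$criterion == "positioning"])
  expect_false(rep2$overall)

  # S17 < S27 fails the fossa criterion
  r3 <- generate_ap(synthetic_params(fossa_bias = -0.03))
  rep3 <- evaluate_ap(r3$box, r3$keypoints)
  expect_false(rep3$verdicts$pass[rep3$verdicts$criterion == "olecranon_fossa"])

  # the lower ratio bound is strict: a ratio below fossa_ratio_min fails
  r4 <- generate_ap(synthetic_params(fossa_bias = 0.01))  # ratio 0.21/0.19
  cfg_strict <- qc_config(fossa_ratio_min = 1.2)
  rep4 <- evaluate_ap(r4$box, r4$keypoints, cfg_strict)
  expect_false(rep4$verdicts$pass[rep4$verdicts$criterion == "olecranon_fossa"])
  # and a ratio above fossa_ratio_max ("slightly" exceeded) also fails
  r5 <- generate_ap(synthetic_params(fossa_bias = 0.06))  # ratio 0.26/0.14
  rep5 <- evaluate_ap(r5$box, r5$keypoints)
  expect_false(rep5$verdicts$pass[rep5$verdicts$criterion == "olecranon_fossa"])
})

test_that("joint-space rule direction follows the axis-convention flag", {
  rec <- nominal_ap_record()   # humeral side above (smaller y)
  up <- evaluate_ap(rec$box, rec$keypoints, qc_config(humeral_side_above = TRUE))
  down <- evaluate_ap(rec$box, rec$keypoints, qc_config(humeral_side_above = FALSE))
  expect_true(up$verdicts$pass[up$verdicts$criterion == "joint_space"])
  expect_false(down$verdicts$pass[down$verdicts$criterion == "joint_space"])
})

test_that("evaluate_ap errors when the fossa ratio is undefined", {
  k <- nominal_ap_record()$keypoints
  k[7, ] <- k[2, ]   # S27 = 0
  expect_error(evaluate_ap(bounding_box(0.5, 0.5, 0.5, 0.3), k),
               "degenerate geometry")
})

test_that("evaluate_lat applies the centering and angle criteria", {
  rec <- nominal_lat_record()
  rep <- evaluate_lat(rec$keypoints)
  expect_equal(nrow(rep$verdicts), 2L)
  expect_setequal(rep$verdicts$criterion, c("positioning", "flexion_angle"))
  expect_true(rep$overall)

  m <- compute_lat_metrics(rec$keypoints)
  expect_equal(m$alpha, 90)
  expect_equal(c(m$X2, m$Y2), c(0.5, 0.5))

  # 70 degrees just fails the default 10-degree tolerance
  r70 <- generate_lat(synthetic_params(flexion_deg = 70))
  rep70 <- evaluate_lat(r70$keypoints)
  expect_false(rep70$verdicts$pass[rep70$verdicts$criterion == "flexion_angle"])
  # 80 degrees sits exactly on the tolerance and passes
  r80 <- generate_lat(synthetic_params(flexion_deg = 80))
  expect_true(evaluate_lat(r80$keypoints)$overall)

  # trochlea off the central region fails positioning
  r_off <- generate_lat(synthetic_params(joint_center = c(0.62, 0.5)))
  rep_off <- evaluate_lat(r_off$keypoints)
  expect_false(rep_off$verdicts$pass[rep_off$verdicts$criterion == "positioning"])
})

test_that("verdicts are monotone in tolerances", {
  set.seed(21)
  for (i in 1:40) {
    p <- synthetic_params(
      joint_center = c(0.5, 0.5) + stats::runif(2, -0.12, 0.12),
      fossa_bias = stats::runif(1, -0.05, 0.06),
      joint_gap = stats::runif(1, 0.01, 0.06),
      flexion_deg = stats::runif(1, 60, 120))
    rec <- generate_ap(p)
    tight <- qc_config(center_tolerance = 0.05, angle_tolerance = 5,
                       joint_space_margin = 0.02)
    loose <- qc_config(center_tolerance = 0.2, angle_tolerance = 25,
                       joint_space_margin = 0.001, fossa_ratio_max = 2)
    vt <- evaluate_ap(rec$box, rec$keypoints, tight)$verdicts
    vl <- evaluate_ap(rec$box, rec$keypoints, loose)$verdicts
    expect_true(all(vl$pass >= vt$pass))
    lrec <- generate_lat(p)
    lt <- evaluate_lat(lrec$keypoints, tight)$verdicts
    ll <- evaluate_lat(lrec$keypoints, loose)$verdicts
    expect_true(all(ll$pass >= lt$pass))
  }
})

test_that("metrics are scale-free across image resolutions", {
  rec <- nominal_ap_record()
  for (size in list(c(640, 640), c(3000, 2000), c(512, 1024))) {
    px <- denormalize_point(rec$keypoints, size)
    back <- normalize_point(px, size)
    m1 <- compute_ap_metrics(rec$box, rec$keypoints)
    m2 <- compute_ap_metrics(rec$box, back)
    expect_equal(unlist(m1), unlist(m2), tolerance = 1e-9)
  }
})

test_that("summarize_batch counts passes and failure reasons", {
  cohort <- generate_cohort(10, c(none = 1), seed = 3)
  reports <- lapply(cohort$records, evaluate_record)
  s <- summarize_batch(reports)
  expect_equal(s$pass_rate, 1)
  expect_equal(s$n, 10L)

  mixed <- c(lapply(generate_cohort(5, c(none = 1), seed = 4)$records,
                    evaluate_record),
             lapply(generate_cohort(5, c(wrong_flexion = 1), seed = 5,
                                    view = "lat")$records,
                    evaluate_record))
  s2 <- summarize_batch(mixed)
  expect_equal(s2$pass_rate, 0.5)
  expect_equal(s2$failure_histogram$flexion_angle, 5L)
  expect_equal(sum(s2$criterion_counts$evaluated),
               nrow(do.call(rbind, lapply(mixed, `[[`, "verdicts"))))
  expect_error(summarize_batch(list()), "empty input")
})

test_that("QC reports round-trip through JSON", {
  rec <- nominal_ap_record("img_007")
  rep <- evaluate_record(rec)
  back <- qc_report_from_json(qc_report_to_json(rep))
  expect_equal(back$view, rep$view)
  expect_equal(back$image_id, "img_007")
  expect_equal(unlist(back$metrics), unlist(rep$metrics), tolerance = 1e-12)
  expect_equal(back$verdicts$pass, rep$verdicts$pass)
  expect_equal(back$overall, rep$overall)
})

test_that("config files override defaults and reject unknown keys", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("center_tolerance: 0.05", "angle_tolerance: 20"), f)
  cfg <- read_qc_config(f)
  expect_equal(cfg$center_tolerance, 0.05)
  expect_equal(cfg$angle_tolerance, 20)
  expect_equal(cfg$fossa_ratio_max, 1.5)
  writeLines("centre_tolerance: 0.05", f)
  expect_error(read_qc_config(f), "unknown config key")
  expect_error(qc_config(fossa_ratio_min = 0.8), "fossa_ratio_min")
})
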