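# Synthetic annotation generator: the closed-form inverse of the QC metrics.
# AP landmarks are laid out symmetrically about a joint center so that the
# generating parameters (center, S17, S27, joint gap, flexion angle) are
# recovered exactly by the metric computations; controllable faults push
# exactly one criterion past its threshold while leaving the others nominal.
# The anatomy template is deliberately schematic -- the QC method consumes
# coordinates only, so realism is unnecessary for correctness testing.

FAULT_LABELS <- c("none", "off_center", "fossa_shift", "space_tilt", "wrong_flexion")

#' Parameters of the synthetic annotation generator
#'
#' All lengths in normalized units, angles in degrees.
#'
#' @param joint_center Target joint center `(x, y)`.
#' @param epicondyle_halfwidth Distance from the fossa line to each
#'   epicondyle (keypoints 1, 2); S17 + S27 = 2 * halfwidth.
#' @param fossa_bias Signed shift of keypoint 7 along the epicondyle line
#'   toward the medial side; S17 = halfwidth + bias, S27 = halfwidth - bias,
#'   so a small positive bias yields the expected "slightly greater" S17.
#' @param joint_gap Mean vertical separation between the humeral-side (3, 4)
#'   and radial-side (5, 6) joint-space keypoints.
#' @param joint_tilt Relative tilt, in degrees, between the two joint lines
#'   (each line shears by half the tilt in opposite directions). Zero keeps
#'   the joint space horizontal; large values collapse one keypoint pair and
#'   violate the joint-space criterion without moving the box center or the
#'   fossa distances.
#' @param flexion_deg LAT flexion angle between the humerus and radius
#'   segments.
#' @param segment_length LAT humerus/radius segment length.
#' @param box_margin Margin added around the keypoint extent when placing
#'   the detection box.
#' @param fault_label One of `"none"`, `"off_center"`, `"fossa_shift"`,
#'   `"space_tilt"`, `"wrong_flexion"`; bookkeeping only (the fault is
#'   expressed through the numeric fields).
#' @return A list of class `"synthetic_params"`.
#' @export
synthetic_params <- function(joint_center = c(0.5, 0.5),
                             epicondyle_halfwidth = 0.2,
                             fossa_bias = 0.02,
                             joint_gap = 0.04,
                             joint_tilt = 0,
                             flexion_deg = 90,
                             segment_length = 0.3,
                             box_margin = 0.05,
                             fault_label = "none") {
  if (epicondyle_halfwidth <= 0 || segment_length <= 0 || box_margin < 0)
    stop("parameter error: lengths must be positive", call. = FALSE)
  if (flexion_deg <= 0 || flexion_deg >= 180)
    stop("parameter error: flexion_deg must lie in (0, 180)", call. = FALSE)
  if (!fault_label %in% FAULT_LABELS)
    stop("parameter error: unknown fault_label '", fault_label, "'", call. = FALSE)
  structure(list(joint_center = as.numeric(joint_center),
                 epicondyle_halfwidth = epicondyle_halfwidth,
                 fossa_bias = fossa_bias, joint_gap = joint_gap,
                 joint_tilt = joint_tilt, flexion_deg = flexion_deg,
                 segment_length = segment_length, box_margin = box_margin,
                 fault_label = fault_label),
            class = "synthetic_params")
}

check_in_frame <- function(k, what) {
  if (any(k < 0) || any(k > 1))
    stop("generation range error: ", what,
         " parameters place keypoints outside the unit frame", call. = FALSE)
}

box_around <- function(k, margin) {
  x1 <- min(k[, 1L]) - margin; x2 <- max(k[, 1L]) + margin
  y1 <- min(k[, 2L]) - margin; y2 <- max(k[, 2L]) + margin
  box_from_corners(max(0, x1), max(0, y1), min(1, x2), min(1, y2))
}

#' Generate a synthetic AP annotation
#'
#' Places the epicondyles (1, 2) at `joint_center +- (halfwidth, 0)`, the
#' fossa center (7) at `joint_center + (fossa_bias, 0)` shifted toward the
#' medial epicondyle, and the joint-space keypoints (3..6) on two lines
#' separated vertically by `joint_gap` (humeral side above under the raster
#' convention) and sheared by `joint_tilt`. The detection box encloses the
#' keypoints with `box_margin`; by central symmetry of the layout its
#' center recovers `joint_center` exactly, and `compute_ap_metrics`
#' recovers S17 = halfwidth + bias, S27 = halfwidth - bias and the mean
#' joint gap exactly.
#'
#' @param params A [synthetic_params()].
#' @param image_id Identifier for the record.
#' @return A ground-truth [annotation_record()] (view AP).
#' @export
generate_ap <- function(params = synthetic_params(), image_id = "synthetic_ap") {
  stopifnot(inherits(params, "synthetic_params"))
  c0 <- params$joint_center
  hw <- params$epicondyle_halfwidth
  a <- 0.6 * hw                                  # joint-line half-width
  g <- params$joint_gap
  shear <- tan(params$joint_tilt / 2 * pi / 180) # opposite shear per line
  k <- rbind(
    c(c0[1L] - hw, c0[2L]),                      # 1 medial epicondyle
    c(c0[1L] + hw, c0[2L]),                      # 2 lateral epicondyle
    c(c0[1L] - a, c0[2L] - g / 2 - a * shear),   # 3 medial humeral
    c(c0[1L] + a, c0[2L] - g / 2 + a * shear),   # 4 lateral humeral
    c(c0[1L] - a, c0[2L] + g / 2 + a * shear),   # 5 medial radial
    c(c0[1L] + a, c0[2L] + g / 2 - a * shear),   # 6 lateral radial
    c(c0[1L] + params$fossa_bias, c0[2L]))       # 7 fossa center
  check_in_frame(k, "AP")
  annotation_record("AP", box_around(k, params$box_margin), k,
                    image_id = image_id)
}

#' Generate a synthetic LAT annotation
#'
#' Places the trochlea center (2) at `joint_center`, the mid-humerus point
#' (1) at `segment_length` straight above it, and the mid-radius point (3)
#' at `segment_length` along the direction making `flexion_deg` with the
#' humerus direction under the given angle convention, so that
#' `flexion_angle` recovers `flexion_deg` exactly.
#'
#' @inheritParams generate_ap
#' @param convention Flexion-angle convention the generated geometry should
#'   satisfy, see [flexion_angle()].
#' @return A ground-truth [annotation_record()] (view LAT).
#' @export
generate_lat <- function(params = synthetic_params(),
                         image_id = "synthetic_lat",
                         convention = c("vector", "vertex")) {
  convention <- match.arg(convention)
  stopifnot(inherits(params, "synthetic_params"))
  c0 <- params$joint_center
  L <- params$segment_length
  theta <- if (convention == "vector") params$flexion_deg
           else 180 - params$flexion_deg
  th <- theta * pi / 180
  u <- c(0, 1)                                   # humerus direction P1 -> P2
  v <- c(-sin(th), cos(th))                      # rotated by the target angle
  k <- rbind(c0 - L * u,                         # 1 mid-humerus
             c0,                                 # 2 trochlea center
             c0 + L * v)                         # 3 mid-radius
  check_in_frame(k, "LAT")
  annotation_record("LAT", box_around(k, params$box_margin), k,
                    image_id = image_id)
}

#' Jitter an annotation into a synthetic detector prediction
#'
#' Displaces every keypoint and the box center by independent zero-mean
#' Gaussian noise of standard deviation `sigma` (normalized units), clipping
#' to the unit square, and attaches a confidence score. With `sigma = 0` the
#' record is returned unchanged with confidence 1.
#'
#' @param record A ground-truth [annotation_record()].
#' @param sigma Jitter standard deviation, >= 0.
#' @param confidence_model `"displacement"` (confidence decays exponentially
#'   with the realized mean displacement, deterministic given the jitter) or
#'   `"uniform"` (drawn uniformly from `[0.5, 1]`).
#' @param seed Optional seed for reproducibility.
#' @return A prediction [annotation_record()] with a confidence score.
#' @export
perturb <- function(record, sigma,
                    confidence_model = c("displacement", "uniform"),
                    seed = NULL) {
  confidence_model <- match.arg(confidence_model)
  stopifnot(inherits(record, "elbow_annotation"), sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  k <- record$keypoints
  b <- as.numeric(record$box)
  if (sigma == 0) {
    out <- record
    out$source <- "prediction"
    out$confidence <- 1
    return(out)
  }
  k2 <- k + matrix(stats::rnorm(length(k), sd = sigma), nrow(k), 2L)
  k2 <- pmin(pmax(k2, 0), 1)
  ctr <- pmin(pmax(b[1:2] + stats::rnorm(2L, sd = sigma), 0), 1)
  disp <- mean(sqrt(rowSums((k2 - k)^2)))
  conf <- switch(confidence_model,
                 displacement = exp(-disp / 0.05),
                 uniform = stats::runif(1L, 0.5, 1))
  annotation_record(record$view, bounding_box(ctr[1L], ctr[2L], b[3L], b[4L]),
                    k2, image_id = record$image_id,
                    image_size = record$image_size,
                    source = "prediction", confidence = conf)
}

# Draws fault-specific parameter overrides; magnitudes are chosen so the
# faulted criterion fails by a clear margin under the default qc_config()
# while everything else stays nominal.
fault_params <- function(fault, view) {
  base <- list(joint_center = c(0.5, 0.5) + stats::runif(2L, -0.03, 0.03),
               fossa_bias = stats::runif(1L, 0.01, 0.03),
               joint_gap = stats::runif(1L, 0.03, 0.05),
               joint_tilt = 0,
               flexion_deg = stats::runif(1L, 86, 94),
               fault_label = fault)
  switch(fault,
    none = base,
    off_center = {
      axis <- sample(2L, 1L)
      base$joint_center[axis] <- 0.5 +
        sample(c(-1, 1), 1L) * stats::runif(1L, 0.15, 0.2)
      base
    },
    fossa_shift = { base$fossa_bias <- stats::runif(1L, -0.04, -0.02); base },
    space_tilt = { base$joint_tilt <- stats::runif(1L, 25, 35); base },
    wrong_flexion = { base$flexion_deg <- stats::runif(1L, 55, 70); base })
}

fault_compatible_view <- function(fault) {
  switch(fault,
         fossa_shift = "AP", space_tilt = "AP", wrong_flexion = "LAT",
         NA_character_)   # none / off_center fit either view
}

#' Generate a synthetic cohort with injected positioning faults
#'
#' Draws `n` annotations with per-record fault labels sampled from
#' `fault_mix`, assigning each record a view compatible with its fault
#' (fossa and joint-space faults are AP-only, flexion faults LAT-only;
#' centering faults and nominal records follow `view`). Nominal parameters
#' vary mildly around their defaults so nominal records pass the default
#' [qc_config()] and each faulted record fails exactly its own criterion.
#'
#' @param n Number of records, >= 1.
#' @param fault_mix Named numeric vector of fault proportions (names from
#'   `"none"`, `"off_center"`, `"fossa_shift"`, `"space_tilt"`,
#'   `"wrong_flexion"`), summing to 1.
#' @param seed Integer seed; the cohort is fully reproducible from
#'   `(n, fault_mix, seed)`.
#' @param view `"both"`, `"ap"` or `"lat"`; forcing a view incompatible
#'   with a requested fault is an error.
#' @param convention Flexion-angle convention for LAT generation.
#' @param render Logical; also render schematic rasters (see
#'   [render_annotation()]).
#' @param render_size Raster side length in pixels.
#' @return List with `records` (annotation records), `fault_log` (data
#'   frame `image_id`, `view`, `fault`) and, when `render = TRUE`,
#'   `images` (list of [image_record()]s).
#' @export
generate_cohort <- function(n, fault_mix = c(none = 1), seed = 1L,
                            view = c("both", "ap", "lat"),
                            convention = c("vector", "vertex"),
                            render = FALSE, render_size = 320L) {
  view <- match.arg(view)
  convention <- match.arg(convention)
  if (n < 1L) stop("parameter error: n must be >= 1", call. = FALSE)
  if (is.null(names(fault_mix)) || !all(names(fault_mix) %in% FAULT_LABELS))
    stop("parameter error: fault_mix names must come from ",
         paste(FAULT_LABELS, collapse = ", "), call. = FALSE)
  if (any(fault_mix < 0) || abs(sum(fault_mix) - 1) > 1e-8)
    stop("parameter error: fault_mix proportions must be nonnegative and sum to 1",
         call. = FALSE)
  forced <- switch(view, ap = "AP", lat = "LAT", NA_character_)
  for (f in names(fault_mix)[fault_mix > 0]) {
    need <- fault_compatible_view(f)
    if (!is.na(forced) && !is.na(need) && need != forced)
      stop("parameter error: fault '", f, "' requires a ", need, " view",
           call. = FALSE)
  }

  set.seed(seed)
  faults <- sample(names(fault_mix), n, replace = TRUE, prob = fault_mix)
  records <- vector("list", n)
  views <- character(n)
  for (i in seq_len(n)) {
    need <- fault_compatible_view(faults[i])
    v <- if (!is.na(forced)) forced
         else if (!is.na(need)) need
         else c("AP", "LAT")[1L + (i %% 2L)]
    views[i] <- v
    ov <- fault_params(faults[i], v)
    p <- do.call(synthetic_params, ov)
    id <- sprintf("syn_%04d", i)
    records[[i]] <- if (v == "AP") generate_ap(p, image_id = id)
                    else generate_lat(p, image_id = id, convention = convention)
  }
  out <- list(records = records,
              fault_log = data.frame(image_id = sprintf("syn_%04d", seq_len(n)),
                                     view = views, fault = faults,
                                     stringsAsFactors = FALSE))
  if (render)
    out$images <- lapply(records, render_annotation, size = render_size)
  out
}

# Stamp a capsule (thick segment) of the given normalized radius into an
# intensity matrix; grid is precomputed by the caller.
stamp_segment <- function(m, gx, gy, p, q, radius, value) {
  vx <- q[1L] - p[1L]; vy <- q[2L] - p[2L]
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else pmin(pmax(((gx - p[1L]) * vx + (gy - p[2L]) * vy) / len2, 0), 1)
  d2 <- (gx - (p[1L] + t * vx))^2 + (gy - (p[2L] + t * vy))^2
  m[d2 <= radius^2] <- value
  m
}

#' Render a schematic raster for an annotation
#'
#' Draws bone-like capsules along the annotated segments (epicondyle and
#' joint lines for AP, humerus and radius segments for LAT) into an 8-bit
#' grayscale image, for exercising the raster IO and preprocessing paths.
#' This is a schematic rendering, not a simulation of radiographic texture.
#'
#' @param record An [annotation_record()].
#' @param size Output side length in pixels.
#' @return An [image_record()] of `size` x `size` pixels.
#' @export
render_annotation <- function(record, size = 320L) {
  stopifnot(inherits(record, "elbow_annotation"))
  px <- (col(matrix(0, size, size)) - 0.5) / size
  py <- (row(matrix(0, size, size)) - 0.5) / size
  m <- matrix(30, size, size)
  k <- record$keypoints
  segs <- if (record$view == "AP") {
    list(list(k[1L, ], k[2L, ], 0.035),        # epicondyle line
         list(k[3L, ], k[4L, ], 0.02),         # humeral joint line
         list(k[5L, ], k[6L, ], 0.02),         # radial joint line
         list(k[7L, ], k[7L, ] - c(0, 0.25), 0.045),  # humeral shaft
         list(colMeans(k[5:6, ]), colMeans(k[5:6, ]) + c(0, 0.25), 0.03))
  } else {
    list(list(k[1L, ], k[2L, ], 0.04),         # humerus
         list(k[2L, ], k[3L, ], 0.03))         # radius
  }
  for (s in segs) m <- stamp_segment(m, px, py, s[[1L]], s[[2L]], s[[3L]], 200)
  for (i in seq_len(nrow(k)))
    m <- stamp_segment(m, px, py, k[i, ], k[i, ], 0.008, 255)
  image_record(matrix(as.integer(m), size, size))
}
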