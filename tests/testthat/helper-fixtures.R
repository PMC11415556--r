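# Fixtures are built in code: DICOM byte streams, Labelme documents and the
# independent oracles used to cross-check the package's computations.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- DICOM byte-stream builder (independent of the package's reader) -------

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

dcm_element <- function(group, elem, vr, value, explicit = TRUE) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2L == 1L) value <- c(value, charToRaw(" "))
  }
  if (length(value) %% 2L == 1L) value <- c(value, as.raw(0))
  head <- c(raw_u16(group), raw_u16(elem))
  if (explicit) {
    if (vr %in% c("OB", "OW", "SQ", "UT", "UN")) {
      c(head, charToRaw(vr), as.raw(c(0, 0)), raw_u32(length(value)), value)
    } else {
      c(head, charToRaw(vr), raw_u16(length(value)), value)
    }
  } else {
    c(head, raw_u32(length(value)), value)
  }
}

# pixels: numeric matrix (rows x cols) of stored values
write_test_dicom <- function(path, pixels, bits = 16L,
                             photometric = "MONOCHROME2",
                             explicit = TRUE, window = NULL,
                             signed = FALSE) {
  ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  meta_body <- c(
    dcm_element(2L, 2L, "UI", "1.2.840.10008.5.1.4.1.1.1"),
    dcm_element(2L, 3L, "UI", "1.2.3.4.5.6.7.8.9"),
    dcm_element(2L, 16L, "UI", ts))
  meta <- c(dcm_element(2L, 0L, "UL", raw_u32(length(meta_body))), meta_body)

  vals <- as.integer(round(t(pixels)))      # row-major order
  if (signed) vals <- ifelse(vals < 0, vals + 65536L, vals)
  pix <- if (bits == 8L) as.raw(vals)
         else writeBin(vals, raw(), size = 2L, endian = "little")

  body <- c(
    dcm_element(0x28L, 0x02L, "US", raw_u16(1L), explicit),   # SamplesPerPixel
    dcm_element(0x28L, 0x04L, "CS", photometric, explicit),
    dcm_element(0x28L, 0x10L, "US", raw_u16(nrow(pixels)), explicit),
    dcm_element(0x28L, 0x11L, "US", raw_u16(ncol(pixels)), explicit),
    dcm_element(0x28L, 0x100L, "US", raw_u16(bits), explicit),
    dcm_element(0x28L, 0x101L, "US", raw_u16(bits), explicit), # BitsStored
    dcm_element(0x28L, 0x102L, "US", raw_u16(bits - 1L), explicit), # HighBit
    dcm_element(0x28L, 0x103L, "US", raw_u16(as.integer(signed)), explicit))
  if (!is.null(window)) {
    body <- c(body,
      dcm_element(0x28L, 0x1050L, "DS", as.character(window[1L]), explicit),
      dcm_element(0x28L, 0x1051L, "DS", as.character(window[2L]), explicit))
  }
  body <- c(body, dcm_element(0x7FE0L, 0x10L, if (bits == 8L) "OB" else "OW",
                              pix, explicit))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), path)
  invisible(path)
}

# ---- Labelme document builder ----------------------------------------------

labelme_doc <- function(record_or_points, box_px, size = c(640, 480),
                        labels = NULL, view = NULL) {
  pts <- record_or_points
  if (is.null(labels)) labels <- as.character(seq_len(nrow(pts)))
  shapes <- c(
    list(list(label = "elbow", shape_type = "rectangle",
              points = list(box_px[1:2], box_px[3:4]))),
    lapply(seq_len(nrow(pts)), function(i)
      list(label = labels[i], shape_type = "point",
           points = list(as.numeric(pts[i, ])))))
  doc <- list(version = "5.3.1", imagePath = "img.jpg",
              imageWidth = size[1L], imageHeight = size[2L], shapes = shapes)
  if (!is.null(view)) doc$view <- view
  doc
}

write_labelme_doc <- function(doc, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}

# ---- Independent oracles ----------------------------------------------------

# Average precision by exhaustive enumeration of confidence cutoffs. Takes the
# ranked tp/fp labels and, for 101-point interpolation, evaluates at each
# recall level the maximum precision over all cutoffs achieving at least that
# recall -- a formulation independent of the envelope computation under test.
oracle_ap_from_labels <- function(tp, n_gt) {
  n <- length(tp)
  pts <- t(vapply(seq_len(n), function(cut) {
    t <- sum(tp[seq_len(cut)])
    c(recall = t / n_gt, precision = t / cut)
  }, numeric(2L)))
  qs <- seq(0, 1, length.out = 101L)
  mean(vapply(qs, function(q) {
    ok <- pts[, "recall"] >= q
    if (any(ok)) max(pts[ok, "precision"]) else 0
  }, numeric(1L)))
}

# Greedy confidence-ordered matching written independently (plain loops over
# data frames) for cross-checking rank assignments on tiny instances.
oracle_rank_labels <- function(pred_df, gt_df, threshold, sim_fun) {
  ord <- order(-pred_df$conf, seq_len(nrow(pred_df)))
  taken <- rep(FALSE, nrow(gt_df))
  tp <- logical(nrow(pred_df))
  for (i in ord) {
    best <- -Inf; best_j <- 0L
    for (j in seq_len(nrow(gt_df))) {
      if (taken[j] || gt_df$image[j] != pred_df$image[i]) next
      s <- sim_fun(i, j)
      if (s > best) { best <- s; best_j <- j }
    }
    if (best_j > 0L && best >= threshold) { taken[best_j] <- TRUE; tp[i] <- TRUE }
  }
  tp[ord]
}

# Definitional two-way ANOVA ICC(A,k) via stats::aov mean squares.
oracle_icc_avg <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(value = as.vector(m),
                  subject = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(value ~ subject + rater, data = d))[[1L]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / n)
}

# pingouin's ICC2k (two-way random, absolute agreement, average measures) via
# the installed Python, as an established external cross-check. Returns NULL
# if the call fails for environmental reasons.
pingouin_icc2k <- function(m) {
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(m, csv, row.names = FALSE)
  script <- sprintf(paste0(
    "import pandas as pd, pingouin as pg\n",
    "w = pd.read_csv('%s')\n",
    "w['subject'] = range(len(w))\n",
    "d = w.melt(id_vars='subject', var_name='rater', value_name='value')\n",
    "r = pg.intraclass_corr(d, targets='subject', raters='rater', ratings='value')\n",
    "row = r[r['Type'] == 'ICC2k'].iloc[0]\n",
    "print(row['ICC'], row['CI95%%'][0], row['CI95%%'][1])\n"), csv)
  out <- suppressWarnings(tryCatch(
    system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = FALSE),
    error = function(e) NULL))
  if (is.null(out) || !length(out)) return(NULL)
  vals <- suppressWarnings(as.numeric(strsplit(tail(out, 1L), " ")[[1L]]))
  if (length(vals) != 3L || anyNA(vals[1L])) return(NULL)
  list(icc = vals[1L], ci = vals[2:3])
}

# A small well-behaved AP record for reuse across tests.
nominal_ap_record <- function(image_id = "img1") {
  generate_ap(synthetic_params(), image_id = image_id)
}
nominal_lat_record <- function(image_id = "img1") {
  generate_lat(synthetic_params(), image_id = image_id)
}
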