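# Annotation interchange: Labelme-style JSON (one document per image, one
# rectangle + point shapes labeled "1".."7"/"1".."3") and the YOLO-pose text
# dialect (one whitespace-separated line: class cx cy w h then x y [v] per
# keypoint, all normalized). Both round-trip losslessly at their stated
# precision.

#' Construct an annotation record
#'
#' The unit of QC: one view, one bounding box and the view's fixed-arity
#' keypoint set in normalized coordinates, optionally carrying the original
#' pixel size and, for detector output, a confidence score.
#'
#' @param view `"AP"` (7 keypoints) or `"LAT"` (3 keypoints).
#' @param box A `"bbox"`.
#' @param keypoints A keypoint matrix matching the view's arity.
#' @param image_id Identifier string.
#' @param image_size Optional pixel `(width, height)`.
#' @param source `"truth"` or `"prediction"`.
#' @param confidence Detector confidence in `[0, 1]`; required iff `source`
#'   is `"prediction"`.
#' @param visibility Optional integer visibility flags, one per keypoint
#'   (parsed from 3-token YOLO-pose dialects; ignored by QC).
#' @return A list of class `"elbow_annotation"`.
#' @export
annotation_record <- function(view, box, keypoints, image_id = NA_character_,
                              image_size = NULL, source = c("truth", "prediction"),
                              confidence = NULL, visibility = NULL) {
  view <- match.arg(toupper(view), c("AP", "LAT"))
  source <- match.arg(source)
  keypoints <- if (view == "AP") ap_keypoints(keypoints) else lat_keypoints(keypoints)
  if (!inherits(box, "bbox")) box <- do.call(bounding_box, as.list(as.numeric(box)))
  if (source == "prediction") {
    if (is.null(confidence) || !is.finite(confidence) || confidence < 0 || confidence > 1)
      stop("predictions require a confidence score in [0, 1]", call. = FALSE)
  } else if (!is.null(confidence)) {
    stop("ground-truth records carry no confidence score", call. = FALSE)
  }
  if (!is.null(visibility) && length(visibility) != nrow(keypoints))
    stop("visibility flags must match keypoint arity", call. = FALSE)
  structure(list(view = view, image_id = image_id, image_size = image_size,
                 box = box, keypoints = keypoints, source = source,
                 confidence = confidence, visibility = visibility),
            class = "elbow_annotation")
}

#' @export
print.elbow_annotation <- function(x, ...) {
  cat(sprintf("%s annotation '%s' (%s%s): box (%.4f, %.4f, %.4f, %.4f), %d keypoints\n",
              x$view, x$image_id, x$source,
              if (!is.null(x$confidence)) sprintf(", conf %.3f", x$confidence) else "",
              x$box[1L], x$box[2L], x$box[3L], x$box[4L], nrow(x$keypoints)))
  invisible(x)
}

view_arity <- function(view) if (view == "AP") 7L else 3L

#' Read a Labelme-style JSON annotation
#'
#' Expects one rectangle shape (the detection box) and point shapes whose
#' labels map to keypoint indices; pixel coordinates are normalized by the
#' document's `imageWidth`/`imageHeight`. The view is taken from a top-level
#' `"view"` flag when present, otherwise inferred from the point count (7 =
#' AP, 3 = LAT).
#'
#' @param path Path to the JSON document.
#' @param label_alias Optional named character vector mapping non-numeric
#'   point labels to index strings, e.g. `c(medial_epicondyle = "1")`.
#' @return An [annotation_record()].
#' @seealso [write_labelme()]
#' @export
read_labelme <- function(path, label_alias = NULL) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed Labelme JSON: ",
                                           conditionMessage(e), call. = FALSE))
  w <- doc$imageWidth; h <- doc$imageHeight
  if (is.null(w) || is.null(h))
    stop("Labelme document lacks imageWidth/imageHeight", call. = FALSE)
  shapes <- doc$shapes
  if (is.null(shapes)) stop("Labelme document has no shapes", call. = FALSE)
  types <- vapply(shapes, function(s) s$shape_type, character(1L))

  rects <- shapes[types == "rectangle"]
  if (length(rects) != 1L)
    stop("expected exactly one rectangle shape, found ", length(rects), call. = FALSE)
  rp <- do.call(rbind, lapply(rects[[1L]]$points, unlist))
  c1 <- normalize_point(c(rp[1L, 1L], rp[1L, 2L]), c(w, h))
  c2 <- normalize_point(c(rp[2L, 1L], rp[2L, 2L]), c(w, h))
  box <- box_from_corners(c1[1L], c1[2L], c2[1L], c2[2L])

  pts <- shapes[types == "point"]
  npts <- length(pts)
  view <- if (!is.null(doc$view)) toupper(doc$view)
          else if (npts == 7L) "AP" else if (npts == 3L) "LAT"
          else stop("keypoint arity error: ", npts,
                    " point shapes (expected 7 for AP or 3 for LAT)", call. = FALSE)
  arity <- view_arity(view)
  if (npts != arity)
    stop("keypoint arity error: ", npts, " point shapes for a ", view,
         " view (expected ", arity, ")", call. = FALSE)

  labels <- vapply(pts, function(s) as.character(s$label), character(1L))
  if (!is.null(label_alias)) {
    hit <- labels %in% names(label_alias)
    labels[hit] <- unname(label_alias[labels[hit]])
  }
  idx <- suppressWarnings(as.integer(labels))
  if (anyNA(idx))
    stop("schema error: unrecognized point label(s): ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  if (anyDuplicated(idx))
    stop("schema error: duplicate point label ",
         idx[duplicated(idx)][1L], call. = FALSE)
  if (!setequal(idx, seq_len(arity)))
    stop("schema error: point labels must be 1..", arity, call. = FALSE)

  k <- matrix(NA_real_, arity, 2L)
  for (i in seq_along(pts)) {
    p <- unlist(pts[[i]]$points[[1L]])
    k[idx[i], ] <- normalize_point(c(p[1L], p[2L]), c(w, h))
  }
  image_id <- if (!is.null(doc$imagePath)) sub("\\.[A-Za-z]+$", "", basename(doc$imagePath))
              else sub("\\.json$", "", basename(path))
  annotation_record(view, box, k, image_id = image_id, image_size = c(w, h))
}

#' Write a Labelme-style JSON annotation
#'
#' Inverse of [read_labelme()]: the box is emitted as a rectangle shape in
#' pixel corner form and keypoints as point shapes labeled by index. If the
#' record has no pixel size a 640 x 640 frame is assumed.
#'
#' @param record An [annotation_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labelme <- function(record, path) {
  stopifnot(inherits(record, "elbow_annotation"))
  size <- if (is.null(record$image_size)) c(640, 640) else record$image_size
  crn <- box_corners(record$box)
  rect <- list(label = "elbow", shape_type = "rectangle",
               points = list(as.numeric(denormalize_point(crn[c("x1", "y1")], size)),
                             as.numeric(denormalize_point(crn[c("x2", "y2")], size))))
  pts <- lapply(seq_len(nrow(record$keypoints)), function(i) {
    list(label = as.character(i), shape_type = "point",
         points = list(as.numeric(denormalize_point(record$keypoints[i, ], size))))
  })
  doc <- list(version = "5.3.1", view = record$view,
              imagePath = paste0(record$image_id, ".jpg"),
              imageWidth = size[1L], imageHeight = size[2L],
              shapes = c(list(rect), pts))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Parse one YOLO-pose text line
#'
#' Token layout: `class cx cy w h` then `x y` or `x y v` per keypoint,
#' whitespace-separated, coordinates normalized. The keypoint arity (and
#' hence view) is inferred from the token count; both the 2- and 3-token
#' per-point dialects are accepted, and visibility flags are preserved but
#' ignored by QC.
#'
#' @param line A single text line.
#' @param image_id,image_size Optional metadata carried into the record.
#' @param confidence Optional confidence; when supplied the record is marked
#'   as a prediction.
#' @return An [annotation_record()].
#' @seealso [write_yolo_pose()]
#' @export
read_yolo_pose <- function(line, image_id = NA_character_, image_size = NULL,
                           confidence = NULL) {
  tok <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
  n <- length(tok)
  valid <- c(ap2 = 5L + 2L * 7L, ap3 = 5L + 3L * 7L,
             lat2 = 5L + 2L * 3L, lat3 = 5L + 3L * 3L)
  if (!n %in% valid)
    stop("dialect error: ", n, " tokens; expected ",
         paste(sort(unique(valid)), collapse = "/"),
         " (5 box tokens + 2 or 3 per keypoint, 7 AP / 3 LAT keypoints)",
         call. = FALSE)
  vals <- suppressWarnings(as.numeric(tok))
  if (anyNA(vals))
    stop("dialect error: non-numeric token '", tok[which(is.na(vals))[1L]], "'",
         call. = FALSE)
  per <- if (n %in% valid[c("ap3", "lat3")]) 3L else 2L
  arity <- (n - 5L) %/% per
  view <- if (arity == 7L) "AP" else "LAT"
  coords <- vals[2:5]
  body <- matrix(vals[-(1:5)], ncol = per, byrow = TRUE)
  if (any(coords < 0 | coords > 1) || any(body[, 1:2] < 0 | body[, 1:2] > 1))
    stop("coordinate out of range: YOLO-pose coordinates must be in [0, 1]",
         call. = FALSE)
  annotation_record(view, bounding_box(coords[1L], coords[2L], coords[3L], coords[4L]),
                    body[, 1:2, drop = FALSE], image_id = image_id,
                    image_size = image_size,
                    source = if (is.null(confidence)) "truth" else "prediction",
                    confidence = confidence,
                    visibility = if (per == 3L) as.integer(body[, 3L]) else NULL)
}

#' Serialize an annotation as a YOLO-pose text line
#'
#' Coordinates are printed with six decimal places, the precision at which
#' the dialect round-trips.
#'
#' @param record An [annotation_record()].
#' @param class_id Integer object class (single-class schema: 0).
#' @return A one-line character string (no trailing newline).
#' @export
write_yolo_pose <- function(record, class_id = 0L) {
  stopifnot(inherits(record, "elbow_annotation"))
  fmt <- function(x) sprintf("%.6f", x)
  k <- record$keypoints
  kp <- if (is.null(record$visibility)) {
    as.vector(t(k))
  } else {
    as.vector(t(cbind(k, record$visibility)))
  }
  paste(c(class_id, fmt(as.numeric(record$box)), fmt(kp)), collapse = " ")
}

#' Read a YOLO-pose label file
#'
#' One annotation per line; the image id defaults to the file stem.
#'
#' @inheritParams read_yolo_pose
#' @param path Path to a `.txt` label file.
#' @return A list of [annotation_record()]s.
#' @export
read_yolo_pose_file <- function(path, image_size = NULL, confidence = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty input: no annotation lines in ", path, call. = FALSE)
  id <- sub("\\.txt$", "", basename(path))
  lapply(lines, read_yolo_pose, image_id = id, image_size = image_size,
         confidence = confidence)
}

#' Read a dataset manifest
#'
#' A CSV with columns `image_id`, `view` and `path` (annotation file per
#' image); `format` (`"labelme"` or `"yolo"`) is inferred from the file
#' extension when absent. Returns the parsed records.
#'
#' @param path Manifest CSV path.
#' @param confidence Optional default confidence (marks records as
#'   predictions); a per-row `confidence` column in the manifest takes
#'   precedence. Without either, records are ground truth.
#' @return A named list of [annotation_record()]s keyed by `image_id`.
#' @export
read_manifest <- function(path, confidence = NULL) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "view", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  base <- dirname(path)
  recs <- lapply(seq_len(nrow(man)), function(i) {
    conf <- if ("confidence" %in% names(man) && is.finite(man$confidence[i]))
      man$confidence[i] else confidence
    f <- man$path[i]
    if (!file.exists(f)) f <- file.path(base, man$path[i])
    rec <- if (grepl("\\.json$", f)) read_labelme(f)
           else read_yolo_pose_file(f, confidence = conf)[[1L]]
    if (!is.null(conf) && rec$source == "truth") {
      rec$source <- "prediction"; rec$confidence <- conf
    }
    rec$image_id <- man$image_id[i]
    if (toupper(man$view[i]) != rec$view)
      stop("manifest view ", man$view[i], " does not match annotation view ",
           rec$view, " for ", man$image_id[i], call. = FALSE)
    rec
  })
  names(recs) <- man$image_id
  recs
}
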