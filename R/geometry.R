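# Pure geometric primitives on normalized image coordinates.
#
# Convention: origin top-left, x rightward, y downward (raster convention of
# the annotation tools that produce the input). All coordinates are fractions
# of image width/height, so every quantity below is dimensionless except
# angles, which are degrees externally and radians internally.

#' Construct a normalized 2-D point
#'
#' A point in normalized image coordinates: `x` is the fraction of image
#' width, `y` the fraction of image height, origin at the top-left corner.
#'
#' @param x,y Numeric scalars in `[0, 1]`.
#' @return A named numeric vector `c(x =, y =)`.
#' @export
#' @examples
#' point2d(0.5, 0.5)
point2d <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L || length(y) != 1L)
    stop("point coordinates must be numeric scalars", call. = FALSE)
  if (!is.finite(x) || !is.finite(y))
    stop("invalid coordinate: point coordinates must be finite", call. = FALSE)
  if (x < 0 || x > 1)
    stop("coordinate out of range on x axis: ", x, " not in [0, 1]", call. = FALSE)
  if (y < 0 || y > 1)
    stop("coordinate out of range on y axis: ", y, " not in [0, 1]", call. = FALSE)
  c(x = x, y = y)
}

# Accepts a length-2 numeric (named or not) and returns c(x, y); used by every
# operation so callers can pass bare vectors, matrix rows or point2d() output.
as_point <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 2L)
    stop(what, " must have exactly two coordinates", call. = FALSE)
  if (any(!is.finite(p)))
    stop("invalid coordinate: non-finite value in ", what, call. = FALSE)
  p
}

#' Normalize a pixel point to the unit square
#'
#' Divides pixel coordinates by image width and height, mapping the image
#' frame onto `[0, 1]^2`.
#'
#' @param p Pixel point, length-2 numeric `(px, py)`, or an n-by-2 matrix of
#'   pixel points.
#' @param image_size Length-2 numeric `(width, height)` in pixels, both > 0.
#' @return Normalized coordinates with the same shape as `p`.
#' @seealso [denormalize_point()]
#' @export
#' @examples
#' normalize_point(c(320, 240), c(640, 480))
normalize_point <- function(p, image_size) {
  image_size <- as.numeric(image_size)
  if (length(image_size) != 2L || any(!is.finite(image_size)) || any(image_size <= 0))
    stop("image_size must be positive (width, height)", call. = FALSE)
  if (is.matrix(p)) {
    return(t(apply(p, 1L, normalize_point, image_size = image_size)))
  }
  p <- as_point(p, "pixel point")
  if (p[1L] < 0 || p[1L] > image_size[1L])
    stop("coordinate out of range on x axis: ", p[1L], " not in [0, ",
         image_size[1L], "]", call. = FALSE)
  if (p[2L] < 0 || p[2L] > image_size[2L])
    stop("coordinate out of range on y axis: ", p[2L], " not in [0, ",
         image_size[2L], "]", call. = FALSE)
  c(x = p[1L] / image_size[1L], y = p[2L] / image_size[2L])
}

#' Map a normalized point back to pixel coordinates
#'
#' Inverse of [normalize_point()]: multiplies by image width and height.
#'
#' @inheritParams normalize_point
#' @param p Normalized point or n-by-2 matrix.
#' @return Pixel coordinates with the same shape as `p`.
#' @export
denormalize_point <- function(p, image_size) {
  image_size <- as.numeric(image_size)
  if (length(image_size) != 2L || any(image_size <= 0))
    stop("image_size must be positive (width, height)", call. = FALSE)
  if (is.matrix(p)) {
    return(t(apply(p, 1L, denormalize_point, image_size = image_size)))
  }
  p <- as_point(p, "normalized point")
  c(x = p[1L] * image_size[1L], y = p[2L] * image_size[2L])
}

#' Euclidean distance between two points
#'
#' The straight-line distance `sqrt((x1 - x2)^2 + (y1 - y2)^2)` in normalized
#' units; this is the distance used for the olecranon-fossa indices S17 and
#' S27 (keypoint 1 or 2 to keypoint 7).
#'
#' @param p,q Length-2 numeric points.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' euclidean_distance(c(0, 0), c(0.3, 0.4)) # 0.5
euclidean_distance <- function(p, q) {
  p <- as_point(p, "first point")
  q <- as_point(q, "second point")
  sqrt(sum((p - q)^2))
}

#' Flexion angle from three lateral-view keypoints
#'
#' The angle between the humerus segment (mid-humerus P1 to trochlea center
#' P2) and the radius segment (P2 to mid-radius P3), in degrees. A correctly
#' positioned lateral elbow radiograph has this angle close to 90 degrees.
#'
#' Two conventions are supported and agree at 90 degrees:
#' \describe{
#'   \item{`"vector"`}{(default) the angle between the *direction* vectors
#'     P1P2 and P2P3, `acos((P1P2 . P2P3) / (|P1P2| |P2P3|))`. A straight arm
#'     (collinear, same direction) gives 0.}
#'   \item{`"vertex"`}{the interior angle at P2 between rays P2->P1 and
#'     P2->P3, the anatomical convention under which a straight arm is 180.}
#' }
#' The two are supplements of one another.
#'
#' @param p1,p2,p3 Length-2 numeric points (mid-humerus, trochlea center,
#'   mid-radius).
#' @param convention `"vector"` or `"vertex"`; see Details.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
#' @examples
#' flexion_angle(c(0.5, 0.1), c(0.5, 0.5), c(0.9, 0.5)) # 90
flexion_angle <- function(p1, p2, p3, convention = c("vector", "vertex")) {
  convention <- match.arg(convention)
  p1 <- as_point(p1, "P1")
  p2 <- as_point(p2, "P2")
  p3 <- as_point(p3, "P3")
  v12 <- p2 - p1
  v23 <- p3 - p2
  n12 <- sqrt(sum(v12^2))
  n23 <- sqrt(sum(v23^2))
  if (n12 == 0)
    stop("degenerate geometry: segment P1P2 has zero length", call. = FALSE)
  if (n23 == 0)
    stop("degenerate geometry: segment P2P3 has zero length", call. = FALSE)
  # clamp absorbs floating-point overshoot for (anti)parallel segments
  cosang <- max(-1, min(1, sum(v12 * v23) / (n12 * n23)))
  ang <- acos(cosang) * 180 / pi
  if (convention == "vertex") ang <- 180 - ang
  ang
}

#' Construct a bounding box in center form
#'
#' Boxes are stored center-form `(cx, cy, w, h)` in normalized coordinates,
#' the YOLO-pose text convention.
#'
#' @param cx,cy Box center, in `[0, 1]`.
#' @param w,h Box width and height, in `(0, 1]`.
#' @return A named numeric vector of class `"bbox"`.
#' @seealso [box_from_corners()], [box_center()]
#' @export
bounding_box <- function(cx, cy, w, h) {
  v <- c(cx = cx, cy = cy, w = w, h = h)
  if (any(!is.finite(v)))
    stop("invalid coordinate: non-finite bounding-box field", call. = FALSE)
  if (cx < 0 || cx > 1 || cy < 0 || cy > 1)
    stop("bounding-box center out of [0, 1]", call. = FALSE)
  if (w <= 0 || w > 1 || h <= 0 || h > 1)
    stop("bounding-box size must be in (0, 1]", call. = FALSE)
  structure(v, class = "bbox")
}

#' Construct a bounding box from two corners
#'
#' Accepts corner-form input `(x1, y1)`--`(x2, y2)` in any corner order,
#' clips the extent to the unit square, and converts to center form.
#'
#' @param x1,y1,x2,y2 Opposite corner coordinates, normalized.
#' @return A `"bbox"` as from [bounding_box()].
#' @export
box_from_corners <- function(x1, y1, x2, y2) {
  xs <- sort(c(x1, x2))
  ys <- sort(c(y1, y2))
  xs <- pmin(pmax(xs, 0), 1)
  ys <- pmin(pmax(ys, 0), 1)
  bounding_box((xs[1L] + xs[2L]) / 2, (ys[1L] + ys[2L]) / 2,
               xs[2L] - xs[1L], ys[2L] - ys[1L])
}

#' Box center coordinates
#'
#' The center `(XA, YA)` of a detection box; the AP positioning criterion
#' requires it near the center of the normalized image.
#'
#' @param b A `"bbox"` (center form) or length-4 numeric `(cx, cy, w, h)`.
#' @return A point `c(x =, y =)`.
#' @export
box_center <- function(b) {
  b <- as.numeric(b)
  if (length(b) != 4L || any(!is.finite(b)))
    stop("box must have four finite fields (cx, cy, w, h)", call. = FALSE)
  c(x = b[1L], y = b[2L])
}

# Corner form (x1, y1, x2, y2) of a center-form box, clipped to the unit square.
box_corners <- function(b) {
  b <- as.numeric(b)
  c(x1 = max(0, b[1L] - b[3L] / 2), y1 = max(0, b[2L] - b[4L] / 2),
    x2 = min(1, b[1L] + b[3L] / 2), y2 = min(1, b[2L] + b[4L] / 2))
}

#' Construct the AP keypoint set
#'
#' Exactly seven anteroposterior-view landmarks, indexed as: 1 medial
#' epicondyle, 2 lateral epicondyle, 3 medial joint space inferior to the
#' humerus, 4 lateral joint space inferior to the humerus, 5 medial joint
#' space superior to the radius, 6 lateral joint space superior to the
#' radius, 7 center of the coronoid/olecranon fossa.
#'
#' @param k A 7-by-2 numeric matrix (rows = keypoints 1..7, columns x, y),
#'   or a list of seven length-2 points.
#' @return A 7-by-2 matrix of class `"ap_keypoints"`.
#' @export
ap_keypoints <- function(k) {
  k <- keypoint_matrix(k, 7L, "AP")
  structure(k, class = c("ap_keypoints", "matrix", "array"))
}

#' Construct the LAT keypoint set
#'
#' Exactly three lateral-view landmarks: 1 mid-humerus, 2 humeral trochlea
#' center, 3 mid-radius. Points 1/2 and 2/3 must be distinct or the flexion
#' angle is undefined.
#'
#' @param k A 3-by-2 numeric matrix or a list of three length-2 points.
#' @return A 3-by-2 matrix of class `"lat_keypoints"`.
#' @export
lat_keypoints <- function(k) {
  k <- keypoint_matrix(k, 3L, "LAT")
  if (all(k[1L, ] == k[2L, ]))
    stop("degenerate geometry: LAT keypoints 1 and 2 coincide", call. = FALSE)
  if (all(k[2L, ] == k[3L, ]))
    stop("degenerate geometry: LAT keypoints 2 and 3 coincide", call. = FALSE)
  structure(k, class = c("lat_keypoints", "matrix", "array"))
}

keypoint_matrix <- function(k, arity, view) {
  if (is.list(k)) k <- do.call(rbind, lapply(k, as_point))
  k <- as.matrix(k)
  storage.mode(k) <- "double"
  if (nrow(k) != arity || ncol(k) != 2L)
    stop("a ", view, " annotation requires exactly ", arity,
         " keypoints (got ", nrow(k), ")", call. = FALSE)
  if (any(!is.finite(k)))
    stop("invalid coordinate: non-finite keypoint", call. = FALSE)
  if (any(k < 0) || any(k > 1))
    stop("keypoint coordinates must be normalized to [0, 1]", call. = FALSE)
  dimnames(k) <- list(seq_len(arity), c("x", "y"))
  k
}
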