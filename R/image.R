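# Raster handling around the 640 x 640 model input frame. Images are plain
# integer matrices (rows = image rows, values 0..255); resizing goes through
# EBImage (bilinear), raster IO through the png/jpeg packages. Letterboxing
# is the default resize mode because it preserves the angles and distance
# ratios every QC criterion depends on; a stretch mode exists for strict
# emulation of stretch-resizing pipelines.

#' Construct an image record
#'
#' @param pixels Integer matrix, rows = image rows, values in 0..255.
#' @param original_size Pixel `(width, height)` of the source image; defaults
#'   to the matrix dimensions.
#' @param transform Mapping from the original frame to this frame (see
#'   [preprocess_image()]); identity by default.
#' @return A list of class `"elbow_image"`.
#' @export
image_record <- function(pixels, original_size = NULL, transform = NULL) {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L || nrow(pixels) == 0L || ncol(pixels) == 0L)
    stop("format error: zero-size image", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (is.null(original_size)) original_size <- c(ncol(pixels), nrow(pixels))
  if (is.null(transform))
    transform <- list(mode = "identity", scale_x = 1, scale_y = 1,
                      pad_x = 0, pad_y = 0,
                      size = c(ncol(pixels), nrow(pixels)))
  structure(list(pixels = pixels, original_size = as.numeric(original_size),
                 transform = transform),
            class = "elbow_image")
}

#' @export
print.elbow_image <- function(x, ...) {
  cat(sprintf("image %dx%d (WxH), original %dx%d, transform %s\n",
              ncol(x$pixels), nrow(x$pixels),
              x$original_size[1L], x$original_size[2L], x$transform$mode))
  invisible(x)
}

resize_matrix <- function(m, w, h) {
  if (ncol(m) == w && nrow(m) == h) return(m)
  img <- EBImage::Image(t(m) / 255)           # EBImage is x-major
  out <- EBImage::resize(img, w = w, h = h)
  matrix(as.integer(round(pmin(pmax(t(EBImage::imageData(out)), 0), 1) * 255)),
         nrow = h, ncol = w)
}

#' Resize an image to the square model input frame
#'
#' Letterbox mode (default) scales uniformly so the long side fits `size`,
#' then pads the short side symmetrically with a constant fill, preserving
#' aspect ratio; stretch mode scales each axis independently. The recorded
#' transform maps original pixel coordinates to frame coordinates and is
#' invertible to within half a pixel.
#'
#' @param img An [image_record()].
#' @param size Output side length in pixels (640, the model input).
#' @param mode `"letterbox"` or `"stretch"`.
#' @param fill Pad intensity for letterboxing, 0..255.
#' @return An [image_record()] whose pixels are exactly `size` x `size`.
#' @export
preprocess_image <- function(img, size = 640L,
                             mode = c("letterbox", "stretch"), fill = 114L) {
  mode <- match.arg(mode)
  stopifnot(inherits(img, "elbow_image"))
  m <- img$pixels
  w <- ncol(m); h <- nrow(m)
  if (mode == "stretch") {
    out <- resize_matrix(m, size, size)
    tr <- list(mode = "stretch", scale_x = size / w, scale_y = size / h,
               pad_x = 0, pad_y = 0, size = c(size, size))
  } else {
    s <- size / max(w, h)
    nw <- round(w * s); nh <- round(h * s)
    content <- resize_matrix(m, nw, nh)
    out <- matrix(as.integer(fill), size, size)
    px <- floor((size - nw) / 2); py <- floor((size - nh) / 2)
    out[(py + 1L):(py + nh), (px + 1L):(px + nw)] <- content
    tr <- list(mode = "letterbox", scale_x = s, scale_y = s,
               pad_x = px, pad_y = py, size = c(size, size))
  }
  image_record(out, original_size = c(w, h), transform = tr)
}

#' Map points between the original and preprocessed frames
#'
#' `frame_to_original` maps a normalized point in the preprocessed (e.g.
#' 640 x 640) frame back to pixel coordinates in the original image;
#' `original_to_frame` is its inverse.
#'
#' @param p Normalized point in the preprocessed frame
#'   (`frame_to_original`) or pixel point in the original image
#'   (`original_to_frame`); an n-by-2 matrix is mapped row-wise.
#' @param transform The `transform` element of a preprocessed
#'   [image_record()].
#' @param original_size Original pixel `(width, height)`.
#' @return Mapped coordinates with the same shape as `p`.
#' @export
frame_to_original <- function(p, transform, original_size) {
  if (is.matrix(p))
    return(t(apply(p, 1L, frame_to_original, transform = transform,
                   original_size = original_size)))
  p <- as_point(p)
  fx <- p[1L] * transform$size[1L]
  fy <- p[2L] * transform$size[2L]
  c(x = (fx - transform$pad_x) / transform$scale_x,
    y = (fy - transform$pad_y) / transform$scale_y)
}

#' @rdname frame_to_original
#' @export
original_to_frame <- function(p, transform, original_size) {
  if (is.matrix(p))
    return(t(apply(p, 1L, original_to_frame, transform = transform,
                   original_size = original_size)))
  p <- as_point(p)
  c(x = (p[1L] * transform$scale_x + transform$pad_x) / transform$size[1L],
    y = (p[2L] * transform$scale_y + transform$pad_y) / transform$size[2L])
}

#' Read a PNG or JPEG raster as an image record
#'
#' Color images are converted to grayscale with the Rec. 601 luma weights.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An [image_record()].
#' @export
read_raster <- function(path) {
  a <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
       else if (grepl("\\.jpe?g$", path, ignore.case = TRUE)) jpeg::readJPEG(path)
       else stop("format error: unsupported raster extension for ", path,
                 call. = FALSE)
  if (length(dim(a)) == 3L)
    a <- 0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
  image_record(matrix(as.integer(round(a * 255)), nrow(a), ncol(a)))
}

#' Write an image record as PNG or JPEG
#'
#' @param img An [image_record()].
#' @param path Output path ending in `.png`, `.jpg` or `.jpeg`.
#' @param quality JPEG quality in (0, 1]; ignored for PNG.
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path, quality = 0.95) {
  stopifnot(inherits(img, "elbow_image"))
  a <- img$pixels / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::writePNG(a, path)
  else if (grepl("\\.jpe?g$", path, ignore.case = TRUE))
    jpeg::writeJPEG(a, path, quality = quality)
  else stop("format error: unsupported raster extension for ", path,
            call. = FALSE)
  invisible(path)
}
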