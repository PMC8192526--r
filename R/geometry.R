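# Bounding-box geometry for annotation targets. Coordinates are 0-based
# pixels, intervals half-open [x, x+width), so tiling arithmetic is exact.

#' Construct a bounding box
#'
#' @param x,y Integer pixel coordinates of the top-left corner (0-based).
#' @param width,height Positive integer extents in pixels.
#' @return A one-row `data.frame` with columns `x`, `y`, `width`, `height`.
#' @export
bounding_box <- function(x, y, width, height) {
  stopifnot(length(x) == 1L, length(y) == 1L)
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    stop("bounding box width and height must be positive")
  data.frame(x = as.integer(x), y = as.integer(y),
             width = as.integer(width), height = as.integer(height))
}

#' Logistic (sigmoid) probability mapping
#'
#' Maps a raw model score z to a probability `1 / (1 + exp(-z))`, the mapping
#' used to turn classifier scores into probabilities in `[0, 1]`.
#'
#' @param raw_score Finite numeric vector of raw scores.
#' @return Probabilities strictly inside (0, 1).
#' @export
#' @examples
#' sigmoid(0)      # 0.5
#' sigmoid(log(3)) # 0.75
sigmoid <- function(raw_score) {
  if (!is.numeric(raw_score) || any(!is.finite(raw_score)))
    stop("sigmoid requires finite numeric input")
  1 / (1 + exp(-raw_score))
}

# split one extent into ceil(len/limit) equal-as-possible half-open strips
.split_extent <- function(origin, len, limit) {
  n <- ceiling(len / limit)
  base <- len %/% n
  rem <- len %% n
  sizes <- rep(base, n) + c(rep(1L, rem), rep(0L, n - rem))
  starts <- origin + c(0L, cumsum(sizes)[-n])
  data.frame(start = as.integer(starts), size = as.integer(sizes))
}

#' Split an oversized region into sub-boxes within a side limit
#'
#' Annotated regions must not exceed 608 px on a side; larger regions are
#' decomposed into a deterministic grid of `ceiling(side/limit)` strips per
#' axis, as equal as possible, that tile the input exactly (disjoint,
#' covering).
#'
#' @param box A bounding box (one-row data.frame from [bounding_box()]).
#' @param limit Maximum allowed side, default 608 px.
#' @return A data.frame of boxes, one row each, tiling `box`.
#' @export
#' @examples
#' nrow(split_roi(bounding_box(0, 0, 500, 400)))   # 1
#' nrow(split_roi(bounding_box(0, 0, 1216, 608)))  # 2
split_roi <- function(box, limit = 608L) {
  stopifnot(nrow(box) == 1L, box$width > 0, box$height > 0)
  xs <- .split_extent(box$x, box$width, limit)
  ys <- .split_extent(box$y, box$height, limit)
  grid <- expand.grid(ix = seq_len(nrow(xs)), iy = seq_len(nrow(ys)))
  data.frame(x = xs$start[grid$ix], y = ys$start[grid$iy],
             width = xs$size[grid$ix], height = ys$size[grid$iy])
}

# clamp a window of length size to [0, dim); returns start
.clamp_start <- function(center, size, dim) {
  start <- round(center - size / 2)
  max(0L, min(as.integer(start), dim - size))
}

#' Context crop around a target box
#'
#' Returns a `size` x `size` (default 1216) region centred on the input box,
#' carrying neighbourhood context for downstream classification. When the
#' centred window would overrun the slide it is shifted inward, preserving its
#' size; if the slide itself is smaller than `size` in a dimension the crop
#' covers the full extent in that dimension (the caller pads on read).
#'
#' @param box A bounding box within the slide.
#' @param slide_dims Integer `c(width, height)` of the slide in pixels.
#' @param size Crop side, default 1216 px.
#' @return A bounding box data.frame; a `padded` attribute marks dimensions
#'   where the slide was smaller than `size`.
#' @export
context_crop <- function(box, slide_dims, size = 1216L) {
  stopifnot(nrow(box) == 1L, length(slide_dims) == 2L)
  w <- as.integer(slide_dims[1]); h <- as.integer(slide_dims[2])
  cx <- box$x + box$width / 2
  cy <- box$y + box$height / 2
  out_w <- min(size, w); out_h <- min(size, h)
  res <- data.frame(
    x = .clamp_start(cx, out_w, w), y = .clamp_start(cy, out_h, h),
    width = out_w, height = out_h)
  attr(res, "padded") <- c(width = w < size, height = h < size)
  res
}

#' Intersection-over-union of two boxes
#'
#' @param a,b Bounding boxes (one row each).
#' @return IoU in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$width, b$x + b$width) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$height, b$y + b$height) - max(a$y, b$y))
  inter <- ix * iy
  union <- a$width * a$height + b$width * b$height - inter
  inter / union
}

#' Bilinear resize of a grayscale or RGB image
#'
#' Utility used when normalising crops to a fixed input size (e.g. 299 x 299
#' for fine-grained classification).
#'
#' @param img Numeric matrix (grayscale) or h x w x 3 array.
#' @param width,height Output size in pixels.
#' @return Resized image of the same kind.
#' @export
resize_bilinear <- function(img, width, height) {
  rs1 <- function(m) {
    sr <- nrow(m); sc <- ncol(m)
    # sample at pixel centres
    ry <- (seq_len(height) - 0.5) * sr / height - 0.5
    rx <- (seq_len(width) - 0.5) * sc / width - 0.5
    y0 <- pmin(pmax(floor(ry), 0), sr - 1); x0 <- pmin(pmax(floor(rx), 0), sc - 1)
    y1 <- pmin(y0 + 1, sr - 1); x1 <- pmin(x0 + 1, sc - 1)
    fy <- ry - y0; fx <- rx - x0
    fy <- pmin(pmax(fy, 0), 1); fx <- pmin(pmax(fx, 0), 1)
    m00 <- m[cbind(rep(y0 + 1, width), rep(x0 + 1, each = height))]
    m01 <- m[cbind(rep(y0 + 1, width), rep(x1 + 1, each = height))]
    m10 <- m[cbind(rep(y1 + 1, width), rep(x0 + 1, each = height))]
    m11 <- m[cbind(rep(y1 + 1, width), rep(x1 + 1, each = height))]
    wy <- rep(fy, width); wx <- rep(fx, each = height)
    v <- (1 - wy) * (1 - wx) * m00 + (1 - wy) * wx * m01 +
      wy * (1 - wx) * m10 + wy * wx * m11
    matrix(v, height, width)
  }
  if (length(dim(img)) == 2L) return(rs1(img))
  out <- array(0, c(height, width, dim(img)[3]))
  for (k in seq_len(dim(img)[3])) out[, , k] <- rs1(img[, , k])
  out
}
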