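# Nucleus morphometry: gray-value and size statistics computed from a
# segmentation mask paired with an image crop. Nuclear enlargement and
# hyperchromasia are the key markers of squamous intraepithelial lesions, so
# targets classified SC, ASC_L_S or ASC_H_S are routed here.

#' Convert an 8-bit RGB image to grayscale
#'
#' Uses ITU-R BT.601 luminance weights (0.299 R + 0.587 G + 0.114 B), the
#' common imaging-library convention, rounded to integers.
#'
#' @param rgb_image h x w x 3 numeric array with values in \[0, 255\].
#' @return h x w numeric matrix of gray values in \[0, 255\].
#' @export
#' @examples
#' to_grayscale(array(255, c(2, 2, 3)))[1, 1]  # 255
to_grayscale <- function(rgb_image) {
  d <- dim(rgb_image)
  if (length(d) != 3L || d[3] != 3L)
    stop("expected an h x w x 3 RGB array")
  if (min(rgb_image) < 0 || max(rgb_image) > 255)
    stop("expected 8-bit values in [0, 255]")
  round(0.299 * rgb_image[, , 1] + 0.587 * rgb_image[, , 2] +
          0.114 * rgb_image[, , 3])
}

#' Nucleus statistics under a segmentation mask
#'
#' Computes the mean gray value and the area of the segmented nucleus
#' (nuclei). Area in square micrometres assumes the scanning resolution of
#' 0.25 um/pixel, i.e. one pixel = 0.0625 um^2.
#'
#' @param gray_image Numeric matrix of gray values.
#' @param mask Logical (or 0/1, or 0/255) matrix of the same shape; TRUE marks
#'   nucleus pixels. Must contain at least one TRUE pixel (an empty mask
#'   signals failed segmentation upstream and is an error).
#' @param um_per_px Scan resolution, default 0.25 um/pixel.
#' @return A one-row data.frame: `mean_gray`, `area_px`, `area_um2`,
#'   `n_components` (4-connected components in the mask).
#' @export
#' @examples
#' img <- matrix(100, 10, 10)
#' m <- matrix(FALSE, 10, 10); m[3:7, 3:7] <- TRUE
#' nucleus_stats(img, m)
nucleus_stats <- function(gray_image, mask, um_per_px = 0.25) {
  if (!all(dim(mask) == dim(gray_image)))
    stop("mask and image dimensions differ")
  m <- mask > 0
  area <- sum(m)
  if (area == 0L)
    stop("empty nucleus mask: segmentation produced no foreground")
  data.frame(
    mean_gray = mean(gray_image[m]),
    area_px = as.integer(area),
    area_um2 = area * um_per_px^2,
    n_components = .count_components(m))
}

# 4-connected components by label propagation
.count_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  idx <- which(m, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (lab[i, j] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ni <- p[1] + d[1]; nj <- p[2] + d[2]
        if (ni >= 1L && ni <= nrow(m) && nj >= 1L && nj <= ncol(m) &&
            m[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  nxt
}

#' Read a mask image (single-channel PNG, 0/255) as a logical matrix
#'
#' @param path PNG path.
#' @return Logical matrix, TRUE where the mask is set.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' Read an 8-bit image (PNG or TIFF) as a 0..255 array
#'
#' @param path Image path; format chosen by extension.
#' @return Numeric matrix (grayscale) or h x w x 3 array, values in
#'   \[0, 255\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L && dim(img)[3] > 3L)
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  round(img * 255)
}

#' Write an 8-bit image (PNG)
#'
#' @param img Matrix or h x w x 3 array with values in \[0, 255\].
#' @param path Output PNG path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}
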