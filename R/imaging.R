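#' Grayscale images for spectral feature extraction
#'
#' A `gray_image` is a plain numeric matrix (rows = image rows, 0-based
#' `(row, column)` coordinates in all documentation) carrying finite
#' intensities, canonically in `[0, 255]`.  Images smaller than 8x8 are
#' rejected: the central-spectrum ellipse fit is meaningless below that.
#'
#' @param pixels numeric matrix of intensities.
#' @return a `gray_image` (matrix with class attribute).
#' @examples
#' img <- gray_image(matrix(0, 16, 16))
#' dim(img)
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    format_error("image must be a numeric matrix")
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    format_error("image must be at least 8x8, got %dx%d",
                 nrow(pixels), ncol(pixels))
  if (!all(is.finite(pixels)))
    format_error("image intensities must be finite")
  structure(pixels, class = c("gray_image", class(pixels)))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%g, %g]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Read a grayscale image from a PNG file
#'
#' Color images collapse to grayscale by the Rec. 601 luma weighting
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel is ignored.  Intensities
#' are rescaled from the PNG unit range to `[0, 255]`.
#'
#' @param path path to an 8- or 16-bit PNG file.
#' @return a [gray_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) input_error("image file not found: %s", path)
  if (!grepl("\\.png$", path, ignore.case = TRUE))
    format_error("unsupported image format (PNG expected): %s", basename(path))
  a <- png::readPNG(path)
  px <- if (length(dim(a)) == 2L) a
  else if (dim(a)[3] >= 3L)
    0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  else a[, , 1]
  if (is.null(dim(px)) || any(dim(px) == 0L))
    format_error("zero-sized or non-2D image: %s", path)
  gray_image(round(px * 255))
}

#' Write a grayscale image to an 8-bit PNG file
#'
#' Intensities are clipped to `[0, 255]` and quantized to 8 bits, so the
#' [load_image()] round trip is lossless for integer-valued images.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  m <- pmin(pmax(unclass(img), 0), 255)
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Read a binary region-of-interest mask from a PNG file
#'
#' Nonzero pixels are inside the region.
#'
#' @param path path to a PNG of the same size as its paired image.
#' @return logical matrix.
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) input_error("mask file not found: %s", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a > 0
}

#' Crop an image to its region of interest
#'
#' Returns the tight bounding box of the mask.  Pixels inside the box but
#' outside the mask are replaced by the mean of the masked pixels, so the
#' crop does not inject artificial hard edges into the Fourier spectrum
#' (a zero fill would dominate it).
#'
#' @param img a [gray_image()].
#' @param mask logical matrix of the same shape, `TRUE` inside the ROI.
#' @return a [gray_image()] covering the mask bounding box.
#' @export
apply_roi <- function(img, mask) {
  if (!is.logical(mask)) mask <- mask > 0
  if (!identical(dim(img), dim(mask)))
    contract_error("mask shape %s does not match image shape %s",
                   paste(dim(mask), collapse = "x"),
                   paste(dim(img), collapse = "x"))
  if (!any(mask)) contract_error("ROI mask has no TRUE pixel")
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  sub  <- unclass(img)[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  msub <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  sub[!msub] <- mean(sub[msub])
  gray_image(sub)
}

#' Enhance a B-mode-like image before feature extraction
#'
#' Default pipeline: a 3x3 median filter (speckle suppression) followed by
#' a linear contrast stretch mapping the 1st-99th intensity percentiles to
#' `[0, 255]`.  Either stage can be disabled.  On a constant image the
#' stretch gain is undefined, so that stage is skipped with a warning.
#'
#' @param img a [gray_image()].
#' @param median_filter apply the 3x3 median filter?
#' @param contrast_stretch apply the percentile stretch?
#' @param probs length-2 percentile pair for the stretch.
#' @return a [gray_image()] of the same shape.
#' @export
enhance <- function(img, median_filter = TRUE, contrast_stretch = TRUE,
                    probs = c(0.01, 0.99)) {
  m <- unclass(img)
  if (median_filter) m <- median3(m)
  if (contrast_stretch) {
    lo <- stats::quantile(m, probs[1], names = FALSE)
    hi <- stats::quantile(m, probs[2], names = FALSE)
    if (hi > lo) {
      m <- pmin(pmax((m - lo) / (hi - lo) * 255, 0), 255)
    } else {
      warning("constant image: contrast stretch skipped")
    }
  }
  gray_image(m)
}

# 3x3 median filter with replicate padding at the borders.
median3 <- function(m) {
  M <- nrow(m); N <- ncol(m)
  stack <- array(NA_real_, c(M, N, 9))
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    r <- pmin(pmax(seq_len(M) + dr, 1L), M)
    cc <- pmin(pmax(seq_len(N) + dc, 1L), N)
    stack[, , k] <- m[r, cc]
  }
  apply(stack, c(1, 2), stats::median)
}
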