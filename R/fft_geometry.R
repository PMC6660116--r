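#' Fourier spectrum of a grayscale image
#'
#' Computes the 2D discrete Fourier transform of an image with the
#' \eqn{1/(MN)} normalization applied to both the real and imaginary
#' parts, i.e.
#' \deqn{F(u,v) = \frac{1}{MN}\sum_{x=0}^{M-1}\sum_{y=0}^{N-1}
#'   f(x,y)\,e^{-2\pi i (ux/M + vy/N)}.}
#' Under this convention a constant image of value \eqn{c} has
#' \eqn{F(0,0)=c}, and Parseval's identity reads
#' \eqn{\sum_{u,v}\|F\|^2 = \frac{1}{MN}\sum_{x,y} f^2}.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @return a `spectrum_image`: list with `re`, `im`, `modulus`, `phase`
#'   matrices and a `centered` flag (`FALSE` on creation).
#' @export
compute_dft <- function(img) {
  m <- unclass(img)
  if (!is.matrix(m) || !is.numeric(m) || !all(is.finite(m)))
    contract_error("compute_dft needs a finite numeric matrix")
  Fc <- stats::fft(m) / length(m)
  spectrum_image(Re(Fc), Im(Fc), centered = FALSE)
}

spectrum_image <- function(re, im, centered = FALSE) {
  structure(list(
    re = re, im = im,
    modulus = sqrt(re^2 + im^2),
    phase = ifelse(re == 0 & im == 0, 0, atan2(im, re)),
    centered = centered
  ), class = "spectrum_image")
}

#' @export
print.spectrum_image <- function(x, ...) {
  cat(sprintf("<spectrum_image %d x %d, %scentered>\n",
              nrow(x$re), ncol(x$re), if (x$centered) "" else "not "))
  invisible(x)
}

#' Spectrum modulus
#'
#' \eqn{\|F(u,v)\| = \sqrt{\mathrm{Re}(F)^2 + \mathrm{Im}(F)^2}},
#' elementwise.
#'
#' @param spec a `spectrum_image`.
#' @return non-negative numeric matrix.
#' @export
spectrum_modulus <- function(spec) sqrt(spec$re^2 + spec$im^2)

#' Spectrum phase
#'
#' Four-quadrant angle \eqn{\phi(F) = \mathrm{atan2}(\mathrm{Im}, \mathrm{Re})}
#' in radians in \eqn{(-\pi, \pi]}; cells with `Re = Im = 0` return 0.
#' Only the modulus is used downstream (the magnitude carries the geometric
#' information); the phase is provided for completeness.
#'
#' @param spec a `spectrum_image`.
#' @return numeric matrix of angles.
#' @export
spectrum_phase <- function(spec) {
  ifelse(spec$re == 0 & spec$im == 0, 0, atan2(spec$im, spec$re))
}

#' Shift the zero-frequency term to the grid center
#'
#' Cyclically rolls every plane of the spectrum so that frequency (0, 0)
#' lands at (`floor(M/2)`, `floor(N/2)`) (0-based), the usual "fftshift".
#' Total spectral energy is unchanged.
#'
#' @param spec a non-centered `spectrum_image`.
#' @return the centered `spectrum_image`.
#' @export
center_spectrum <- function(spec) {
  if (isTRUE(spec$centered)) contract_error("spectrum is already centered")
  M <- nrow(spec$re); N <- ncol(spec$re)
  # output cell (i, j) pulls from input ((i - 1 - floor(M/2)) mod M) + 1,
  # so input (1, 1) (frequency 0) lands at (floor(M/2)+1, floor(N/2)+1)
  sr <- 1L + (seq_len(M) - 1L - M %/% 2L) %% M
  sc <- 1L + (seq_len(N) - 1L - N %/% 2L) %% N
  spectrum_image(spec$re[sr, sc, drop = FALSE],
                 spec$im[sr, sc, drop = FALSE],
                 centered = TRUE)
}

# 1-based (row, col) of the centered zero-frequency cell.
spectrum_center <- function(M, N) c(M %/% 2L + 1L, N %/% 2L + 1L)

#' Binarize a centered spectrum at a threshold on the log-modulus
#'
#' The mask is `TRUE` where `log(1 + modulus)` strictly exceeds the
#' threshold.  When `threshold` is `NULL` the threshold defaults to the
#' image's own `q`-quantile of the log-modulus; a trained global
#' threshold (see [train_threshold()] / [pooled_log_threshold()], the
#' recommended route — per-image quantiles fix the super-threshold pixel
#' budget and wash out between-image differences in spectral spread) is
#' passed through `threshold`.  The center cell (the zero-frequency term,
#' carrying the total image energy) is always forced `TRUE` so a central
#' blob exists even for degenerate spectra.
#'
#' @param spec a centered `spectrum_image`.
#' @param q quantile in (0, 1); ignored when `threshold` is given.
#' @param threshold optional absolute threshold on `log(1 + modulus)`.
#' @return a `binary_spectrum`: list with logical `mask`, `threshold_used`,
#'   `quantile_used` (`NA` under an absolute threshold).
#' @export
binarize_spectrum <- function(spec, q = NULL, threshold = NULL) {
  if (!isTRUE(spec$centered))
    contract_error("binarize_spectrum needs a centered spectrum")
  lm <- log1p(spectrum_modulus(spec))
  if (is.null(threshold)) {
    if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1)
      contract_error("quantile q must lie strictly in (0, 1)")
    thr <- stats::quantile(lm, q, names = FALSE)
  } else {
    thr <- threshold
    q <- q %||% NA_real_
  }
  mask <- lm > thr
  ctr <- spectrum_center(nrow(mask), ncol(mask))
  mask[ctr[1], ctr[2]] <- TRUE
  structure(list(mask = mask, threshold_used = thr, quantile_used = q),
            class = "binary_spectrum")
}

# 8-connected component of `mask` containing linear index `start`.
# Vectorized frontier flood fill; returns linear indices.
connected_component <- function(mask, start) {
  M <- nrow(mask); N <- ncol(mask)
  if (!mask[start]) return(integer(0))
  seen <- matrix(FALSE, M, N)
  seen[start] <- TRUE
  frontier <- start
  comp <- start
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  while (length(frontier)) {
    r <- (frontier - 1L) %% M + 1L
    cc <- (frontier - 1L) %/% M + 1L
    nr <- rep(r, times = 8L) + rep(dr, each = length(r))
    nc <- rep(cc, times = 8L) + rep(dc, each = length(r))
    ok <- nr >= 1L & nr <= M & nc >= 1L & nc <= N
    ni <- (nc[ok] - 1L) * M + nr[ok]
    ni <- unique(ni[mask[ni] & !seen[ni]])
    seen[ni] <- TRUE
    comp <- c(comp, ni)
    frontier <- ni
  }
  comp
}

#' Moment ellipse of the central spectral blob
#'
#' Takes the 8-connected component of the mask containing the center cell
#' and summarizes it by (a) its pixel count and (b) the full axis lengths
#' of the ellipse with the same second central moments: axis length =
#' 4 sqrt(eigenvalue) of the 2x2 covariance of the component's pixel
#' coordinates.  This convention recovers the exact diameters of an ideal
#' filled ellipse.  Degenerate (thin or single-pixel) components floor
#' each axis at 1 pixel, so `major >= minor >= 1` always holds.
#'
#' @param bin a `binary_spectrum` (or any list with a logical `mask` whose
#'   center cell is `TRUE`).
#' @return an `ffgf_vector`: named numeric `c(major, minor, area)`.
#' @export
central_ellipse <- function(bin) {
  mask <- bin$mask
  M <- nrow(mask); N <- ncol(mask)
  ctr <- spectrum_center(M, N)
  start <- (ctr[2] - 1L) * M + ctr[1]
  if (!mask[start]) contract_error("center cell of the mask must be TRUE")
  comp <- connected_component(mask, start)
  area <- length(comp)
  r <- (comp - 1L) %% M + 1L
  cc <- (comp - 1L) %/% M + 1L
  if (area == 1L) {
    ev <- c(0, 0)
  } else {
    # population covariance of pixel coordinates
    S <- stats::cov(cbind(r, cc)) * (area - 1) / area
    ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
  }
  axes <- pmax(4 * sqrt(pmax(ev, 0)), 1)
  structure(c(major = axes[1], minor = axes[2], area = as.numeric(area)),
            class = "ffgf_vector")
}

#' Extract the 3D FFGF descriptor of an image
#'
#' Composition of the full feature pipeline: DFT, center, binarize (at
#' the per-image quantile `q`, or at a trained absolute `threshold` when
#' supplied), fit the central moment ellipse.  Returns the
#' (major axis, minor axis, area) triple.  Because only the spectrum
#' modulus is used, the descriptor is invariant under cyclic spatial
#' translation of the image.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param q binarization quantile in (0, 1).
#' @param threshold optional trained absolute threshold on the
#'   log-modulus (see [train_threshold()]).
#' @return an `ffgf_vector`: named numeric `c(major, minor, area)`.
#' @export
extract_ffgf <- function(img, q = NULL, threshold = NULL) {
  central_ellipse(binarize_spectrum(center_spectrum(compute_dft(img)),
                                    q, threshold = threshold))
}

#' Default quantile grid for threshold training
#' @export
ffgf_quantile_grid <- function() c(0.90, 0.925, 0.95, 0.975, 0.99, 0.995)

# Fisher ratio (between-class variance over within-class variance) of a
# single feature; Inf when classes separate with zero within-class spread.
fisher_ratio <- function(x, t) {
  m <- mean(x)
  between <- 0; within <- 0
  for (cl in c(-1, 1)) {
    xi <- x[t == cl]
    between <- between + length(xi) * (mean(xi) - m)^2
    within <- within + sum((xi - mean(xi))^2)
  }
  if (within == 0) {
    if (between == 0) 0 else Inf
  } else between / within
}

#' Pooled global threshold on the log-modulus
#'
#' The `q`-quantile of `log(1 + modulus)` pooled over all cells of all
#' supplied spectra: one absolute cut applied to every image, so images
#' with more spectral spread (more geometric discontinuity) grow larger
#' central blobs.
#'
#' @param spectra list of `spectrum_image`.
#' @param q quantile in (0, 1).
#' @return the absolute threshold value.
#' @export
pooled_log_threshold <- function(spectra, q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1)
    contract_error("quantile q must lie strictly in (0, 1)")
  stats::quantile(unlist(lapply(spectra, function(s)
    log1p(spectrum_modulus(s)))), q, names = FALSE)
}

#' Train the binarization quantile on labeled spectra
#'
#' For each candidate quantile `q`, the training spectra are binarized at
#' the pooled global threshold [pooled_log_threshold()] at `q` and the
#' blob area extracted; the returned quantile maximizes the Fisher ratio
#' (between-class over within-class variance) of the area feature.  Ties
#' break toward the smaller quantile; a candidate separating the classes
#' with zero within-class variance is returned immediately.
#'
#' @param spectra list of `spectrum_image` (centered or not).
#' @param labels +1/-1 vector, one per spectrum, both classes present.
#' @param grid candidate quantiles in (0, 1).
#' @return the selected quantile; the matching absolute threshold is
#'   recomputed from the same spectra by [pooled_log_threshold()].
#' @export
train_threshold <- function(spectra, labels, grid = ffgf_quantile_grid()) {
  labels <- assert_labels(labels)
  if (length(spectra) != length(labels))
    contract_error("one label per spectrum required")
  if (length(unique(labels)) < 2L)
    contract_error("threshold training needs both classes")
  spectra <- lapply(spectra, function(s)
    if (isTRUE(s$centered)) s else center_spectrum(s))
  areas <- sapply(grid, function(q) {
    thr <- pooled_log_threshold(spectra, q)
    vapply(spectra, function(s)
      central_ellipse(binarize_spectrum(s, threshold = thr))[["area"]],
      numeric(1))
  })
  select_quantile(as.matrix(areas), labels, grid)
}

# Shared selection rule on a precomputed (n_images x n_quantiles) area
# matrix; used by train_threshold and the fold-wise CV hook.
select_quantile <- function(areas, labels, grid) {
  grid_order <- order(grid)  # scan ascending so ties keep the smaller q
  best_q <- grid[grid_order[1]]; best_f <- -Inf
  for (j in grid_order) {
    f <- fisher_ratio(areas[, j], labels)
    if (is.infinite(f)) return(grid[j])
    if (f > best_f) { best_f <- f; best_q <- grid[j] }
  }
  best_q
}
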