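#' Specification of a synthetic ultrasound-like phantom
#'
#' The phantom emulates the two image classes the spectral features are
#' designed to separate: a benign-like cyst is a smooth dark ellipse with
#' soft walls and few internal structures; a malignant-like mass carries
#' many bright internal structures (papillary blobs, septa, arcs) that
#' create geometric discontinuities, hence more mid-frequency spectral
#' energy.  Defaults: `texture_density` 2 for benign (+1), 25 for
#' malignant (-1); multiplicative exponential speckle of strength 0.3.
#'
#' @param size `c(M, N)` image size in pixels (default 128 x 128).
#' @param class_label +1 (benign) or -1 (malignant).
#' @param texture_density expected count of internal structures
#'   (Poisson rate, `>= 0`); default depends on `class_label`.
#' @param speckle multiplicative speckle strength in `[0, 1]`.
#' @param seed integer; the phantom is a pure function of this spec.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(size = c(128L, 128L), class_label = 1,
                         texture_density = if (class_label == 1) 2 else 25,
                         speckle = 0.3, seed = 1L) {
  if (!class_label %in% c(-1, 1)) contract_error("class_label must be +1/-1")
  if (texture_density < 0) contract_error("texture_density must be >= 0")
  if (speckle < 0) contract_error("speckle level must be >= 0")
  structure(list(size = as.integer(size), class_label = class_label,
                 texture_density = texture_density, speckle = speckle,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Separable Gaussian blur, edge-renormalized band matrices.
blur_gaussian <- function(m, sigma) {
  band <- function(n) {
    K <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = sigma)
    K / rowSums(K)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Generate a phantom image and its ROI mask
#'
#' Draws the base cyst (dark interior, brighter soft wall on a dark
#' background), superimposes `Poisson(texture_density)` sharp internal
#' structures, multiplies by exponential speckle
#' (`pixel * ((1 - s) + s * Exp(1))`), and clips to `[0, 255]`.  The ROI
#' mask covers the (slightly dilated) cyst ellipse.  Output is
#' bit-reproducible from the spec alone.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a [gray_image()]), `mask` (logical matrix)
#'   and the `spec`.
#' @export
gen_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    M <- spec$size[1]; N <- spec$size[2]
    R <- matrix(seq_len(M), M, N)
    C <- matrix(seq_len(N), M, N, byrow = TRUE)
    ctr <- c(M / 2 + stats::runif(1, -3, 3), N / 2 + stats::runif(1, -3, 3))
    a <- stats::runif(1, 0.28, 0.36) * M
    b <- stats::runif(1, 0.24, 0.32) * N
    th <- stats::runif(1, 0, pi)
    xr <- (R - ctr[1]) * cos(th) + (C - ctr[2]) * sin(th)
    yr <- -(R - ctr[1]) * sin(th) + (C - ctr[2]) * cos(th)
    rho <- sqrt((xr / a)^2 + (yr / b)^2)
    img <- matrix(28, M, N)           # background tissue
    img[rho <= 1] <- 14               # cyst fluid
    img[rho > 0.88 & rho <= 1.04] <- 115  # cyst wall
    img <- blur_gaussian(img, 2)      # soft edges: benign walls are smooth
    n_struct <- stats::rpois(1, spec$texture_density)
    for (k in seq_len(n_struct)) {
      type <- sample(c("blob", "septum", "arc"), 1)
      u <- sqrt(stats::runif(1)) * 0.8
      ang <- stats::runif(1, 0, 2 * pi)
      px <- ctr[1] + u * a * (cos(ang) * cos(th) - sin(ang) * sin(th))
      py <- ctr[2] + u * b * (cos(ang) * sin(th) + sin(ang) * cos(th))
      if (type == "blob") {
        rad <- stats::runif(1, 1.5, 4)
        hit <- (R - px)^2 + (C - py)^2 <= rad^2
        img[hit] <- stats::runif(1, 150, 230)
      } else if (type == "septum") {
        la <- stats::runif(1, 0, pi)
        dist_line <- abs((R - px) * sin(la) - (C - py) * cos(la))
        img[dist_line <= 0.8 & rho <= 1] <- stats::runif(1, 140, 200)
      } else {
        rad <- stats::runif(1, 4, 12)
        a0 <- stats::runif(1, 0, 2 * pi)
        span <- stats::runif(1, 0.5, 2)
        rr <- sqrt((R - px)^2 + (C - py)^2)
        aa <- atan2(C - py, R - px)
        dd <- (aa - a0) %% (2 * pi)
        img[abs(rr - rad) <= 0.9 & dd <= span] <- stats::runif(1, 150, 210)
      }
    }
    if (spec$speckle > 0) {
      img <- img * ((1 - spec$speckle) +
                      spec$speckle * stats::rexp(M * N))
    }
    img <- pmin(pmax(img, 0), 255)
    list(image = gray_image(round(img)), mask = rho <= 1.08, spec = spec)
  })
}

#' Specification of two shared-covariance Gaussian feature clusters
#'
#' The linear discriminant is Bayes-optimal for Gaussian classes with a
#' shared covariance; this generator provides that reference world for
#' classifier testing.
#'
#' @param mu_benign,mu_malignant class means in `R^d`.
#' @param sigma shared `d x d` symmetric positive-definite covariance.
#' @param n_per_class cases per class, `>= 2`.
#' @param seed integer.
#' @return a `cluster_spec`.
#' @export
cluster_spec <- function(mu_benign, mu_malignant, sigma, n_per_class,
                         seed = 1L) {
  sigma <- as.matrix(sigma)
  if (!isSymmetric(sigma, tol = 1e-8) ||
      inherits(try(chol(sigma), silent = TRUE), "try-error"))
    contract_error("sigma must be symmetric positive definite")
  if (n_per_class < 2) contract_error("n_per_class must be >= 2")
  structure(list(mu_benign = mu_benign, mu_malignant = mu_malignant,
                 sigma = sigma, n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed)),
            class = "cluster_spec")
}

#' Sample a labeled dataset from two Gaussian clusters
#'
#' @param spec a [cluster_spec()].
#' @return a [labeled_dataset()]: `n_per_class` benign (+1) rows followed
#'   by `n_per_class` malignant (-1) rows.
#' @export
gen_feature_clusters <- function(spec) {
  stopifnot(inherits(spec, "cluster_spec"))
  d <- length(spec$mu_benign)
  L <- chol(spec$sigma)
  with_seed(spec$seed, {
    n <- spec$n_per_class
    Z <- matrix(stats::rnorm(2 * n * d), 2 * n, d) %*% L
    X <- Z + rbind(matrix(spec$mu_benign, n, d, byrow = TRUE),
                   matrix(spec$mu_malignant, n, d, byrow = TRUE))
    labeled_dataset(X, rep(c(1, -1), each = n))
  })
}

#' Write a two-class phantom benchmark to disk
#'
#' Generates `n_per_class` benign and `n_per_class` malignant phantoms,
#' writes each image and its ROI mask as 8-bit PNG, and a
#' `manifest.csv` (`image_id, label, seed, lambda, speckle, image, mask`).
#' Per-image seeds are derived deterministically from `seed`, so a rerun
#' reproduces the files byte for byte.
#'
#' @param out_dir output directory (created if missing).
#' @param n_per_class phantoms per class (default 40).
#' @param seed master seed.
#' @param lambda_benign,lambda_malignant texture densities per class.
#' @param speckle speckle strength.
#' @param size image size `c(M, N)`.
#' @return the manifest data.frame, invisibly; also written as CSV.
#' @export
gen_benchmark_suite <- function(out_dir, n_per_class = 40L, seed = 7L,
                                lambda_benign = 2, lambda_malignant = 25,
                                speckle = 0.3, size = c(128L, 128L)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) input_error("cannot create directory %s", out_dir)
  n <- as.integer(n_per_class)
  img_seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2L * n))
  label <- rep(c(1, -1), each = n)
  lambda <- ifelse(label == 1, lambda_benign, lambda_malignant)
  id <- sprintf("%s%03d", ifelse(label == 1, "benign", "malig"),
                c(seq_len(n), seq_len(n)))
  img_path <- file.path(out_dir, paste0(id, ".png"))
  mask_path <- file.path(out_dir, paste0(id, "_mask.png"))
  for (i in seq_along(id)) {
    ph <- gen_phantom(phantom_spec(size = size, class_label = label[i],
                                   texture_density = lambda[i],
                                   speckle = speckle, seed = img_seeds[i]))
    write_image(ph$image, img_path[i])
    write_image(ph$mask * 255, mask_path[i])
  }
  manifest <- data.frame(image_id = id, label = label, seed = img_seeds,
                         lambda = lambda, speckle = speckle,
                         image = basename(img_path),
                         mask = basename(mask_path))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
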