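#' Batch-extract FFGF features with a pooled threshold
#'
#' Computes each image's centered spectrum, pools the log-moduli to fix
#' the global threshold at quantile `q` (see [pooled_log_threshold()]),
#' and extracts each image's (major, minor, area) triple at that cut.
#'
#' @param images list of [gray_image()] (or numeric matrices).
#' @param q binarization quantile.
#' @return `N x 3` matrix with columns `major`, `minor`, `area`;
#'   attribute `"threshold"` carries the pooled cut used.
#' @export
extract_features <- function(images, q = 0.975) {
  spectra <- lapply(images, function(im) center_spectrum(compute_dft(im)))
  thr <- pooled_log_threshold(spectra, q)
  X <- t(vapply(spectra, function(s)
    unclass(central_ellipse(binarize_spectrum(s, threshold = thr))),
    numeric(3)))
  colnames(X) <- c("major", "minor", "area")
  structure(X, threshold = thr)
}

#' Case-indexed dataset over a list of images
#'
#' Wraps images for fold-wise trained feature extraction inside
#' [loocv()]: the dataset's single "feature" is the case index, and the
#' paired [threshold_trainer()] hook maps training indices to FFGF
#' features after training the binarization threshold on the fold's
#' training spectra only.  Spectra are computed once here; images may
#' differ in size.
#'
#' @param images list of [gray_image()] (or numeric matrices).
#' @param labels +1/-1 vector.
#' @return a [labeled_dataset()] whose `X` is the `N x 1` index matrix,
#'   with the centered spectra stored in attribute `"spectra"`.
#' @export
spectra_dataset <- function(images, labels) {
  spectra <- lapply(images, function(im) center_spectrum(compute_dft(im)))
  X <- matrix(seq_along(images), ncol = 1L,
              dimnames = list(NULL, "case"))
  d <- labeled_dataset(X, labels)
  attr(d$X, "spectra") <- spectra
  d
}

#' Fold-wise binarization-threshold trainer for [loocv()]
#'
#' Returns a `preprocess` hook for a [spectra_dataset()]: given a fold's
#' training portion, it trains the binarization quantile on the training
#' spectra only ([train_threshold()]'s Fisher-ratio rule), fixes the
#' pooled absolute threshold, and returns the transform mapping case
#' indices to (major, minor, area) features at that trained cut.  The
#' held-out case contributes to neither the quantile choice nor the
#' pooled threshold.
#'
#' @param spectra the full list of centered spectra (the hook indexes
#'   into it with the training indices the fold supplies).
#' @param grid candidate quantiles (default [ffgf_quantile_grid()]).
#' @param record optional environment for auditing: each fold appends
#'   its chosen quantile to `record$chosen` and the set of case indices
#'   shown to the trainer to `record$seen`.
#' @return a function suitable as the `preprocess` argument of [loocv()].
#' @export
threshold_trainer <- function(spectra, grid = ffgf_quantile_grid(),
                              record = NULL) {
  function(train) {
    ids <- as.integer(train$X[, 1])
    tr_spectra <- spectra[ids]
    # candidate-wise pooled thresholds and training feature triples
    feats_by_q <- vector("list", length(grid))
    areas <- matrix(NA_real_, length(ids), length(grid))
    for (j in seq_along(grid)) {
      thr <- pooled_log_threshold(tr_spectra, grid[j])
      F <- t(vapply(tr_spectra, function(s)
        unclass(central_ellipse(binarize_spectrum(s, threshold = thr))),
        numeric(3)))
      feats_by_q[[j]] <- structure(F, threshold = thr)
      areas[, j] <- F[, 3]
    }
    q <- select_quantile(areas, train$t, grid)
    j <- match(q, grid)
    thr <- attr(feats_by_q[[j]], "threshold")
    if (is.environment(record)) {
      record$chosen <- c(record$chosen, q)
      record$seen <- c(record$seen, list(ids))
    }
    function(X) {
      out_ids <- as.integer(X[, 1])
      hit <- match(out_ids, ids)
      out <- matrix(NA_real_, length(out_ids), 3L,
                    dimnames = list(NULL, c("major", "minor", "area")))
      if (any(!is.na(hit)))  # training rows: reuse the fills from above
        out[!is.na(hit), ] <- feats_by_q[[j]][hit[!is.na(hit)], ]
      for (k in which(is.na(hit)))
        out[k, ] <- central_ellipse(
          binarize_spectrum(spectra[[out_ids[k]]], threshold = thr))
      out
    }
  }
}

#' Load a benchmark directory and apply an imaging setting
#'
#' Reads `manifest.csv` plus the images/masks a [gen_benchmark_suite()]
#' run (or any directory with the same layout) produced, and applies one
#' of the four imaging settings: `original` (no preprocessing),
#' `enhanced` (median filter + contrast stretch), `roi` (crop to the
#' mask), `roi-enhanced` (enhance the full image, then crop).
#'
#' @param dir directory containing `manifest.csv`.
#' @param setting one of `"original"`, `"enhanced"`, `"roi"`,
#'   `"roi-enhanced"`.
#' @return list with `images` (list of [gray_image()]), `labels`, and the
#'   `manifest`.
#' @export
load_benchmark <- function(dir,
                           setting = c("original", "enhanced", "roi",
                                       "roi-enhanced")) {
  setting <- match.arg(setting)
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) input_error("no manifest.csv in %s", dir)
  mf <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  images <- lapply(seq_len(nrow(mf)), function(i) {
    img <- load_image(file.path(dir, mf$image[i]))
    if (setting %in% c("enhanced", "roi-enhanced")) img <- enhance(img)
    if (setting %in% c("roi", "roi-enhanced"))
      img <- apply_roi(img, load_mask(file.path(dir, mf$mask[i])))
    img
  })
  list(images = images, labels = mf$label, manifest = mf)
}

#' Read / write a run configuration
#'
#' Configurations are YAML mappings mirroring [run_experiment()]'s `cfg`
#' argument and round-trip losslessly.
#'
#' @param path YAML file path.
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) input_error("config file not found: %s", path)
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param cfg configuration list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run a full extract-train-evaluate experiment
#'
#' Orchestrates the pipeline on a benchmark directory: load images under
#' the configured setting, run LOO-CV with the fold-wise threshold
#' trainer and the configured classifier (the repeated protocol for the
#' stochastic ELM family when `reps > 1`), and write a self-describing
#' JSON report (schema version, package version, resolved config,
#' per-fold chosen quantiles, confusion counts, ACC / AUC / SEN / SPE,
#' per-case scores).
#'
#' @param cfg configuration list (or path to a YAML file): fields
#'   `images` (benchmark directory), `setting`, `grid`, `classifier`
#'   (list with `method` and hyperparameters), `reps`, `seed`,
#'   `positive` (`"benign"` or `"malignant"`), `out` (report path,
#'   optional).
#' @return the report list, invisibly if written to `cfg$out`.
#' @export
run_experiment <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  setting <- cfg$setting %||% "original"
  grid <- cfg$grid %||% ffgf_quantile_grid()
  seed <- cfg$seed %||% 1L
  reps <- cfg$reps %||% 1L
  positive <- if ((cfg$positive %||% "benign") == "malignant") -1 else 1
  cls <- cfg$classifier %||% list(method = "ld")
  spec <- do.call(classifier_spec, cls)

  bench <- load_benchmark(cfg$images, setting = setting)
  data <- spectra_dataset(bench$images, bench$labels)
  rec <- new.env()
  hook <- threshold_trainer(attr(data$X, "spectra"), grid, record = rec)

  stochastic <- spec$method %in% c("elm", "opelm")
  if (stochastic && reps > 1L) {
    summ <- repeat_elm_loocv(data, spec, R = reps, base_seed = seed,
                             preprocess = hook, positive = positive)
    rep_out <- summ$best
    extra <- list(repetitions = reps, seeds = summ$seeds,
                  mean = as.list(summ$mean), sd = as.list(summ$sd))
  } else {
    rep_out <- loocv(data, spec, seed = seed, preprocess = hook,
                     positive = positive)
    extra <- list(repetitions = 1L, seeds = seed)
  }
  report <- c(list(
    schema = "ffgf-report/1",
    package_version = as.character(utils::packageVersion("ffgf")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = list(images = cfg$images, setting = setting, grid = grid,
                  classifier = cls, reps = reps, seed = seed,
                  positive = cfg$positive %||% "benign"),
    method = spec$method,
    acc = rep_out$acc, auc = rep_out$auc,
    sen = rep_out$sen, spe = rep_out$spe,
    counts = unclass(rep_out$counts),
    chosen_quantiles = rec$chosen,
    scores = rep_out$scores
  ), extra)
  if (!is.null(cfg$out)) {
    jsonlite::write_json(report, cfg$out, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    return(invisible(report))
  }
  report
}
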