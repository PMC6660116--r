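#' Labeled feature dataset
#'
#' Bundles an `N x d` feature matrix with +1/-1 targets.  The package
#' convention (following the clinical labeling of the source problem) is
#' +1 = benign (class C1), -1 = malignant (class C2); sensitivity is
#' therefore computed for the +1 class unless re-flagged in the
#' evaluation functions.
#'
#' @param X numeric matrix, one row per case (a vector is treated as a
#'   single-feature column).
#' @param t numeric vector of targets in `{+1, -1}`.
#' @return a `labeled_dataset` with elements `X` and `t`.
#' @examples
#' d <- labeled_dataset(matrix(rnorm(20 * 3), 20), rep(c(1, -1), 10))
#' nrow(d$X)
#' @export
labeled_dataset <- function(X, t) {
  if (is.vector(X)) X <- matrix(X, ncol = 1L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  t <- assert_labels(t)
  if (nrow(X) != length(t))
    contract_error("X has %d rows but t has %d targets", nrow(X), length(t))
  if (anyNA(X) || !all(is.finite(X)))
    contract_error("features must be finite with no missing values")
  if (nrow(X) < 2L) contract_error("a dataset needs at least 2 cases")
  structure(list(X = X, t = t), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d cases x %d features, %d benign (+1) / %d malignant (-1)>\n",
              nrow(x$X), ncol(x$X), sum(x$t == 1), sum(x$t == -1)))
  invisible(x)
}

assert_two_classes <- function(t) {
  if (length(unique(t)) < 2L)
    contract_error("supervised fitting needs both classes present")
  invisible(t)
}

# Subset a labeled_dataset by row index.
dataset_subset <- function(data, idx) {
  labeled_dataset(data$X[idx, , drop = FALSE], data$t[idx])
}

# label = sign(score) with score 0 mapped to +1 (documented tie rule).
score_to_label <- function(score) ifelse(score >= 0, 1, -1)

#' Read a feature table from CSV
#'
#' Expects the header `image_id,major,minor,area,label` (the `label`
#' column may be absent for unlabeled extraction output).
#'
#' @param path CSV path.
#' @return a `labeled_dataset` when labels are present, otherwise a list
#'   with `X` and `image_id`.
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) input_error("feature file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("major", "minor", "area")
  if (!all(need %in% names(df)))
    format_error("feature CSV must have columns major, minor, area")
  X <- as.matrix(df[, need])
  rownames(X) <- df$image_id
  if ("label" %in% names(df) && !anyNA(df$label))
    labeled_dataset(X, df$label)
  else list(X = X, image_id = df$image_id)
}

#' Write a feature table to CSV
#'
#' @param X feature matrix with columns major, minor, area.
#' @param path output path.
#' @param image_id row identifiers (defaults to rownames or indices).
#' @param label optional +1/-1 labels.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(X, path, image_id = NULL, label = NULL) {
  X <- as.matrix(X)
  if (is.null(image_id))
    image_id <- rownames(X) %||% sprintf("img%04d", seq_len(nrow(X)))
  df <- data.frame(image_id = image_id, major = X[, 1], minor = X[, 2],
                   area = X[, 3])
  if (!is.null(label)) df$label <- label
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
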