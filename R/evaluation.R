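#' Confusion counts for +1/-1 labels
#'
#' The positive class is +1 (benign under the package convention).
#'
#' @param labels_true,labels_pred +1/-1 vectors of equal length.
#' @return a `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(labels_true, labels_pred) {
  assert_labels(labels_true); assert_labels(labels_pred)
  if (length(labels_true) != length(labels_pred) || length(labels_true) < 1L)
    contract_error("label vectors must have equal positive length")
  structure(list(
    TP = sum(labels_true == 1 & labels_pred == 1),
    TN = sum(labels_true == -1 & labels_pred == -1),
    FP = sum(labels_true == -1 & labels_pred == 1),
    FN = sum(labels_true == 1 & labels_pred == -1)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP=%d TN=%d FP=%d FN=%d>\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Classification accuracy, `(TP + TN) / total`
#' @param c a [confusion()] result.
#' @return fraction in `[0, 1]`.
#' @export
accuracy <- function(c) {
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) contract_error("accuracy undefined for zero cases")
  (c$TP + c$TN) / total
}

#' Sensitivity and specificity
#'
#' `sen = TP / (TP + FN)` (true-positive rate of the +1 class),
#' `spe = TN / (TN + FP)`.
#'
#' @param c a [confusion()] result.
#' @return named numeric `c(sen, spe)`.
#' @export
sensitivity_specificity <- function(c) {
  if (c$TP + c$FN == 0)
    contract_error("sensitivity undefined: no positive (+1) cases")
  if (c$TN + c$FP == 0)
    contract_error("specificity undefined: no negative (-1) cases")
  c(sen = c$TP / (c$TP + c$FN), spe = c$TN / (c$TN + c$FP))
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney form: the fraction of (positive, negative) pairs in which
#' the positive case scores higher, counting ties as 1/2.  Equivalent to
#' trapezoidal integration of the ROC curve over score thresholds.
#'
#' @param scores real decision scores, higher = more positive.
#' @param labels_true +1/-1 vector.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels_true) {
  assert_labels(labels_true)
  pos <- labels_true == 1
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    contract_error("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Describe a classifier configuration for the CV harness
#'
#' @param method one of `"knn"`, `"ld"`, `"svm"`, `"elm"`, `"opelm"`.
#' @param ... hyperparameters: `K`, `p` (knn); `trainer`, `C` (svm);
#'   `M`, `node_types` (elm); `M_init`, `node_types` (opelm).
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(method = c("knn", "ld", "svm", "elm", "opelm"),
                            ...) {
  method <- match.arg(method)
  structure(c(list(method = method), list(...)), class = "classifier_spec")
}

#' Fit the classifier a `classifier_spec` describes
#'
#' @param spec a [classifier_spec()].
#' @param data a [labeled_dataset()].
#' @param seed passed to the stochastic fitters (ELM/OP-ELM); ignored by
#'   the deterministic ones.
#' @return a fitted model with a `predict` method.
#' @export
fit_classifier <- function(spec, data, seed = NULL) {
  switch(spec$method,
    knn = knn_fit(data, K = spec$K %||% 1L, p = spec$p %||% 2),
    ld = ld_fit(data),
    svm = svm_fit(data, trainer = spec$trainer %||% "SMO",
                  C = spec$C %||% 1),
    elm = elm_fit(data, M = spec$M %||% 20L,
                  node_types = spec$node_types %||% "sigmoid", seed = seed),
    opelm = op_elm_fit(data, M_init = spec$M_init %||% 100L,
                       node_types = spec$node_types %||% "sigmoid",
                       seed = seed))
}

# Assemble an eval_report from per-case truths, predictions and scores.
eval_report <- function(t, labels_pred, scores, positive = 1,
                        hidden = NULL) {
  if (positive == -1) { t <- -t; labels_pred <- -labels_pred; scores <- -scores }
  cts <- confusion(t, labels_pred)
  ss <- sensitivity_specificity(cts)
  structure(list(
    acc = accuracy(cts), auc = auc(scores, t),
    sen = ss[["sen"]], spe = ss[["spe"]], counts = cts,
    scores = data.frame(score = scores, label = t, predicted = labels_pred),
    mean_hidden = if (is.null(hidden)) NULL else mean(hidden)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: ACC %.4f  AUC %.4f  SEN %.4f  SPE %.4f (n=%d)>\n",
              x$acc, x$auc, x$sen, x$spe, nrow(x$scores)))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' For each case `i`, the classifier (and any trained preprocessing
#' supplied through `preprocess`) is fit on the other `N - 1` cases and
#' case `i` is scored; the four performance measures are computed once
#' from the pooled per-case predictions after all `N` folds.
#'
#' `preprocess`, when given, is called once per fold with the fold's
#' training [labeled_dataset()] only — the held-out case is never shown
#' to it — and must return a feature-transform `function(X)` applied to
#' both the training and the test features.  The fold-wise binarization
#' quantile trainer of the image pipeline is the canonical use.
#'
#' @param data a [labeled_dataset()] with `N >= 3`.
#' @param spec a [classifier_spec()].
#' @param seed optional integer; per-fold fitting seeds are derived from
#'   it so stochastic classifiers are reproducible.
#' @param preprocess optional fold-wise trained transform (see above).
#' @param positive +1 (benign, default) or -1: which class counts as
#'   positive for SEN/SPE/AUC.
#' @return an `eval_report`.
#' @export
loocv <- function(data, spec, seed = NULL, preprocess = NULL, positive = 1) {
  stopifnot(inherits(data, "labeled_dataset"))
  N <- nrow(data$X)
  if (N < 3L) contract_error("LOO-CV needs at least 3 cases")
  fold_seeds <- if (is.null(seed)) NULL
                else with_seed(seed, sample.int(.Machine$integer.max, N))
  scores <- numeric(N); labels <- numeric(N)
  hidden <- if (spec$method == "opelm") numeric(N) else NULL
  for (i in seq_len(N)) {
    train <- dataset_subset(data, -i)
    if (length(unique(train$t)) < 2L)
      contract_error("training portion of fold %d holds a single class", i)
    Xte <- data$X[i, , drop = FALSE]
    if (!is.null(preprocess)) {
      tf <- preprocess(train)
      train <- labeled_dataset(tf(train$X), train$t)
      Xte <- tf(Xte)
    }
    model <- fit_classifier(spec, train, seed = fold_seeds[i])
    pred <- predict(model, Xte)
    scores[i] <- pred$score; labels[i] <- pred$label
    if (!is.null(hidden)) hidden[i] <- model$n_hidden
  }
  eval_report(data$t, labels, scores, positive = positive, hidden = hidden)
}

#' Repeated LOO-CV for randomly initialized classifiers
#'
#' Runs [loocv()] `R` times with seeds `base_seed .. base_seed + R - 1`
#' (the 30-repetition protocol used for ELMs, whose hidden weights are
#' random) and summarizes the repetitions: the best report (highest ACC,
#' ties by AUC), and mean and sample standard deviation of ACC, AUC and
#' — for OP-ELM — the selected hidden-neuron count.
#'
#' @param data a [labeled_dataset()].
#' @param spec a [classifier_spec()].
#' @param R repetition count (default 30).
#' @param base_seed first seed.
#' @inheritParams loocv
#' @return a `repetition_summary` with `reports`, `best`, `mean`, `sd`.
#' @export
repeat_elm_loocv <- function(data, spec, R = 30L, base_seed = 1L,
                             preprocess = NULL, positive = 1) {
  if (R < 1L) contract_error("R must be >= 1")
  seeds <- base_seed + seq_len(R) - 1L
  reports <- lapply(seeds, function(s)
    loocv(data, spec, seed = s, preprocess = preprocess,
          positive = positive))
  accs <- vapply(reports, `[[`, numeric(1), "acc")
  aucs <- vapply(reports, `[[`, numeric(1), "auc")
  hid <- vapply(reports, function(r) r$mean_hidden %||% NA_real_, numeric(1))
  best <- reports[[order(-accs, -aucs)[1]]]
  structure(list(
    reports = reports, seeds = seeds, best = best,
    mean = c(acc = mean(accs), auc = mean(aucs), hidden = mean(hid)),
    sd = c(acc = stats::sd(accs), auc = stats::sd(aucs),
           hidden = stats::sd(hid))
  ), class = "repetition_summary")
}

#' @export
print.repetition_summary <- function(x, ...) {
  cat(sprintf(
    "<repetition_summary: R=%d  best ACC %.4f  ACC %.4f+/-%.4f  AUC %.4f+/-%.4f>\n",
    length(x$reports), x$best$acc, x$mean[["acc"]], x$sd[["acc"]],
    x$mean[["auc"]], x$sd[["auc"]]))
  invisible(x)
}
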