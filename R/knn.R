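#' Minkowski distance between two feature vectors
#'
#' \eqn{d(a, b) = (\sum_i |a_i - b_i|^p)^{1/p}}; `p = 1` is the city-block
#' metric, `p = 2` the Euclidean distance.
#'
#' @param a,b numeric vectors of equal length.
#' @param p exponent, `p >= 1`.
#' @return non-negative scalar.
#' @export
minkowski_distance <- function(a, b, p = 2) {
  if (length(a) != length(b)) contract_error("vectors must have equal length")
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 1)
    contract_error("Minkowski exponent p must be >= 1")
  sum(abs(a - b)^p)^(1 / p)
}

#' Fit a k-nearest-neighbor classifier
#'
#' KNN is memory-based: all training cases are retained and the fit only
#' validates and stores them.
#'
#' @param data a [labeled_dataset()].
#' @param K neighbor count, `1 <= K <= N`.
#' @param p Minkowski exponent (1 = city block, 2 = Euclidean).
#' @return a `knn_model`.
#' @export
knn_fit <- function(data, K = 1L, p = 2) {
  stopifnot(inherits(data, "labeled_dataset"))
  assert_two_classes(data$t)
  if (K < 1L || K > nrow(data$X))
    contract_error("K must lie in [1, %d], got %s", nrow(data$X), K)
  if (p < 1) contract_error("Minkowski exponent p must be >= 1")
  structure(list(K = as.integer(K), p = p, X = data$X, t = data$t),
            class = c("knn_model", "ffgf_model"))
}

#' Predict with a KNN model
#'
#' Majority vote among the K nearest training cases.  The score is
#' `(votes for +1 - votes for -1) / K` in `[-1, 1]`, usable for ROC
#' curves.  Distance ties break toward the lower training index; vote
#' ties (even K) break toward +1 via the `score >= 0` rule.
#'
#' @param object a `knn_model`.
#' @param newdata matrix of query rows (or a single vector).
#' @param ... unused.
#' @return data.frame with columns `score` and `label`.
#' @export
predict.knn_model <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  n <- nrow(newdata)
  score <- numeric(n)
  for (i in seq_len(n)) {
    d <- apply(object$X, 1L, minkowski_distance, b = newdata[i, ],
               p = object$p)
    nb <- order(d, seq_along(d))[seq_len(object$K)]  # index breaks ties
    score[i] <- sum(object$t[nb]) / object$K
  }
  data.frame(score = score, label = score_to_label(score))
}
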