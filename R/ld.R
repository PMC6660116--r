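#' Fit a least-squares linear discriminant
#'
#' Minimizes \eqn{E = \frac{1}{2}\sum_n (y_n - t_n)^2} over the affine
#' score \eqn{y(x) = w_0 + w \cdot x} by solving the least-squares
#' problem on the bias-augmented design matrix with the Moore-Penrose
#' pseudoinverse, computed through the singular value decomposition (so
#' rank-deficient designs are handled by the minimum-norm solution).
#'
#' @param data a [labeled_dataset()].
#' @return an `ld_model` with elements `w0` (bias) and `w` (weights).
#' @export
ld_fit <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  assert_two_classes(data$t)
  Xa <- cbind(1, data$X)
  w <- drop(lstsq(Xa, data$t))
  structure(list(w0 = w[1], w = w[-1]),
            class = c("ld_model", "ffgf_model"))
}

#' Predict with a linear discriminant
#'
#' Score is the affine function \eqn{w_0 + w \cdot x}; the label is +1
#' for positive scores, -1 for negative, and +1 when the score is exactly
#' 0 (documented tie rule).
#'
#' @param object an `ld_model`.
#' @param newdata matrix of query rows (or a single vector).
#' @param ... unused.
#' @return data.frame with columns `score` and `label`.
#' @export
predict.ld_model <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  score <- drop(newdata %*% object$w) + object$w0
  data.frame(score = score, label = score_to_label(score))
}
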