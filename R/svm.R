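#' Fit a linear-kernel support vector machine
#'
#' Two trainers are provided.  `"SMO"` solves the soft-margin dual by
#' sequential minimal optimization with a deterministic first-violator
#' scan (KKT tolerance `tol`, at most `10 * N` passes); the weight vector
#' is recovered as \eqn{w = \sum_n \alpha_n t_n x_n}.  `"LS"` solves the
#' least-squares SVM linear system (equality-constrained ridge form with
#' regularization `1/C`), in which every training case receives a dual
#' coefficient.  Both trainers are deterministic for a fixed dataset and
#' row order.
#'
#' @param data a [labeled_dataset()].
#' @param trainer `"SMO"` or `"LS"`.
#' @param C positive box/regularization constant (default 1).
#' @param tol SMO KKT tolerance.
#' @return an `svm_model` with `w`, `b`, `trainer`, `C`, `alpha`,
#'   `support_indices`.
#' @export
svm_fit <- function(data, trainer = c("SMO", "LS"), C = 1, tol = 1e-3) {
  stopifnot(inherits(data, "labeled_dataset"))
  assert_two_classes(data$t)
  trainer <- match.arg(trainer)
  if (!is.numeric(C) || C <= 0) contract_error("C must be positive")
  fit <- if (trainer == "SMO") svm_smo(data$X, data$t, C, tol)
         else svm_ls(data$X, data$t, C)
  structure(c(fit, list(trainer = trainer, C = C)),
            class = c("svm_model", "ffgf_model"))
}

# Platt-style SMO on the linear kernel.  Working pair: outer index = first
# KKT violator in a full deterministic scan; inner index maximizes
# |E_i - E_j| (ties toward the lower index).
svm_smo <- function(X, t, C, tol) {
  N <- nrow(X)
  K <- tcrossprod(X)
  alpha <- numeric(N)
  b <- 0
  max_passes <- 10L * N
  passes <- 0L
  repeat {
    changed <- 0L
    for (i in seq_len(N)) {
      Ei <- sum(alpha * t * K[, i]) + b - t[i]
      if (!((t[i] * Ei < -tol && alpha[i] < C) ||
            (t[i] * Ei > tol && alpha[i] > 0))) next
      E <- drop(K %*% (alpha * t)) + b - t
      # second index: try candidates by decreasing |E_i - E_j| (ties by
      # index) until one admits a productive update
      for (j in setdiff(order(-abs(Ei - E), seq_len(N)), i)) {
        Ej <- E[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (t[i] != t[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - t[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-12) next
        ai <- ai_old + t[i] * t[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - t[i] * (ai - ai_old) * K[i, i] -
          t[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - t[i] * (ai - ai_old) * K[i, j] -
          t[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1
             else if (aj > 0 && aj < C) b2
             else (b1 + b2) / 2
        changed <- changed + 1L
        break
      }
    }
    passes <- passes + 1L
    if (changed == 0L) break
    if (passes >= max_passes) {
      w <- drop(crossprod(X, alpha * t))
      primal <- 0.5 * sum(w^2) +
        C * sum(pmax(0, 1 - t * (drop(X %*% w) + b)))
      dual <- sum(alpha) - 0.5 * sum(w^2)
      ffgf_error("ffgf_convergence_error",
                 "SMO did not converge in %d passes (duality gap %.3g)",
                 max_passes, primal - dual)
    }
  }
  w <- drop(crossprod(X, alpha * t))
  list(w = w, b = b, alpha = alpha,
       support_indices = which(alpha > 1e-8))
}

# Least-squares SVM (Suykens form): solve
#   [ 0   t^T          ] [b]     [0]
#   [ t   Omega + I/C  ] [a]  =  [1],  Omega = (t t^T) * K,
# then w = X^T (a * t).
svm_ls <- function(X, t, C) {
  N <- nrow(X)
  Omega <- tcrossprod(t) * tcrossprod(X)
  A <- rbind(c(0, t), cbind(t, Omega + diag(N) / C))
  sol <- drop(lstsq(A, c(0, rep(1, N))))
  b <- sol[1]; a <- sol[-1]
  list(w = drop(crossprod(X, a * t)), b = b, alpha = a,
       support_indices = seq_len(N))
}

#' Predict with a linear SVM
#'
#' Score is \eqn{w \cdot x + b}; labels follow the same sign/tie rule as
#' [predict.ld_model()].
#'
#' @param object an `svm_model`.
#' @param newdata matrix of query rows (or a single vector).
#' @param ... unused.
#' @return data.frame with columns `score` and `label`.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  score <- drop(newdata %*% object$w) + object$b
  data.frame(score = score, label = score_to_label(score))
}
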