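#' Fit an extreme learning machine
#'
#' A single-hidden-layer network whose hidden parameters are drawn at
#' random and frozen; only the output weights are learned, by solving the
#' linear least-squares problem \eqn{H B = T} with the Moore-Penrose
#' pseudoinverse (\eqn{B = H^\dagger T}, via SVD).  Node types:
#' \describe{
#'   \item{linear}{\eqn{f(x) = w \cdot x + b}, `w` and `b` uniform on
#'     \eqn{[-1, 1]}.}
#'   \item{sigmoid}{logistic \eqn{1/(1+e^{-(w \cdot x + b)})}, same draw.}
#'   \item{gaussian}{\eqn{\exp(-\|x - w\|^2 / b^2)} with the center `w`
#'     drawn from the training points and the width `b` uniform on
#'     `[0.2, 0.8]` times the median pairwise training distance.}
#' }
#' Mixed layers (e.g. `c("linear", "sigmoid", "gaussian")`) split `M`
#' nodes in equal proportions, assigning remainders to the earlier-listed
#' types.  With `M = N` distinct training points and sigmoid nodes the
#' network interpolates the targets (zero training error) almost surely.
#'
#' Inputs are standardized internally (training mean and standard
#' deviation, stored in the model and applied at prediction), following
#' the usual OP-ELM convention: with `[-1, 1]` input weights, raw
#' features on large scales (such as blob areas) would saturate every
#' sigmoid node.
#'
#' @param data a [labeled_dataset()].
#' @param M hidden-node count, `M >= 1`.
#' @param node_types character vector over
#'   `{"linear", "sigmoid", "gaussian"}`.
#' @param seed integer fixing the random draw; `NULL` consumes the
#'   current RNG stream (used inside seeded cross-validation).
#' @return an `elm_model` with `nodes`, output weights `B`, `n_hidden`.
#' @export
elm_fit <- function(data, M, node_types = "sigmoid", seed = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!is.numeric(M) || M < 1) contract_error("M must be >= 1")
  M <- as.integer(M)
  std <- standardizer(data$X)
  Xs <- std$apply(data$X)
  nodes <- with_seed(seed, draw_hidden_nodes(M, node_types, Xs))
  H <- hidden_output(nodes, Xs)
  B <- lstsq(H, data$t)
  structure(list(nodes = nodes, B = drop(B), M = M, seed = seed,
                 n_hidden = M, center = std$center, scale = std$scale),
            class = c("elm_model", "ffgf_model"))
}

# Training-set standardization; zero-variance columns pass through.
standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl,
       apply = function(M) sweep(sweep(M, 2, ctr), 2, scl, "/"))
}

# Split M nodes over the listed types, remainders to earlier types, and
# draw each node's parameters.  Draws happen type-block by type-block in
# listed order so the layout is reproducible under a fixed seed.
draw_hidden_nodes <- function(M, node_types, X) {
  node_types <- match.arg(node_types, c("linear", "sigmoid", "gaussian"),
                          several.ok = TRUE)
  k <- length(node_types)
  counts <- rep(M %/% k, k)
  extra <- M %% k
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  d <- ncol(X)
  med_dist <- NULL
  nodes <- list()
  for (ti in seq_len(k)) {
    type <- node_types[ti]
    for (j in seq_len(counts[ti])) {
      if (type == "gaussian") {
        if (is.null(med_dist)) {
          med_dist <- stats::median(stats::dist(X))
          if (!is.finite(med_dist) || med_dist <= 0) med_dist <- 1
        }
        w <- X[sample.int(nrow(X), 1L), ]
        b <- stats::runif(1, 0.2, 0.8) * med_dist
      } else {
        w <- stats::runif(d, -1, 1)
        b <- stats::runif(1, -1, 1)
      }
      nodes[[length(nodes) + 1L]] <- list(type = type, w = w, b = b)
    }
  }
  nodes
}

# N x M hidden-layer output matrix (rows = cases, cols = nodes).
hidden_output <- function(nodes, X) {
  H <- matrix(NA_real_, nrow(X), length(nodes))
  for (j in seq_along(nodes)) {
    nd <- nodes[[j]]
    H[, j] <- switch(nd$type,
      linear = drop(X %*% nd$w) + nd$b,
      sigmoid = 1 / (1 + exp(-(drop(X %*% nd$w) + nd$b))),
      gaussian = exp(-rowSums(sweep(X, 2, nd$w)^2) / nd$b^2))
  }
  H
}

#' Predict with an extreme learning machine
#'
#' Score is \eqn{\sum_j \beta_j f_j(x)}; labels follow the sign/tie rule
#' of [predict.ld_model()].
#'
#' @param object an `elm_model`.
#' @param newdata matrix of query rows (or a single vector).
#' @param ... unused.
#' @return data.frame with columns `score` and `label`.
#' @export
predict.elm_model <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  score <- drop(hidden_output(object$nodes, Xs) %*% object$B)
  data.frame(score = score, label = score_to_label(score))
}

#' Closed-form leave-one-out error of a linear least-squares model
#'
#' Allen's PRESS statistic: with hat matrix
#' \eqn{P = H (H^T H)^\dagger H^T} and fitted values \eqn{\hat y = P t},
#' the leave-one-out residual of case `i` is
#' \eqn{(t_i - \hat y_i) / (1 - P_{ii})}, so no refitting is needed.
#' Returns the mean squared PRESS residual.  Leverages are clipped to
#' `1 - 1e-10` for numerical safety; `N > M` is required so residual
#' degrees of freedom exist.
#'
#' @param H numeric `N x M` regressor matrix (e.g. an ELM hidden-layer
#'   output matrix).
#' @param t numeric length-`N` target vector.
#' @return non-negative scalar.
#' @export
press_loo_error <- function(H, t) {
  H <- as.matrix(H)
  if (nrow(H) <= ncol(H))
    contract_error("PRESS needs N > M (got N = %d, M = %d)",
                   nrow(H), ncol(H))
  s <- svd(H)
  tol <- max(dim(H)) * .Machine$double.eps * max(s$d, 0)
  U <- s$u[, s$d > tol, drop = FALSE]
  h <- pmin(rowSums(U^2), 1 - 1e-10)
  yhat <- drop(U %*% crossprod(U, t))
  mean(((t - yhat) / (1 - h))^2)
}

#' Least Angle Regression entry order of regressor columns
#'
#' Runs the LARS path on standardized columns against the centered
#' target and records the order in which variables join the active set.
#' Columns with zero variance are appended at the end; if the active
#' Gram matrix becomes numerically singular the remaining columns are
#' appended by decreasing current correlation.
#'
#' @param X numeric `N x M` regressor matrix.
#' @param y numeric target vector.
#' @return integer permutation of `1:M` (most important first).
#' @export
lars_order <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  ctr <- scale(X, center = TRUE, scale = FALSE)
  nrm <- sqrt(colSums(ctr^2))
  usable <- which(nrm > 1e-12)
  dropped <- setdiff(seq_len(m), usable)
  if (length(usable) == 0L) return(seq_len(m))
  Xs <- sweep(ctr[, usable, drop = FALSE], 2, nrm[usable], "/")
  yc <- y - mean(y)
  p <- ncol(Xs)
  A <- integer(0)
  mu <- numeric(n)
  fallback <- integer(0)
  for (step in seq_len(p)) {
    c_all <- drop(crossprod(Xs, yc - mu))
    inactive <- setdiff(seq_len(p), A)
    if (length(A) == 0L) {
      j <- inactive[order(-abs(c_all[inactive]), inactive)[1]]
      A <- j
      inactive <- setdiff(inactive, j)
      if (length(inactive) == 0L) break
    }
    Cmax <- mean(abs(c_all[A]))
    if (Cmax < 1e-12) { fallback <- inactive; break }
    s <- sign(c_all[A]); s[s == 0] <- 1
    XA <- sweep(Xs[, A, drop = FALSE], 2, s, "*")
    G <- crossprod(XA)
    Ginv <- tryCatch(solve(G), error = function(e) NULL)
    if (is.null(Ginv) || sum(Ginv) <= 0) {
      fallback <- inactive[order(-abs(c_all[inactive]), inactive)]
      break
    }
    w <- rowSums(Ginv)
    Anorm <- 1 / sqrt(sum(w))
    u <- drop(XA %*% (w * Anorm))
    if (length(inactive) == 0L) break
    a <- drop(crossprod(Xs, u))
    g1 <- (Cmax - c_all[inactive]) / (Anorm - a[inactive])
    g2 <- (Cmax + c_all[inactive]) / (Anorm + a[inactive])
    cand <- pmin(ifelse(g1 > 1e-12, g1, Inf), ifelse(g2 > 1e-12, g2, Inf))
    if (all(!is.finite(cand))) { fallback <- inactive; break }
    pick <- order(cand, inactive)[1]
    gamma <- cand[pick]
    mu <- mu + gamma * u
    A <- c(A, inactive[pick])
  }
  ord <- c(A, fallback, setdiff(seq_len(p), c(A, fallback)))
  c(usable[ord], dropped)
}

#' Fit an optimally pruned extreme learning machine
#'
#' Builds an ELM with `M_init` hidden nodes (capped at `N - 2` so the
#' PRESS leave-one-out error stays defined), ranks the hidden-layer
#' columns by their Least Angle Regression entry order against the
#' targets, evaluates [press_loo_error()] on every prefix of the ranking,
#' and keeps the prefix with minimal PRESS (ties toward fewer neurons).
#' Output weights are refit on the kept columns.
#'
#' @param data a [labeled_dataset()].
#' @param M_init initial hidden-node count (default 100).
#' @param node_types as in [elm_fit()].
#' @param seed integer fixing the random draw; `NULL` uses the current
#'   RNG stream.
#' @return an `elm_model` whose `n_hidden` records the selected neuron
#'   count; `press` holds the PRESS value per prefix.
#' @export
op_elm_fit <- function(data, M_init = 100L, node_types = "sigmoid",
                       seed = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!is.numeric(M_init) || M_init < 1) contract_error("M_init must be >= 1")
  N <- nrow(data$X)
  if (N < 3L) contract_error("OP-ELM needs at least 3 cases")
  M <- min(as.integer(M_init), N - 2L)
  std <- standardizer(data$X)
  Xs <- std$apply(data$X)
  nodes <- with_seed(seed, draw_hidden_nodes(M, node_types, Xs))
  H <- hidden_output(nodes, Xs)
  ranking <- lars_order(H, data$t)
  press <- vapply(seq_len(M), function(k)
    press_loo_error(H[, ranking[seq_len(k)], drop = FALSE], data$t),
    numeric(1))
  k_best <- which.min(press)  # which.min takes the first (smallest k) tie
  keep <- ranking[seq_len(k_best)]
  B <- lstsq(H[, keep, drop = FALSE], data$t)
  structure(list(nodes = nodes[keep], B = drop(B), M = M, seed = seed,
                 n_hidden = k_best, press = press, ranking = ranking,
                 center = std$center, scale = std$scale),
            class = c("elm_model", "ffgf_model"))
}
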