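# Independent oracles used across the suite.  Each reimplements the
# checked quantity by direct enumeration or a dense solve, never through
# the package's own code path.

# Direct double-loop evaluation of the normalized 2D DFT:
#   F(u,v) = (1/MN) sum_xy f(x,y) exp(-2 pi i (ux/M + vy/N))
brute_dft <- function(m) {
  M <- nrow(m); N <- ncol(m)
  out <- matrix(complex(real = 0), M, N)
  for (u in 0:(M - 1)) for (v in 0:(N - 1)) {
    s <- 0 + 0i
    for (x in 0:(M - 1)) for (y in 0:(N - 1)) {
      s <- s + m[x + 1, y + 1] * exp(-2i * pi * (u * x / M + v * y / N))
    }
    out[u + 1, v + 1] <- s / (M * N)
  }
  out
}

# O(n^2) pairwise Mann-Whitney AUC with ties counted 1/2.
brute_auc <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == -1]
  tot <- 0
  for (p in ps) for (n in ns)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(ps) * length(ns))
}

# Exhaustive second-moment ellipse of a pixel set (double loop).
brute_moment_ellipse <- function(rows, cols) {
  n <- length(rows)
  mr <- sum(rows) / n; mc <- sum(cols) / n
  srr <- scc <- src <- 0
  for (i in seq_len(n)) {
    srr <- srr + (rows[i] - mr)^2
    scc <- scc + (cols[i] - mc)^2
    src <- src + (rows[i] - mr) * (cols[i] - mc)
  }
  S <- matrix(c(srr, src, src, scc), 2) / n
  ev <- sort(eigen(S, symmetric = TRUE)$values, decreasing = TRUE)
  pmax(4 * sqrt(pmax(ev, 0)), 1)
}

# Scalar queue-based 8-connected flood fill (independent of the
# vectorized frontier implementation).
brute_component <- function(mask, r0, c0) {
  M <- nrow(mask); N <- ncol(mask)
  seen <- matrix(FALSE, M, N)
  queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
  out <- NULL
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    out <- rbind(out, p)
    for (dr in -1:1) for (dc in -1:1) {
      r <- p[1] + dr; c <- p[2] + dc
      if (r >= 1 && r <= M && c >= 1 && c <= N &&
          mask[r, c] && !seen[r, c]) {
        seen[r, c] <- TRUE
        queue[[length(queue) + 1]] <- c(r, c)
      }
    }
  }
  out
}

# Dense normal-equations least squares (independent of the SVD route).
brute_normal_solve <- function(A, b) {
  solve(crossprod(A), crossprod(A, b))
}

# Explicit leave-one-out over a fitter/predictor pair.
brute_loo <- function(X, t, fit, pred) {
  n <- nrow(X)
  out <- data.frame(score = numeric(n), label = numeric(n))
  for (i in seq_len(n)) {
    m <- fit(X[-i, , drop = FALSE], t[-i])
    p <- pred(m, X[i, , drop = FALSE])
    out$score[i] <- p$score; out$label[i] <- p$label
  }
  out
}

# Small reproducible Gaussian two-class dataset.
toy_clusters <- function(n = 20, sep = 4, d = 3, seed = 1) {
  gen_feature_clusters(cluster_spec(rep(0, d), rep(sep / sqrt(d), d),
                                    diag(d), n, seed = seed))
}

# Tiny fast phantom for pipeline tests.
tiny_phantom <- function(seed, class_label = 1, lambda = NULL, size = 64L,
                         speckle = 0.3) {
  spec <- if (is.null(lambda))
    phantom_spec(size = c(size, size), class_label = class_label,
                 speckle = speckle, seed = seed)
  else
    phantom_spec(size = c(size, size), class_label = class_label,
                 texture_density = lambda, speckle = speckle, seed = seed)
  gen_phantom(spec)
}
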