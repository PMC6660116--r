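test_that("minkowski_distance: hand values, metric axioms, contract", {
  a <- c(1, 2, 3); b <- c(4, 6, 3)
  expect_equal(minkowski_distance(a, b, 2), 5)   # sqrt(9 + 16)
  expect_equal(minkowski_distance(a, b, 1), 7)   # city block
  expect_equal(minkowski_distance(b, a, 1), 7)   # symmetry
  expect_equal(minkowski_distance(a, a, 3.5), 0)
  expect_error(minkowski_distance(a, b, 0.5), class = "ffgf_contract_error")
  expect_error(minkowski_distance(a, c(1, 2), 2),
               class = "ffgf_contract_error")
})

test_that("knn: self-match, vote arithmetic, global vote, oracle", {
  X <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0),
             c(5, 5, 5), c(5.1, 5, 5))
  t <- c(1, 1, -1, -1, -1)
  d <- labeled_dataset(X, t)

  m1 <- knn_fit(d, K = 1)
  expect_equal(predict(m1, X[4, ])$label, -1)  # exact training point

  m3 <- knn_fit(d, K = 3)
  p <- predict(m3, c(0.05, 0, 0))   # neighbors labeled (1, 1, -1)
  expect_equal(p$label, 1)
  expect_equal(p$score, 1 / 3)

  mN <- knn_fit(d, K = 5)
  expect_equal(predict(mN, c(100, 0, 0))$label, -1)  # dataset majority

  expect_error(knn_fit(d, K = 6), class = "ffgf_contract_error")

  # exhaustive neighbor-enumeration oracle on random data
  set.seed(8)
  Xr <- matrix(rnorm(60), 20, 3); tr <- rep(c(1, -1), 10)
  mod <- knn_fit(labeled_dataset(Xr, tr), K = 5, p = 1)
  for (k in 1:5) {
    x <- rnorm(3)
    dists <- apply(Xr, 1, function(r) sum(abs(r - x)))
    nb <- order(dists, seq_along(dists))[1:5]
    expect_equal(predict(mod, x)$score, sum(tr[nb]) / 5)
  }
})

test_that("ld: closed forms, replication invariance, dense-solve oracle", {
  d <- labeled_dataset(matrix(c(-1, 1), 2, 1), c(-1, 1))
  m <- ld_fit(d)
  expect_equal(m$w0, 0, tolerance = 1e-12)
  expect_equal(unname(m$w), 1, tolerance = 1e-12)

  set.seed(13)
  X <- matrix(rnorm(60), 20, 3); t <- rep(c(1, -1), 10)
  m <- ld_fit(labeled_dataset(X, t))
  m2 <- ld_fit(labeled_dataset(rbind(X, X), c(t, t)))
  expect_equal(m$w, m2$w, tolerance = 1e-10)
  expect_equal(m$w0, m2$w0, tolerance = 1e-10)

  Xa <- cbind(1, X)
  w_oracle <- drop(brute_normal_solve(Xa, t))
  expect_equal(c(m$w0, m$w), unname(w_oracle), tolerance = 1e-8)
  # normal-equation orthogonality
  resid <- drop(crossprod(Xa, Xa %*% c(m$w0, m$w) - t))
  expect_lt(sqrt(sum(resid^2)), 1e-8 * sqrt(sum(t^2)))

  p <- predict(structure(list(w0 = 0, w = c(1, 0, 0)), class = "ld_model"),
               c(2, 5, -1))
  expect_equal(p$score, 2); expect_equal(p$label, 1)
  p0 <- predict(structure(list(w0 = 0, w = c(0, 0, 0)), class = "ld_model"),
                c(1, 1, 1))
  expect_equal(p0$label, 1)  # exact zero goes to +1
})

test_that("svm: analytic two-point solution for both trainers", {
  d <- labeled_dataset(matrix(c(-1, 1), 2, 1), c(-1, 1))
  for (tr in c("SMO", "LS")) {
    m <- svm_fit(d, tr, C = 1e4)
    expect_equal(unname(m$w), 1, tolerance = 1e-2)
    expect_equal(m$b, 0, tolerance = 1e-2)
    expect_equal(predict(m, matrix(1))$score, 1, tolerance = 1e-2)
  }
})

test_that("svm SMO: dual constraint, KKT conditions, QP oracle", {
  set.seed(17)
  d <- toy_clusters(n = 10, sep = 6, seed = 17)
  C <- 100
  m <- svm_fit(d, "SMO", C = C)
  expect_lt(abs(sum(m$alpha * d$t)), 1e-6)

  marg <- d$t * (drop(d$X %*% m$w) + m$b)
  tol <- 1e-3
  expect_true(all(marg[m$alpha < 1e-8] >= 1 - tol))
  free <- m$alpha > 1e-8 & m$alpha < C - 1e-8
  expect_true(all(abs(marg[free] - 1) <= tol + 1e-6))
  expect_true(all(marg[abs(m$alpha - C) < 1e-8] <= 1 + tol))
  # separable data, large C: all margins >= 1 - 1e-3
  expect_true(all(marg >= 1 - 1e-3))

  # independent dense QP oracle (dual with equality + box constraints)
  K <- tcrossprod(d$X)
  Q <- (d$t %o% d$t) * K + diag(nrow(K)) * 1e-8
  sol <- quadprog::solve.QP(Q, rep(1, 20),
                            cbind(d$t, diag(20), -diag(20)),
                            c(0, rep(0, 20), rep(-C, 20)), meq = 1)
  w_qp <- drop(crossprod(d$X, sol$solution * d$t))
  sv <- sol$solution > 1e-6 & sol$solution < C - 1e-6
  b_qp <- mean(d$t[sv] - drop(d$X %*% w_qp)[sv])
  lab_qp <- ifelse(drop(d$X %*% w_qp) + b_qp >= 0, 1, -1)
  expect_equal(predict(m, d$X)$label, lab_qp)
})

test_that("elm: interpolation, span equivalence with LD, determinism", {
  set.seed(23)
  X <- matrix(rnorm(60), 20, 3); t <- rep(c(1, -1), 10)
  d <- labeled_dataset(X, t)

  m <- elm_fit(d, M = 20, seed = 7)  # M = N sigmoid nodes interpolate
  expect_lt(sum(abs(predict(m, X)$score - t)), 1e-6)

  ml <- elm_fit(d, M = 10, node_types = "linear", seed = 3)
  expect_lt(max(abs(predict(ml, X)$score - predict(ld_fit(d), X)$score)),
            1e-8)

  expect_identical(elm_fit(d, M = 15, seed = 99),
                   elm_fit(d, M = 15, seed = 99))
  expect_error(elm_fit(d, M = 0), class = "ffgf_contract_error")

  # mixed layers split nodes with remainders to earlier types
  mm <- elm_fit(d, M = 7, node_types = c("linear", "sigmoid", "gaussian"),
                seed = 1)
  types <- vapply(mm$nodes, `[[`, character(1), "type")
  expect_equal(unname(table(types)[c("linear", "sigmoid", "gaussian")]),
               c(3L, 2L, 2L), ignore_attr = TRUE)
})

test_that("elm predict: zero weights, affine single node, H B identity", {
  set.seed(29)
  d <- toy_clusters(n = 6, seed = 29)
  m <- elm_fit(d, M = 4, node_types = "linear", seed = 5)
  m0 <- m; m0$B <- rep(0, 4)
  p <- predict(m0, d$X)
  expect_true(all(p$score == 0))
  expect_true(all(p$label == 1))

  # single linear node with unit output weight reproduces its affine map
  # (on the model's standardized coordinates)
  m1 <- m; m1$nodes <- m$nodes[1]; m1$B <- 1
  x <- rnorm(3)
  xs <- (x - m$center) / m$scale
  nd <- m$nodes[[1]]
  expect_equal(predict(m1, x)$score, sum(nd$w * xs) + nd$b)

  # training-point scores equal the rows of H B
  Xs <- scale(d$X, center = m$center, scale = m$scale)
  H <- vapply(m$nodes, function(nd) drop(Xs %*% nd$w) + nd$b,
              numeric(nrow(d$X)))
  expect_equal(predict(m, d$X)$score, drop(H %*% m$B), tolerance = 1e-12)
})

test_that("press_loo_error: closed form, brute-force refits, contract", {
  set.seed(31)
  t <- rnorm(9)
  H <- matrix(1, 9, 1)
  expected <- mean(((t - mean(t)) / (1 - 1 / 9))^2)
  expect_equal(press_loo_error(H, t), expected, tolerance = 1e-12)

  for (k in 1:3) {
    n <- sample(6:12, 1)
    H <- cbind(1, matrix(rnorm(n * 2), n, 2))
    t <- rnorm(n)
    brute <- mean(sapply(seq_len(n), function(i) {
      b <- brute_normal_solve(H[-i, , drop = FALSE], t[-i])
      (t[i] - sum(H[i, ] * b))^2
    }))
    expect_equal(press_loo_error(H, t), brute, tolerance = 1e-8)
  }

  # perfectly predictable target with leverage < 1
  H <- cbind(1, seq_len(10))
  expect_lt(press_loo_error(H, 2 + 3 * seq_len(10)), 1e-16)

  expect_error(press_loo_error(matrix(rnorm(9), 3, 3), rnorm(3)),
               class = "ffgf_contract_error")
})

test_that("lars_order ranks an exact predictor first; prefix rule picks k=1", {
  set.seed(37)
  n <- 30
  H <- matrix(rnorm(n * 5), n, 5)
  t <- H[, 3]                         # column 3 predicts exactly
  ord <- lars_order(H, t)
  expect_equal(ord[1], 3L)
  press <- sapply(seq_len(5), function(k)
    press_loo_error(H[, ord[seq_len(k)], drop = FALSE], t))
  # the length-1 prefix already predicts exactly; longer prefixes can
  # only tie at floating-point noise, never improve
  expect_lt(press[1], 1e-16)
  expect_lt(press[1], min(press) + 1e-16)
})

test_that("op_elm_fit: prefix optimality, pruning under noise, determinism", {
  set.seed(41)
  d <- toy_clusters(n = 15, sep = 5, seed = 41)
  m <- op_elm_fit(d, M_init = 20, seed = 3)
  expect_equal(m$n_hidden, which.min(m$press))
  expect_true(all(m$press[m$n_hidden] <= m$press))
  expect_lte(m$M, nrow(d$X) - 2L)     # cap keeps PRESS defined
  expect_identical(op_elm_fit(d, M_init = 20, seed = 3),
                   op_elm_fit(d, M_init = 20, seed = 3))

  # pure-noise targets: long prefixes overfit, selection stays small
  ks <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    dn <- labeled_dataset(matrix(rnorm(120), 40, 3),
                          sample(c(1, -1), 40, TRUE))
    op_elm_fit(dn, M_init = 20, seed = s)$n_hidden
  })
  expect_lte(stats::median(ks), 5)
})

test_that("all predictors agree with direct affine evaluation on random inputs", {
  set.seed(43)
  d <- toy_clusters(n = 10, seed = 43)
  msvm <- svm_fit(d, "LS")
  mld <- ld_fit(d)
  for (k in 1:5) {
    x <- rnorm(3)
    expect_equal(predict(msvm, x)$score, sum(msvm$w * x) + msvm$b)
    expect_equal(predict(mld, x)$score, sum(mld$w * x) + mld$w0)
  }
})

test_that("models round-trip through flat JSON", {
  set.seed(47)
  d <- toy_clusters(n = 8, seed = 47)
  path <- withr::local_tempfile(fileext = ".json")
  for (m in list(knn_fit(d, K = 3, p = 1), ld_fit(d), svm_fit(d, "LS"),
                 elm_fit(d, M = 5, node_types = c("sigmoid", "gaussian"),
                         seed = 2))) {
    write_model(m, path)
    back <- read_model(path)
    expect_equal(predict(back, d$X)$score, predict(m, d$X)$score,
                 tolerance = 1e-12)
  }
})
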