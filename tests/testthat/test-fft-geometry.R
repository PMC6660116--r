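test_that("DFT of simple signals matches the closed forms", {
  sp <- compute_dft(gray_image(matrix(3, 8, 8)))
  expect_equal(sp$re[1, 1], 3)
  expect_equal(max(abs(sp$modulus[-1])), 0)

  # single pixel of value 64 at (0,0): every coefficient has modulus 1
  imp <- matrix(0, 8, 8); imp[1, 1] <- 64
  sp <- compute_dft(imp)
  expect_equal(unname(sp$modulus), matrix(1, 8, 8))
})

test_that("DFT, modulus and phase match the brute-force oracle", {
  set.seed(21)
  for (dims in list(c(8, 8), c(8, 12))) {
    m <- matrix(runif(prod(dims), 0, 255), dims[1], dims[2])
    oracle <- brute_dft(m)
    sp <- compute_dft(m)
    expect_equal(sp$re, Re(oracle), tolerance = 1e-10)
    expect_equal(sp$im, Im(oracle), tolerance = 1e-10)
    expect_equal(spectrum_modulus(sp), Mod(oracle), tolerance = 1e-10)
    # conjugate symmetry of the modulus for real input
    M <- dims[1]; N <- dims[2]
    for (u in 0:(M - 1)) for (v in 0:(N - 1)) {
      expect_equal(sp$modulus[u + 1, v + 1],
                   sp$modulus[(M - u) %% M + 1, (N - v) %% N + 1],
                   tolerance = 1e-10)
    }
  }
})

test_that("Parseval holds under the 1/(MN) normalization", {
  set.seed(5)
  for (k in 1:5) {
    M <- sample(8:32, 1); N <- sample(8:32, 1)
    m <- matrix(runif(M * N, 0, 255), M, N)
    sp <- compute_dft(m)
    lhs <- sum(spectrum_modulus(sp)^2)
    rhs <- sum(m^2) / (M * N)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("modulus and phase scalar identities", {
  sp <- spectrum_image(matrix(3, 8, 8), matrix(4, 8, 8))
  expect_equal(spectrum_modulus(sp)[1, 1], 5)
  z <- spectrum_image(matrix(0, 8, 8), matrix(0, 8, 8))
  expect_true(all(spectrum_modulus(z) == 0))
  expect_true(all(spectrum_phase(z) == 0))

  one <- matrix(1, 8, 8)
  expect_equal(spectrum_phase(spectrum_image(one, 0 * one))[1, 1], 0)
  expect_equal(spectrum_phase(spectrum_image(0 * one, one))[1, 1], pi / 2)
  expect_equal(spectrum_phase(spectrum_image(-one, -one))[1, 1], -3 * pi / 4)
})

test_that("center_spectrum moves DC to the grid center and conserves values", {
  sp <- compute_dft(gray_image(matrix(9, 10, 12)))
  ce <- center_spectrum(sp)
  expect_equal(ce$modulus[6, 7], 9)  # (floor(10/2), floor(12/2)) 0-based
  expect_equal(sum(ce$modulus > 1e-12), 1L)
  expect_error(center_spectrum(ce), class = "ffgf_contract_error")

  set.seed(2)
  sp <- compute_dft(matrix(runif(16 * 16, 0, 255), 16))
  ce <- center_spectrum(sp)
  expect_equal(sort(as.vector(ce$modulus)), sort(as.vector(sp$modulus)))
})

test_that("binarize_spectrum thresholds, degenerate cases, contract", {
  set.seed(7)
  sp <- center_spectrum(compute_dft(matrix(runif(256, 0, 255), 16)))
  b <- binarize_spectrum(sp, 0.9999)
  expect_equal(sum(b$mask), 1L)  # only the forced center survives q -> 1

  b <- binarize_spectrum(sp, 0.5)
  # count against an independent quantile computation (the DC cell is in
  # the upper half, so the forced center does not change the count)
  lm <- log1p(spectrum_modulus(sp))
  expect_equal(sum(b$mask), sum(lm > stats::quantile(lm, 0.5)))
  expect_lt(abs(sum(b$mask) - 128), 8)

  # constant-modulus spectrum: strict inequality leaves center only
  cm <- spectrum_image(matrix(2, 8, 8), matrix(0, 8, 8), centered = TRUE)
  expect_equal(sum(binarize_spectrum(cm, 0.5)$mask), 1L)

  expect_error(binarize_spectrum(sp, 1.2), class = "ffgf_contract_error")
  expect_error(binarize_spectrum(compute_dft(matrix(1:64, 8)), 0.5),
               class = "ffgf_contract_error")
})

test_that("central_ellipse recovers analytic shapes and the moment oracle", {
  # single-pixel blob
  mask <- matrix(FALSE, 9, 9); mask[5, 5] <- TRUE
  expect_equal(unclass(central_ellipse(list(mask = mask))),
               c(major = 1, minor = 1, area = 1))

  # filled axis-aligned ellipse, semi-axes 10 and 5
  R <- matrix(1:101, 101, 101); C <- t(R)
  mask <- ((R - 51) / 10)^2 + ((C - 51) / 5)^2 <= 1
  v <- central_ellipse(list(mask = mask))
  expect_equal(v[["area"]], sum(mask))
  expect_lt(abs(v[["major"]] - 20) / 20, 0.05)
  expect_lt(abs(v[["minor"]] - 10) / 10, 0.05)

  # disc: axes within 2% of each other
  mask <- (R - 51)^2 + (C - 51)^2 <= 8^2
  v <- central_ellipse(list(mask = mask))
  expect_lt(abs(v[["major"]] / v[["minor"]] - 1), 0.02)

  # exhaustive moment oracle on an irregular centered blob
  set.seed(4)
  mask <- matrix(FALSE, 21, 21)
  mask[11, 11] <- TRUE
  mask[cbind(sample(7:15, 30, TRUE), sample(7:15, 30, TRUE))] <- TRUE
  v <- central_ellipse(list(mask = mask))
  comp <- brute_component(mask, 11, 11)  # independent scalar flood fill
  expect_equal(v[["area"]], nrow(comp))
  o <- brute_moment_ellipse(comp[, 1], comp[, 2])
  expect_equal(unname(v[1:2]), o, tolerance = 1e-10)
})

test_that("central_ellipse uses only the component connected to the center", {
  mask <- matrix(FALSE, 16, 16)
  mask[9, 9] <- TRUE; mask[9, 10] <- TRUE; mask[10, 10] <- TRUE
  mask[2, 2] <- TRUE; mask[2, 3] <- TRUE   # far disconnected blob
  v <- central_ellipse(list(mask = mask))
  expect_equal(v[["area"]], 3)
})

test_that("extract_ffgf invariances: translation, negation, constant image", {
  set.seed(12)
  m <- matrix(runif(256, 0, 255), 16)
  v1 <- extract_ffgf(m, 0.9)
  shifted <- m[c(6:16, 1:5), c(12:16, 1:11)]  # cyclic translation
  expect_equal(extract_ffgf(shifted, 0.9), v1)
  expect_equal(extract_ffgf(255 - m, 0.9), v1)

  expect_equal(unclass(extract_ffgf(matrix(100, 16, 16), 0.9)),
               c(major = 1, minor = 1, area = 1))
})

test_that("train_threshold matches exhaustive grid evaluation and tie rules", {
  set.seed(31)
  spectra <- lapply(1:8, function(i) {
    ph <- tiny_phantom(seed = 100 + i,
                       class_label = if (i <= 4) 1 else -1)
    compute_dft(ph$image)     # non-centered on purpose: op centers itself
  })
  labels <- rep(c(1, -1), each = 4)
  grid <- ffgf_quantile_grid()
  q_star <- train_threshold(spectra, labels, grid)
  expect_true(q_star %in% grid)

  # independent exhaustive evaluation of the selection criterion
  centered <- lapply(spectra, center_spectrum)
  fisher <- sapply(grid, function(q) {
    thr <- pooled_log_threshold(centered, q)
    a <- sapply(centered, function(s)
      central_ellipse(binarize_spectrum(s, threshold = thr))[["area"]])
    m1 <- mean(a[labels == 1]); m2 <- mean(a[labels == -1]); m <- mean(a)
    btw <- 4 * (m1 - m)^2 + 4 * (m2 - m)^2
    wth <- sum((a[labels == 1] - m1)^2) + sum((a[labels == -1] - m2)^2)
    if (wth == 0) Inf else btw / wth
  })
  expect_equal(q_star, grid[which.max(fisher)])

  # identical images in both classes: ratio 0 everywhere, smallest q wins
  same <- rep(spectra[1], 4)
  expect_equal(train_threshold(same, c(1, 1, -1, -1), grid), min(grid))

  # determinism: bit-identical across runs
  expect_identical(q_star, train_threshold(spectra, labels, grid))

  expect_error(train_threshold(spectra, rep(1, 8)),
               class = "ffgf_contract_error")
})
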