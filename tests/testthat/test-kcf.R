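test_that("the Gaussian response target peaks at zero shift and shifts cleanly", {
  expect_identical(gaussian_response_target(1, 1), matrix(1, 1, 1))
  b <- gaussian_response_target(8, 6)
  expect_identical(arrayInd(which.max(b), dim(b)), matrix(c(1L, 1L), 1))
  expect_equal(max(b), 1)
  bs <- circshift(b, 3, 2)
  expect_identical(arrayInd(which.max(bs), dim(bs)), matrix(c(4L, 3L), 1))
})

test_that("build_circulant enumerates cyclic shifts and diagonalises under
           the DFT", {
  A <- build_circulant(c(1, 2, 3))
  expect_equal(A, rbind(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1)))
  set.seed(2)
  a <- matrix(rnorm(12), 4, 3)
  A <- build_circulant(a)
  expect_lt(max(Mod(Conj(t(A)) %*% A - A %*% Conj(t(A)))), 1e-9)  # normal
  ev <- eigen(A, only.values = TRUE)$values
  dft <- as.vector(stats::fft(a))
  expect_equal(sort(Re(ev)), sort(Re(dft)), tolerance = 1e-9)
  expect_equal(sort(Im(ev)), sort(Im(dft)), tolerance = 1e-9)
  expect_error(build_circulant(matrix(0, 70, 70)), "test-scale")
})

test_that("Fourier-domain linear ridge equals the explicit primal solve", {
  a_hat <- matrix(1 + 0i, 2, 2); b_hat <- matrix(1 + 0i, 2, 2)
  expect_equal(train_linear(a_hat, b_hat, 1), matrix(0.5 + 0i, 2, 2))
  set.seed(7)
  for (dims in list(c(8, 1), c(4, 4), c(5, 3))) {
    a <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    b <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    w_hat <- train_linear(stats::fft(a), stats::fft(b), 0.37)
    w <- Re(stats::fft(w_hat, inverse = TRUE)) / length(a)
    expect_equal(as.vector(w), as.vector(bf_primal_w(a, b, 0.37)),
                 tolerance = 1e-8)
  }
  # ridge shrinkage: lambda -> Inf drives the filter to zero
  expect_lt(max(Mod(train_linear(stats::fft(a), stats::fft(b), 1e12))), 1e-9)
  # zero Fourier coefficient with no regularisation is rejected
  expect_error(train_linear(stats::fft(matrix(1, 3, 3)),
                            stats::fft(matrix(1, 3, 3)), 0), "ridge")
})

test_that("kernel correlation matches shift-enumeration for all kernels", {
  # impulse autocorrelation: delta scaled by the 1/N dot-product convention
  del <- matrix(0, 4, 4); del[1, 1] <- 1
  k <- kernel_correlation(del, del, kernel_spec("linear"))
  expect_equal(k, del / 16, tolerance = 1e-12)
  set.seed(8)
  x <- matrix(rnorm(36), 6, 6); z <- matrix(rnorm(36), 6, 6)
  for (ks in list(kernel_spec("linear"),
                  kernel_spec("polynomial", poly_offset = 1, poly_degree = 3),
                  kernel_spec("gaussian", gauss_sigma = 0.5))) {
    expect_equal(kernel_correlation(x, z, ks), bf_kernel_map(x, z, ks),
                 tolerance = 1e-8, info = ks$kind)
  }
  expect_error(kernel_correlation(x, matrix(0, 3, 3)), "differ")
})

test_that("the Gaussian kernel map lies in (0,1] and hits 1 only on exact
           alignment", {
  set.seed(10)
  x <- matrix(rnorm(30), 5, 6)
  ks <- kernel_spec("gaussian", gauss_sigma = 0.4)
  k <- kernel_correlation(x, circshift(x, 2, 3), ks)
  expect_true(all(k > 0 & k <= 1 + 1e-12))
  # the shift that undoes (2, 3) on a 5 x 6 grid is (3, 3) -> entry [4, 4]
  expect_equal(k[4, 4], 1, tolerance = 1e-12)
  expect_lt(max(k[-(4 + (4 - 1) * 5)]), 1 - 1e-6) # all other shifts below 1
})

test_that("Fourier-domain dual training equals the dense kernel ridge solve
           and the linear kernel reproduces the primal regression", {
  set.seed(11)
  x <- matrix(rnorm(36), 6, 6)
  b <- gaussian_response_target(6, 6)
  for (ks in list(kernel_spec("linear"),
                  kernel_spec("polynomial"),
                  kernel_spec("gaussian", gauss_sigma = 0.5))) {
    m <- kcf(x, response = b, lambda = 0.01, kernel = ks)
    alpha <- Re(stats::fft(m$alpha_hat, inverse = TRUE)) / 36
    expect_equal(as.vector(alpha), bf_dual_alpha(x, b, 0.01, ks),
                 tolerance = 1e-8, info = ks$kind)
  }
  # b = 0 gives alpha = 0
  m0 <- kcf(x, response = matrix(0, 6, 6), lambda = 0.01)
  expect_true(all(Mod(m0$alpha_hat) == 0))
  # dual detection with the linear kernel equals the primal filter response:
  # the 1/N dot-product convention corresponds to samples scaled by 1/sqrt(N)
  z <- matrix(rnorm(36), 6, 6)
  m <- kcf(x, response = b, lambda = 0.01, kernel = kernel_spec("linear"))
  resp_dual <- predict(m, z)$response
  w <- bf_primal_w(x / 6, b, 0.01)
  resp_primal <- matrix(bf_shift_rows(z / 6) %*% w, 6, 6)
  expect_equal(resp_dual, resp_primal, tolerance = 1e-8)
})

test_that("detection response equals the explicit dual classifier and peaks
           at self-match", {
  set.seed(12)
  x <- matrix(rnorm(48), 6, 8)
  b <- gaussian_response_target(6, 8)
  for (ks in list(kernel_spec("linear"), kernel_spec("gaussian"))) {
    m <- kcf(x, response = b, lambda = 0.01, kernel = ks)
    z <- matrix(rnorm(48), 6, 8)
    alpha <- bf_dual_alpha(x, b, 0.01, ks)
    Sz <- bf_shift_rows(x)
    f <- vapply(seq_len(48), function(i) {
      p <- (i - 1) %% 6; q <- (i - 1) %/% 6
      sum(alpha * vapply(seq_len(48), function(j) {
        pj <- (j - 1) %% 6; qj <- (j - 1) %/% 6
        kappa_pointwise(circshift(z, p, q), circshift(x, pj, qj), ks)
      }, 1))
    }, 1)
    d <- predict(m, z)
    expect_equal(max(d$response), max(f), tolerance = 1e-8, info = ks$kind)
    expect_equal(as.vector(d$response), f, tolerance = 1e-8, info = ks$kind)
  }
  m <- kcf(x, kernel = kernel_spec("gaussian"))
  expect_equal(unname(predict(m, x)$peak_offset), c(0, 0))
})

test_that("model interpolation blends coefficients and template linearly", {
  set.seed(13)
  x1 <- matrix(rnorm(16), 4, 4); x2 <- matrix(rnorm(16), 4, 4)
  m1 <- kcf(x1); m2 <- kcf(x2)
  expect_identical(update(m1, m2, eta = 0)$alpha_hat, m1$alpha_hat)
  expect_identical(update(m1, m2, eta = 1)$template, m2$template)
  mid <- update(m1, m2, eta = 0.5)
  expect_equal(mid$alpha_hat, (m1$alpha_hat + m2$alpha_hat) / 2)
  expect_equal(mid$template, (m1$template + m2$template) / 2)
})
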