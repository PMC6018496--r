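# Brute-force reference implementations, independent of the package's
# Fourier fast path: kernels evaluated pointwise over explicitly enumerated
# cyclic shifts, and regressions solved with dense linear algebra.

# pointwise kernel between two equal-size samples (single channel),
# using the package's N-normalised dot-product convention
kappa_pointwise <- function(c1, c2, ks) {
  N <- length(c1)
  switch(ks$kind,
    linear = sum(c1 * c2) / N,
    polynomial = (sum(c1 * c2) / N + ks$poly_offset)^ks$poly_degree,
    gaussian = exp(-sum((c1 - c2)^2) / (ks$gauss_sigma^2 * N))
  )
}

# kernel correlation map by explicit shift enumeration
bf_kernel_map <- function(x, z, ks) {
  h <- nrow(x); w <- ncol(x)
  k <- matrix(0, h, w)
  for (p in 0:(h - 1)) for (q in 0:(w - 1))
    k[p + 1, q + 1] <- kappa_pointwise(circshift(z, p, q), x, ks)
  k
}

# sample matrix whose row m is the vectorised shift (p, q) of x, with
# m = p + q*h + 1 (column-major over the shift grid)
bf_shift_rows <- function(x) {
  h <- nrow(x); w <- ncol(x)
  t(sapply(seq_len(h * w), function(m) {
    p <- (m - 1) %% h; q <- (m - 1) %/% h
    as.vector(circshift(x, p, q))
  }))
}

# dense dual ridge solve alpha = (K + lambda I)^-1 b over all shifts of x
bf_dual_alpha <- function(x, b, lambda, ks) {
  S <- bf_shift_rows(x)
  N <- nrow(S)
  K <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    K[i, j] <- kappa_pointwise(S[i, ], S[j, ], ks)
  solve(K + lambda * diag(N), as.vector(b))
}

# dense primal ridge solve w = (A^H A + lambda I)^-1 A^H b
bf_primal_w <- function(a, b, lambda) {
  A <- build_circulant(a)
  AH <- Conj(t(A))
  Re(solve(AH %*% A + lambda * diag(length(a)), AH %*% as.vector(b)))
}

# a tiny deterministic moving-blob frame sequence with known truth, drawn
# directly (independent of the package renderer): dark disc on a textured
# light background
tiny_blob_sequence <- function(n_frames = 30, h = 80, w = 120, r = 5,
                               path_u = NULL, path_v = NULL, seed = 42,
                               noise = 0, blob_int = 0.2) {
  set.seed(seed)
  bg <- 0.8 + 0.04 * matrix(stats::runif(h * w) - 0.5, h, w)
  bg <- (bg + circshift(bg, 1, 0) + circshift(bg, 0, 1) +
           circshift(bg, 1, 1)) / 4          # mildly smoothed static texture
  if (is.null(path_u)) path_u <- 20 + 2 * (0:(n_frames - 1))
  if (is.null(path_v)) path_v <- 40 + 0.5 * (0:(n_frames - 1))
  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    f <- bg
    du <- outer(rep(1, h), (0:(w - 1)) - path_u[t])
    dv <- outer((0:(h - 1)) - path_v[t], rep(1, w))
    cov <- pmin(pmax(1.5 * (1 - sqrt(du^2 + dv^2) / r), 0), 1)
    f <- f * (1 - cov) + blob_int * cov
    if (noise > 0) f <- f + matrix(stats::rnorm(h * w, 0, noise), h, w)
    frames[[t]] <- pmin(pmax(f, 0), 1)
  }
  list(fs = frame_sequence(frames, fps = 60),
       truth = data.frame(frame = 0:(n_frames - 1), u = path_u, v = path_v))
}
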