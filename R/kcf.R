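#' Kernel specification for the correlation filter
#'
#' The regression is kernelized; three kernels are supported. Dot products
#' between all cyclic shifts of two feature maps are computed at once by
#' cross-correlation in the Fourier domain, so training and detection cost
#' O(N log N) regardless of kernel.
#'
#' @param kind `"linear"`, `"polynomial"` or `"gaussian"`.
#' @param poly_offset additive constant of the polynomial kernel
#'   `(x.z + offset)^degree`.
#' @param poly_degree polynomial exponent (>= 1).
#' @param gauss_sigma Gaussian bandwidth; the kernel is
#'   `exp(-||x - z||^2 / (sigma^2 N))` with `N` the feature element count,
#'   the conventional normalisation in this tracker family.
#' @return a `kernel_spec` list.
#' @export
kernel_spec <- function(kind = c("linear", "polynomial", "gaussian"),
                        poly_offset = 1, poly_degree = 3, gauss_sigma = 0.2) {
  kind <- match.arg(kind)
  stopifnot(gauss_sigma > 0, poly_degree >= 1)
  structure(list(kind = kind, poly_offset = poly_offset,
                 poly_degree = poly_degree, gauss_sigma = gauss_sigma),
            class = "kernel_spec")
}

# ---- small Fourier helpers ------------------------------------------------

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# real part with a hygiene check: inverse transforms of conjugate-symmetric
# spectra must be numerically real
re_checked <- function(x) {
  im <- max(abs(Im(x)))
  if (im > 1e-8 * (max(abs(x)) + 1e-12))
    stop("inverse DFT produced a non-negligible imaginary part")
  Re(x)
}

#' Circularly shift a matrix
#'
#' Shifts `p` rows down and `q` columns right (cyclically); negative shifts
#' go the other way.
#'
#' @param m matrix.
#' @param p,q row/column shift.
#' @return the shifted matrix.
#' @export
circshift <- function(m, p, q) {
  nr <- nrow(m); nc <- ncol(m)
  p <- ((p %% nr) + nr) %% nr
  q <- ((q %% nc) + nc) %% nc
  ri <- if (p == 0) seq_len(nr) else c((nr - p + 1):nr, seq_len(nr - p))
  ci <- if (q == 0) seq_len(nc) else c((nc - q + 1):nc, seq_len(nc - q))
  m[ri, ci, drop = FALSE]
}

#' Periodic Gaussian regression target
#'
#' The desired classifier output over all cyclic shifts: a periodic 2-D
#' Gaussian with its peak (value 1) at zero shift. Bandwidth follows the
#' tracker family's convention `sigma = sigma_factor * sqrt(h*w) / padding`,
#' i.e. proportional to the underlying target size rather than the padded
#' window size.
#'
#' @param h,w target dimensions (rows, cols).
#' @param sigma_factor bandwidth factor (default 0.1).
#' @param padding search-window padding the dimensions include.
#' @return an `h x w` matrix with `max = 1` at `[1, 1]`.
#' @export
gaussian_response_target <- function(h, w, sigma_factor = 0.1, padding = 2) {
  stopifnot(h >= 1, w >= 1)
  sigma <- sigma_factor * sqrt(h * w) / padding
  dr <- 0:(h - 1); dr <- pmin(dr, h - dr)
  dc <- 0:(w - 1); dc <- pmin(dc, w - dc)
  exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2))
}

#' Explicit circulant matrix of all cyclic shifts (brute-force oracle)
#'
#' Builds the full matrix whose rows are the vectorised cyclic shifts
#' `D^p R^q a` of a sample, ordered column-major over the shift pair
#' `(p, q)` so that row `p + q*h + 1` corresponds to shift `(p, q)` -- the
#' same ordering as `as.vector()` of an `h x w` shift-indexed matrix.
#' This is the O(N^2)-memory reference object for validating the Fourier
#' fast path; it is deliberately size-guarded.
#'
#' @param a numeric vector or matrix (total elements <= 4096).
#' @return an `N x N` matrix, `N = length(a)`.
#' @export
build_circulant <- function(a) {
  if (is.vector(a)) a <- matrix(a, nrow = 1)
  N <- length(a)
  if (N > 4096) stop("build_circulant is a test-scale oracle; N <= 4096")
  h <- nrow(a); w <- ncol(a)
  A <- matrix(0, N, N)
  for (q in 0:(w - 1)) for (p in 0:(h - 1))
    A[p + q * h + 1, ] <- as.vector(circshift(a, p, q))
  A
}

#' Linear ridge regression in the Fourier domain
#'
#' Elementwise closed form of the circulant ridge solve: each Fourier
#' coefficient of the filter is `a_hat * b_hat / (conj(a_hat)*a_hat + lambda)`.
#' With sample rows ordered as cyclic shifts `a[j - m]`, the shift operator
#' diagonalises to `conj(a_hat)`, and this unconjugated numerator is the form
#' that agrees with the explicit normal-equations solve.
#'
#' @param a_hat DFT of the sample.
#' @param b_hat DFT of the regression target.
#' @param lambda ridge regularizer (>= 0).
#' @return `w_hat`, the DFT of the filter.
#' @export
train_linear <- function(a_hat, b_hat, lambda) {
  stopifnot(all(dim(a_hat) == dim(b_hat)) || length(a_hat) == length(b_hat),
            lambda >= 0)
  den <- Conj(a_hat) * a_hat + lambda
  if (any(Mod(den) < 1e-14))
    stop("zero Fourier coefficient with lambda = 0: ridge solve undefined")
  a_hat * b_hat / den
}

#' Kernel correlation over all cyclic shifts
#'
#' Computes `k[p, q] = kappa(shift(z, p, q), x)` for every cyclic shift at
#' once. Channel dot products are summed before the kernel nonlinearity
#' (the standard multi-channel extension). Following this tracker family's
#' convention, dot products are normalised by the feature element count `N`:
#' `kappa_linear = (z.x)/N`, `kappa_poly = ((z.x)/N + offset)^degree`,
#' `kappa_gauss = exp(-||z - x||^2 / (sigma^2 N))`, which keeps kernel values
#' O(1) so the ridge regularizer `lambda` acts on a fixed scale regardless
#' of window size.
#'
#' @param x,z `feature_map`s (or plain matrices) of identical shape.
#' @param kernel a [kernel_spec()].
#' @return a real matrix of kernel values, one per shift.
#' @export
kernel_correlation <- function(x, z, kernel = kernel_spec("linear")) {
  xv <- feature_values(x); zv <- feature_values(z)
  if (!all(dim(xv) == dim(zv))) stop("feature shapes differ")
  cc <- 0
  for (ch in seq_len(dim(xv)[3]))
    cc <- cc + re_checked(ifft2(Conj(fft2(zv[, , ch])) * fft2(xv[, , ch])))
  N <- length(xv)
  switch(kernel$kind,
    linear = cc / N,
    polynomial = (cc / N + kernel$poly_offset)^kernel$poly_degree,
    gaussian = exp(-pmax(sum(xv^2) + sum(zv^2) - 2 * cc, 0) /
                     (kernel$gauss_sigma^2 * N))
  )
}

feature_values <- function(x) {
  if (inherits(x, "feature_map")) x <- x$values
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  x
}

#' Fit a kernelized correlation filter
#'
#' Trains the dual ridge regression over all cyclic shifts of the feature
#' template: the Fourier-domain dual coefficients are
#' `alpha_hat = b_hat / (k_hat_xx + lambda)` with `k_hat_xx` the DFT of the
#' kernel autocorrelation of the template. Returns a classed model usable
#' with [predict.kcf()] and [update.kcf()].
#'
#' @param x feature template (`feature_map` or matrix).
#' @param response regression target matrix; by default a
#'   [gaussian_response_target()] matched to the template size.
#' @param lambda ridge regularizer (default 1e-4).
#' @param kernel a [kernel_spec()].
#' @param sigma_factor,padding passed to the default response target.
#' @return an object of class `kcf` with elements `alpha_hat`, `template`,
#'   `b_hat`, `lambda`, `kernel`, `cell_size`.
#' @export
kcf <- function(x, response = NULL, lambda = 1e-4,
                kernel = kernel_spec("linear"),
                sigma_factor = 0.1, padding = 2) {
  xv <- feature_values(x)
  cell <- if (inherits(x, "feature_map")) x$cell_size else 1L
  if (is.null(response))
    response <- gaussian_response_target(dim(xv)[1], dim(xv)[2],
                                         sigma_factor, padding)
  stopifnot(all(dim(response) == dim(xv)[1:2]))
  b_hat <- fft2(response)
  k_hat <- fft2(kernel_correlation(xv, xv, kernel))
  alpha_hat <- b_hat / (k_hat + lambda)
  structure(list(alpha_hat = alpha_hat, template = xv, b_hat = b_hat,
                 lambda = lambda, kernel = kernel, cell_size = cell),
            class = "kcf")
}

#' @export
print.kcf <- function(x, ...) {
  d <- dim(x$template)
  cat(sprintf("<kcf> %s kernel, template %d x %d x %d, lambda %g\n",
              x$kernel$kind, d[1], d[2], d[3], x$lambda))
  invisible(x)
}

#' Detect the target in a new search window
#'
#' Evaluates the classifier on every cyclic shift of the candidate features
#' and returns the full response map plus the displacement of its peak.
#' The peak offset is reported as the cyclic shift of the template that best
#' explains the candidate, with indices above half the window wrapped to
#' negative shifts, scaled by the feature cell size to pixels: `(du, dv)` in
#' `(column, row)` order.
#'
#' @param object a fitted [kcf()] model.
#' @param z candidate features, same shape as the template.
#' @param ... unused.
#' @return list with `response` (matrix), `peak_offset` (`c(du, dv)` in
#'   pixels) and `peak_value`.
#' @export
predict.kcf <- function(object, z, ...) {
  zv <- feature_values(z)
  if (!all(dim(zv) == dim(object$template)))
    stop("candidate feature shape does not match the template")
  k <- kernel_correlation(object$template, zv, object$kernel)
  response <- re_checked(ifft2(fft2(k) * object$alpha_hat))
  if (!all(is.finite(response))) stop("non-finite detection response")
  idx <- arrayInd(which.max(response), dim(response))
  h <- nrow(response); w <- ncol(response)
  # response index m peaks where shift(z, m) re-aligns with the template,
  # i.e. m = -displacement; negate and wrap to a signed shift
  p <- -(idx[1] - 1L); q <- -(idx[2] - 1L)
  if (p <= -h / 2) p <- p + h
  if (q <= -w / 2) q <- q + w
  list(response = response,
       peak_offset = c(du = q * object$cell_size, dv = p * object$cell_size),
       peak_value = response[idx])
}

#' Blend a freshly trained model into the running model
#'
#' Linear interpolation of the dual coefficients and the template:
#' `new = (1 - eta) * old + eta * fresh`. `eta = 0` keeps the first-frame
#' model (the literal no-adaptation reading); small `eta` lets the tracker
#' follow slow appearance change such as wingbeat deformation.
#'
#' @param object the running [kcf()] model.
#' @param fresh a model trained on the current frame (same configuration).
#' @param eta interpolation factor in `[0, 1]`.
#' @param ... unused.
#' @return the blended `kcf` model.
#' @export
update.kcf <- function(object, fresh, eta = 0.02, ...) {
  stopifnot(eta >= 0, eta <= 1,
            all(dim(object$template) == dim(fresh$template)))
  object$alpha_hat <- (1 - eta) * object$alpha_hat + eta * fresh$alpha_hat
  object$template <- (1 - eta) * object$template + eta * fresh$template
  object
}
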