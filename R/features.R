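#' Feature-extraction configuration
#'
#' The tracker learns over a search window cut around the target box and
#' enlarged by `padding` so it contains some surrounding background. Two
#' representations are supported: raw grayscale intensities (`gray`, one
#' channel at pixel resolution) and orientation-histogram features (`hog`,
#' one channel per orientation bin at cell resolution).
#'
#' @param kind `"gray"` or `"hog"`.
#' @param padding search-window scale factor relative to the target box
#'   (>= 1; default 2, standard correlation-filter practice).
#' @param hog_cell HOG cell side in pixels.
#' @param hog_bins number of unsigned-orientation bins over `[0, pi)`.
#' @param window `"hann"` (cosine taper, suppresses the wrap-around seam of
#'   the cyclic-shift model) or `"none"`.
#' @return a `feature_config` list.
#' @export
feature_config <- function(kind = c("gray", "hog"), padding = 2,
                           hog_cell = 4, hog_bins = 9,
                           window = c("hann", "none")) {
  kind <- match.arg(kind)
  window <- match.arg(window)
  stopifnot(padding >= 1, hog_cell >= 1, hog_bins >= 2)
  structure(list(kind = kind, padding = padding, hog_cell = as.integer(hog_cell),
                 hog_bins = as.integer(hog_bins), window = window),
            class = "feature_config")
}

#' 2-D Hann window
#'
#' Outer product of 1-D Hann tapers; endpoints are exactly zero for n > 1.
#'
#' @param h,w window dimensions.
#' @return an `h x w` matrix.
#' @export
hann2 <- function(h, w) outer(hann1(h), hann1(w))

hann1 <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

#' Extract the padded search window around a target box
#'
#' Cuts the window of size `round(padding * box size)` centred on the box
#' centre. Pixels outside the frame are filled by edge replication, so boxes
#' at the frame border remain usable.
#'
#' @param frame grayscale matrix.
#' @param box target box `list(u, v, w, h)`: top-left corner `(u, v)` in
#'   0-based pixel coordinates plus width/height in pixels.
#' @param padding window scale factor.
#' @return the window as a matrix of size `round(padding*h) x round(padding*w)`.
#' @export
extract_patch <- function(frame, box, padding = 2) {
  stopifnot(is.matrix(frame), box$w > 0, box$h > 0)
  nr <- nrow(frame); nc <- ncol(frame)
  cu <- box$u + (box$w - 1) / 2      # 0-based centre column
  cv <- box$v + (box$h - 1) / 2
  if (box$u + box$w <= 0 || box$u >= nc || box$v + box$h <= 0 || box$v >= nr)
    stop("target box lies entirely outside the frame")
  W <- max(1L, as.integer(round(padding * box$w)))
  H <- max(1L, as.integer(round(padding * box$h)))
  cols <- round(cu - (W - 1) / 2) + 0:(W - 1)   # 0-based, may exceed frame
  rows <- round(cv - (H - 1) / 2) + 0:(H - 1)
  cols <- pmin(pmax(cols, 0L), nc - 1L)         # edge replication
  rows <- pmin(pmax(rows, 0L), nr - 1L)
  frame[rows + 1L, cols + 1L, drop = FALSE]
}

#' Grayscale features
#'
#' Scales intensities to `[0, 1]`, removes the window mean (so a constant
#' patch maps to zero) and applies the Hann taper.
#'
#' @param patch grayscale matrix.
#' @param window `"hann"` or `"none"`.
#' @return a `feature_map`: array `H x W x 1` with `cell_size = 1`.
#' @export
gray_features <- function(patch, window = c("hann", "none")) {
  window <- match.arg(window)
  stopifnot(is.matrix(patch))
  g <- patch
  if (max(g) > 1) g <- g / 255     # accept 8-bit inputs
  g <- g - mean(g)
  if (window == "hann") g <- g * hann2(nrow(g), ncol(g))
  feature_map(array(g, c(dim(g), 1L)), cell_size = 1L)
}

feature_map <- function(values, cell_size) {
  structure(list(values = values, cell_size = as.integer(cell_size)),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_map> %d x %d x %d, cell %d px\n", d[1], d[2], d[3],
              x$cell_size))
  invisible(x)
}

#' Histogram-of-oriented-gradients features
#'
#' Per-cell unsigned orientation histograms (hard nearest-bin assignment of
#' gradient magnitude, central-difference gradients with replicated edges),
#' L2-hys normalised per cell, then Hann-tapered over the cell grid.
#'
#' @param patch grayscale matrix, at least one cell in each dimension.
#' @param cfg a [feature_config()] with `kind = "hog"` (uses `hog_cell`,
#'   `hog_bins`, `window`).
#' @return a `feature_map`: array `floor(H/cell) x floor(W/cell) x bins`.
#' @export
hog_features <- function(patch, cfg = feature_config("hog")) {
  cell <- cfg$hog_cell; bins <- cfg$hog_bins
  if (nrow(patch) < cell || ncol(patch) < cell)
    stop("patch smaller than one HOG cell")
  H2 <- nrow(patch) %/% cell; W2 <- ncol(patch) %/% cell
  p <- patch[seq_len(H2 * cell), seq_len(W2 * cell), drop = FALSE]
  g <- hog_cell_histograms(p, cell, bins)
  # L2-hys per cell: normalise, clip at 0.2, renormalise
  eps <- 1e-10
  nrm <- sqrt(apply(g^2, c(1, 2), sum) + eps)
  g <- g / array(nrm, dim(g))
  g <- pmin(g, 0.2)
  nrm <- sqrt(apply(g^2, c(1, 2), sum) + eps)
  g <- g / array(nrm, dim(g))
  if (cfg$window == "hann") g <- g * array(hann2(H2, W2), dim(g))
  feature_map(g, cell_size = cell)
}

# magnitude-weighted orientation histograms on the cell grid (no norm/window);
# exposed internally so tests can compare against a per-pixel oracle
hog_cell_histograms <- function(p, cell, bins) {
  nr <- nrow(p); nc <- ncol(p)
  gx <- (p[, c(2:nc, nc), drop = FALSE] - p[, c(1, 1:(nc - 1)), drop = FALSE]) / 2
  gy <- (p[c(2:nr, nr), , drop = FALSE] - p[c(1, 1:(nr - 1)), , drop = FALSE]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi                 # unsigned orientation in [0, pi)
  bin <- pmin(floor(ang / (pi / bins)), bins - 1)
  H2 <- nr %/% cell; W2 <- nc %/% cell
  crow <- (row(p) - 1L) %/% cell             # 0-based cell indices
  ccol <- (col(p) - 1L) %/% cell
  idx <- crow + H2 * ccol + H2 * W2 * bin + 1
  g <- array(0, c(H2, W2, bins))
  acc <- tapply(as.vector(mag), as.vector(idx), sum)
  g[as.integer(names(acc))] <- acc
  g
}

#' Extract features for the tracker
#'
#' Dispatches on the configured representation.
#'
#' @param patch search-window matrix from [extract_patch()].
#' @param cfg a [feature_config()].
#' @return a `feature_map`.
#' @export
extract_features <- function(patch, cfg) {
  switch(cfg$kind,
    gray = gray_features(patch, window = cfg$window),
    hog  = hog_features(patch, cfg)
  )
}
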