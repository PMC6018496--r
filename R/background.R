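#' Build a static background model
#'
#' Three estimators: the first frame; the per-pixel median of the first `n`
#' frames; or (default) the per-pixel median of `n` frames sampled evenly
#' across the whole sequence. The sampled median is the robust choice for
#' batch tracking: a target that lingers near its release point can occupy
#' a pixel for most of the opening frames -- leaving a static "ghost" in a
#' leading-frames median that background subtraction then re-detects forever
#' -- but it covers any one pixel for only a small fraction of the full
#' recording.
#'
#' @param fs a [frame_sequence()].
#' @param method `"median_sampled"`, `"median_n"` or `"first_frame"`.
#' @param n number of frames used for the median (capped at the sequence
#'   length).
#' @return a `background_model` with fields `image`, `method`, `n_frames`.
#' @export
build_background <- function(fs, method = c("median_sampled", "median_n",
                                            "first_frame"), n = 20) {
  method <- match.arg(method)
  stopifnot(inherits(fs, "frame_sequence"), n >= 1)
  if (length(fs$frames) == 0L) stop("empty frame sequence")
  n <- min(n, length(fs$frames))
  idx <- switch(method,
    first_frame = 1L,
    median_n = seq_len(n),
    median_sampled = unique(round(seq(1, length(fs$frames), length.out = n)))
  )
  img <- if (length(idx) == 1L) {
    fs$frames[[idx]]
  } else {
    stack <- vapply(fs$frames[idx], identity,
                    matrix(0, nrow(fs$frames[[1]]), ncol(fs$frames[[1]])))
    apply(stack, c(1, 2), stats::median)
  }
  structure(list(image = img, method = method, n_frames = length(idx)),
            class = "background_model")
}

#' Difference a frame against the background and binarise
#'
#' `|frame - background| > thresh` followed by one pass of 3x3 morphological
#' opening (removes isolated single-pixel noise).
#'
#' @param frame grayscale matrix in `[0, 1]`.
#' @param bg a [build_background()] model.
#' @param thresh intensity difference threshold on the 8-bit scale
#'   (default 25); divided by 255 to match unit-range frames.
#' @return a logical matrix.
#' @export
subtract_and_mask <- function(frame, bg, thresh = 25) {
  stopifnot(all(dim(frame) == dim(bg$image)))
  mask <- abs(frame - bg$image) > thresh / 255
  opened <- EBImage::opening(mask * 1, EBImage::makeBrush(3, "box"))
  matrix(opened > 0.5, nrow(frame), ncol(frame))
}

#' Centroid of the largest connected foreground component
#'
#' Labels the mask with 8-connectivity, discards components below
#' `min_area`, and returns the coordinate mean of the largest survivor.
#' Ties in component size are broken by the smallest label in scan order.
#'
#' @param mask logical matrix.
#' @param min_area minimum component size in pixels.
#' @return `c(u, v)` centroid in 0-based pixel coordinates, or `NULL` when
#'   no component survives.
#' @export
largest_component_centroid <- function(mask, min_area = 20) {
  stopifnot(is.logical(mask))
  lab <- label_components8(mask)
  if (is.null(lab)) return(NULL)
  sizes <- tabulate(lab$comp)
  keep <- which(sizes >= min_area)
  if (length(keep) == 0L) return(NULL)
  best <- keep[which.max(sizes[keep])]       # which.max takes the first tie
  px <- lab$comp == best
  c(u = mean(lab$col[px]) - 1, v = mean(lab$row[px]) - 1)
}

# 8-connected component labels of the foreground pixels, via the components
# of the 8-neighbour adjacency graph (EBImage::bwlabel is 4-connected, which
# splits diagonal links the centroid step must keep together)
label_components8 <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(NULL)
  nr <- nrow(mask)
  rw <- ((idx - 1L) %% nr) + 1L
  cl <- ((idx - 1L) %/% nr) + 1L
  key <- rw + (cl - 1L) * (nr + 2L)          # collision-free coordinate key
  pos <- seq_along(idx)
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nb <- match(key + d[1] + d[2] * (nr + 2L), key)
    ok <- which(!is.na(nb))
    if (length(ok)) edges <- c(edges, rbind(pos[ok], nb[ok]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber components by first appearance in column-major scan order
  comp <- match(comp, unique(comp))
  list(comp = comp, row = rw, col = cl)
}
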