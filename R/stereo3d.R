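#' Pinhole camera model for the orthogonal two-view rig
#'
#' Wind-tunnel world frame: `x` along the tunnel length, `y` along its
#' depth, `z` along its height, origin at the tunnel's top-left corner,
#' millimetres. The top camera views along the height axis (image `u` maps
#' `x`, `v` maps `y`); the side camera views along the depth axis (`u` maps
#' `x`, `v` maps `z`). For either camera the perpendicular distance from the
#' optical centre to a world point is `standoff_mm` minus the point's
#' coordinate along the viewing axis, so `standoff_mm` must exceed the
#' tunnel extent on that axis. Zero skew, no lens distortion (distortion, if
#' any, is handled upstream at calibration time).
#'
#' @param f_px focal length in pixels.
#' @param cu,cv principal point, 0-based pixel coordinates.
#' @param axis `"top"` or `"side"`.
#' @param standoff_mm optical-centre distance to the tunnel origin plane
#'   along the viewing axis.
#' @param width_px,height_px sensor size (used by the renderer and for
#'   frustum checks).
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(f_px, cu, cv, axis = c("top", "side"),
                         standoff_mm, width_px = NULL, height_px = NULL) {
  axis <- match.arg(axis)
  stopifnot(f_px > 0, standoff_mm > 0)
  structure(list(f_px = f_px, cu = cu, cv = cv, axis = axis,
                 standoff_mm = standoff_mm, width_px = width_px,
                 height_px = height_px),
            class = "camera_model")
}

#' Wind-tunnel dimensions
#'
#' @param length_mm,width_mm,height_mm tunnel extent along `x`, `y`, `z`
#'   (defaults 1800 x 580 x 580 mm).
#' @return a `tunnel_frame` list.
#' @export
tunnel_frame <- function(length_mm = 1800, width_mm = 580, height_mm = 580) {
  stopifnot(length_mm > 0, width_mm > 0, height_mm > 0)
  structure(list(length_mm = length_mm, width_mm = width_mm,
                 height_mm = height_mm, origin = "top-left"),
            class = "tunnel_frame")
}

#' Project a world point through a camera
#'
#' @param cam a [camera_model()].
#' @param p world point `c(x, y, z)` in mm.
#' @return `c(u, v, depth)`: pixel coordinates plus the perpendicular depth
#'   (mm) used.
#' @export
project_point <- function(cam, p) {
  p <- unname(as.numeric(p))
  if (cam$axis == "top") {
    depth <- cam$standoff_mm - p[3]
    uv <- c(cam$cu + cam$f_px * p[1] / depth, cam$cv + cam$f_px * p[2] / depth)
  } else {
    depth <- cam$standoff_mm - p[2]
    uv <- c(cam$cu + cam$f_px * p[1] / depth, cam$cv + cam$f_px * p[3] / depth)
  }
  if (depth <= 0) stop("point behind the camera (non-positive depth)")
  c(u = uv[1], v = uv[2], depth = depth)
}

#' Fuse one frame's two-view centroids into a 3-D point
#'
#' Each pinhole observation is linear in `(x, y, z)`; the two views give
#' four equations for three unknowns. The default solves them by least
#' squares, which reconciles the doubly observed abscissa `x` for any
#' camera pair; `method = "average_abscissa"` instead back-substitutes the
#' depth coordinates exactly and averages the two per-view `x` estimates
#' (the two coincide for consistent observations).
#'
#' @param top_uv,side_uv centroids `c(u, v)` in each view.
#' @param top_cam,side_cam the two [camera_model()]s (`axis` must be
#'   `"top"` and `"side"` respectively).
#' @param method `"lsq"` or `"average_abscissa"`.
#' @return `c(x, y, z)` in mm.
#' @export
fuse_frame <- function(top_uv, side_uv, top_cam, side_cam,
                       method = c("lsq", "average_abscissa")) {
  method <- match.arg(method)
  stopifnot(all(is.finite(top_uv)), all(is.finite(side_uv)),
            top_cam$axis == "top", side_cam$axis == "side")
  a1 <- c(top_uv[1] - top_cam$cu, top_uv[2] - top_cam$cv)    # top offsets
  a2 <- c(side_uv[1] - side_cam$cu, side_uv[2] - side_cam$cv)
  f1 <- top_cam$f_px; s1 <- top_cam$standoff_mm
  f2 <- side_cam$f_px; s2 <- side_cam$standoff_mm
  if (method == "lsq") {
    A <- rbind(c(f1, 0, a1[1]),     # f*x + (u-cu)*z = (u-cu)*s   (top)
               c(0, f1, a1[2]),     # f*y + (v-cv)*z = (v-cv)*s   (top)
               c(f2, a2[1], 0),     # f*x + (u-cu)*y = (u-cu)*s   (side)
               c(0, a2[2], f2))     # f*z + (v-cv)*y = (v-cv)*s   (side)
    rhs <- c(a1[1] * s1, a1[2] * s1, a2[1] * s2, a2[2] * s2)
    if (qr(A)$rank < 3) stop("degenerate camera geometry: rank-deficient fuse")
    sol <- qr.solve(A, rhs)
    return(c(x = sol[1], y = sol[2], z = sol[3]))
  }
  # average-abscissa mode: y = (v1/f1)*(s1 - z), z = (v2/f2)*(s2 - y) solve
  # exactly, then x from each view, averaged
  b1 <- a1[2] / f1; b2 <- a2[2] / f2
  den <- 1 - b1 * b2
  if (abs(den) < 1e-12) stop("degenerate camera geometry in abscissa mode")
  z <- b2 * (s2 - b1 * s1) / den
  y <- b1 * (s1 - z)
  x <- mean(c(a1[1] / f1 * (s1 - z), a2[1] / f2 * (s2 - y)))
  c(x = x, y = y, z = z)
}

#' Reconstruct a 3-D trajectory from two tracked views
#'
#' Matches the two per-view trajectories on their shared, hardware-
#' synchronised frame clock and fuses every frame that is non-lost in both
#' views. Frames lost in either view become lost 3-D records (coordinates
#' `NA`); optionally, interior gaps of at most `gap_fill` frames are filled
#' by linear interpolation between their good neighbours.
#'
#' @param top,side trajectory data frames (`frame, u, v, status`).
#' @param top_cam,side_cam the two [camera_model()]s.
#' @param method fusion method, see [fuse_frame()].
#' @param gap_fill maximum gap length (frames) to interpolate; `0` disables.
#' @return an object of class `trajectory3d`: data frame
#'   `frame, x_mm, y_mm, z_mm, status` (status `fused`, `lost` or
#'   `interpolated`).
#' @export
reconstruct3d <- function(top, side, top_cam, side_cam,
                          method = c("lsq", "average_abscissa"),
                          gap_fill = 0) {
  method <- match.arg(method)
  common <- intersect(top$frame, side$frame)
  if (length(common) == 0L) stop("the two views share no frame indices")
  common <- sort(common)
  ti <- match(common, top$frame); si <- match(common, side$frame)
  n <- length(common)
  x <- y <- z <- rep(NA_real_, n)
  status <- rep("lost", n)
  for (i in seq_len(n)) {
    if (top$status[ti[i]] == "lost" || side$status[si[i]] == "lost") next
    p <- fuse_frame(c(top$u[ti[i]], top$v[ti[i]]),
                    c(side$u[si[i]], side$v[si[i]]),
                    top_cam, side_cam, method = method)
    x[i] <- p[1]; y[i] <- p[2]; z[i] <- p[3]
    status[i] <- "fused"
  }
  if (gap_fill > 0) {
    good <- which(status == "fused")
    runs <- rle(status == "lost")
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      a <- starts[r] - 1L; b <- ends[r] + 1L
      len <- runs$lengths[r]
      if (a < 1L || b > n || len > gap_fill) next
      if (status[a] != "fused" || status[b] != "fused") next
      w <- seq_len(len) / (len + 1)
      idx <- starts[r]:ends[r]
      x[idx] <- (1 - w) * x[a] + w * x[b]
      y[idx] <- (1 - w) * y[a] + w * y[b]
      z[idx] <- (1 - w) * z[a] + w * z[b]
      status[idx] <- "interpolated"
    }
  }
  structure(data.frame(frame = common, x_mm = x, y_mm = y, z_mm = z,
                       status = status, stringsAsFactors = FALSE),
            class = c("trajectory3d", "data.frame"))
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("<trajectory3d> %d frames: %d fused, %d interpolated, %d lost\n",
              nrow(x), sum(x$status == "fused"),
              sum(x$status == "interpolated"), sum(x$status == "lost")))
  NextMethod()
}

#' @export
plot.trajectory3d <- function(x, ...) {
  ok <- x$status != "lost"
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  graphics::plot(x$x_mm[ok], x$y_mm[ok], type = "l", xlab = "x (mm)",
                 ylab = "y (mm)", main = "top view")
  graphics::plot(x$x_mm[ok], x$z_mm[ok], type = "l", xlab = "x (mm)",
                 ylab = "z (mm)", main = "side view")
  graphics::plot(x$y_mm[ok], x$z_mm[ok], type = "l", xlab = "y (mm)",
                 ylab = "z (mm)", main = "cross-section")
  invisible(x)
}
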