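#' Flight dynamics parameters for the synthetic generator
#'
#' The simulated insect is a damped second-order random walk: per frame the
#' velocity receives a Gaussian acceleration kick and exponential damping,
#' plus a constant wind drift along `-x` (emulating the tunnel's 0.4 m/s
#' airflow); positions reflect off the bounding box. At 60 fps a cruising
#' speed around 0.5 m/s corresponds to roughly 8 mm/frame, which the default
#' kick/damping pair settles near.
#'
#' @param accel_sigma acceleration noise, mm/frame^2.
#' @param damping velocity retained per frame (0..1).
#' @param drift constant drift `c(dx, dy, dz)` in mm/frame.
#' @param bounds 3x2 matrix of `(lo, hi)` per axis, mm. Default keeps the
#'   flight inside the volume both default cameras image sharply.
#' @param v0 initial velocity, mm/frame.
#' @return a `flight_params` list.
#' @export
flight_params <- function(accel_sigma = 1.2, damping = 0.9,
                          drift = c(-0.8, 0, 0),
                          bounds = rbind(x = c(120, 880), y = c(50, 530),
                                         z = c(50, 530)),
                          v0 = c(4, 2, 1)) {
  structure(list(accel_sigma = accel_sigma, damping = damping, drift = drift,
                 bounds = bounds, v0 = v0),
            class = "flight_params")
}

# run code under a private RNG stream without disturbing the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulate a ground-truth flight trajectory
#'
#' @param params a [flight_params()].
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed; identical seeds give identical trajectories.
#' @param start starting position, mm; default the bounds centre.
#' @return data frame `frame, x_mm, y_mm, z_mm` (class `trajectory3d`, all
#'   frames `fused`).
#' @export
simulate_flight <- function(params = flight_params(), n_frames, seed = 1,
                            start = NULL) {
  stopifnot(n_frames >= 2)
  b <- params$bounds
  if (is.null(start)) start <- rowMeans(b)
  pos <- matrix(0, n_frames, 3)
  pos[1, ] <- start
  v <- params$v0
  with_seed(seed, {
    for (t in 2:n_frames) {
      v <- params$damping * v + stats::rnorm(3, 0, params$accel_sigma)
      p <- pos[t - 1, ] + v + params$drift
      for (k in 1:3) {                       # reflective walls
        while (p[k] < b[k, 1] || p[k] > b[k, 2]) {
          if (p[k] < b[k, 1]) { p[k] <- 2 * b[k, 1] - p[k]; v[k] <- -v[k] }
          if (p[k] > b[k, 2]) { p[k] <- 2 * b[k, 2] - p[k]; v[k] <- -v[k] }
        }
      }
      pos[t, ] <- p
    }
  })
  structure(data.frame(frame = 0:(n_frames - 1L), x_mm = pos[, 1],
                       y_mm = pos[, 2], z_mm = pos[, 3],
                       status = "fused", stringsAsFactors = FALSE),
            class = c("trajectory3d", "data.frame"))
}

#' Default orthogonal camera pair
#'
#' Both cameras image a 640 x 400 px frame with a 290 px focal length from
#' 1000 mm standoff. That keeps every point of the default flight volume
#' (plus the target's own extent) inside both frusta at 0.3-0.6 px/mm of
#' magnification.
#'
#' @return list with elements `top` and `side` ([camera_model()]s).
#' @export
default_cameras <- function() {
  list(
    top = camera_model(f_px = 290, cu = 30, cv = 10, axis = "top",
                       standoff_mm = 1000, width_px = 640, height_px = 400),
    side = camera_model(f_px = 290, cu = 30, cv = 10, axis = "side",
                        standoff_mm = 1000, width_px = 640, height_px = 400)
  )
}

#' Synthetic wind-tunnel scene configuration
#'
#' Describes everything the renderer needs: tunnel, cameras, the deformable
#' dark target (an anti-aliased ellipse whose axes oscillate with wingbeat
#' phase over a light, weakly textured background), optional static opaque
#' occluder slabs ("plants"), an optional similar-colour zone whose uniform
#' intensity equals the target's (the low-contrast failure case), sensor
#' noise, and the RNG seed. All stochastic draws (flight, background
#' texture, per-frame noise) derive from `seed`, so scenes are bit
#' reproducible.
#'
#' @param tunnel a [tunnel_frame()].
#' @param cams list with `top` and `side` [camera_model()]s.
#' @param n_frames frames to render.
#' @param fps frame rate metadata (60, the rig's trigger rate).
#' @param target list: `size_mm` (body+wing extent, 40 mm), `intensity`
#'   (dark target, 0.25), `wingbeat_amp` (relative axis oscillation, 0.3),
#'   `wingbeat_period` (frames, 8).
#' @param background list: `base` intensity (0.75), `texture_amp` (0.05),
#'   `texture_scale` (px, correlation length of the static texture).
#' @param occluders list of slabs, each
#'   `list(xlim =, ylim =, zlim =, intensity =)` in mm.
#' @param similar_zone optional slab (same form) painted uniformly at the
#'   target intensity; rendered in the view(s) named by its `views` element
#'   (default `"top"`).
#' @param noise_sigma Gaussian pixel noise sd on the unit intensity scale
#'   (default 0.008, about 2 grey levels of an 8-bit sensor).
#' @param flight a [flight_params()].
#' @param seed integer RNG seed.
#' @return a `scene_config` list.
#' @export
scene_config <- function(tunnel = tunnel_frame(), cams = default_cameras(),
                         n_frames = 120, fps = 60,
                         target = list(size_mm = 40, intensity = 0.25,
                                       wingbeat_amp = 0.3,
                                       wingbeat_period = 8),
                         background = list(base = 0.75, texture_amp = 0.05,
                                           texture_scale = 8),
                         occluders = list(), similar_zone = NULL,
                         noise_sigma = 0.008,
                         flight = flight_params(), seed = 1) {
  stopifnot(n_frames >= 2)
  structure(list(tunnel = tunnel, cams = cams, n_frames = n_frames,
                 fps = fps, target = target, background = background,
                 occluders = occluders, similar_zone = similar_zone,
                 noise_sigma = noise_sigma, flight = flight,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# smooth static texture: low-pass filtered white noise, scaled to amplitude
make_texture <- function(h, w, amp, scale) {
  if (amp <= 0) return(matrix(0, h, w))
  z <- matrix(stats::rnorm(h * w), h, w)
  fr <- pmin(0:(h - 1), h - 0:(h - 1)) / h
  fc <- pmin(0:(w - 1), w - 0:(w - 1)) / w
  filt <- exp(-2 * (pi * scale)^2 * outer(fr^2, fc^2, "+"))
  tx <- Re(stats::fft(stats::fft(z) * filt, inverse = TRUE)) / (h * w)
  tx <- tx - mean(tx)
  tx / max(abs(tx)) * amp
}

# slab footprint (pixel rect) in a view, projected at the slab face nearest
# the camera; returns list(rows, cols, depth) or NULL if off-frame
slab_footprint <- function(cam, slab) {
  if (cam$axis == "top") {
    zn <- max(slab$zlim)                    # closest face to the top camera
    d <- cam$standoff_mm - zn
    u <- cam$cu + cam$f_px * slab$xlim / d
    v <- cam$cv + cam$f_px * slab$ylim / d
  } else {
    yn <- max(slab$ylim)
    d <- cam$standoff_mm - yn
    u <- cam$cu + cam$f_px * slab$xlim / d
    v <- cam$cv + cam$f_px * slab$zlim / d
  }
  rows <- max(1L, floor(min(v)) + 1L):min(cam$height_px, ceiling(max(v)) + 1L)
  cols <- max(1L, floor(min(u)) + 1L):min(cam$width_px, ceiling(max(u)) + 1L)
  if (length(rows) == 0L || length(cols) == 0L) return(NULL)
  list(rows = rows, cols = cols, depth = d)
}

# anti-aliased ellipse blend into canvas; centre (uc,vc) 0-based px
draw_ellipse <- function(canvas, uc, vc, au, av, intensity) {
  r0 <- max(1L, floor(vc - av - 1) + 1L)
  r1 <- min(nrow(canvas), ceiling(vc + av + 1) + 1L)
  c0 <- max(1L, floor(uc - au - 1) + 1L)
  c1 <- min(ncol(canvas), ceiling(uc + au + 1) + 1L)
  if (r0 > r1 || c0 > c1) return(canvas)
  vr <- (r0:r1) - 1 - vc
  uc_ <- (c0:c1) - 1 - uc
  r <- sqrt(outer((vr / av)^2, (uc_ / au)^2, "+"))
  cov <- pmin(pmax(1.5 * (1 - r), 0), 1)    # soft 1-px anti-aliased edge
  sub <- canvas[r0:r1, c0:c1, drop = FALSE]
  canvas[r0:r1, c0:c1] <- sub * (1 - cov) + intensity * cov
  canvas
}

#' Render a trajectory through both cameras
#'
#' Produces the two synchronised grayscale views plus exact per-view pixel
#' ground truth. The target is drawn as a dark anti-aliased ellipse whose
#' apparent size scales with inverse depth and whose axes oscillate with
#' wingbeat phase; occluder slabs are painted into the static background and
#' re-painted over the target whenever they sit between it and the camera;
#' the similar-colour zone is a uniform background region at the target's
#' own intensity, inside which the target is invisible.
#'
#' @param traj a trajectory data frame (`frame, x_mm, y_mm, z_mm`), e.g.
#'   from [simulate_flight()].
#' @param scene a [scene_config()].
#' @return list with `top` and `side` [frame_sequence()]s and `truth`, a
#'   list of data frames: `top`/`side` (`frame, u, v, occluded`) and `xyz`
#'   (the input trajectory).
#' @export
render_views <- function(traj, scene) {
  n <- nrow(traj)
  out <- list()
  tgt <- scene$target
  with_seed(scene$seed + 1L, {
    for (view in c("top", "side")) {
      cam <- scene$cams[[view]]
      h <- cam$height_px; w <- cam$width_px
      bg <- scene$background$base +
        make_texture(h, w, scene$background$texture_amp,
                     scene$background$texture_scale)
      occ_fp <- list()
      for (ob in scene$occluders) {
        fp <- slab_footprint(cam, ob)
        if (!is.null(fp)) {
          fp$intensity <- ob$intensity
          bg[fp$rows, fp$cols] <- ob$intensity
          occ_fp[[length(occ_fp) + 1L]] <- fp
        }
      }
      if (!is.null(scene$similar_zone)) {
        zviews <- scene$similar_zone$views
        if (is.null(zviews)) zviews <- "top"
        if (view %in% zviews) {
          fp <- slab_footprint(cam, scene$similar_zone)
          if (!is.null(fp)) bg[fp$rows, fp$cols] <- tgt$intensity
        }
      }
      frames <- vector("list", n)
      tu <- tv <- numeric(n); occluded <- logical(n)
      for (t in seq_len(n)) {
        p <- c(traj$x_mm[t], traj$y_mm[t], traj$z_mm[t])
        pr <- project_point(cam, p)
        tu[t] <- pr["u"]; tv[t] <- pr["v"]
        if (pr["u"] < 0 || pr["u"] > w - 1 || pr["v"] < 0 || pr["v"] > h - 1)
          stop("target outside the ", view, " camera frustum at frame ", t - 1)
        phase <- sin(2 * pi * (t - 1) / tgt$wingbeat_period)
        half <- tgt$size_mm / 2 * cam$f_px / pr["depth"]
        au <- half * (1 + tgt$wingbeat_amp * phase)
        av <- half * (1 - tgt$wingbeat_amp * phase)
        fr <- draw_ellipse(bg, pr["u"], pr["v"], au, av, tgt$intensity)
        for (fp in occ_fp) {
          if (fp$depth < pr["depth"]) {      # slab closer to the camera
            fr[fp$rows, fp$cols] <- fp$intensity
            if (pr["u"] >= min(fp$cols) - 1 && pr["u"] <= max(fp$cols) - 1 &&
                pr["v"] >= min(fp$rows) - 1 && pr["v"] <= max(fp$rows) - 1)
              occluded[t] <- TRUE
          }
        }
        if (scene$noise_sigma > 0)
          fr <- fr + matrix(stats::rnorm(h * w, 0, scene$noise_sigma), h, w)
        frames[[t]] <- pmin(pmax(fr, 0), 1)
      }
      out[[view]] <- frame_sequence(frames, fps = scene$fps)
      out$truth[[view]] <- data.frame(frame = traj$frame, u = tu, v = tv,
                                      occluded = occluded)
    }
  })
  out$truth$xyz <- traj
  out
}

#' Canned benchmark scenes
#'
#' The four wind-tunnel test cases as ready-made scene + flight bundles:
#' `"centre"` (open flight, no obstacles), `"occluded"` (an opaque plant
#' slab placed over part of the flight path in the top view), `"edge"`
#' (flight hugging a tunnel wall), and `"similar"` (a uniform zone at the
#' target's own intensity in the top view). The occluder and zone are
#' positioned from the simulated path itself so the scripted failure mode is
#' guaranteed to occur, deterministically for a given seed.
#'
#' @param case one of `"centre"`, `"occluded"`, `"edge"`, `"similar"`.
#' @param n_frames frames to simulate and render.
#' @param seed RNG seed.
#' @param ... overrides passed on to [scene_config()].
#' @return list: `scene` ([scene_config()]), `traj` (ground-truth 3-D
#'   trajectory) and `rendered` ([render_views()] output).
#' @export
make_scene <- function(case = c("centre", "occluded", "edge", "similar"),
                       n_frames = 120, seed = 1, ...) {
  case <- match.arg(case)
  fp <- flight_params()
  if (case == "edge")
    fp$bounds <- rbind(x = c(120, 880), y = c(50, 90), z = c(50, 530))
  if (case %in% c("occluded", "similar")) {
    # these cases need a flight that decisively crosses the obstructed
    # stretch rather than hovering inside it: steady upwind progress with
    # milder jitter
    fp$accel_sigma <- 0.6
    fp$drift <- c(-2.5, 0, 0)
    fp$v0 <- c(-4, 1, 0.5)
  }
  traj <- simulate_flight(fp, n_frames, seed = seed)
  occluders <- list()
  similar_zone <- NULL
  # The top camera's optical centre sits at world (0, 0, standoff); anything
  # meant to sit between target and camera must straddle the target->pinhole
  # rays, so path points are projected onto the slab plane through the
  # pinhole before taking the covering rectangle.
  ray_rect <- function(i, z_plane, margin = 12) {
    s <- scene_cam_standoff <- default_cameras()$top$standoff_mm
    tt <- (s - z_plane) / (s - traj$z_mm[i])
    list(xlim = range(traj$x_mm[i] * tt) + c(-margin, margin),
         ylim = range(traj$y_mm[i] * tt) + c(-margin, margin))
  }
  if (case == "occluded") {
    # opaque "plant" slab intercepting the top-view rays over frames 11..21
    # (0-based 10..20): long enough that the target re-emerges outside the
    # search window of a stuck correlation box
    rr <- ray_rect(13:23, z_plane = 552.5)
    occluders <- list(list(xlim = rr$xlim, ylim = rr$ylim,
                           zlim = c(545, 560), intensity = 0.45))
  }
  if (case == "similar") {
    # uniform floor patch at the target's own intensity under the same
    # stretch of path
    # wider margin than the occluder: the zone must exceed the target's own
    # footprint so there are frames with the insect fully inside it
    rr <- ray_rect(13:23, z_plane = 2.5, margin = 35)
    similar_zone <- list(xlim = rr$xlim, ylim = rr$ylim,
                         zlim = c(0, 5), views = "top")
  }
  scene <- scene_config(n_frames = n_frames, occluders = occluders,
                        similar_zone = similar_zone, flight = fp,
                        seed = seed, ...)
  list(scene = scene, traj = traj, rendered = render_views(traj, scene))
}

#' First-frame target box from ground truth
#'
#' Convenience: the axis-aligned box around the target's frame-1 truth
#' centroid, sized from the projected target extent.
#'
#' @param truth_view per-view truth data frame from [render_views()].
#' @param scene the [scene_config()].
#' @param view `"top"` or `"side"`.
#' @return `list(u, v, w, h)` usable as `init_box`.
#' @export
init_box_from_truth <- function(truth_view, scene, view = "top") {
  cam <- scene$cams[[view]]
  depth <- cam$standoff_mm - mean(scene$flight$bounds[
    if (cam$axis == "top") 3 else 2, ])
  half <- scene$target$size_mm / 2 * cam$f_px / depth
  side <- 2 * ceiling(half * (1 + scene$target$wingbeat_amp)) + 4
  list(u = truth_view$u[1] - (side - 1) / 2,
       v = truth_view$v[1] - (side - 1) / 2, w = side, h = side)
}
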