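test_that("flight simulation honours degenerate dynamics and determinism", {
  still <- flight_params(accel_sigma = 0, drift = c(0, 0, 0), v0 = c(0, 0, 0))
  tr <- simulate_flight(still, 10, seed = 1)
  expect_true(all(tr$x_mm == tr$x_mm[1] & tr$z_mm == tr$z_mm[1]))
  # pure drift: x decreases 2 mm per frame until the wall
  bal <- flight_params(accel_sigma = 0, drift = c(-2, 0, 0), v0 = c(0, 0, 0))
  tr2 <- simulate_flight(bal, 20, seed = 1)
  expect_equal(diff(tr2$x_mm), rep(-2, 19))
  expect_identical(simulate_flight(n_frames = 30, seed = 5),
                   simulate_flight(n_frames = 30, seed = 5))
  expect_false(identical(simulate_flight(n_frames = 30, seed = 5),
                         simulate_flight(n_frames = 30, seed = 6)))
  # reflection keeps the trajectory inside bounds
  fast <- flight_params(accel_sigma = 4, drift = c(-5, 0, 0))
  tr3 <- simulate_flight(fast, 300, seed = 8)
  b <- fast$bounds
  expect_true(all(tr3$x_mm >= b[1, 1] & tr3$x_mm <= b[1, 2]))
  expect_true(all(tr3$z_mm >= b[3, 1] & tr3$z_mm <= b[3, 2]))
})

test_that("rendering is self-consistent: BS centroids sit on the projected
           truth in a clean scene", {
  # steady crossing flight so the median background is target-free
  fp <- flight_params(accel_sigma = 0, drift = c(-6, 0, 0), v0 = c(0, 0, 0))
  scene <- scene_config(n_frames = 12, noise_sigma = 0,
                        background = list(base = 0.75, texture_amp = 0,
                                          texture_scale = 8),
                        flight = fp, seed = 2)
  traj <- simulate_flight(scene$flight, 12, seed = 2)
  rv <- render_views(traj, scene)
  for (view in c("top", "side")) {
    bg <- build_background(rv[[view]], "median_n", n = 12)
    err <- vapply(seq_len(12), function(t) {
      cen <- largest_component_centroid(
        subtract_and_mask(rv[[view]]$frames[[t]], bg, thresh = 25),
        min_area = 20)
      truth <- rv$truth[[view]][t, ]
      sqrt((cen["u"] - truth$u)^2 + (cen["v"] - truth$v)^2)
    }, 1)
    # thresholding the anti-aliased edge quantises the mask: individual
    # frames may be off by up to about a pixel, the average stays well under
    expect_lt(max(err), 1.5)
    expect_lt(mean(err), 0.75)
  }
})

test_that("projected truth fused back through the cameras recovers the 3-D
           flight to 1e-6 mm", {
  sc <- make_scene("centre", n_frames = 15, seed = 3)
  cams <- sc$scene$cams
  tt <- sc$rendered$truth
  for (i in seq_len(15)) {
    got <- fuse_frame(c(tt$top$u[i], tt$top$v[i]),
                      c(tt$side$u[i], tt$side$v[i]), cams$top, cams$side)
    want <- as.numeric(sc$traj[i, c("x_mm", "y_mm", "z_mm")])
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("occluder slabs hide the target in the obstructed view only, for
           exactly the flagged frames", {
  sc <- make_scene("occluded", n_frames = 60, seed = 3)
  rv <- sc$rendered
  occ <- which(rv$truth$top$occluded)
  expect_gt(length(occ), 3)
  expect_false(any(rv$truth$side$occluded))
  bg_t <- build_background(rv$top); bg_s <- build_background(rv$side)
  # the entry/exit frames are only partially covered (the flag marks the
  # centroid crossing the slab); test full occlusion mid-run
  mid <- occ[floor(length(occ) / 2)]
  for (t in c(mid - 1, mid)) {
    expect_null(largest_component_centroid(
      subtract_and_mask(rv$top$frames[[t]], bg_t), 20))
    expect_false(is.null(largest_component_centroid(
      subtract_and_mask(rv$side$frames[[t]], bg_s), 20)))
  }
  # an unoccluded frame is visible in the top view too
  vis <- max(occ) + 3
  expect_false(is.null(largest_component_centroid(
    subtract_and_mask(rv$top$frames[[vis]], bg_t), 20)))
})

test_that("rendering a fixed scene twice is bit-identical", {
  scene <- scene_config(n_frames = 5, seed = 17)
  traj <- simulate_flight(scene$flight, 5, seed = 17)
  r1 <- render_views(traj, scene)
  r2 <- render_views(traj, scene)
  expect_identical(r1$top$frames, r2$top$frames)
  expect_identical(r1$side$frames, r2$side$frames)
})
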