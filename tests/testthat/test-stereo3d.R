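test_that("principal-ray observations fuse to the tunnel origin", {
  cams <- default_cameras()
  p <- fuse_frame(c(cams$top$cu, cams$top$cv), c(cams$side$cu, cams$side$cv),
                  cams$top, cams$side)
  expect_equal(unname(p), c(0, 0, 0), tolerance = 1e-9)
})

test_that("project-then-fuse recovers random in-tunnel points to 1e-6 mm for
           randomized camera parameters, in both fusion modes", {
  set.seed(14)
  for (rep in 1:20) {
    top <- camera_model(f_px = runif(1, 250, 600), cu = runif(1, 0, 60),
                        cv = runif(1, 0, 60), axis = "top",
                        standoff_mm = runif(1, 800, 2500))
    side <- camera_model(f_px = runif(1, 250, 600), cu = runif(1, 0, 60),
                         cv = runif(1, 0, 60), axis = "side",
                         standoff_mm = runif(1, 800, 2500))
    p <- c(runif(1, 0, 700), runif(1, 0, 550), runif(1, 0, 550))
    pt <- project_point(top, p); ps <- project_point(side, p)
    for (mode in c("lsq", "average_abscissa")) {
      got <- fuse_frame(pt[c("u", "v")], ps[c("u", "v")], top, side, mode)
      expect_lt(max(abs(got - p)), 1e-6)
    }
  }
})

test_that("a one-pixel abscissa perturbation moves x by at most the
           single-view sensitivity, and by exactly half of it in
           average-abscissa mode", {
  cams <- default_cameras()
  p <- c(400, 250, 300)
  pt <- project_point(cams$top, p); ps <- project_point(cams$side, p)
  sens <- (cams$top$standoff_mm - p[3]) / cams$top$f_px   # mm per px
  base <- fuse_frame(pt[c("u", "v")], ps[c("u", "v")], cams$top, cams$side)
  pert <- fuse_frame(pt[c("u", "v")] + c(1, 0), ps[c("u", "v")],
                     cams$top, cams$side)
  dx <- pert["x"] - base["x"]
  expect_gt(dx, 0)
  expect_lte(dx, sens + 1e-9)
  pa <- fuse_frame(pt[c("u", "v")] + c(1, 0), ps[c("u", "v")],
                   cams$top, cams$side, "average_abscissa")
  expect_equal(unname(pa["x"] - base["x"]), sens / 2, tolerance = 1e-9)
})

test_that("trajectory reconstruction keeps lost bookkeeping and fills short
           gaps linearly", {
  cams <- default_cameras()
  traj <- simulate_flight(n_frames = 20, seed = 2)
  top <- side <- data.frame(frame = traj$frame, u = NA, v = NA,
                            status = "tracked")
  for (i in seq_len(20)) {
    pt <- project_point(cams$top, as.numeric(traj[i, c("x_mm", "y_mm", "z_mm")]))
    ps <- project_point(cams$side, as.numeric(traj[i, c("x_mm", "y_mm", "z_mm")]))
    top[i, c("u", "v")] <- pt[c("u", "v")]
    side[i, c("u", "v")] <- ps[c("u", "v")]
  }
  side$status[6:10] <- "lost"
  out <- reconstruct3d(top, side, cams$top, cams$side)
  expect_identical(out$status[6:10], rep("lost", 5))
  expect_true(all(is.na(out$x_mm[6:10])))
  expect_identical(out$status[-(6:10)], rep("fused", 15))
  e <- error_distances(out[out$status == "fused", ], traj)
  expect_lt(e$max, 1e-6)
  # a 2-frame gap under gap_fill = 2 interpolates on the straight line
  side2 <- side; side2$status <- "tracked"; side2$status[8:9] <- "lost"
  out2 <- reconstruct3d(top, side2, cams$top, cams$side, gap_fill = 2)
  expect_identical(out2$status[8:9], rep("interpolated", 2))
  expect_equal(out2$x_mm[8], out2$x_mm[7] + (out2$x_mm[10] - out2$x_mm[7]) / 3,
               tolerance = 1e-9)
  # disjoint frame ranges are an input error
  top2 <- top; top2$frame <- top2$frame + 100
  expect_error(reconstruct3d(top2, side, cams$top, cams$side), "no frame")
})

test_that("3-D error grows monotonically with added pixel noise", {
  cams <- default_cameras()
  traj <- simulate_flight(n_frames = 60, seed = 4)
  proj <- function(cam) t(apply(traj[, c("x_mm", "y_mm", "z_mm")], 1,
                                function(p) project_point(cam, p)[c("u", "v")]))
  pt <- proj(cams$top); ps <- proj(cams$side)
  rmse <- sapply(c(0.5, 1, 2), function(sig) {
    set.seed(99)
    top <- data.frame(frame = traj$frame, u = pt[, 1] + rnorm(60, 0, sig),
                      v = pt[, 2] + rnorm(60, 0, sig), status = "tracked")
    side <- data.frame(frame = traj$frame, u = ps[, 1] + rnorm(60, 0, sig),
                       v = ps[, 2] + rnorm(60, 0, sig), status = "tracked")
    out <- reconstruct3d(top, side, cams$top, cams$side)
    sqrt(mean((out$x_mm - traj$x_mm)^2 + (out$y_mm - traj$y_mm)^2 +
                (out$z_mm - traj$z_mm)^2))
  })
  expect_true(all(diff(rmse) > 0))
  expect_equal(rmse[3] / rmse[1], 4, tolerance = 0.5)   # roughly linear in sigma
})
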