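#' Per-frame Euclidean error between a track and ground truth
#'
#' Matches on frame index and measures the Euclidean distance per frame,
#' in pixels for 2-D trajectories (`u, v` columns) or millimetres for 3-D
#' ones (`x_mm, y_mm, z_mm` columns).
#'
#' @param traj,truth trajectory data frames sharing a `frame` column.
#' @return an `error_summary`: list with `per_frame` (data frame
#'   `frame, error`), `max`, `min`, `mean`.
#' @export
error_distances <- function(traj, truth) {
  cols <- if (all(c("x_mm", "y_mm", "z_mm") %in% names(traj)))
    c("x_mm", "y_mm", "z_mm") else c("u", "v")
  common <- intersect(traj$frame, truth$frame)
  if (length(common) == 0L) stop("no common frame indices")
  common <- sort(common)
  a <- as.matrix(traj[match(common, traj$frame), cols])
  b <- as.matrix(truth[match(common, truth$frame), cols])
  err <- sqrt(rowSums((a - b)^2))
  structure(list(per_frame = data.frame(frame = common, error = err),
                 max = max(err), min = min(err), mean = mean(err),
                 units = if (length(cols) == 3) "mm" else "px"),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("error over %d frames (%s): mean %.2f, min %.2f, max %.2f\n",
              nrow(x$per_frame), x$units, x$mean, x$min, x$max))
  invisible(x)
}

#' Tracking success rate
#'
#' Percentage of frames that are both non-lost and within `tol_px` of the
#' ground truth, reported to one decimal place. The tolerance defines what
#' counts as a successful frame and is reported alongside results.
#'
#' @param traj tracked trajectory (`frame, u, v, status`).
#' @param truth ground truth (`frame, u, v`).
#' @param tol_px success tolerance in pixels (default 20).
#' @return percentage in `[0, 100]`, rounded to 1 decimal.
#' @export
success_rate <- function(traj, truth, tol_px = 20) {
  common <- intersect(traj$frame, truth$frame)
  if (length(common) == 0L) stop("no common frame indices")
  ti <- match(common, traj$frame); gi <- match(common, truth$frame)
  err <- sqrt((traj$u[ti] - truth$u[gi])^2 + (traj$v[ti] - truth$v[gi])^2)
  ok <- traj$status[ti] != "lost" & err <= tol_px
  round(100 * sum(ok) / length(common), 1)
}

#' Error statistics of a calculated-vs-actual distance table
#'
#' For a table of calculated and tape-measured pairwise distances, computes
#' the absolute errors and their mean, population standard deviation
#' (divide by n -- the convention that matches the reference table), min and
#' max, plus per-row relative errors `100 * error / actual`. When the table
#' carries previously printed error columns, rows whose printed relative
#' error disagrees with the recomputed one (at the printed 2-decimal
#' precision) are flagged rather than silently matched.
#'
#' @param table data frame with columns `calculated_mm` and `actual_mm`
#'   (optionally `pair`, `printed_error_mm`, `printed_relative_error_pct`).
#' @return list with `mean_error_mm`, `std_error_mm`, `min_error_mm`,
#'   `max_error_mm`, and `rows` (the table plus `error_mm`,
#'   `relative_error_pct` and, when printed values exist, `printed_mismatch`).
#' @export
pairwise_distance_stats <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1,
            all(c("calculated_mm", "actual_mm") %in% names(table)))
  err <- abs(table$calculated_mm - table$actual_mm)
  rel <- 100 * err / table$actual_mm
  rows <- table
  rows$error_mm <- err
  rows$relative_error_pct <- rel
  if ("printed_relative_error_pct" %in% names(table))
    rows$printed_mismatch <-
      round2(rel, 2) != table$printed_relative_error_pct
  list(mean_error_mm = mean(err),
       std_error_mm = sqrt(mean((err - mean(err))^2)),   # population sd
       min_error_mm = min(err),
       max_error_mm = max(err),
       rows = rows)
}

# half-away-from-zero rounding, the convention of printed report tables
# (base round() rounds half to even)
round2 <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Ping-pong-ball accuracy fixture
#'
#' The packaged table of calculated vs tape-measured distances between five
#' ping-pong balls suspended in the wind tunnel -- the rig's 3-D accuracy
#' reference experiment. Columns: `pair`, `calculated_mm`, `actual_mm`,
#' plus the originally printed error columns.
#'
#' @return a data frame with 10 rows.
#' @export
table4_balls <- function() {
  path <- system.file("extdata", "table4_balls.csv", package = "kcfbs",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
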