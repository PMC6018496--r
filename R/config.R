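#' Read a tracker configuration from YAML
#'
#' The file may contain `features:`, `kcf:` and `bs:` blocks; anything
#' omitted keeps the package default. Recognised keys --
#' `features`: `kind`, `padding`, `hog_cell`, `hog_bins`, `window`;
#' `kcf`: `kernel` (linear/polynomial/gaussian), `lambda`, `eta`,
#' `loss_threshold_T`, `sigma_factor`, `gauss_sigma`, `poly_offset`,
#' `poly_degree`, `bs_enabled`;
#' `bs`: `method`, `n_frames`, `thresh`, `min_area`.
#'
#' @param path YAML file path.
#' @return a [tracker_config()].
#' @export
read_tracker_config <- function(path) {
  y <- yaml::read_yaml(path)
  fe <- y$features %||% list()
  kc <- y$kcf %||% list()
  bs_def <- list(method = "median_sampled", n_frames = 20, thresh = 25,
                 min_area = 20)
  bs <- utils::modifyList(bs_def, y$bs %||% list())
  feature <- feature_config(
    kind = fe$kind %||% "gray",
    padding = fe$padding %||% 2,
    hog_cell = fe$hog_cell %||% 4,
    hog_bins = fe$hog_bins %||% 9,
    window = fe$window %||% "hann")
  kernel <- kernel_spec(
    kind = kc$kernel %||% "gaussian",
    poly_offset = kc$poly_offset %||% 1,
    poly_degree = kc$poly_degree %||% 3,
    gauss_sigma = kc$gauss_sigma %||%
      (if ((fe$kind %||% "gray") == "hog") 0.5 else 0.2))
  tracker_config(
    feature = feature, kernel = kernel,
    lambda = kc$lambda %||% 1e-4,
    eta = kc$eta %||% 0.02,
    loss_threshold_T = kc$loss_threshold_T %||% 3,
    sigma_factor = kc$sigma_factor %||% 0.1,
    bs = bs,
    bs_enabled = kc$bs_enabled %||% TRUE)
}

#' Read the two-camera rig from YAML
#'
#' Expects top-level `top:` and `side:` blocks, each with `f_px`, `cu`,
#' `cv`, `standoff_mm` and optionally `width_px`/`height_px`; the block name
#' fixes the viewing axis.
#'
#' @param path YAML file path.
#' @return list with `top` and `side` [camera_model()]s.
#' @export
read_cameras <- function(path) {
  y <- yaml::read_yaml(path)
  mk <- function(b, axis) camera_model(
    f_px = b$f_px, cu = b$cu, cv = b$cv, axis = axis,
    standoff_mm = b$standoff_mm,
    width_px = b$width_px, height_px = b$height_px)
  if (is.null(y$top) || is.null(y$side))
    stop("camera YAML needs 'top:' and 'side:' blocks")
  list(top = mk(y$top, "top"), side = mk(y$side, "side"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
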