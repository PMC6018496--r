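#' Frame sequence container
#'
#' An ordered sequence of grayscale frames plus frame-rate metadata. Frames
#' are stored as numeric matrices indexed `[row, col]` with intensities on the
#' unit interval `[0, 1]`; the `range` attribute records that convention.
#' Pixel coordinates everywhere in this package are `(u, v) = (column, row)`,
#' 0-based, origin at the image top-left.
#'
#' @param frames list of 2-D numeric matrices, all of identical dimensions.
#' @param fps frames per second (default 60, the acquisition rate the two
#'   wind-tunnel cameras are triggered at).
#' @param range intensity convention of the stored values; only `"unit"`
#'   (values in `[0, 1]`) is produced by this package's readers.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps = 60, range = "unit") {
  if (!is.list(frames) || length(frames) == 0L)
    stop("'frames' must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share identical height x width")
  if (!is.numeric(fps) || fps <= 0) stop("'fps' must be > 0")
  structure(
    list(frames = frames, fps = fps, frame_index_origin = 0L, range = range),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames, %d x %d px, %g fps, range %s\n",
              length(x$frames), d[1], d[2], x$fps, x$range))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

# extensions handled by the image-sequence reader
.frame_exts <- c("png", "pgm", "tif", "tiff")

#' Read a grayscale frame sequence from disk
#'
#' Reads a directory (or glob) of numbered still images (PNG, PGM, TIFF) in
#' natural numeric order. Colour images are converted to gray with the
#' BT.601 luma weights (0.299 R + 0.587 G + 0.114 B). Video containers
#' (AVI/MP4) cannot be decoded here; decode them to an image sequence first.
#'
#' @param path directory containing the images, or a glob pattern.
#' @param fps frame rate to record on the sequence (metadata only).
#' @return a [frame_sequence()].
#' @export
read_frames <- function(path, fps = 60) {
  if (length(path) != 1L || !is.character(path)) stop("'path' must be a single path")
  if (grepl("\\.(avi|mp4|mov|mkv)$", tolower(path)))
    stop("video containers are not decodable here; export '", basename(path),
         "' to a numbered PNG/PGM/TIFF image sequence first")
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
  } else {
    files <- Sys.glob(path)
    if (length(files) == 0L && !file.exists(path))
      stop("path not found: ", path)
  }
  ext <- tolower(tools::file_ext(files))
  files <- files[ext %in% .frame_exts]
  if (length(files) == 0L)
    stop("no decodable frames (PNG/PGM/TIFF) under: ", path)
  files <- files[natural_order(basename(files))]
  frames <- lapply(files, read_frame_file)
  frame_sequence(frames, fps = fps)
}

# order filenames by their first embedded integer, falling back to lexicographic
natural_order <- function(names) {
  num <- suppressWarnings(as.numeric(sub(".*?(\\d+)\\D*$", "\\1", names)))
  if (anyNA(num)) order(names) else order(num, names)
}

read_frame_file <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- switch(ext,
    png = png::readPNG(f),
    pgm = read_pgm(f),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(f)
    },
    stop("unsupported frame format: ", ext)
  )
  to_gray(img)
}

# collapse an H x W x C array to grayscale; drop alpha, luma-weight RGB
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc >= 3L)
      return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    return(img[, , 1])
  }
  stop("unrecognised image array layout")
}

#' Write a frame sequence as numbered images
#'
#' Frames are quantized to 8-bit before writing, so a write/read round trip
#' is bit-exact for data that is already 8-bit quantized.
#'
#' @param fs a [frame_sequence()].
#' @param dir output directory (created if missing).
#' @param format `"png"` or `"pgm"`.
#' @param prefix filename prefix; files are named `<prefix>_%05d.<ext>`.
#' @return invisibly, the written file paths.
#' @export
write_frames <- function(fs, dir, format = c("png", "pgm"), prefix = "frame") {
  format <- match.arg(format)
  stopifnot(inherits(fs, "frame_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(fs$frames))
  for (i in seq_along(fs$frames)) {
    m <- quantize8(fs$frames[[i]])
    p <- file.path(dir, sprintf("%s_%05d.%s", prefix, i - 1L, format))
    if (format == "png") png::writePNG(m, p) else write_pgm(m, p)
    paths[i] <- p
  }
  invisible(paths)
}

quantize8 <- function(m) round(pmin(pmax(m, 0), 1) * 255) / 255

#' Read / write plain PGM (P2) grayscale images
#'
#' Minimal ASCII PGM support for small text-only fixtures. Values are scaled
#' to `[0, 1]` on read using the header's maxval.
#'
#' @param path file path.
#' @return `read_pgm`: a numeric matrix in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("only ASCII PGM (P2) is supported")
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); mx <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) stop("PGM pixel count mismatch")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / mx
}

#' @rdname read_pgm
#' @param m numeric matrix in `[0, 1]`.
#' @export
write_pgm <- function(m, path) {
  v <- round(pmin(pmax(m, 0), 1) * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
  apply(v, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' Write / read trajectory tables
#'
#' 2-D trajectories are data frames with columns `frame, u, v, status`
#' (status one of tracked/redetected/lost/init); 3-D trajectories add
#' `x_mm, y_mm, z_mm`. Floats are written with 4 decimal places.
#'
#' @param records a trajectory data frame.
#' @param path output CSV path.
#' @export
write_trajectory <- function(records, path) {
  stopifnot(is.data.frame(records), "frame" %in% names(records))
  out <- records
  for (nm in names(out))
    if (is.numeric(out[[nm]]) && nm != "frame")
      out[[nm]] <- sprintf("%.4f", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory`: the trajectory data frame.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(names(df), c("u", "v", "x_mm", "y_mm", "z_mm")))
    df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  df
}
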