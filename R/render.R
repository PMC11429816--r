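#' Construct an image stack
#'
#' An `image_stack` is the in-memory form of a time-lapse video: an ordered
#' list of numeric matrices (rows = y, columns = x, unit intensity scale)
#' plus the physical calibration needed to interpret it.
#'
#' @param frames List of numeric matrices with identical dimensions.
#' @param resolution um/px (> 0).
#' @param frame_interval min/frame (> 0).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, resolution, frame_interval) {
  if (length(frames)) {
    d <- dim(frames[[1]])
    ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d), TRUE)
    if (!all(ok)) stop("image_stack: all frames must share dimensions", call. = FALSE)
  }
  if (resolution <= 0 || frame_interval <= 0)
    stop("image_stack: calibration must be positive", call. = FALSE)
  structure(list(frames = frames, resolution = resolution,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- if (length(x$frames)) dim(x$frames[[1]]) else c(0L, 0L)
  cat(sprintf("<image_stack> %d frames of %d x %d px, %.3g um/px, %.3g min/frame\n",
              length(x$frames), d[2], d[1], x$resolution, x$frame_interval))
  invisible(x)
}

#' Render ground-truth trajectories as a synthetic time-lapse stack
#'
#' Each frame starts at `background_level`; every cell present in that frame
#' is drawn as a filled disk of its radius (converted to pixels through the
#' scene resolution) at intensity `cell_intensity`; the frame is then blurred
#' with a 1-px Gaussian (a crude point-spread-function stand-in), corrupted
#' with zero-mean Gaussian noise of sd `noise_sigma`, and clipped to
#' `[0, 1]`. With `scene$invert`, background and cell intensities are
#' swapped, giving dark cells on a bright background.
#'
#' Coordinates follow the package-wide convention: x = column, y = row,
#' 0-based, pixel centers at integer coordinates; physical position
#' `x_um = x_px * resolution`.
#'
#' @param truth A `ground_truth` data frame from [simulate_tracks()].
#' @param scene A [scene_config()]; must match the truth's calibration.
#' @param seed Seed for the pixel noise (per-frame substreams).
#' @return An [image_stack()].
#' @export
render_frames <- function(truth, scene, seed = 1L) {
  stopifnot(inherits(scene, "scene_config"))
  r_px_min <- min(scene$cell_radius_range) / scene$resolution
  if (nrow(truth) && min(truth$radius_um) / scene$resolution < 1)
    stop("render_frames: cell radius below 1 px at this resolution", call. = FALSE)
  w <- scene$width_px; h <- scene$height_px
  bg <- if (scene$invert) scene$cell_intensity else scene$background_level
  fg <- if (scene$invert) scene$background_level else scene$cell_intensity
  xs <- matrix(rep(0:(w - 1L), each = h), h, w)
  ys <- matrix(rep(0:(h - 1L), w), h, w)
  by_frame <- if (nrow(truth)) split(truth, truth$frame) else list()
  frames <- vector("list", scene$n_frames)
  for (f in seq_len(scene$n_frames)) {
    img <- matrix(bg, h, w)
    cells <- by_frame[[as.character(f - 1L)]]
    if (!is.null(cells) && nrow(cells)) {
      for (i in seq_len(nrow(cells))) {
        cx <- cells$x_um[i] / scene$resolution
        cy <- cells$y_um[i] / scene$resolution
        r <- cells$radius_um[i] / scene$resolution
        win_x <- max(0, floor(cx - r - 1)):min(w - 1, ceiling(cx + r + 1))
        win_y <- max(0, floor(cy - r - 1)):min(h - 1, ceiling(cy + r + 1))
        sub_d2 <- outer((win_y - cy)^2, (win_x - cx)^2, "+")
        sel <- sub_d2 <= r^2
        img[win_y + 1L, win_x + 1L][sel] <- fg
      }
    }
    img <- EBImage::gblur(img, sigma = 1, radius = 7, boundary = "replicate")
    if (scene$noise_sigma > 0) {
      set.seed(derive_seed(seed, 500000L, f - 1L))
      img <- img + matrix(stats::rnorm(h * w, 0, scene$noise_sigma), h, w)
    }
    frames[[f]] <- pmin(pmax(img, 0), 1)
  }
  image_stack(frames, scene$resolution, scene$frame_interval)
}

#' Write / read a multi-page TIFF with a JSON calibration sidecar
#'
#' Frames are written as one multi-page grayscale TIFF (bit depth from
#' `bit_depth`), and the physical calibration (resolution, frame interval)
#' plus an optional seed go to `<path>.json` so a stack can be re-read
#' without external bookkeeping.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @param bit_depth 8 or 16.
#' @param seed Optional seed to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, bit_depth = 8L, seed = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  tiff::writeTIFF(stack$frames, path, bits.per.sample = as.integer(bit_depth))
  side <- list(resolution_um_px = stack$resolution,
               frame_interval_min = stack$frame_interval,
               n_frames = length(stack$frames),
               bit_depth = as.integer(bit_depth))
  if (!is.null(seed)) side$seed <- as.integer(seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_image_stack
#' @param resolution,frame_interval Calibration overrides; by default read
#'   from the sidecar (an error if neither is available).
#' @export
read_image_stack <- function(path, resolution = NULL, frame_interval = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar)
    if (is.null(resolution)) resolution <- side$resolution_um_px
    if (is.null(frame_interval)) frame_interval <- side$frame_interval_min
  }
  if (is.null(resolution) || is.null(frame_interval))
    stop("read_image_stack: no calibration sidecar found; pass 'resolution' ",
         "and 'frame_interval'", call. = FALSE)
  image_stack(frames, resolution, frame_interval)
}
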