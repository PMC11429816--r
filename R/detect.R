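#' Detection parameters for the circle Hough transform
#'
#' @param rel_threshold Accumulator peaks are kept if their
#'   perimeter-normalized vote count is at least this fraction of the global
#'   accumulator maximum (across all radii). Relative thresholding makes
#'   detection invariant to rescaling the image intensities.
#' @param edge_method `"otsu"` (default) thresholds the Sobel gradient
#'   magnitude with Otsu's method; `"fraction"` uses
#'   `edge_fraction * max(gradient)`.
#' @param edge_fraction Fraction for `edge_method = "fraction"`.
#' @param min_sep_px Minimum center separation enforced by non-maximum
#'   suppression; `NULL` (default) uses the minimum search radius in px.
#' @param polarity `"both"` votes on both sides of each edge (works for
#'   bright-on-dark and dark-on-bright); `"bright"`/`"dark"` vote only toward
#'   the brighter/darker side and halve the work.
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(rel_threshold = 0.5,
                          edge_method = c("otsu", "fraction"),
                          edge_fraction = 0.2,
                          min_sep_px = NULL,
                          polarity = c("both", "bright", "dark")) {
  structure(list(rel_threshold = rel_threshold,
                 edge_method = match.arg(edge_method),
                 edge_fraction = edge_fraction,
                 min_sep_px = min_sep_px,
                 polarity = match.arg(polarity)),
            class = "detect_params")
}

# Sobel gradient of a matrix (rows = y, cols = x); returns list(gx, gy, mag).
.sobel <- function(img) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dx (columns)
  ky <- t(kx)                                               # d/dy (rows)
  gx <- EBImage::filter2(img, kx, boundary = "replicate")
  gy <- EBImage::filter2(img, ky, boundary = "replicate")
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Detect cells in one frame with a circle Hough transform
#'
#' Edge pixels (Sobel gradient magnitude above an Otsu-derived threshold)
#' vote for candidate circle centers at every integer radius between
#' `round(r_min / resolution)` and `round(r_max / resolution)` pixels, along
#' the local gradient direction. Each radius accumulator is smoothed with a
#' 3x3 box (to pool sub-pixel vote scatter) and normalized by the circle
#' perimeter `2 * pi * r`, so scores are comparable across radii (a perfect,
#' fully voting circle scores around 9 under the box pooling, regardless of
#' radius). Peaks at or above `rel_threshold` times the global maximum are
#' kept, then greedy non-maximum suppression enforces a minimum center
#' separation; the surviving peak centers are refined to sub-pixel accuracy
#' by a local vote centroid.
#'
#' A constant frame has no edges and yields an empty detection table — not
#' an error.
#'
#' @param frame Numeric matrix (rows = y, columns = x).
#' @param resolution um/px.
#' @param r_min,r_max Physical radius search range in um (default 5--8).
#' @param params A [detect_params()].
#' @return A data frame `x_px, y_px, radius_px, score` sorted by descending
#'   score (0-based pixel coordinates, pixel centers at integers).
#' @examples
#' sc <- scene_config(n_frames = 1, noise_sigma = 0)
#' gt <- simulate_tracks(motion_model("stationary"), 1, sc)
#' st <- render_frames(gt, sc)
#' detect_cells(st$frames[[1]], sc$resolution)
#' @export
detect_cells <- function(frame, resolution, r_min = 5, r_max = 8,
                         params = detect_params()) {
  if (r_min > r_max) stop("detect_cells: r_min must be <= r_max", call. = FALSE)
  radii <- seq.int(round(r_min / resolution), round(r_max / resolution))
  if (max(radii) < 1)
    stop("detect_cells: radius search range collapses below 1 px", call. = FALSE)
  empty <- data.frame(x_px = numeric(), y_px = numeric(),
                      radius_px = numeric(), score = numeric())
  h <- nrow(frame); w <- ncol(frame)
  rng <- diff(range(frame))
  if (rng <= 1e-12 * max(abs(frame))) return(empty)   # flat up to rounding
  g <- .sobel(frame)
  gmax <- max(g$mag)
  if (gmax <= 1e-9 * rng) return(empty)    # numerically flat frame
  thr <- if (params$edge_method == "otsu") {
    gmax * EBImage::otsu(g$mag / gmax, range = c(0, 1))
  } else gmax * params$edge_fraction
  idx <- which(g$mag > thr)
  if (!length(idx)) return(empty)
  ex <- (idx - 1L) %/% h          # 0-based column
  ey <- (idx - 1L) %% h           # 0-based row
  ux <- g$gx[idx] / g$mag[idx]
  uy <- g$gy[idx] / g$mag[idx]
  signs <- switch(params$polarity, both = c(1, -1), bright = 1, dark = -1)

  acc <- vector("list", length(radii))
  for (ri in seq_along(radii)) {
    r <- radii[ri]
    votes <- numeric(h * w)
    for (sgn in signs) {
      cx <- round(ex + sgn * r * ux)
      cy <- round(ey + sgn * r * uy)
      ok <- cx >= 0 & cx < w & cy >= 0 & cy < h
      if (any(ok)) {
        lin <- cy[ok] + 1L + cx[ok] * h
        votes <- votes + tabulate(lin, nbins = h * w)
      }
    }
    a <- matrix(votes, h, w)
    # 3x3 box pooling, then perimeter normalization
    a <- a + rbind(0, a[-h, , drop = FALSE]) + rbind(a[-1, , drop = FALSE], 0)
    a <- a + cbind(0, a[, -w, drop = FALSE]) + cbind(a[, -1, drop = FALSE], 0)
    acc[[ri]] <- a / (2 * pi * r)
  }
  amax <- max(vapply(acc, max, 0))
  if (amax <= 0) return(empty)
  cand <- do.call(rbind, lapply(seq_along(radii), function(ri) {
    hit <- which(acc[[ri]] >= params$rel_threshold * amax)
    if (!length(hit)) return(NULL)
    cbind(x = (hit - 1L) %/% h, y = (hit - 1L) %% h, ri = ri,
          score = acc[[ri]][hit])
  }))
  if (is.null(cand)) return(empty)
  # Deterministic order: descending score, then (y, x, r)
  o <- order(-cand[, "score"], cand[, "y"], cand[, "x"], cand[, "ri"])
  cand <- cand[o, , drop = FALSE]
  min_sep <- if (is.null(params$min_sep_px)) min(radii) else params$min_sep_px
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(keep) ||
        all((cand[keep, "x"] - cand[i, "x"])^2 +
            (cand[keep, "y"] - cand[i, "y"])^2 >= min_sep^2))
      keep <- c(keep, i)
  }
  cand <- cand[keep, , drop = FALSE]
  ref <- t(apply(cand, 1, function(p) {
    .refine_center(acc[[p[["ri"]]]], p[["x"]], p[["y"]], w, h)
  }))
  data.frame(x_px = ref[, 1], y_px = ref[, 2],
             radius_px = radii[cand[, "ri"]],
             score = cand[, "score"], row.names = NULL)
}

# Sub-pixel refinement: centroid of the accumulator over a 3x3 neighborhood.
.refine_center <- function(a, x, y, w, h) {
  xs <- max(0, x - 1):min(w - 1, x + 1)
  ys <- max(0, y - 1):min(h - 1, y + 1)
  wgt <- a[ys + 1L, xs + 1L, drop = FALSE]
  s <- sum(wgt)
  if (s <= 0) return(c(x, y))
  c(sum(outer(rep(1, length(ys)), xs) * wgt) / s,
    sum(outer(ys, rep(1, length(xs))) * wgt) / s)
}

#' Detect cells in every frame of a stack
#'
#' Applies [detect_cells()] frame by frame, preserving frame order, and
#' reports per-frame detection counts through `message()` when `verbose`.
#'
#' @param stack An [image_stack()].
#' @param r_min,r_max Radius search range in um.
#' @param params A [detect_params()].
#' @param verbose Log per-frame counts.
#' @return A data frame `frame` (0-based), `x_px`, `y_px`, `radius_px`,
#'   `score`, with the stack calibration as attributes.
#' @export
detect_stack <- function(stack, r_min = 5, r_max = 8,
                         params = detect_params(), verbose = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  out <- vector("list", length(stack$frames))
  for (f in seq_along(stack$frames)) {
    det <- tryCatch(
      detect_cells(stack$frames[[f]], stack$resolution, r_min, r_max, params),
      error = function(e) stop("detect_stack: frame ", f - 1L, ": ",
                               conditionMessage(e), call. = FALSE))
    if (verbose) message("frame ", f - 1L, ": ", nrow(det), " detections")
    if (nrow(det)) out[[f]] <- cbind(frame = f - 1L, det)
  }
  dets <- if (any(!vapply(out, is.null, TRUE))) do.call(rbind, out) else
    data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
               radius_px = numeric(), score = numeric())
  rownames(dets) <- NULL
  attr(dets, "resolution") <- stack$resolution
  attr(dets, "frame_interval") <- stack$frame_interval
  dets
}

#' Write / read a detections CSV
#'
#' Dialect: header `frame,x_px,y_px,radius_px,score`.
#' @param dets Detections data frame from [detect_stack()].
#' @param path File path.
#' @export
write_detections <- function(dets, path) {
  utils::write.csv(as.data.frame(dets)[, c("frame", "x_px", "y_px",
                                           "radius_px", "score")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame", "x_px", "y_px", "radius_px", "score")
  if (!all(need %in% names(d)))
    stop("read_detections: missing columns ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  d
}
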