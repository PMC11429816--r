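#' Simulate ground-truth cell trajectories
#'
#' Draws one trajectory per cell under the given motion model, sampled at the
#' scene's frame interval for `scene$n_frames` frames. Positions are in
#' physical units (um) with the origin at the center of pixel (0, 0). Cells
#' start uniformly inside the scene (outside the scratch band, if one is
#' configured, and at least one cell radius from the edges) and reflect off
#' the scene boundary, so no track ever leaves the field of view.
#'
#' @param model A [motion_model()].
#' @param n_cells Number of cells (>= 0).
#' @param scene A [scene_config()].
#' @param seed Master seed; defaults to `model$seed`. Each cell consumes an
#'   independent substream derived from it (see the package configuration
#'   reference in the vignette).
#'
#' @return A `ground_truth` data frame with columns
#'   `cell_id` (integer, 0-based), `frame` (integer, 0-based), `x_um`,
#'   `y_um`, `radius_um`, carrying the scene's `resolution` and
#'   `frame_interval` as attributes.
#' @examples
#' sc <- scene_config(n_frames = 20)
#' gt <- simulate_tracks(motion_model("brownian", diffusion_coefficient = 1), 3, sc)
#' head(gt)
#' @export
simulate_tracks <- function(model, n_cells, scene, seed = model$seed) {
  stopifnot(inherits(model, "motion_model"), inherits(scene, "scene_config"))
  if (n_cells < 0) stop("simulate_tracks: n_cells must be >= 0", call. = FALSE)
  n_frames <- scene$n_frames
  w_um <- scene$width_px * scene$resolution
  h_um <- scene$height_px * scene$resolution
  dt <- scene$frame_interval
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    set.seed(derive_seed(seed, 0L, i - 1L))
    r_cell <- stats::runif(1, scene$cell_radius_range[1], scene$cell_radius_range[2])
    start <- .draw_start(scene, r_cell, w_um, h_um)
    pos <- .propagate(model, start, n_frames, dt)
    pos[, 1] <- .reflect(pos[, 1], r_cell, w_um - r_cell)
    pos[, 2] <- .reflect(pos[, 2], r_cell, h_um - r_cell)
    out[[i]] <- data.frame(cell_id = i - 1L,
                           frame = seq_len(n_frames) - 1L,
                           x_um = pos[, 1], y_um = pos[, 2],
                           radius_um = r_cell)
  }
  gt <- if (n_cells > 0) do.call(rbind, out) else
    data.frame(cell_id = integer(), frame = integer(),
               x_um = numeric(), y_um = numeric(), radius_um = numeric())
  rownames(gt) <- NULL
  attr(gt, "resolution") <- scene$resolution
  attr(gt, "frame_interval") <- scene$frame_interval
  class(gt) <- c("ground_truth", "data.frame")
  gt
}

.draw_start <- function(scene, r_cell, w_um, h_um) {
  for (try in 1:200) {
    x <- stats::runif(1, r_cell, w_um - r_cell)
    y <- stats::runif(1, r_cell, h_um - r_cell)
    band <- scene$scratch_band
    if (is.null(band) || x < band[1] || x > band[2]) return(c(x, y))
  }
  stop("simulate_tracks: could not place a cell outside the scratch band",
       call. = FALSE)
}

# Trajectory of n positions (matrix n x 2) starting at `start`, one row per
# frame, under the model's law; randomness comes from the current RNG stream.
.propagate <- function(model, start, n, dt) {
  if (n == 0L) return(matrix(numeric(), 0, 2))
  switch(model$kind,
    stationary = matrix(rep(start, each = n), n, 2),
    brownian = {
      sd_step <- sqrt(2 * model$diffusion_coefficient * dt)
      dx <- c(0, stats::rnorm(n - 1, 0, sd_step))
      dy <- c(0, stats::rnorm(n - 1, 0, sd_step))
      cbind(start[1] + cumsum(dx), start[2] + cumsum(dy))
    },
    persistent = {
      theta0 <- stats::runif(1, -pi, pi)
      dtheta <- stats::rnorm(n - 1, 0, sqrt(2 * dt / model$persistence_time))
      theta <- theta0 + c(0, cumsum(dtheta))
      step <- model$mean_speed * dt
      cbind(start[1] + cumsum(c(0, step * cos(theta[-n]))),
            start[2] + cumsum(c(0, step * sin(theta[-n]))))
    },
    circular = {
      phi0 <- stats::runif(1, -pi, pi)
      phi <- phi0 + model$angular_speed * dt * (seq_len(n) - 1)
      center <- start - model$radius * c(cos(phi0), sin(phi0))
      cbind(center[1] + model$radius * cos(phi),
            center[2] + model$radius * sin(phi))
    })
}

# Reflect a coordinate vector into [lo, hi] (billiard reflection, exact for
# arbitrarily large excursions via the standard fold of period 2*(hi-lo)).
.reflect <- function(z, lo, hi) {
  if (hi <= lo) return(pmin(pmax(z, lo), hi))
  span <- hi - lo
  z <- (z - lo) %% (2 * span)
  lo + ifelse(z > span, 2 * span - z, z)
}

#' Simulate a labeled two-group dataset
#'
#' Generates ground truth for a control-like group (model A) and a
#' treated-like group (model B), each with its own substream derived from one
#' master seed, and optionally renders both image stacks. This emulates
#' acquiring separate videos for two experimental conditions.
#'
#' @param model_a,model_b [motion_model()]s for the two groups.
#' @param n_cells Cells per group.
#' @param scene A [scene_config()] shared by both groups.
#' @param seed Master seed.
#' @param render If `TRUE` (default) also render the two image stacks.
#'
#' @return A list with `truth_a`, `truth_b` (`ground_truth` data frames) and,
#'   when `render = TRUE`, `stack_a`, `stack_b` ([image_stack()]s).
#' @export
make_two_group_dataset <- function(model_a, model_b, n_cells, scene,
                                   seed = 1L, render = TRUE) {
  seed_a <- derive_seed(seed, 900000L)
  seed_b <- derive_seed(seed, 910000L)
  truth_a <- simulate_tracks(model_a, n_cells, scene, seed = seed_a)
  truth_b <- simulate_tracks(model_b, n_cells, scene, seed = seed_b)
  out <- list(truth_a = truth_a, truth_b = truth_b)
  if (render) {
    out$stack_a <- render_frames(truth_a, scene, seed = seed_a)
    out$stack_b <- render_frames(truth_b, scene, seed = seed_b)
  }
  out
}

#' Convert ground truth to track tables
#'
#' Re-expresses simulated ground truth in the same `tracks` form that
#' [build_tracks()] produces from detections, so the kinematic stages can be
#' run directly on noiseless trajectories (bypassing imaging).
#'
#' @param truth A `ground_truth` data frame from [simulate_tracks()].
#' @return A `tracks` data frame (`track_id`, `frame`, `t_min`, `x_um`,
#'   `y_um`).
#' @export
truth_to_tracks <- function(truth) {
  dt <- attr(truth, "frame_interval")
  tr <- data.frame(track_id = truth$cell_id,
                   frame = truth$frame,
                   t_min = truth$frame * dt,
                   x_um = truth$x_um, y_um = truth$y_um)
  attr(tr, "frame_interval") <- dt
  attr(tr, "resolution") <- attr(truth, "resolution")
  class(tr) <- c("tracks", "data.frame")
  tr
}

#' Write / read ground-truth CSV
#'
#' Plain CSV with header `cell_id,frame,x_um,y_um,radius_um`.
#'
#' @param truth A `ground_truth` data frame.
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(as.data.frame(truth)[, c("cell_id", "frame", "x_um", "y_um",
                                            "radius_um")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @param resolution,frame_interval Calibration to attach on read.
#' @export
read_ground_truth <- function(path, resolution = NA_real_,
                              frame_interval = NA_real_) {
  gt <- utils::read.csv(path)
  need <- c("cell_id", "frame", "x_um", "y_um", "radius_um")
  if (!all(need %in% names(gt)))
    stop("read_ground_truth: missing columns ",
         paste(setdiff(need, names(gt)), collapse = ", "), call. = FALSE)
  attr(gt, "resolution") <- resolution
  attr(gt, "frame_interval") <- frame_interval
  class(gt) <- c("ground_truth", "data.frame")
  gt
}
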