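#' Define a cell motility model
#'
#' A motion model specifies the stochastic law that a simulated cell's
#' trajectory follows. Four laws are available:
#'
#' * `"brownian"` — isotropic diffusion; per-axis increments over an interval
#'   \eqn{\Delta t} are independent Gaussians with variance
#'   \eqn{2 D \Delta t}, so the two-dimensional mean squared displacement
#'   grows as \eqn{4 D \tau}.
#' * `"persistent"` — a persistent random walk: constant speed with a heading
#'   that diffuses, decorrelating over the persistence time
#'   \eqn{P} (heading increments have variance \eqn{2\Delta t / P}).
#' * `"circular"` — deterministic motion on a circle of the given radius at
#'   constant angular speed; only the starting phase is random.
#' * `"stationary"` — the cell does not move.
#'
#' @param kind One of `"brownian"`, `"persistent"`, `"circular"`,
#'   `"stationary"`.
#' @param diffusion_coefficient Diffusion coefficient D in um^2/min
#'   (brownian).
#' @param mean_speed Speed in um/min (persistent).
#' @param persistence_time Heading decorrelation time in min (persistent).
#' @param radius Circle radius in um (circular).
#' @param angular_speed Angular speed in rad/min (circular).
#' @param seed Integer seed; identical `(kind, parameters, seed)` yield
#'   bit-identical trajectories.
#'
#' @return An object of class `motion_model`.
#' @examples
#' motion_model("brownian", diffusion_coefficient = 1, seed = 1)
#' motion_model("circular", radius = 10, angular_speed = 0.1, seed = 2)
#' @export
motion_model <- function(kind = c("brownian", "persistent", "circular", "stationary"),
                         diffusion_coefficient = NULL,
                         mean_speed = NULL,
                         persistence_time = NULL,
                         radius = NULL,
                         angular_speed = NULL,
                         seed = 1L) {
  kind <- match.arg(kind)
  chk <- function(value, field, positive = FALSE) {
    if (is.null(value) || !is.numeric(value) || length(value) != 1L || !is.finite(value))
      stop("motion_model: field '", field, "' must be a finite number for kind '",
           kind, "'", call. = FALSE)
    if (positive && value <= 0)
      stop("motion_model: field '", field, "' must be > 0", call. = FALSE)
    if (!positive && value < 0)
      stop("motion_model: field '", field, "' must be >= 0", call. = FALSE)
    value
  }
  m <- list(kind = kind, seed = as.integer(seed))
  if (kind == "brownian") {
    m$diffusion_coefficient <- chk(diffusion_coefficient, "diffusion_coefficient")
  } else if (kind == "persistent") {
    m$mean_speed <- chk(mean_speed, "mean_speed")
    m$persistence_time <- chk(persistence_time, "persistence_time", positive = TRUE)
  } else if (kind == "circular") {
    m$radius <- chk(radius, "radius", positive = TRUE)
    m$angular_speed <- chk(angular_speed, "angular_speed")
  }
  structure(m, class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  pars <- x[setdiff(names(x), c("kind", "seed"))]
  cat("<motion_model> ", x$kind,
      if (length(pars)) paste0(" (", paste(names(pars), unlist(pars),
                                           sep = " = ", collapse = ", "), ")"),
      "  seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Describe the synthetic imaging scene
#'
#' Holds the geometry, physical calibration and rendering parameters of a
#' synthetic time-lapse acquisition. The defaults mirror a small-scale
#' inverted-microscope setup: 0.66 um/px, one frame per minute, cells of
#' radius 5--8 um rendered as bright disks on a dark background.
#'
#' Intensities live on a unit scale: `background_level` and `cell_intensity`
#' are in `[0, 1]` and frames are clipped to that range after noise is added
#' (matching 8- or 16-bit export, selected via `bit_depth`).
#'
#' @param width_px,height_px Frame size in pixels.
#' @param resolution Spatial calibration in um/px (> 0).
#' @param frame_interval Time between frames in min (> 0).
#' @param n_frames Number of frames.
#' @param cell_radius_range Length-2 numeric, cell radius bounds in um
#'   (min <= max); each simulated cell draws its radius uniformly from this
#'   interval.
#' @param noise_sigma Standard deviation of the additive zero-mean Gaussian
#'   pixel noise (intensity units).
#' @param background_level,cell_intensity Background and in-cell plateau
#'   intensity (unit scale).
#' @param invert If `TRUE`, render dark cells on a bright background.
#' @param scratch_band Optional `c(x_min_um, x_max_um)`: a vertical band kept
#'   cell-free at t = 0, emulating a scratch-wound gap.
#' @param bit_depth 8 or 16; used when exporting TIFF.
#'
#' @return An object of class `scene_config`.
#' @examples
#' scene_config(n_frames = 60)
#' @export
scene_config <- function(width_px = 256L, height_px = 256L,
                         resolution = 0.66, frame_interval = 1,
                         n_frames = 120L,
                         cell_radius_range = c(5, 8),
                         noise_sigma = 0.04,
                         background_level = 0.1, cell_intensity = 0.9,
                         invert = FALSE,
                         scratch_band = NULL,
                         bit_depth = 8L) {
  if (!is.numeric(resolution) || resolution <= 0)
    stop("scene_config: 'resolution' must be > 0", call. = FALSE)
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("scene_config: 'frame_interval' must be > 0", call. = FALSE)
  if (length(cell_radius_range) != 2L || diff(cell_radius_range) < 0)
    stop("scene_config: 'cell_radius_range' must be c(min, max) with min <= max",
         call. = FALSE)
  if (width_px < 1 || height_px < 1 || n_frames < 0)
    stop("scene_config: frame geometry must be positive", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L))
    stop("scene_config: 'bit_depth' must be 8 or 16", call. = FALSE)
  if (!is.null(scratch_band) &&
      (length(scratch_band) != 2L || diff(scratch_band) < 0))
    stop("scene_config: 'scratch_band' must be c(x_min_um, x_max_um)", call. = FALSE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 resolution = resolution, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 cell_radius_range = as.numeric(cell_radius_range),
                 noise_sigma = noise_sigma,
                 background_level = background_level,
                 cell_intensity = cell_intensity,
                 invert = isTRUE(invert),
                 scratch_band = scratch_band,
                 bit_depth = as.integer(bit_depth)),
            class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("<scene_config> %d x %d px, %d frames, %.3g um/px, %.3g min/frame\n",
              x$width_px, x$height_px, x$n_frames, x$resolution, x$frame_interval))
  invisible(x)
}

#' Derive a reproducible random-number substream seed
#'
#' Every consumer of randomness in the synthetic-data generator seeds its own
#' stream as `(master * 1009 + offset + counter) mod (2^31 - 1)`, so whole
#' runs are reproducible from one master seed and streams do not collide by
#' construction within a run. Offsets used by the package: 0 = per-cell
#' trajectories (counter = cell index), 500000 = frame noise (counter = frame
#' index), 900000 / 910000 = the two groups of a paired dataset.
#'
#' @param master Master seed (integer).
#' @param offset Stream family offset.
#' @param counter Index within the family.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(master, offset, counter = 0L) {
  as.integer((as.numeric(master) * 1009 + offset + counter) %% 2147483647)
}
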