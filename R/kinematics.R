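#' Smooth one trajectory with cubic smoothing splines
#'
#' Fits independent cubic smoothing splines to `x(t)` and `y(t)` and
#' evaluates positions and first/second derivatives at the original sample
#' times. Smoothing mitigates pixel-quantization and localization error,
#' which otherwise dominates derivative-based descriptors (curvature most of
#' all).
#'
#' One smoothing parameter is shared by the two axes so that the operation
#' commutes with rotations of the coordinate frame (per-axis parameter
#' selection does not). It is chosen by:
#'
#' * `smoothing = "gcv"` (default): minimize the sum of the two axes'
#'   generalized cross-validation scores over `spar`;
#' * `smoothing = "localization"`: discrepancy principle — the lightest
#'   smoothing whose root-mean-square residual reaches `sigma_loc`, the
#'   assumed localization noise scale (for pure pixel quantization,
#'   `resolution / sqrt(12)`, about 0.19 um at 0.66 um/px);
#' * a number: a fixed `spar` passed to [stats::smooth.spline()].
#'
#' Splines are fitted with `all.knots = TRUE`; the default knot subset
#' imposes a resolution floor that distorts fine-scale motion.
#'
#' @param track A `tracks` data frame restricted to one `track_id`, or any
#'   data frame with columns `t_min`, `x_um`, `y_um`.
#' @param smoothing `"gcv"`, `"localization"`, or a numeric `spar`.
#' @param sigma_loc Localization noise scale in um (for
#'   `smoothing = "localization"`).
#' @return An object of class `smoothed_track`: list with `track_id`, `t`
#'   (min), raw positions `x_raw`, `y_raw`, smoothed positions `x`, `y`,
#'   derivatives `dx`, `dy` (um/min), `ddx`, `ddy` (um/min^2), and the
#'   selected `spar`. `NULL` (with a warning) for tracks with fewer than 4
#'   samples.
#' @examples
#' tr <- data.frame(t_min = 0:19, x_um = (0:19) * 2, y_um = 0)
#' st <- smooth_track(tr)
#' range(st$dx)  # ~2 um/min everywhere
#' @export
smooth_track <- function(track, smoothing = "gcv", sigma_loc = 0.2) {
  ids <- unique(track$track_id)
  if (length(ids) > 1L)
    stop("smooth_track: one track at a time (got ", length(ids),
         " ids); see smooth_tracks()", call. = FALSE)
  t <- track$t_min
  if (anyDuplicated(t)) stop("smooth_track: repeated time stamps", call. = FALSE)
  o <- order(t)
  t <- t[o]; x <- track$x_um[o]; y <- track$y_um[o]
  n <- length(t)
  if (n < 4L) {
    warning("smooth_track: track ", if (length(ids)) ids else "?",
            " has fewer than 4 samples; skipped", call. = FALSE)
    return(NULL)
  }
  spar <- .select_spar(t, x, y, smoothing, sigma_loc)
  fit <- function(z) stats::smooth.spline(t, z, spar = spar, all.knots = TRUE,
                                          keep.data = FALSE)
  fx <- fit(x); fy <- fit(y)
  structure(list(track_id = if (length(ids)) ids else NA_integer_,
                 t = t, x_raw = x, y_raw = y,
                 x = stats::predict(fx, t)$y,
                 y = stats::predict(fy, t)$y,
                 dx = stats::predict(fx, t, deriv = 1)$y,
                 dy = stats::predict(fy, t, deriv = 1)$y,
                 ddx = stats::predict(fx, t, deriv = 2)$y,
                 ddy = stats::predict(fy, t, deriv = 2)$y,
                 spar = spar),
            class = "smoothed_track")
}

# Shared-spar selection (rotation-invariant criteria; see smooth_track).
.select_spar <- function(t, x, y, smoothing, sigma_loc) {
  lo <- -1.5; hi <- 1.5
  if (is.numeric(smoothing)) return(smoothing)
  if (identical(smoothing, "gcv")) {
    total_gcv <- function(s)
      stats::smooth.spline(t, x, spar = s, all.knots = TRUE, cv = FALSE)$cv.crit +
      stats::smooth.spline(t, y, spar = s, all.knots = TRUE, cv = FALSE)$cv.crit
    return(stats::optimize(total_gcv, c(lo, hi), tol = 1e-2)$minimum)
  }
  if (identical(smoothing, "localization")) {
    rms <- function(s) {
      fx <- stats::smooth.spline(t, x, spar = s, all.knots = TRUE)
      fy <- stats::smooth.spline(t, y, spar = s, all.knots = TRUE)
      sqrt(mean((stats::predict(fx, t)$y - x)^2 +
                (stats::predict(fy, t)$y - y)^2) / 2)
    }
    if (rms(hi) <= sigma_loc) return(hi)
    if (rms(lo) >= sigma_loc) return(lo)
    return(stats::uniroot(function(s) rms(s) - sigma_loc, c(lo, hi),
                          tol = 1e-3)$root)
  }
  stop("smooth_track: unknown smoothing rule '", smoothing, "'", call. = FALSE)
}

#' Tangential speed signal
#'
#' Forward-difference step speed on the smoothed positions:
#' `v(t_k) = |r_s(t_{k+1}) - r_s(t_k)| / (t_{k+1} - t_k)`, length `n - 1`.
#'
#' @param st A `smoothed_track`.
#' @return Numeric vector of speeds (um/min).
#' @export
speed_signal <- function(st) {
  v <- .step_velocity(st)
  sqrt(v$vx^2 + v$vy^2)
}

.step_velocity <- function(st) {
  dt <- diff(st$t)
  if (any(dt == 0)) stop("speed_signal: repeated time stamps", call. = FALSE)
  list(vx = diff(st$x) / dt, vy = diff(st$y) / dt)
}

#' Curvature signal
#'
#' Path curvature from the spline derivatives,
#' `chi(t_k) = |x' y'' - y' x''| / (x'^2 + y'^2)^(3/2)` (um^-1); the
#' magnitude is taken so that averaging does not cancel left and right
#' turns. Points where the squared speed falls below `eps` are returned as
#' `NA` (direction undefined at rest) and are excluded from descriptor
#' means.
#'
#' @param st A `smoothed_track`.
#' @param eps Squared-speed floor in (um/min)^2.
#' @return Numeric vector, one value per sample (`NA` where undefined).
#' @export
curvature_signal <- function(st, eps = 1e-10) {
  sp2 <- st$dx^2 + st$dy^2
  chi <- abs(st$dx * st$ddy - st$dy * st$ddx) / sp2^1.5
  chi[sp2 < eps] <- NA_real_
  chi
}

#' Turning-angle signal
#'
#' Heading angle of the step velocity, in `(-pi, pi]`. The default
#' `convention = "printed"` measures the angle from the +y axis as
#' `atan2(v_x, v_y)` (the platform's printed argument order);
#' `convention = "math"` gives the conventional `atan2(v_y, v_x)` from the
#' +x axis. Zero-velocity steps yield `NA`.
#'
#' @param st A `smoothed_track`.
#' @param convention `"printed"` or `"math"`.
#' @return Numeric vector of angles (rad), length `n - 1`.
#' @export
turning_angle_signal <- function(st, convention = c("printed", "math")) {
  convention <- match.arg(convention)
  v <- .step_velocity(st)
  th <- if (convention == "printed") atan2(v$vx, v$vy) else atan2(v$vy, v$vx)
  th[v$vx == 0 & v$vy == 0] <- NA_real_
  th
}

#' Mean squared displacement profile and log-log fit
#'
#' Time-averaged MSD with overlapping windows:
#' `msd(m * dt) = mean_k |r(t_{k+m}) - r(t_k)|^2`, computed from the track's
#' measured (raw) positions. Smoothing is deliberately not applied here: a
#' smoothing spline suppresses exactly the short-lag displacement content
#' that the MSD of a diffusive path is made of, and deflates the fitted
#' intercept (see the methods vignette).
#'
#' An ordinary least-squares line is fitted to `ln msd` versus `ln tau` over
#' the short-lag window `1 .. max(3, floor(n/4))` (configurable), giving the
#' scaling exponent `alpha` (slope) and the natural-log intercept `y0`; for
#' two-dimensional Brownian motion `msd = 4 D tau`, so `alpha = 1` and
#' `y0 = ln(4 D)`.
#'
#' @param st A `smoothed_track` (its raw positions are used) or a one-track
#'   `tracks` data frame.
#' @param fit_lags Integer lags used in the fit; default
#'   `1:max(3, floor(n/4))`.
#' @return An object of class `msd_profile`: list with `tau` (min), `msd`
#'   (um^2), `alpha`, `y0`, `fit_lags`, `n`. `alpha`/`y0` are `NA` when the
#'   fit is undefined (fewer than 3 usable lags, e.g. a stationary track).
#' @export
msd_profile <- function(st, fit_lags = NULL) {
  if (inherits(st, "smoothed_track")) {
    t <- st$t; x <- st$x_raw; y <- st$y_raw
  } else {
    if (length(unique(st$track_id)) > 1L)
      stop("msd_profile: one track at a time", call. = FALSE)
    o <- order(st$t_min)
    t <- st$t_min[o]; x <- st$x_um[o]; y <- st$y_um[o]
  }
  n <- length(t)
  if (n < 8L) stop("msd_profile: need at least 8 samples", call. = FALSE)
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-8 * max(dt))
    stop("msd_profile: sampling must be uniform", call. = FALSE)
  dt <- dt[1]
  max_lag <- max(3L, n %/% 4L)
  if (is.null(fit_lags)) fit_lags <- seq_len(max_lag)
  lags <- seq_len(max(max_lag, max(fit_lags)))
  msd <- vapply(lags, function(m)
    mean((x[(1 + m):n] - x[1:(n - m)])^2 + (y[(1 + m):n] - y[1:(n - m)])^2),
    0)
  usable <- fit_lags[msd[fit_lags] > 0]
  if (length(usable) >= 3L) {
    fit <- stats::lm.fit(cbind(1, log(usable * dt)), log(msd[usable]))
    y0 <- fit$coefficients[1]; alpha <- fit$coefficients[2]
  } else {
    y0 <- NA_real_; alpha <- NA_real_
  }
  structure(list(tau = lags * dt, msd = msd, alpha = unname(alpha),
                 y0 = unname(y0), fit_lags = usable, n = n),
            class = "msd_profile")
}

#' Diffusion coefficient from an MSD profile
#'
#' `D = (1/4) * exp(y0)` with `y0` the natural-log intercept of the log-log
#' MSD fit — the two-dimensional relation `msd = 4 D tau` evaluated at the
#' fitted intercept.
#'
#' @param profile An [msd_profile()].
#' @return D in um^2/min, or `NA` if the fit was undefined.
#' @examples
#' diffusion_coefficient(structure(list(y0 = log(4)), class = "msd_profile"))  # 1
#' @export
diffusion_coefficient <- function(profile) {
  if (is.na(profile$y0)) return(NA_real_)
  exp(profile$y0) / 4
}

#' Global kinematic descriptors of one track
#'
#' Reduces the per-sample signals to one row of global descriptors: the
#' arithmetic mean of tangential speed and curvature over their valid
#' points, the circular mean of the turning angle (angles are periodic, so
#' an arithmetic mean would depend on the branch cut), and the diffusion
#' coefficient from the MSD fit. An all-missing signal gives `NA` for that
#' field; the row is kept.
#'
#' @param st A `smoothed_track`.
#' @param group Group label to pass through.
#' @param angle_convention See [turning_angle_signal()].
#' @param fit_lags See [msd_profile()].
#' @return One-row data frame: `track_id`, `group`, `mean_speed_um_min`,
#'   `mean_curvature_per_um`, `mean_turning_angle_rad`, `diffusion_um2_min`.
#' @export
summarize_track <- function(st, group = NA_character_,
                            angle_convention = "printed", fit_lags = NULL) {
  mean_ok <- function(z) if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
  circ_mean <- function(th) {
    th <- th[!is.na(th)]
    if (!length(th)) return(NA_real_)
    atan2(mean(sin(th)), mean(cos(th)))
  }
  v <- speed_signal(st)
  chi <- curvature_signal(st)
  th <- turning_angle_signal(st, convention = angle_convention)
  D <- if (length(st$t) >= 8L) diffusion_coefficient(msd_profile(st, fit_lags))
       else NA_real_
  data.frame(track_id = st$track_id, group = group,
             mean_speed_um_min = mean_ok(v),
             mean_curvature_per_um = mean_ok(chi),
             mean_turning_angle_rad = circ_mean(th),
             diffusion_um2_min = D)
}

#' Descriptor table for a whole track set
#'
#' Smooths every track and computes its global descriptors; tracks with
#' fewer than 4 samples are skipped with a warning.
#'
#' @param tracks A `tracks` data frame.
#' @param group Group label for all rows.
#' @param smoothing,sigma_loc See [smooth_track()].
#' @param angle_convention See [turning_angle_signal()].
#' @param fit_lags See [msd_profile()].
#' @return Data frame with one descriptor row per track.
#' @export
summarize_tracks <- function(tracks, group = NA_character_,
                             smoothing = "gcv", sigma_loc = 0.2,
                             angle_convention = "printed", fit_lags = NULL) {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    st <- smooth_track(tracks[tracks$track_id == id, , drop = FALSE],
                       smoothing = smoothing, sigma_loc = sigma_loc)
    if (is.null(st)) return(NULL)
    summarize_track(st, group = group, angle_convention = angle_convention,
                    fit_lags = fit_lags)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(track_id = integer(), group = character(),
                      mean_speed_um_min = numeric(),
                      mean_curvature_per_um = numeric(),
                      mean_turning_angle_rad = numeric(),
                      diffusion_um2_min = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a descriptors CSV
#'
#' Dialect: header
#' `track_id,group,mean_speed_um_min,mean_curvature_per_um,mean_turning_angle_rad,diffusion_um2_min`.
#' @param descriptors Descriptor data frame from [summarize_tracks()].
#' @param path File path.
#' @export
write_descriptors <- function(descriptors, path) {
  utils::write.csv(descriptors, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  d <- utils::read.csv(path)
  need <- c("track_id", "mean_speed_um_min", "mean_curvature_per_um",
            "mean_turning_angle_rad", "diffusion_um2_min")
  if (!all(need %in% names(d)))
    stop("read_descriptors: missing columns ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  d
}
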