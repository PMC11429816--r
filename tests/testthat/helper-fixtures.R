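# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

# One-track table from explicit coordinates.
make_track <- function(x, y, dt = 1, id = 0L) {
  n <- length(x)
  tr <- data.frame(track_id = id, frame = seq_len(n) - 1L,
                   t_min = (seq_len(n) - 1L) * dt, x_um = x, y_um = y)
  attr(tr, "frame_interval") <- dt
  class(tr) <- c("tracks", "data.frame")
  tr
}

circle_track <- function(R = 10, omega = 0.1, n = 200, dt = 1, phase = 0,
                         center = c(0, 0), id = 0L) {
  phi <- phase + omega * dt * (seq_len(n) - 1)
  make_track(center[1] + R * cos(phi), center[2] + R * sin(phi), dt, id)
}

brownian_track <- function(n = 200, D = 1, dt = 1, id = 0L) {
  make_track(cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt)))),
             cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt)))), dt, id)
}

straight_track <- function(speed = 1, n = 60, dt = 1, angle = 0, id = 0L) {
  s <- speed * dt * (seq_len(n) - 1)
  make_track(s * cos(angle), s * sin(angle), dt, id)
}

# Stack several one-track tables into one multi-track table.
bind_tracks <- function(trs) {
  out <- do.call(rbind, lapply(seq_along(trs), function(i) {
    tr <- as.data.frame(trs[[i]])
    tr$track_id <- i - 1L
    tr
  }))
  attr(out, "frame_interval") <- attr(trs[[1]], "frame_interval")
  class(out) <- c("tracks", "data.frame")
  out
}

# Exhaustive minimum-cost assignment (permutation oracle, n <= 7).
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, n <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- Inf
  for (p in perms(seq_len(m)))
    best <- min(best, sum(cost[cbind(seq_len(n), p[seq_len(n)])]))
  best
}

# Literal double-loop time-averaged MSD (definition oracle).
double_loop_msd <- function(x, y, lags) {
  vapply(lags, function(m) {
    n <- length(x)
    acc <- 0
    for (k in seq_len(n - m))
      acc <- acc + (x[k + m] - x[k])^2 + (y[k + m] - y[k])^2
    acc / (n - m)
  }, 0)
}

# Pairwise-counting AUC (Mann-Whitney oracle, 1/2 credit per tie).
pairwise_auc <- function(neg, pos) {
  gt <- outer(pos, neg, ">")
  eq <- outer(pos, neg, "==")
  (sum(gt) + 0.5 * sum(eq)) / (length(neg) * length(pos))
}

# Ground truth with planted, well-separated cells at chosen positions (um).
planted_truth <- function(x_um, y_um, radius_um, n_frames = 1, scene) {
  k <- length(x_um)
  gt <- data.frame(cell_id = rep(seq_len(k) - 1L, each = n_frames),
                   frame = rep(seq_len(n_frames) - 1L, k),
                   x_um = rep(x_um, each = n_frames),
                   y_um = rep(y_um, each = n_frames),
                   radius_um = rep(radius_um, each = n_frames))
  attr(gt, "resolution") <- scene$resolution
  attr(gt, "frame_interval") <- scene$frame_interval
  class(gt) <- c("ground_truth", "data.frame")
  gt
}

# Random non-overlapping positions on a grid-jittered layout (um).
scatter_positions <- function(k, scene, min_sep_um, margin_um = 8) {
  w <- scene$width_px * scene$resolution
  h <- scene$height_px * scene$resolution
  pts <- matrix(numeric(), 0, 2)
  guard <- 0
  while (nrow(pts) < k && guard < 20000) {
    guard <- guard + 1
    p <- c(runif(1, margin_um, w - margin_um), runif(1, margin_um, h - margin_um))
    if (!nrow(pts) || all((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 >= min_sep_um^2))
      pts <- rbind(pts, p)
  }
  stopifnot(nrow(pts) == k)
  pts
}

# Match detections to planted centers (px); returns per-cell nearest distance.
match_to_truth <- function(det, x_px, y_px) {
  vapply(seq_along(x_px), function(i) {
    if (!nrow(det)) return(Inf)
    min(sqrt((det$x_px - x_px[i])^2 + (det$y_px - y_px[i])^2))
  }, 0)
}
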