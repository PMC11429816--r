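#' Link detections between two consecutive frames
#'
#' Builds the Euclidean distance matrix (in um) between the detections of two
#' consecutive frames and solves the minimum-cost bipartite assignment with
#' the Kuhn--Munkres algorithm ([solve_assignment()]). Pairs farther apart
#' than `max_disp` are forbidden: the cost matrix is padded with
#' forbidden-cost dummies so the smaller side is always fully matched, and
#' links that land on a forbidden pair or a dummy are reported as unassigned.
#' Among feasible links the solution maximizes the number of links and, for
#' that number, minimizes the total distance.
#'
#' @param dets_a,dets_b Data frames with columns `x_um`, `y_um` (any extra
#'   columns are ignored). Either may be empty.
#' @param max_disp Gate: maximum allowed displacement in um (> 0).
#' @return A list with `pairs` (data frame `index_a`, `index_b`, `cost`;
#'   1-based row indices into the inputs, sorted by `index_a`),
#'   `unassigned_a`, `unassigned_b` (integer vectors).
#' @examples
#' a <- data.frame(x_um = c(0, 10), y_um = c(0, 0))
#' b <- data.frame(x_um = c(9, 1), y_um = c(0, 0))
#' link_frames(a, b, max_disp = 10)$pairs   # crossing match, total cost 2
#' @export
link_frames <- function(dets_a, dets_b, max_disp) {
  if (max_disp <= 0) stop("link_frames: max_disp must be > 0", call. = FALSE)
  na <- nrow(dets_a); nb <- nrow(dets_b)
  empty <- list(pairs = data.frame(index_a = integer(), index_b = integer(),
                                   cost = numeric()),
                unassigned_a = seq_len(na), unassigned_b = seq_len(nb))
  if (na == 0L || nb == 0L) return(empty)
  d <- sqrt(outer(dets_a$x_um, dets_b$x_um, "-")^2 +
            outer(dets_a$y_um, dets_b$y_um, "-")^2)
  big <- 1e6 * max(max_disp, d, 1)    # forbidden-cost sentinel
  cost <- ifelse(d <= max_disp, d, big)
  transposed <- na > nb
  if (transposed) cost <- t(cost)
  n <- nrow(cost); m <- ncol(cost)
  assign <- solve_assignment(cost)
  rows <- seq_len(n)
  ok <- cost[cbind(rows, assign)] < big
  ia <- if (transposed) assign[ok] else rows[ok]
  ib <- if (transposed) rows[ok] else assign[ok]
  o <- order(ia)
  pairs <- data.frame(index_a = ia[o], index_b = ib[o],
                      cost = d[cbind(ia[o], ib[o])])
  list(pairs = pairs,
       unassigned_a = setdiff(seq_len(na), pairs$index_a),
       unassigned_b = setdiff(seq_len(nb), pairs$index_b))
}

#' Build trajectories from per-frame detections
#'
#' Greedy-forward construction: tracks active in frame `k` are linked to the
#' detections of frame `k + 1` with [link_frames()]; matched detections
#' extend their track, unmatched detections seed new tracks, and unmatched
#' active tracks terminate. There is no gap closing — a missed detection
#' splits a trajectory in two — and no merging or splitting. Detections that
#' never link to anything (single-sample candidates) are dropped from the
#' track table and counted in the `singletons` attribute, so every returned
#' track has at least two samples.
#'
#' Pixel detections are converted to physical units
#' (`x_um = x_px * resolution`) and frames to time (`t_min = frame *
#' frame_interval`).
#'
#' @param dets Detections data frame (`frame`, `x_px`, `y_px`, ...) from
#'   [detect_stack()], or a list of per-frame data frames.
#' @param resolution um/px; defaults to the attribute carried by `dets`.
#' @param frame_interval min/frame; same default mechanism.
#' @param max_disp Gate in um; default `4 * r_max_um` with `r_max_um = 8`.
#' @param r_max_um Used only for the default gate.
#' @return A `tracks` data frame (`track_id`, `frame`, `t_min`, `x_um`,
#'   `y_um`), `track_id` dense from 0 in order of first appearance;
#'   attributes `singletons`, `resolution`, `frame_interval`.
#' @export
build_tracks <- function(dets, resolution = attr(dets, "resolution"),
                         frame_interval = attr(dets, "frame_interval"),
                         max_disp = 4 * r_max_um, r_max_um = 8) {
  if (is.null(resolution) || is.null(frame_interval))
    stop("build_tracks: resolution and frame_interval are required", call. = FALSE)
  if (is.data.frame(dets)) {
    if (nrow(dets) && any(dets$frame < 0))
      stop("build_tracks: negative frame indices", call. = FALSE)
    n_frames <- if (nrow(dets)) max(dets$frame) + 1L else 0L
    by_frame <- vector("list", n_frames)
    if (nrow(dets)) {
      sp <- split(dets, dets$frame)
      for (nm in names(sp)) by_frame[[as.integer(nm) + 1L]] <- sp[[nm]]
    }
  } else by_frame <- dets
  frames_um <- lapply(by_frame, function(d) {
    if (is.null(d) || !nrow(d))
      return(data.frame(x_um = numeric(), y_um = numeric()))
    data.frame(x_um = d$x_px * resolution, y_um = d$y_px * resolution)
  })

  next_id <- 0L
  active <- list()       # active[[k]]: list(id, rows = data.frame(frame, x_um, y_um))
  done <- list()
  singletons <- 0L
  start_tracks <- function(d, f) {
    lapply(seq_len(nrow(d)), function(i) {
      id <- next_id; next_id <<- next_id + 1L
      list(id = id, rows = data.frame(frame = f, x_um = d$x_um[i], y_um = d$y_um[i]))
    })
  }
  retire <- function(tr) {
    if (nrow(tr$rows) >= 2L) done[[length(done) + 1L]] <<- tr
    else singletons <<- singletons + 1L
  }
  if (length(frames_um) > 0L) active <- start_tracks(frames_um[[1L]], 0L)
  for (f in seq_len(length(frames_um) - 1L)) {
    cur <- if (length(active)) {
      data.frame(x_um = vapply(active, function(t) t$rows$x_um[nrow(t$rows)], 0),
                 y_um = vapply(active, function(t) t$rows$y_um[nrow(t$rows)], 0))
    } else data.frame(x_um = numeric(), y_um = numeric())
    nxt <- frames_um[[f + 1L]]
    lk <- link_frames(cur, nxt, max_disp)
    surv <- vector("list", nrow(lk$pairs))
    for (i in seq_len(nrow(lk$pairs))) {
      tr <- active[[lk$pairs$index_a[i]]]
      j <- lk$pairs$index_b[i]
      tr$rows <- rbind(tr$rows,
                       data.frame(frame = f, x_um = nxt$x_um[j], y_um = nxt$y_um[j]))
      surv[[i]] <- tr
    }
    for (i in lk$unassigned_a) retire(active[[i]])
    active <- c(surv, start_tracks(nxt[lk$unassigned_b, , drop = FALSE], f))
  }
  for (tr in active) retire(tr)

  if (length(done)) {
    done <- done[order(vapply(done, `[[`, 0L, "id"))]
    rows <- do.call(rbind, lapply(seq_along(done), function(k) {
      cbind(track_id = k - 1L, done[[k]]$rows)
    }))
  } else {
    rows <- data.frame(track_id = integer(), frame = integer(),
                       x_um = numeric(), y_um = numeric())
  }
  tracks <- data.frame(track_id = rows$track_id, frame = rows$frame,
                       t_min = rows$frame * frame_interval,
                       x_um = rows$x_um, y_um = rows$y_um)
  attr(tracks, "singletons") <- singletons
  attr(tracks, "resolution") <- resolution
  attr(tracks, "frame_interval") <- frame_interval
  class(tracks) <- c("tracks", "data.frame")
  tracks
}

#' Discard short trajectories
#'
#' Tracks lasting less than `min_duration` minutes are dropped to keep only
#' trajectories long enough for stable kinematic descriptors. Duration is
#' `t_last - t_first`; the boundary is kept (`duration >= min_duration`).
#' Track order and ids are preserved.
#'
#' @param tracks A `tracks` data frame.
#' @param min_duration Minimum duration in min (default 50).
#' @return The filtered `tracks` data frame.
#' @export
filter_tracks <- function(tracks, min_duration = 50) {
  if (min_duration < 0) stop("filter_tracks: min_duration must be >= 0", call. = FALSE)
  if (!nrow(tracks)) return(tracks)
  dur <- tapply(tracks$t_min, tracks$track_id, function(t) max(t) - min(t))
  keep_ids <- as.numeric(names(dur))[dur >= min_duration]
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  if (!nrow(out))
    warning("filter_tracks: no track reaches min_duration = ", min_duration,
            " min", call. = FALSE)
  rownames(out) <- NULL
  for (a in c("singletons", "resolution", "frame_interval"))
    attr(out, a) <- attr(tracks, a)
  class(out) <- class(tracks)
  out
}

#' Per-track durations
#' @param tracks A `tracks` data frame.
#' @return Named numeric vector of durations (min) by `track_id`.
#' @export
track_durations <- function(tracks) {
  if (!nrow(tracks)) return(stats::setNames(numeric(), character()))
  d <- tapply(tracks$t_min, tracks$track_id, function(t) max(t) - min(t))
  stats::setNames(as.vector(d), names(d))
}

#' Write / read a tracks CSV
#'
#' Dialect: header `track_id,frame,t_min,x_um,y_um`.
#' @param tracks A `tracks` data frame.
#' @param path File path.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks)[, c("track_id", "frame", "t_min",
                                             "x_um", "y_um")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @param resolution,frame_interval Calibration to attach on read
#'   (`frame_interval` inferred from `t_min` when omitted).
#' @export
read_tracks <- function(path, resolution = NA_real_, frame_interval = NULL) {
  tr <- utils::read.csv(path)
  need <- c("track_id", "frame", "t_min", "x_um", "y_um")
  if (!all(need %in% names(tr)))
    stop("read_tracks: missing columns ",
         paste(setdiff(need, names(tr)), collapse = ", "), call. = FALSE)
  if (is.null(frame_interval)) {
    df <- diff(tr$frame); dtm <- diff(tr$t_min)
    ok <- df > 0
    frame_interval <- if (any(ok)) stats::median(dtm[ok] / df[ok]) else NA_real_
  }
  attr(tr, "resolution") <- resolution
  attr(tr, "frame_interval") <- frame_interval
  class(tr) <- c("tracks", "data.frame")
  tr
}
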