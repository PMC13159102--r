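#' Construct a particle track
#'
#' A track is a time-ordered table of positions along a filament axis
#' (plus an optional lateral coordinate), sampled at a uniform frame
#' interval.  Positions are abscissae from the minus end, so
#' minus-end-directed transport has a negative slope in x.
#'
#' @param df data frame with columns `t` (or `t_s`) in seconds and `x`
#'   (or `x_um`) in micrometres; optional `y`/`y_um`.
#' @param frame_interval frame interval in seconds; default inferred
#'   from the time stamps (the TIRF assays use 5 s).
#' @param filament_length length of the underlying microtubule in um
#'   (needed for run-length ratios).
#' @return a `track` object.
#' @export
as_track <- function(df, frame_interval = NULL, filament_length = NULL) {
  pick <- function(d, a, b) if (a %in% names(d)) d[[a]] else d[[b]]
  t <- pick(df, "t", "t_s")
  x <- pick(df, "x", "x_um")
  y <- if ("y" %in% names(df)) df$y else if ("y_um" %in% names(df)) df$y_um
       else NULL
  if (is.null(t) || is.null(x)) stop("track needs t and x columns",
                                     call. = FALSE)
  if (any(diff(t) <= 0)) stop("track times must be strictly increasing",
                              call. = FALSE)
  dtv <- diff(t)
  if (length(dtv) && (max(dtv) - min(dtv)) > 1e-6 * mean(dtv))
    stop("track frames must be uniformly spaced", call. = FALSE)
  if (is.null(frame_interval)) frame_interval <- if (length(dtv)) dtv[1] else 5
  out <- list(t = as.numeric(t), x = as.numeric(x),
              y = if (!is.null(y)) as.numeric(y),
              frame_interval = frame_interval,
              filament_length = filament_length)
  class(out) <- "track"
  out
}

#' Segment a track into processive / diffusive / static events
#'
#' Frame-to-frame steps are labelled by sign once they exceed the
#' localization noise floor.  Maximal runs of at least
#' `min_processive_steps` same-sign above-floor steps become processive
#' events.  The remaining stretches are diffusive when most of their
#' steps exceed the noise floor and the stretch persists for more than
#' three frame intervals (15 s at the 5 s TIRF cadence); otherwise they
#' are static.  Segments partition the track;
#' consecutive events share their boundary frame, and ties at
#' changepoints go to the earlier event.
#'
#' @param track a [as_track] object.
#' @param noise_floor minimum per-frame step treated as real motion, um.
#'   Default 0.1 um (twice the default localization sigma).
#' @param min_processive_steps minimum same-sign steps for a processive
#'   call.
#' @return data frame with columns `class`, `start`, `end` (frame
#'   indices), `n_frames`, `velocity` (um/s, + toward the minus end, NA
#'   for non-processive), `run_distance`, `run_over_length_ratio`.
#' @export
segment_events <- function(track, noise_floor = 0.1,
                           min_processive_steps = 3L) {
  stopifnot(inherits(track, "track"))
  n <- length(track$x)
  if (n < 4L) stop("track too short to segment (need >= 4 frames)",
                   call. = FALSE)
  d <- diff(track$x)
  s <- ifelse(d > noise_floor, 1L, ifelse(d < -noise_floor, -1L, 0L))
  n_steps <- length(s)
  # maximal same-sign runs
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  is_proc <- runs$values != 0L & runs$lengths >= min_processive_steps
  # merge non-processive runs into gap segments
  seg_class <- character(0)
  seg_start <- integer(0)   # first step index of segment
  seg_end <- integer(0)     # last step index
  i <- 1L
  while (i <= length(runs$values)) {
    if (is_proc[i]) {
      seg_class <- c(seg_class, "processive")
      seg_start <- c(seg_start, starts[i])
      seg_end <- c(seg_end, ends[i])
      i <- i + 1L
    } else {
      j <- i
      while (j <= length(runs$values) && !is_proc[j]) j <- j + 1L
      gs <- starts[i]; ge <- ends[j - 1L]
      # diffusive = sustained non-monotone motion: more than half the
      # steps above the noise floor, persisting > 3 frame intervals;
      # occasional localization jitter above the floor stays static
      moving <- mean(abs(d[gs:ge]) > noise_floor) > 0.5
      cls <- if (moving && (ge - gs + 1L) > 3L) "diffusive" else "static"
      seg_class <- c(seg_class, cls)
      seg_start <- c(seg_start, gs)
      seg_end <- c(seg_end, ge)
      i <- j
    }
  }
  start_frame <- seg_start
  end_frame <- seg_end + 1L
  run_dist <- abs(track$x[end_frame] - track$x[start_frame])
  vel <- rep(NA_real_, length(seg_class))
  ratio <- rep(NA_real_, length(seg_class))
  ev <- data.frame(class = seg_class, start = start_frame, end = end_frame,
                   n_frames = end_frame - start_frame + 1L,
                   velocity = vel, run_distance = run_dist,
                   run_over_length_ratio = ratio,
                   stringsAsFactors = FALSE)
  for (k in which(ev$class == "processive")) {
    ev$velocity[k] <- event_velocity(ev[k, ], track)
    if (!is.null(track$filament_length))
      ev$run_over_length_ratio[k] <- run_ratio(ev[k, ], track, quiet = TRUE)
  }
  attr(ev, "noise_floor") <- noise_floor
  ev
}

#' Velocity of a processive event
#'
#' Least-squares slope of position versus time over the event, with the
#' sign flipped so that motion toward the minus end (decreasing
#' abscissa) is positive.
#'
#' @param event one row of the [segment_events()] table.
#' @param track the track the event belongs to.
#' @return velocity in um/s.
#' @export
event_velocity <- function(event, track) {
  stopifnot(inherits(track, "track"))
  if (event$class != "processive")
    stop("velocity is defined for processive events only", call. = FALSE)
  idx <- event$start:event$end
  tt <- track$t[idx]; xx <- track$x[idx]
  if (length(idx) == 2L) return(-(diff(xx) / diff(tt)))
  -unname(stats::coef(stats::lm.fit(cbind(1, tt), xx))[2])
}

#' Run distance and run/length ratio of a processive event
#'
#' Run distance is the straight-line distance along the filament between
#' the event's first and last frame.  The ratio divides by the
#' filament's length and is capped at 1 (localization noise can push a
#' full-length run slightly past the end).
#'
#' @inheritParams event_velocity
#' @param quiet suppress the capping warning.
#' @return run distance in um; ratio dimensionless in `[0, 1]`.
#' @export
run_distance <- function(event, track) {
  stopifnot(inherits(track, "track"))
  if (event$class != "processive")
    stop("run distance is defined for processive events only", call. = FALSE)
  abs(track$x[event$end] - track$x[event$start])
}

#' @rdname run_distance
#' @export
run_ratio <- function(event, track, quiet = FALSE) {
  if (is.null(track$filament_length))
    stop("filament_length is required for the run/length ratio",
         call. = FALSE)
  r <- run_distance(event, track) / track$filament_length
  if (r > 1) {
    if (!quiet)
      warning("run distance exceeds filament length; ratio capped at 1",
              call. = FALSE)
    r <- 1
  }
  r
}

#' Event rate normalized to microtubule length and imaging time
#'
#' Events are reported per micrometre of microtubule per minute of
#' acquisition, the TIRF normalization `n / (L x T)`.
#'
#' @param events event table from [segment_events()] (possibly pooled
#'   over tracks), or an integer count.
#' @param mt_length microtubule length in um.
#' @param duration total acquisition time in minutes.
#' @param classes which event classes to tabulate.
#' @return data frame with one row per class: `class`, `n_events`,
#'   `mt_length`, `duration`, `rate`.
#' @examples
#' event_rate(4L, mt_length = 10, duration = 20)  # 0.02 events/(um min)
#' @export
event_rate <- function(events, mt_length, duration,
                       classes = c("processive", "diffusive")) {
  if (mt_length <= 0) stop("mt_length must be positive", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (is.numeric(events)) {
    counts <- stats::setNames(as.integer(events),
                              classes[seq_along(events)])
  } else {
    counts <- vapply(classes, function(cl) sum(events$class == cl),
                     integer(1))
  }
  data.frame(class = names(counts), n_events = as.integer(counts),
             mt_length = mt_length, duration = duration,
             rate = as.numeric(counts) / (mt_length * duration),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Whole-track summary statistics
#'
#' Track length is the cumulative distance traveled (sum of consecutive
#' Euclidean steps, using the lateral coordinate when present);
#' displacement is the straight-line distance between the first and last
#' positions.  Mean velocity is track length over elapsed time.
#'
#' @param track a [as_track] object.
#' @return list with `track_length`, `displacement`, `mean_velocity`.
#' @export
track_summary <- function(track) {
  stopifnot(inherits(track, "track"))
  n <- length(track$x)
  if (n < 2L) stop("track needs at least two samples", call. = FALSE)
  xy <- cbind(track$x, if (is.null(track$y)) 0 else track$y)
  steps <- sqrt(rowSums(diff(xy)^2))
  track_length <- sum(steps)
  displacement <- sqrt(sum((xy[n, ] - xy[1, ])^2))
  list(track_length = track_length, displacement = displacement,
       mean_velocity = track_length / (track$t[n] - track$t[1]))
}

#' Read tracks from a long-format CSV
#'
#' @param path CSV with columns `track_id`, `t_s`, `x_um` and optional
#'   `y_um`.
#' @param frame_interval,filament_length passed to [as_track()];
#'   `filament_length` may be a named vector keyed by track id.
#' @return named list of `track` objects.
#' @export
read_tracks <- function(path, frame_interval = NULL,
                        filament_length = NULL) {
  df <- utils::read.csv(path)
  ids <- unique(df$track_id)
  stats::setNames(lapply(ids, function(id) {
    fl <- if (length(filament_length) > 1) filament_length[[as.character(id)]]
          else filament_length
    as_track(df[df$track_id == id, , drop = FALSE], frame_interval, fl)
  }), ids)
}
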