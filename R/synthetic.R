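#' @name synthetic
#' @title Seeded synthetic-data generators
#' @description Every analysis stage in the package has a matching
#'   generator that produces fixtures with known ground truth, so the
#'   whole pipeline builds and tests without external data.  Each
#'   generator is a pure function of its arguments (including `seed`):
#'   the caller's RNG state is saved and restored, and the full argument
#'   list is attached to the output as `$spec`.
NULL

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic FRAP traces
#'
#' Normalized recovery follows the single-exponential model
#' `N(t) = F0 + (plateau - F0) (1 - exp(-k t))` with
#' `plateau = F0 + mobile (1 - F0)` and `mobile = 1 - immobile_fraction`.
#' Gaussian noise of sd `noise_sd` is added to N(t), which is then
#' re-embedded into raw ROI / background / reference channels (with mild
#' acquisition photobleaching on the reference) such that
#' [normalize_trace()] recovers the noisy N(t) exactly.
#'
#' @param n number of traces.
#' @param t_half ground-truth half-time of recovery, s.
#' @param immobile_fraction ground-truth immobile fraction in `[0, 1]`.
#' @param F0 normalized post-bleach floor (bleach depth `1 - F0`).
#' @param noise_sd Gaussian noise sd on the normalized curve.
#' @param t_max post-bleach duration, s.
#' @param dt sampling interval, s.
#' @param n_prebleach pre-bleach frames.
#' @param acq_bleach_rate reference photobleaching rate, 1/s.
#' @param seed RNG seed.
#' @return list with `traces` (list of [frap_trace]), `truth` (one row
#'   per trace: F0, plateau, k, t_half, mobile/immobile fraction) and
#'   `spec`.
#' @export
gen_frap_traces <- function(n = 100, t_half = 9.92, immobile_fraction = 0.70,
                            F0 = 0.2, noise_sd = 0.02, t_max = 120, dt = 1,
                            n_prebleach = 5, acq_bleach_rate = 0.001,
                            seed = 1) {
  if (t_half <= 0) stop("t_half must be positive", call. = FALSE)
  if (immobile_fraction < 0 || immobile_fraction > 1)
    stop("immobile_fraction must be in [0, 1]", call. = FALSE)
  if (F0 < 0 || F0 >= 1) stop("F0 must be in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  k <- log(2) / t_half
  mobile <- 1 - immobile_fraction
  plateau <- F0 + mobile * (1 - F0)
  times <- c(seq(-n_prebleach, -1) * dt, seq(0, t_max, by = dt))
  model <- ifelse(times < 0, 1, F0 + (plateau - F0) * (1 - exp(-k * times)))
  spec <- list(kind = "frap", n = n, t_half = t_half,
               immobile_fraction = immobile_fraction, F0 = F0,
               noise_sd = noise_sd, t_max = t_max, dt = dt,
               n_prebleach = n_prebleach, acq_bleach_rate = acq_bleach_rate,
               seed = seed)
  traces <- with_seed(seed, lapply(seq_len(n), function(i) {
    noisy <- model + stats::rnorm(length(model), 0, noise_sd)
    bg <- 100
    ref <- bg + 900 * exp(-acq_bleach_rate * (times - times[1]))
    roi <- bg + (ref - bg) * noisy * 0.8   # 0.8: arbitrary gain factor
    frap_trace(times, roi, bg + numeric(length(times)), ref,
               n_prebleach = n_prebleach)
  }))
  truth <- data.frame(trace_id = seq_len(n), F0 = F0, plateau = plateau,
                      k = k, t_half = t_half, mobile_fraction = mobile,
                      immobile_fraction = immobile_fraction)
  list(traces = traces, truth = truth, spec = spec)
}

#' Generate synthetic particle tracks
#'
#' Emulates kymograph-derived condensate trajectories at the TIRF frame
#' cadence: each processive track is a static lead-in, a constant-drift
#' run toward the minus end (per-track speed drawn from
#' `Normal(speed_mean, speed_sd)`, truncated positive), and a static
#' tail, with Gaussian localization noise.  When `run_mean` is given,
#' per-track run distances are drawn from `Normal(run_mean, run_sd)`
#' (truncated to `(0, filament_length]`: a run cannot outrun its
#' filament) and the drift duration
#' is `run / speed`; otherwise the drift lasts `drift_frames` frames.
#' Tracks of kind `"diffusive"` are reflected random walks, `"static"`
#' pure noise; `"mixture"` draws each track's kind from
#' `mixture_weights`.
#'
#' @param n number of tracks.
#' @param kind `"processive"`, `"diffusive"`, `"static"`, or
#'   `"mixture"`.
#' @param speed_mean,speed_sd per-track speed distribution, um/s.
#' @param run_mean,run_sd optional per-track run-distance distribution,
#'   um.
#' @param frame_interval s per frame (TIRF default 5).
#' @param loc_sd localization noise sd, um.
#' @param filament_length um.
#' @param n_frames frames per track.
#' @param pre_frames static frames before the run.
#' @param drift_frames drift duration in frames when `run_mean` is NULL.
#' @param diff_step_sd per-frame step sd of diffusive tracks, um.
#' @param mixture_weights length-3 weights (processive, diffusive,
#'   static) for `kind = "mixture"`.
#' @param seed RNG seed.
#' @return list with `tracks` (list of [as_track]), `truth` (per track:
#'   kind, speed, run distance, changepoint frames), `labels` (per-frame
#'   ground-truth class per track), `spec`.
#' @export
gen_tracks <- function(n = 66, kind = "processive",
                       speed_mean = 0.055, speed_sd = 0.016,
                       run_mean = NULL, run_sd = NULL,
                       frame_interval = 5, loc_sd = 0.05,
                       filament_length = 10, n_frames = 30,
                       pre_frames = 3, drift_frames = 20,
                       diff_step_sd = 0.3,
                       mixture_weights = c(0.5, 0.3, 0.2), seed = 1) {
  stopifnot(speed_mean >= 0, speed_sd >= 0, loc_sd >= 0)
  if (!is.null(run_mean) && is.null(run_sd)) run_sd <- 0
  spec <- list(kind = "tracks", n = n, track_kind = kind,
               speed_mean = speed_mean, speed_sd = speed_sd,
               run_mean = run_mean, run_sd = run_sd,
               frame_interval = frame_interval, loc_sd = loc_sd,
               filament_length = filament_length, n_frames = n_frames,
               pre_frames = pre_frames, drift_frames = drift_frames,
               diff_step_sd = diff_step_sd,
               mixture_weights = mixture_weights, seed = seed)
  res <- with_seed(seed, {
    tracks <- vector("list", n)
    labels <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      this_kind <- if (kind == "mixture")
        sample(c("processive", "diffusive", "static"), 1,
               prob = mixture_weights)
      else kind
      tt <- (seq_len(n_frames) - 1) * frame_interval
      if (this_kind == "processive") {
        v <- 0
        while (v < 1e-3) v <- stats::rnorm(1, speed_mean, speed_sd)
        if (!is.null(run_mean)) {
          # physical truncation only: a run cannot exceed the filament
          run <- -1
          while (run <= 0 || run > filament_length)
            run <- stats::rnorm(1, run_mean, run_sd)
          dur <- run / v
          # extend the track so the whole run plus a static tail fits
          nf <- max(n_frames, pre_frames + ceiling(dur / frame_interval) + 3)
        } else {
          dur <- drift_frames * frame_interval
          run <- v * dur
          nf <- n_frames
        }
        tt <- (seq_len(nf) - 1) * frame_interval
        t1 <- pre_frames * frame_interval
        x0 <- min(filament_length - 0.2, run + 0.3)
        xc <- ifelse(tt < t1, x0,
                     ifelse(tt < t1 + dur, x0 - v * (tt - t1), x0 - run))
        lab <- ifelse(tt < t1, "static",
                      ifelse(tt < t1 + dur + frame_interval, "processive",
                             "static"))
        truth[[i]] <- data.frame(track_id = i, kind = this_kind, speed = v,
                                 run_distance = run,
                                 drift_start_frame = pre_frames + 1,
                                 drift_end_frame = pre_frames +
                                   ceiling(dur / frame_interval) + 1)
      } else if (this_kind == "diffusive") {
        steps <- stats::rnorm(n_frames - 1, 0, diff_step_sd)
        xc <- filament_length / 2 + c(0, cumsum(steps))
        xc <- pmin(pmax(xc, 0), filament_length)
        lab <- rep("diffusive", n_frames)
        truth[[i]] <- data.frame(track_id = i, kind = this_kind,
                                 speed = NA_real_, run_distance = NA_real_,
                                 drift_start_frame = NA_integer_,
                                 drift_end_frame = NA_integer_)
      } else {
        xc <- rep(filament_length / 2, n_frames)
        lab <- rep("static", n_frames)
        truth[[i]] <- data.frame(track_id = i, kind = this_kind,
                                 speed = NA_real_, run_distance = NA_real_,
                                 drift_start_frame = NA_integer_,
                                 drift_end_frame = NA_integer_)
      }
      x <- xc + stats::rnorm(length(xc), 0, loc_sd)
      tracks[[i]] <- as_track(data.frame(t = tt, x = x),
                              frame_interval = frame_interval,
                              filament_length = filament_length)
      labels[[i]] <- lab
    }
    list(tracks = tracks, labels = labels, truth = do.call(rbind, truth))
  })
  c(res, list(spec = spec))
}

#' Generate a synthetic condensate image
#'
#' Non-overlapping disks at `partition` times the dilute-phase
#' intensity, over a uniform dilute background, with Poisson shot noise
#' and Gaussian readout noise.  The image emulates a single confocal
#' channel of an in vitro droplet field; no camera offset is added, so
#' intensities are directly proportional to concentration.
#'
#' @param n_disks number of droplets.
#' @param radius_px mean disk radius in pixels.
#' @param radius_sd sd of disk radii.
#' @param partition ground-truth dense/dilute intensity ratio (> 1 for
#'   visible droplets; exactly 1 makes them invisible).
#' @param dilute_intensity mean dilute-phase photon count per pixel.
#' @param size image size `c(rows, cols)`.
#' @param pixel_size um per pixel.
#' @param read_noise_sd Gaussian readout noise sd.
#' @param max_tries placement retries before giving up.
#' @param seed RNG seed.
#' @return list with `image` (numeric matrix), `truth` (disk centres,
#'   radii, partition), `spec`.
#' @export
gen_droplet_image <- function(n_disks = 25, radius_px = 5, radius_sd = 0,
                              partition = 50, dilute_intensity = 200,
                              size = c(160, 160), pixel_size = 0.1,
                              read_noise_sd = 2, max_tries = 2000,
                              seed = 1) {
  if (partition < 1) stop("partition (enrichment) must be >= 1",
                          call. = FALSE)
  if (n_disks < 0 || radius_px <= 0)
    stop("invalid disk parameters", call. = FALSE)
  spec <- list(kind = "droplet_image", n_disks = n_disks,
               radius_px = radius_px, radius_sd = radius_sd,
               partition = partition, dilute_intensity = dilute_intensity,
               size = size, pixel_size = pixel_size,
               read_noise_sd = read_noise_sd, seed = seed)
  with_seed(seed, {
    nr <- size[1]; nc <- size[2]
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    tries <- 0
    while (nrow(centers) < n_disks) {
      if (tries >= max_tries)
        stop("could not place ", n_disks,
             " non-overlapping disks after ", max_tries, " tries",
             call. = FALSE)
      tries <- tries + 1
      r <- max(1.5, stats::rnorm(1, radius_px, radius_sd))
      ci <- stats::runif(1, r + 3, nr - r - 3)
      cj <- stats::runif(1, r + 3, nc - r - 3)
      if (nrow(centers)) {
        d <- sqrt((centers[, 1] - ci)^2 + (centers[, 2] - cj)^2)
        if (any(d < radii + r + 4)) next
      }
      centers <- rbind(centers, c(ci, cj))
      radii <- c(radii, r)
    }
    ii <- matrix(seq_len(nr), nr, nc)
    jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    lambda <- matrix(dilute_intensity, nr, nc)
    for (d in seq_along(radii)) {
      inside <- (ii - centers[d, 1])^2 + (jj - centers[d, 2])^2 <=
        radii[d]^2
      lambda[inside] <- dilute_intensity * partition
    }
    img <- matrix(stats::rpois(nr * nc, lambda) +
                    stats::rnorm(nr * nc, 0, read_noise_sd), nr, nc)
    truth <- if (length(radii))
      data.frame(disk_id = seq_along(radii), row = centers[, 1],
                 col = centers[, 2], radius_px = radii,
                 partition = partition)
    else data.frame(disk_id = integer(0), row = numeric(0),
                    col = numeric(0), radius_px = numeric(0),
                    partition = numeric(0))
    list(image = img, truth = truth, spec = spec)
  })
}

#' Generate a clustered / dispersed 2-D point set
#'
#' Gaussian blobs plus uniform background points inside a circular
#' arena; a desk-scale stand-in for simulated complex-position
#' snapshots.
#'
#' @param n_clusters number of Gaussian blobs.
#' @param points_per_cluster points per blob.
#' @param cluster_sd blob sd, um.
#' @param n_background uniformly scattered points.
#' @param arena_radius um.
#' @param min_cluster_sep minimum distance between blob centres, um.
#' @param seed RNG seed.
#' @return list with `positions` (matrix), `labels` (blob index, 0 for
#'   background), `spec`.
#' @export
gen_point_set <- function(n_clusters = 3, points_per_cluster = 10,
                          cluster_sd = 0.5, n_background = 10,
                          arena_radius = 10, min_cluster_sep = 0,
                          seed = 1) {
  spec <- list(kind = "point_set", n_clusters = n_clusters,
               points_per_cluster = points_per_cluster,
               cluster_sd = cluster_sd, n_background = n_background,
               arena_radius = arena_radius,
               min_cluster_sep = min_cluster_sep, seed = seed)
  with_seed(seed, {
    centers <- matrix(numeric(0), 0, 2)
    while (nrow(centers) < n_clusters) {
      r <- 0.8 * arena_radius * sqrt(stats::runif(1))
      a <- stats::runif(1, 0, 2 * pi)
      p <- c(r * cos(a), r * sin(a))
      if (nrow(centers) && min_cluster_sep > 0 &&
          any(sqrt(colSums((t(centers) - p)^2)) < min_cluster_sep)) next
      centers <- rbind(centers, p)
    }
    pos <- NULL
    labels <- integer(0)
    for (cl in seq_len(n_clusters)) {
      pts <- cbind(stats::rnorm(points_per_cluster, centers[cl, 1],
                                cluster_sd),
                   stats::rnorm(points_per_cluster, centers[cl, 2],
                                cluster_sd))
      pos <- rbind(pos, pts)
      labels <- c(labels, rep(cl, points_per_cluster))
    }
    if (n_background > 0) {
      r <- arena_radius * sqrt(stats::runif(n_background))
      a <- stats::runif(n_background, 0, 2 * pi)
      pos <- rbind(pos, cbind(r * cos(a), r * sin(a)))
      labels <- c(labels, rep(0L, n_background))
    }
    colnames(pos) <- c("x", "y")
    list(positions = pos, labels = labels, spec = spec)
  })
}

#' Write a generated fixture to disk
#'
#' Writes the fixture in the same plain-text dialects the analysis
#' modules read (CSV tables, CSV image matrices) with its generator
#' spec as `spec.json` alongside.
#'
#' @param fixture output of one of the `gen_*` generators.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- fixture$spec
  jsonlite::write_json(spec, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  switch(spec$kind,
    frap = {
      tab <- do.call(rbind, lapply(seq_along(fixture$traces), function(i) {
        tr <- fixture$traces[[i]]
        data.frame(trace_id = i, t_s = tr$times, roi = tr$roi,
                   background = tr$background, reference = tr$reference)
      }))
      utils::write.csv(tab, file.path(dir, "traces.csv"), row.names = FALSE)
      utils::write.csv(fixture$truth, file.path(dir, "truth.csv"),
                       row.names = FALSE)
    },
    tracks = {
      tab <- do.call(rbind, lapply(seq_along(fixture$tracks), function(i) {
        tr <- fixture$tracks[[i]]
        data.frame(track_id = i, t_s = tr$t, x_um = tr$x,
                   label = fixture$labels[[i]])
      }))
      utils::write.csv(tab, file.path(dir, "tracks.csv"), row.names = FALSE)
      utils::write.csv(fixture$truth, file.path(dir, "truth.csv"),
                       row.names = FALSE)
    },
    droplet_image = {
      write_image_csv(fixture$image, file.path(dir, "image.csv"))
      utils::write.csv(fixture$truth, file.path(dir, "truth.csv"),
                       row.names = FALSE)
    },
    point_set = {
      utils::write.csv(
        data.frame(x_um = fixture$positions[, 1],
                   y_um = fixture$positions[, 2], label = fixture$labels),
        file.path(dir, "points.csv"), row.names = FALSE)
    },
    stop("unknown fixture kind: ", spec$kind, call. = FALSE))
  invisible(dir)
}
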