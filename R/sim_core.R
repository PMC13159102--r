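#' Initialize a microtubule network state
#'
#' Places `n_filaments` straight filaments with uniformly random centres
#' and orientations inside the circular arena, and `n_hset` unbound
#' bivalent motor couplers.  Condensate complexes are added later by
#' [add_complexes()].
#'
#' The returned state is a plain list of matrices (`fil`, `vert`,
#' `motor`, `cplx`) plus the scalar bookkeeping fields `time`,
#' `complexes_added` and the serialized RNG stream.  Filament ids inside
#' the matrices are 0-based with -1 meaning "free/none"; this is the
#' engine's internal convention and is documented here because tests and
#' power users may edit states directly.
#'
#' @param config a [sim_config].
#' @return a `sim_state` list.
#' @export
init_network <- function(config) {
  validate_sim_config(config)
  st <- cx_init(unclass(config))
  class(st) <- "sim_state"
  st
}

#' Advance a simulation state
#'
#' Runs `n_steps` explicit time steps of length `config$dt`: Brownian and
#' elastic forces, load-dependent minus-end-directed walking, stochastic
#' (un)binding with per-step probability `1 - exp(-rate * dt)`, and
#' adhesive bond turnover between complexes.
#'
#' @param state a `sim_state`.
#' @param config the [sim_config] the state was built with.
#' @param n_steps number of time steps to take.
#' @return the advanced `sim_state`.
#' @export
sim_step <- function(state, config, n_steps = 1L) {
  stopifnot(inherits(state, "sim_state"))
  validate_sim_config(config)
  st <- cx_step(unclass(state), unclass(config), as.integer(n_steps))
  class(st) <- "sim_state"
  st
}

#' Add condensate complexes to a running simulation
#'
#' Places `n_complexes` complexes uniformly at random in the arena with
#' all hands free.  If `nucleation_enabled`, each complex seeds one
#' filament whose minus end is anchored at the complex and which grows to
#' full length over `nucleation_growth_time` seconds.  Complexes can be
#' added exactly once per run.
#'
#' @inheritParams sim_step
#' @return the updated `sim_state`.
#' @export
add_complexes <- function(state, config) {
  stopifnot(inherits(state, "sim_state"))
  validate_sim_config(config)
  st <- cx_add_complexes(unclass(state), unclass(config))
  class(st) <- "sim_state"
  st
}

#' Complex positions of a state
#'
#' @param state a `sim_state`.
#' @return a two-column matrix (x, y) in micrometres.
#' @export
complex_positions <- function(state) {
  state$cplx[, c("x", "y"), drop = FALSE]
}

#' Filament minus-end positions of a state
#'
#' @param state a `sim_state`.
#' @return a two-column matrix (x, y); one row per filament (vertex 0).
#' @export
filament_minus_ends <- function(state) {
  nv <- state$fil[, "nv"]
  if (!length(nv)) return(matrix(numeric(0), 0, 2,
                                 dimnames = list(NULL, c("x", "y"))))
  first <- cumsum(c(1, nv))[seq_along(nv)]
  state$vert[first, , drop = FALSE]
}

#' Run the two-phase clustering experiment
#'
#' Phase 1 (`[0, t_bundle]`): HSET couplers bundle the filament network.
#' Complexes are then added and the run continues to `t_total`.  Complex
#' positions (and filament minus ends) are recorded immediately after
#' addition, every `snapshot_interval` seconds, and at `t_total`.
#'
#' @param config a [sim_config].
#' @param verbose print per-phase progress.
#' @return a `sim_record`: list with `config`, `times`, `positions` (one
#'   matrix per snapshot), `minus_ends`, `seed`, and `final_state`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  validate_sim_config(config)
  dt <- config$dt
  n1 <- round(config$t_bundle / dt)
  state <- init_network(config)
  failed <- FALSE
  times <- numeric(0)
  positions <- list()
  minus_ends <- list()
  record_snap <- function(state, t_nominal) {
    # nominal protocol time: state$time accumulates 1e5 floating dt
    # increments and drifts in the last digits
    times[[length(times) + 1L]] <<- t_nominal
    positions[[length(positions) + 1L]] <<- complex_positions(state)
    minus_ends[[length(minus_ends) + 1L]] <<- filament_minus_ends(state)
  }
  snap_times <- unique(c(
    seq(config$t_bundle, config$t_total, by = max(config$snapshot_interval, dt)),
    config$t_total))
  t_start <- Sys.time()
  res <- tryCatch({
    if (n1 > 0) state <- sim_step(state, config, n1)
    if (verbose) message(sprintf("phase 1 complete at t = %.1f s", state$time))
    state <- add_complexes(state, config)
    record_snap(state, config$t_bundle)
    t_now <- config$t_bundle
    for (tt in snap_times[-1]) {
      n <- round((tt - t_now) / dt)
      if (n > 0) state <- sim_step(state, config, n)
      t_now <- tt
      record_snap(state, tt)
      if (verbose) message(sprintf("snapshot at t = %.1f s", tt))
    }
    state
  }, error = function(e) {
    failed <<- TRUE
    warning("simulation failed, flushing partial record: ",
            conditionMessage(e), call. = FALSE)
    NULL
  })
  rec <- list(
    config = config,
    times = unlist(times),
    positions = positions,
    minus_ends = minus_ends,
    seed = as.integer(config$seed),
    failed = failed,
    runtime_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    final_state = res
  )
  class(rec) <- "sim_record"
  rec
}

#' @export
print.sim_record <- function(x, ...) {
  cat("<sim_record>\n")
  cat(sprintf("  %d snapshots at t = %s s\n", length(x$times),
              paste(signif(x$times, 4), collapse = ", ")))
  cat(sprintf("  %d complexes, seed %d%s\n",
              if (length(x$positions)) nrow(x$positions[[1]]) else 0L,
              x$seed, if (isTRUE(x$failed)) " [FAILED]" else ""))
  invisible(x)
}

#' Parameter sweep over simulation configurations
#'
#' Runs [run_experiment()] once per grid cell.  The grid is the cross
#' product of the supplied value vectors; each cell's overrides are
#' applied to `base_config` and its seed is `base seed + cell index - 1`
#' so that columns of the grid share a seed ladder.
#'
#' @param base_config a [sim_config].
#' @param grid named list of value vectors to cross (e.g.
#'   `list(hset_unbinding_rate = c(0.05, 0.5, 5), n_hset = c(50, 100))`).
#' @param n_seeds replicate runs per cell (seeds stack after the grid).
#' @param verbose print progress per cell.
#' @return list of `sim_record`s; each carries a `grid_cell` attribute
#'   (named list of that cell's parameter values plus `replicate`).
#' @export
sweep_experiments <- function(base_config, grid, n_seeds = 1L,
                              verbose = FALSE) {
  validate_sim_config(base_config)
  if (!length(grid)) stop("empty sweep grid", call. = FALSE)
  stopifnot(!is.null(names(grid)), all(names(grid) %in% names(base_config)))
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  records <- vector("list", nrow(cells) * n_seeds)
  idx <- 0L
  for (r in seq_len(nrow(cells))) {
    for (s in seq_len(n_seeds)) {
      idx <- idx + 1L
      overrides <- as.list(cells[r, , drop = FALSE])
      overrides$seed <- as.integer(base_config$seed) + idx - 1L
      cfg <- do.call(sim_config,
                     utils::modifyList(unclass(base_config), overrides))
      if (verbose)
        message(sprintf("sweep cell %d/%d replicate %d", r, nrow(cells), s))
      rec <- run_experiment(cfg)
      attr(rec, "grid_cell") <- c(as.list(cells[r, , drop = FALSE]),
                                  list(replicate = s))
      records[[idx]] <- rec
    }
  }
  records
}

#' Write or read a simulation record directory
#'
#' Layout: `config.json` (config echo), `snapshots.csv` (time_s,
#' complex_id, x_um, y_um), `filaments.csv` (time_s, filament_id,
#' minus_x_um, minus_y_um), `meta.json` (seed, version, runtime).
#'
#' @param record a `sim_record`.
#' @param dir output directory (created if needed).
#' @return `write_sim_record` returns `dir` invisibly; `read_sim_record`
#'   returns a `sim_record` (without `final_state`).
#' @export
write_sim_record <- function(record, dir) {
  stopifnot(inherits(record, "sim_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sim_config(record$config, file.path(dir, "config.json"))
  snaps <- do.call(rbind, lapply(seq_along(record$times), function(i) {
    p <- record$positions[[i]]
    if (!nrow(p)) return(NULL)
    data.frame(time_s = record$times[i], complex_id = seq_len(nrow(p)),
               x_um = p[, 1], y_um = p[, 2])
  }))
  if (is.null(snaps))
    snaps <- data.frame(time_s = numeric(0), complex_id = integer(0),
                        x_um = numeric(0), y_um = numeric(0))
  utils::write.csv(snaps, file.path(dir, "snapshots.csv"), row.names = FALSE)
  fils <- do.call(rbind, lapply(seq_along(record$times), function(i) {
    p <- record$minus_ends[[i]]
    if (!nrow(p)) return(NULL)
    data.frame(time_s = record$times[i], filament_id = seq_len(nrow(p)),
               minus_x_um = p[, 1], minus_y_um = p[, 2])
  }))
  if (is.null(fils))
    fils <- data.frame(time_s = numeric(0), filament_id = integer(0),
                       minus_x_um = numeric(0), minus_y_um = numeric(0))
  utils::write.csv(fils, file.path(dir, "filaments.csv"), row.names = FALSE)
  meta <- list(seed = record$seed, failed = record$failed,
               runtime_s = record$runtime_s,
               version = as.character(utils::packageVersion("centroclust")))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_sim_record
#' @export
read_sim_record <- function(dir) {
  cfg <- read_sim_config(file.path(dir, "config.json"))
  snaps <- utils::read.csv(file.path(dir, "snapshots.csv"))
  fils <- utils::read.csv(file.path(dir, "filaments.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  times <- sort(unique(snaps$time_s))
  positions <- lapply(times, function(tt) {
    s <- snaps[snaps$time_s == tt, , drop = FALSE]
    s <- s[order(s$complex_id), , drop = FALSE]
    m <- cbind(x = s$x_um, y = s$y_um)
    m
  })
  minus_ends <- lapply(times, function(tt) {
    s <- fils[fils$time_s == tt, , drop = FALSE]
    s <- s[order(s$filament_id), , drop = FALSE]
    cbind(x = s$minus_x_um, y = s$minus_y_um)
  })
  rec <- list(config = cfg, times = times, positions = positions,
              minus_ends = minus_ends, seed = meta$seed,
              failed = isTRUE(meta$failed), runtime_s = meta$runtime_s,
              final_state = NULL)
  class(rec) <- "sim_record"
  rec
}
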