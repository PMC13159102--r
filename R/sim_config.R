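#' Simulation configuration
#'
#' Build a validated configuration for the two-phase clustering
#' simulation: microtubule bundles are formed by bivalent HSET couplers
#' during `[0, t_bundle]`, condensate complexes are then added, and the
#' run continues to `t_total`.  All lengths are in micrometres, times in
#' seconds, forces in piconewtons.
#'
#' Defaults are documented design values: motor speed 0.087 um/s (the
#' measured condensate transport velocity), stall force 5 pN, link
#' stiffness 100 pN/um, binding rate 5/s within a 0.05 um capture range,
#' unbinding rate 0.1/s, 50 filaments of 8 um in a 10 um-radius arena,
#' viscosity 1 pN s/um^2, kT = 0.0042 pN um.  Every value can be
#' overridden and is echoed into each [sim_record].
#'
#' @param ... named overrides of the default fields; unknown names are
#'   rejected.
#' @return an object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_filaments = 10, seed = 1)
#' cfg$hset_speed
#' @export
sim_config <- function(...) {
  cfg <- sim_config_defaults()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all config overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(dots)] <- dots
  }
  cfg <- lapply(cfg, function(x) if (is.logical(x)) x else as.numeric(x))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

sim_config_defaults <- function() {
  list(
    arena_radius = 10,          # um
    dt = 0.005,                 # s
    t_bundle = 100,             # s, phase-1 bundling
    t_total = 500,              # s
    n_filaments = 50,
    filament_length = 8,        # um
    filament_rigidity = 20,     # pN um^2 (microtubule flexural rigidity)
    segment_length = 1,         # um, discretization
    n_hset = 100,
    hset_binding_rate = 5,      # 1/s
    hset_unbinding_rate = 0.1,  # 1/s (swept to vary processivity)
    hset_speed = 0.087,         # um/s toward the minus end
    hset_stall_force = 5,       # pN
    hset_link_stiffness = 100,  # pN/um
    hset_capture_range = 0.05,  # um
    n_complexes = 20,
    complex_adhesive_on_rate = 10,    # 1/s within range
    complex_adhesive_off_rate = 0.1,  # 1/s
    complex_adhesive_range = 0.25,    # um
    complex_adhesive_stiffness = 100, # pN/um
    complex_adhesive_rest_length = 0.1, # um
    lattice_binding_rate = 1,   # 1/s, weak lattice association
    lattice_unbinding_rate = 1, # 1/s
    lattice_link_stiffness = 100,
    nucleation_enabled = TRUE,
    nucleation_growth_time = 20, # s to reach full length
    anchor_stiffness = 200,     # pN/um, complex <-> nucleated minus end
    confinement_stiffness = 100, # pN/um, soft circular wall
    viscosity = 1,              # pN s/um^2
    temperature_kT = 0.0042,    # pN um (~300 K)
    motor_drag_length = 0.05,   # um; gamma = viscosity * length
    complex_drag_length = 1,    # um (condensate-scale drag)
    snapshot_interval = 100,    # s
    seed = 1
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$dt <= 0) stop("dt must be positive", call. = FALSE)
  if (cfg$arena_radius <= 0)
    stop("arena_radius must be positive", call. = FALSE)
  if (cfg$t_bundle > cfg$t_total)
    stop("t_bundle must not exceed t_total", call. = FALSE)
  if (cfg$n_filaments > 0 && cfg$filament_length <= 0)
    stop("filament_length must be positive", call. = FALSE)
  counts <- c("n_filaments", "n_hset", "n_complexes")
  for (f in counts)
    if (cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      stop(f, " must be a non-negative integer", call. = FALSE)
  rates <- c("hset_binding_rate", "hset_unbinding_rate",
             "complex_adhesive_on_rate", "complex_adhesive_off_rate",
             "lattice_binding_rate", "lattice_unbinding_rate")
  for (f in rates)
    if (cfg[[f]] < 0) stop(f, " must be non-negative", call. = FALSE)
  if (cfg$segment_length <= 0)
    stop("segment_length must be positive", call. = FALSE)
  if (cfg$viscosity <= 0) stop("viscosity must be positive", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  arena %g um, dt %g s, phases %g / %g s\n",
              x$arena_radius, x$dt, x$t_bundle, x$t_total))
  cat(sprintf("  %d filaments x %g um, %d HSET couplers, %d complexes\n",
              x$n_filaments, x$filament_length, x$n_hset, x$n_complexes))
  cat(sprintf("  unbinding rate %g /s, speed %g um/s, seed %d\n",
              x$hset_unbinding_rate, x$hset_speed, as.integer(x$seed)))
  invisible(x)
}

#' Read or write a simulation configuration as JSON
#'
#' One JSON document per run.  Unknown keys are rejected on read so that
#' a typo cannot silently fall back to a default.
#'
#' @param path file path.
#' @param cfg a [sim_config] object.
#' @return `read_sim_config` returns a `sim_config`;
#'   `write_sim_config` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
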