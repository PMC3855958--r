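# Structured simulation configuration: schema, defaults, validation,
# JSON (de)serialization, and named fixture generators.

#' Default simulation configuration
#'
#' Full nested configuration with every key at its default. The defaults
#' reproduce the reduced reference cube isometric-tetanus experiment: a
#' 1-element, 2 cm cube with 4 embedded fibers of 16 linear elements,
#' passive 20% prestretch, 100 Hz stimulation of every fiber's central
#' half-sarcomere, and the shipped three-rate schedule.
#'
#' @return Object of class `sim_config` (a validated nested list).
#' @export
default_config <- function() {
  cfg <- list(
    geometry = list(nx = 1L, ny = 1L, nz = 1L, L = 2, fiber_axis = 1L),
    material = list(c10 = 6.352e-10, c01 = 3.627, b1 = 2.756e-5,
                    d1 = 43.373, Pmax = 73, lambda_opt = 1.2,
                    a_rel = 0.25, b_rel = 0.25, vmax = 0.02, Fiso = 1,
                    sigma = 3.8, Am = 500, Cm_slow = 0.58, Cm_fast = 1.0),
    fibers = list(n_fibers = 4L, n_elem_per_fiber = 16L),
    cellmodel = list(name = "reduced", fiber_type = "fast", params = list()),
    stimulus = list(frequency = 100, amplitude = 700, width = 0.5),
    schedule = list(dt_hsm = 1e-3, n_hsm_per_deq = 10L, n_deq_per_cmm = 50L,
                    t_end = 160),
    experiment = list(mode = "isometric", prestretch = 0.2,
                      t_prestretch = 10, speed_fraction = 0,
                      lumped_mass = FALSE),
    output = list(dir = "", write_csv = FALSE, write_vtu = FALSE))
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks the nested schema (unknown keys rejected at every level), value
#' types, and positivity/range constraints; fills nothing in (use
#' [load_config()] to merge partial input over the defaults).
#'
#' @param cfg nested configuration list.
#' @return The configuration, classed `sim_config`.
#' @export
validate_config <- function(cfg) {
  ref <- list(
    geometry = c("nx", "ny", "nz", "L", "fiber_axis"),
    material = c("c10", "c01", "b1", "d1", "Pmax", "lambda_opt", "a_rel",
                 "b_rel", "vmax", "Fiso", "sigma", "Am", "Cm_slow",
                 "Cm_fast"),
    fibers = c("n_fibers", "n_elem_per_fiber"),
    cellmodel = c("name", "fiber_type", "params"),
    stimulus = c("frequency", "amplitude", "width"),
    schedule = c("dt_hsm", "n_hsm_per_deq", "n_deq_per_cmm", "t_end"),
    experiment = c("mode", "prestretch", "t_prestretch", "speed_fraction",
                   "lumped_mass"),
    output = c("dir", "write_csv", "write_vtu"))
  unknown_top <- setdiff(names(cfg), names(ref))
  if (length(unknown_top))
    stop("unknown config block(s): ", paste(unknown_top, collapse = ", "))
  for (blk in names(cfg)) {
    unknown <- setdiff(names(cfg[[blk]]), ref[[blk]])
    if (length(unknown))
      stop("unknown key(s) in config block '", blk, "': ",
           paste(unknown, collapse = ", "))
  }
  g <- cfg$geometry
  stopifnot(g$nx >= 1, g$ny >= 1, g$nz >= 1, all(g$L > 0),
            g$fiber_axis %in% 1:3)
  do.call(material_params, cfg$material)   # enforces material invariants
  stopifnot(cfg$fibers$n_fibers >= 1, cfg$fibers$n_elem_per_fiber >= 1)
  if (!cfg$cellmodel$name %in% "reduced")
    stop("config: unknown cell model '", cfg$cellmodel$name, "'")
  if (!cfg$cellmodel$fiber_type %in% c("fast", "slow"))
    stop("config: fiber_type must be 'fast' or 'slow'")
  stopifnot(cfg$stimulus$frequency > 0, cfg$stimulus$amplitude >= 0,
            cfg$stimulus$width > 0)
  s <- cfg$schedule
  stopifnot(s$dt_hsm > 0, s$n_hsm_per_deq >= 1, s$n_deq_per_cmm >= 1,
            s$t_end >= 0)
  e <- cfg$experiment
  if (!e$mode %in% c("isometric", "shortening", "passive", "fiber_only"))
    stop("config: unknown experiment mode '", e$mode, "'")
  stopifnot(e$prestretch > -1, e$t_prestretch >= 0,
            e$speed_fraction >= 0, e$speed_fraction <= 1)
  structure(cfg, class = "sim_config")
}

#' Load (and fully default) a configuration from JSON
#'
#' Reads a JSON configuration file, merges it over the defaults
#' (an empty file yields the full default configuration), rejects unknown
#' keys, and validates. Use [write_config()] for a round-trippable dump,
#' e.g. as an effective-configuration echo next to outputs.
#'
#' @param path JSON file path.
#' @return A validated `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list()
          else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  cfg <- unclass(default_config())
  for (blk in names(user)) {
    if (!blk %in% names(cfg))
      stop("unknown config block(s): ", blk)
    cfg[[blk]] <- utils::modifyList(cfg[[blk]], as.list(user[[blk]]))
  }
  validate_config(cfg)
}

#' Write a configuration as JSON
#'
#' @param cfg a `sim_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Named fixture configurations
#'
#' Ready-to-run configurations for the reference cube setups and reduced
#' variants:
#' \describe{
#'   \item{cube8_400}{2 cm cube, 8 Taylor-Hood elements, 400 fibers of 60
#'     elements (the full reference setup).}
#'   \item{cube8_36}{as above with 36 fibers (3 x 3 per 3D element).}
#'   \item{cube1_4}{reduced cube: 1 element, 4 fibers of 16 elements.}
#'   \item{fiber_only}{a single 60-element fiber, electrophysiology only
#'     (static geometry, no mechanics solve).}
#' }
#'
#' @param name fixture name.
#' @return A validated `sim_config`.
#' @export
make_fixture <- function(name = c("cube1_4", "cube8_400", "cube8_36",
                                  "fiber_only")) {
  name <- match.arg(name)
  cfg <- unclass(default_config())
  if (name == "cube8_400") {
    cfg$geometry[c("nx", "ny", "nz")] <- list(2L, 2L, 2L)
    cfg$fibers <- list(n_fibers = 400L, n_elem_per_fiber = 60L)
  } else if (name == "cube8_36") {
    cfg$geometry[c("nx", "ny", "nz")] <- list(2L, 2L, 2L)
    cfg$fibers <- list(n_fibers = 36L, n_elem_per_fiber = 60L)
  } else if (name == "fiber_only") {
    cfg$fibers <- list(n_fibers = 1L, n_elem_per_fiber = 60L)
    cfg$experiment$mode <- "fiber_only"
    cfg$experiment$t_prestretch <- 0
    cfg$schedule$t_end <- 50
  }
  validate_config(cfg)
}
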