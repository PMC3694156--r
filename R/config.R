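# Run configuration: one human-editable YAML file per model profile.
# Unknown keys are rejected with their location so typos cannot silently
# change a simulation.

config_schema <- list(
  name = NULL,
  model = c("skull_length", "body_mass", "canine_length", "canine_arc_radius",
            "canine_arc_ratio", "condyle_radius", "cotyle_clearance",
            "gape_bone_contact_deg", "cartilage_mm", "element_budget", "seed"),
  materials = c("bone", "dentine", "enamel"),
  muscles = c("specific_tension", "n_trusses"),
  depressors = c("ellipse_axes", "circle_radius", "n_sterno", "n_obliquus",
                 "pretension", "standoff_frac"),
  gape = c("cartilage_mm", "backoff_deg"),
  scaling = c("exponent", "reference"),
  sweep = c("angles"),
  output = NULL, seed = NULL, log_level = NULL)

#' Read and validate a run configuration
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return a validated list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) {
      stop_craniofem(sprintf("config file not found: %s", path), "craniofem_io_error")
    }
    yaml::read_yaml(path)
  } else path
  unknown_top <- setdiff(names(cfg), names(config_schema))
  if (length(unknown_top)) {
    stop_craniofem(sprintf("unknown config key(s): %s",
                           paste(unknown_top, collapse = ", ")), "craniofem_bad_config")
  }
  for (sec in names(config_schema)) {
    keys <- config_schema[[sec]]
    if (is.null(keys) || is.null(cfg[[sec]])) next
    bad <- setdiff(names(cfg[[sec]]), keys)
    if (length(bad)) {
      stop_craniofem(sprintf("unknown key(s) under '%s': %s", sec,
                             paste(bad, collapse = ", ")), "craniofem_bad_config")
    }
  }
  cfg$name <- cfg$name %||% "model"
  cfg$seed <- as.integer(cfg$seed %||% cfg$model$seed %||% 1L)
  cfg$model$seed <- cfg$seed
  cfg$gape <- utils::modifyList(list(cartilage_mm = 1, backoff_deg = 2),
                                cfg$gape %||% list())
  cfg$muscles <- utils::modifyList(list(specific_tension = 0.3, n_trusses = 5),
                                   cfg$muscles %||% list())
  cfg$depressors <- utils::modifyList(
    list(n_sterno = 40, n_obliquus = 30, pretension = 25, standoff_frac = 0.5),
    cfg$depressors %||% list())
  cfg$scaling <- utils::modifyList(list(exponent = 2 / 3), cfg$scaling %||% list())
  cfg$sweep <- utils::modifyList(list(angles = c(15, 30, 45, 60)),
                                 cfg$sweep %||% list())
  structure(cfg, class = "run_config")
}

config_materials <- function(cfg) {
  m <- default_materials()
  for (nm in names(cfg$materials %||% list())) {
    spec <- cfg$materials[[nm]]
    m[[nm]] <- material(nm, E = spec$E, nu = spec$nu)
  }
  m
}

config_skull_params <- function(cfg) {
  args <- cfg$model
  do.call(skull_params, args)
}

#' Locate a bundled demo profile
#'
#' Three demo profiles ship with the package, loosely themed on a large
#' dirk-toothed felid (259 kg), a saber-toothed sparassodont (82 kg) and a
#' conical-toothed leopard (68 kg).
#'
#' @param name `"sabercat"`, `"pouched_saber"` or `"leopard"`; NULL lists
#'   all bundled profiles.
#' @return a file path (or named vector of paths).
#' @export
demo_profile <- function(name = NULL) {
  dir <- system.file("extdata", "profiles", package = "craniofem")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  names(files) <- sub("\\.yaml$", "", basename(files))
  if (is.null(name)) return(files)
  if (!name %in% names(files)) {
    stop_craniofem(sprintf("no demo profile '%s' (have: %s)", name,
                           paste(names(files), collapse = ", ")),
                   "craniofem_io_error")
  }
  files[[name]]
}
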