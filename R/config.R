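# YAML run configuration: schema-validated scenario description resolving to
# the package's domain/load/solver objects.

config_schema <- function() {
  list(
    paths = c("curves", "mesh", "output"),
    domain = c("tissue_width", "tissue_height", "tissue_depth",
               "effective_depth", "dressing_thickness", "dressing_extent",
               "mattress_thickness", "prominence_tip_radius",
               "prominence_depth", "prominence_height", "dimensionality"),
    materials = c("tissue_shear_modulus_kpa", "tissue_bulk_modulus_kpa",
                  "bone_mode", "bone_youngs_modulus_kpa", "bone_poisson",
                  "mattress_youngs_modulus_kpa", "mattress_poisson",
                  "dressing_poisson", "dressing_solid_fraction"),
    load = c("direction_angle", "target_reaction_force",
             "max_displacement_guess"),
    contact = c("friction_coefficient", "normal_penalty",
                "tangential_penalty"),
    solver = c("load_steps", "newton_tolerance", "max_newton_iterations",
               "force_target_tolerance", "line_search"),
    histogram = c("range_lo", "range_hi", "bin_width", "threshold"),
    top = c("paths", "domain", "materials", "load", "contact", "solver",
            "histogram", "seed", "verbosity")
  )
}

config_defaults <- function() {
  list(
    paths = list(curves = NULL, mesh = NULL, output = "."),
    domain = list(tissue_width = 200, tissue_height = 75, tissue_depth = 250,
                  effective_depth = 80, dressing_thickness = 5.5,
                  dressing_extent = 150, mattress_thickness = 75,
                  prominence_tip_radius = 8, prominence_depth = 15,
                  prominence_height = 35, dimensionality = "2D"),
    materials = list(tissue_shear_modulus_kpa = 19.254,
                     tissue_bulk_modulus_kpa = 1919.022,
                     bone_mode = "rigid",
                     bone_youngs_modulus_kpa = 3.4e6, bone_poisson = 0.36,
                     mattress_youngs_modulus_kpa = 50, mattress_poisson = 0.3,
                     dressing_poisson = 0.1, dressing_solid_fraction = 0.02),
    load = list(direction_angle = 45, target_reaction_force = 40,
                max_displacement_guess = 25),
    contact = list(friction_coefficient = 0.4, normal_penalty = NULL,
                   tangential_penalty = NULL),
    solver = list(load_steps = 10, newton_tolerance = 1e-6,
                  max_newton_iterations = 60, force_target_tolerance = 0.1,
                  line_search = TRUE),
    histogram = list(range_lo = 0.05, range_hi = 1.0, bin_width = 0.05,
                     threshold = 0.5),
    seed = 1L,
    verbosity = 1L
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML scenario configuration, rejects unknown keys, merges the
#' packaged defaults (the physiological constants and the 40 N / 45 degree
#' load case), and validates the physical invariants. The fully resolved
#' configuration is what downstream stages consume, so there are no silent
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config`: the resolved nested list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  schema <- config_schema()
  bad <- setdiff(names(raw), schema$top)
  if (length(bad)) {
    stop("config schema violation: unknown key '", bad[1], "'", call. = FALSE)
  }
  cfg <- config_defaults()
  for (sec in intersect(names(raw), schema$top)) {
    if (sec %in% c("seed", "verbosity")) {
      cfg[[sec]] <- raw[[sec]]
      next
    }
    badk <- setdiff(names(raw[[sec]]), schema[[sec]])
    if (length(badk)) {
      stop("config schema violation: unknown key '", sec, ".", badk[1], "'",
           call. = FALSE)
    }
    cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
  }
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  m <- cfg$materials
  # elastic_constants() enforces the admissible ranges (e.g. nu < 0.5)
  elastic_constants(G = m$tissue_shear_modulus_kpa,
                    K = m$tissue_bulk_modulus_kpa)
  elastic_constants(E = m$bone_youngs_modulus_kpa, nu = m$bone_poisson)
  elastic_constants(E = m$mattress_youngs_modulus_kpa,
                    nu = m$mattress_poisson)
  if (!m$bone_mode %in% c("rigid", "deformable")) {
    stop("config schema violation: materials.bone_mode must be 'rigid' or ",
         "'deformable'", call. = FALSE)
  }
  if (m$dressing_poisson < 0 || m$dressing_poisson >= 0.5) {
    stop("config schema violation: dressing_poisson must lie in [0, 0.5)",
         call. = FALSE)
  }
  do.call(domain_spec, cfg$domain)
  do.call(load_case, cfg$load)
  do.call(solver_settings, cfg$solver)
  h <- cfg$histogram
  if (h$range_lo >= h$range_hi || h$bin_width <= 0) {
    stop("config schema violation: invalid histogram range", call. = FALSE)
  }
  if (abs((h$threshold - h$range_lo) / h$bin_width -
          round((h$threshold - h$range_lo) / h$bin_width)) > 1e-9) {
    stop("config schema violation: threshold must be a histogram bin edge",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Save a run configuration as YAML
#'
#' @param config A `run_config` (or compatible nested list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build the scenario suite described by a configuration
#'
#' @param config A `run_config`.
#' @param table Dressing table (default packaged).
#' @return A `scenario_suite`.
#' @export
config_to_suite <- function(config, table = packaged_dressing_table()) {
  m <- config$materials
  spec <- do.call(domain_spec, config$domain)
  bone <- if (m$bone_mode == "deformable") {
    material_linear_elastic(elastic_constants(E = m$bone_youngs_modulus_kpa,
                                              nu = m$bone_poisson),
                            name = "bone")
  } else NULL
  generate_scenario_suite(
    spec = spec, table = table, load = do.call(load_case, config$load),
    friction_coefficient = config$contact$friction_coefficient,
    tissue = material_neo_hookean(
      elastic_constants(G = m$tissue_shear_modulus_kpa,
                        K = m$tissue_bulk_modulus_kpa), name = "soft_tissue"),
    bone = bone,
    mattress = material_linear_elastic(
      elastic_constants(E = m$mattress_youngs_modulus_kpa,
                        nu = m$mattress_poisson), name = "foam_mattress"),
    solid_fraction = m$dressing_solid_fraction,
    poisson = m$dressing_poisson)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
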