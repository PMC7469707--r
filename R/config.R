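# YAML run configuration: schema defaults, validation, and the pipeline
# driver behind the command-line entry point (inst/cli/edem.R).

#' Default run configuration
#'
#' The nested list mirrors the YAML schema. Material defaults are the
#' standard cartilage/ligament profile (E = 10.35 MPa, nu = 0.4247,
#' hT = 3.5 mm, Elig = 255 MPa); every entry can be overridden. Geometry
#' comes either from a synthetic fixture (`fixture`) or from mesh files
#' (`geometry`), and loading from a gait CSV or a synthetic profile.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    fixture = list(kind = "cylinder_congruent", extent = c(20, 20),
                   gap = 1.5, radius_talus = 20, radius_tibia = NULL,
                   arc_deg = 90, axis_length = 20, resolution = 800),
    geometry = list(talus = NULL, tibia = NULL, units_scale = 1),
    gait = list(csv = NULL, profile = "half_sine", n_frames = 21,
                peak_force = 2000, peak_angle = 0),
    material = list(E_cartilage = 10.35, nu = 0.4247, h_threshold = 3.5,
                    E_ligament = 255),
    ligaments = list(enabled = TRUE, fibre_area = 1, fibres_per_bundle = 5,
                     bilateral = FALSE, rotate_anchors = TRUE),
    solver = list(residual_tol = NULL, max_active_set_iterations = NULL,
                  stiffness_update = "lagged", removal_rule = "all_tensile"),
    method = "both",
    out_dir = "edem_out",
    log_level = "info",
    seed = 1
  )
}

.check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("config: '%s' must be a finite number", name))
  }
  if (positive && x <= 0) stop(sprintf("config: '%s' must be > 0", name))
  invisible(TRUE)
}

#' Validate a run configuration
#'
#' Merges the given configuration over [default_config()], rejecting unknown
#' keys at any nesting level and checking value ranges before any computation
#' runs.
#'
#' @param config nested named list (e.g. from [read_config()]).
#' @return the merged, validated configuration.
#' @export
validate_config <- function(config) {
  defaults <- default_config()
  check_keys <- function(given, template, path) {
    unknown <- setdiff(names(given), names(template))
    if (length(unknown)) {
      stop(sprintf("config: unknown key(s) %s under '%s'",
                   paste(sQuote(unknown), collapse = ", "), path))
    }
    for (k in names(given)) {
      if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
          !is.null(given[[k]])) {
        if (!is.list(given[[k]])) {
          stop(sprintf("config: '%s.%s' must be a mapping", path, k))
        }
        check_keys(given[[k]], template[[k]], paste(path, k, sep = "."))
      }
    }
  }
  check_keys(config, defaults, "config")
  merge <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
                       is.list(over[[k]])) {
        merge(base[[k]], over[[k]])
      } else {
        over[[k]]
      }
    }
    base
  }
  cfg <- merge(defaults, config)
  .check_scalar(cfg$material$E_cartilage, "material.E_cartilage", positive = TRUE)
  .check_scalar(cfg$material$h_threshold, "material.h_threshold", positive = TRUE)
  .check_scalar(cfg$material$E_ligament, "material.E_ligament", positive = TRUE)
  .check_scalar(cfg$material$nu, "material.nu")
  if (cfg$material$nu < 0 || cfg$material$nu >= 0.5) {
    stop("config: 'material.nu' must satisfy 0 <= nu < 0.5")
  }
  if (!cfg$method %in% c("edem", "dem", "both", "EDEM", "DEM")) {
    stop("config: 'method' must be one of edem, dem, both")
  }
  if (!cfg$gait$profile %in% c("half_sine", "table1_like")) {
    stop("config: 'gait.profile' must be half_sine or table1_like")
  }
  .check_scalar(cfg$gait$n_frames, "gait.n_frames", positive = TRUE)
  .check_scalar(cfg$gait$peak_force, "gait.peak_force")
  if (cfg$gait$peak_force < 0) stop("config: 'gait.peak_force' must be >= 0")
  if (!is.null(cfg$fixture$kind) &&
      !cfg$fixture$kind %in% c("flat_congruent", "cylinder_congruent",
                               "cylinder_incongruent", "flat_with_depressions")) {
    stop(sprintf("config: unknown fixture kind '%s'", cfg$fixture$kind))
  }
  if (!cfg$log_level %in% names(.log_levels)) {
    stop("config: 'log_level' must be debug, info or warn")
  }
  cfg
}

#' Read a YAML run configuration
#' @param path YAML file path.
#' @return the validated configuration.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  validate_config(yaml::read_yaml(path))
}

.config_geometry <- function(cfg) {
  if (!is.null(cfg$geometry$talus) && !is.null(cfg$geometry$tibia)) {
    talus <- load_surface(cfg$geometry$talus, cfg$geometry$units_scale)
    tibia <- load_surface(cfg$geometry$tibia, cfg$geometry$units_scale)
    talus <- orient_facing(talus, tibia)
    axis <- fit_cylinder_axis(talus)
    list(talus = talus, tibia = tibia, axis = axis, attachments = NULL)
  } else {
    fx <- cfg$fixture
    spec <- fixture_spec(kind = fx$kind, extent = fx$extent, gap = fx$gap,
                         radius_talus = fx$radius_talus,
                         radius_tibia = fx$radius_tibia, arc_deg = fx$arc_deg,
                         axis_length = fx$axis_length,
                         resolution = fx$resolution)
    make_joint(spec)
  }
}

.config_frames <- function(cfg) {
  if (!is.null(cfg$gait$csv)) {
    load_gait_csv(cfg$gait$csv)
  } else {
    make_gait_profile(cfg$gait$n_frames, cfg$gait$peak_force,
                      cfg$gait$peak_angle, shape = cfg$gait$profile)
  }
}

#' Run the full pipeline from a configuration
#'
#' Builds (or loads) the joint geometry, the loading frames and the ligament
#' bundles, runs the requested method(s), writes result CSVs and a
#' reproducibility manifest (`manifest.yaml`: the echoed configuration,
#' geometry fingerprints and the package version) into `out_dir`.
#'
#' @param config a configuration list; validated with [validate_config()].
#' @return invisibly, a list with the `stance_result`(s) and, when both
#'   methods run, their `method_comparison`.
#' @export
run_config <- function(config = default_config()) {
  cfg <- validate_config(config)
  old <- options(edem.log_level = cfg$log_level)
  on.exit(options(old))
  set.seed(cfg$seed %% .Machine$integer.max)
  geom <- .config_geometry(cfg)
  frames <- .config_frames(cfg)
  bundles <- NULL
  if (isTRUE(cfg$ligaments$enabled) && !is.null(geom$attachments)) {
    bundles <- make_bundles(geom$attachments,
                            material = do.call(material_params, cfg$material),
                            fibre_area = cfg$ligaments$fibre_area,
                            fibres_per_bundle = cfg$ligaments$fibres_per_bundle,
                            bilateral = cfg$ligaments$bilateral)
  }
  material <- do.call(material_params, cfg$material)
  sp <- solver_params(cfg$solver$residual_tol,
                      cfg$solver$max_active_set_iterations,
                      cfg$solver$stiffness_update, cfg$solver$removal_rule)
  methods <- switch(tolower(cfg$method), both = c("EDEM", "DEM"),
                    toupper(cfg$method))
  out <- list()
  for (m in methods) {
    edem_log("info", "running %s over %d frames", m, nrow(frames))
    res <- run_stance(geom$talus, geom$tibia, geom$axis, bundles, frames,
                      material, sp, method = m,
                      rotate_ligament_anchors = cfg$ligaments$rotate_anchors)
    write_results(res, cfg$out_dir)
    out[[tolower(m)]] <- res
  }
  if (length(methods) == 2L) {
    out$comparison <- compare_methods(out$edem, out$dem)
    .atomic_write_csv(out$comparison$per_frame,
                      file.path(cfg$out_dir, "comparison.csv"))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("edem")),
                   config = cfg,
                   geometry = list(talus = surface_fingerprint(geom$talus),
                                   tibia = surface_fingerprint(geom$tibia)))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(out)
}
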