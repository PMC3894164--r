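# Structured configuration, validation and run manifests.

#' Default configuration
#'
#' Full configuration tree with the production defaults for the force field,
#' integrator and protocols.  \code{\link{load_config}} merges a user file
#' over these values.
#'
#' @return Nested list with sections \code{forcefield}, \code{integrator}
#'   and \code{protocol}.
#' @export
default_config <- function() {
  list(
    forcefield = list(
      k_bond = 20, k_angle = 10, V1 = 0.5, V3 = 0.25, epsilon = 0.6,
      sigma_vdw = 4, eps_rep = 0.6, ionic_strength = 0.15,
      dielectric = 78.4, temperature = 298, viscosity = 8.9e-4,
      z_wall = 16.5, k_restraint = 5.0, k_wall = 5.0, r_short = 12.5,
      r_medium = 25, contact_form = "12-10-6"),
    integrator = list(
      timestep_fs = 125, list_interval_ps = 6, medium_interval_ps = 1,
      tensor_interval_ps = 24, snapshot_interval_ps = 100,
      check_interval_ps = 6, hydrodynamics = "free-draining",
      noise_scheme = "cholesky", tea_beta = 0.5, max_time_ns = 1000,
      pairlist_skin_A = 2),
    protocol = list(
      n_trajectories = 5, duration_us = 10, sample_interval_us = 0.1,
      n_trials = 100, timeout_ns = 5000, contact_gamma = 1.2,
      trigger_size = 9, nonproductive_threshold_A = 12,
      nonproductive_dwell_ns = 1, pH = 7.6, contact_cutoff = 5.5,
      proximity_radius_A = 40))
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, merges it over the defaults, rejects unknown
#' keys, and validates values (positive constants, known selectors).  An
#' empty file yields the full default configuration.
#'
#' @param path YAML file (or \code{NULL} for pure defaults).
#' @return Validated configuration list with class \code{gophos_config}.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    for (sec in names(user)) {
      if (!sec %in% names(cfg))
        stop("unknown configuration section: ", sec)
      for (key in names(user[[sec]])) {
        if (!key %in% names(cfg[[sec]]))
          stop("unknown configuration key: ", sec, ".", key)
        cfg[[sec]][[key]] <- user[[sec]][[key]]
      }
    }
  }
  validate_config(cfg)
  class(cfg) <- "gophos_config"
  cfg
}

validate_config <- function(cfg) {
  ffv <- cfg$forcefield
  num <- setdiff(names(ffv), "contact_form")
  bad <- num[!vapply(ffv[num], function(v)
    is.numeric(v) && is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("force-field values must be positive numbers: ",
         paste(bad, collapse = ", "))
  if (!ffv$contact_form %in% c("12-10-6", "12-10"))
    stop("contact_form must be '12-10-6' or '12-10'")
  iv <- cfg$integrator
  if (iv$timestep_fs <= 0) stop("timestep must be positive")
  if (!iv$hydrodynamics %in% c("free-draining", "tensor"))
    stop("hydrodynamics must be 'free-draining' or 'tensor'")
  invisible(TRUE)
}

#' Force field from a configuration
#' @param config a \code{gophos_config}.
#' @return A \code{go_forcefield}.
#' @export
config_forcefield <- function(config) {
  f <- config$forcefield
  go_forcefield(k_bond = f$k_bond, k_angle = f$k_angle, V1 = f$V1,
                V3 = f$V3, epsilon = f$epsilon, sigma_vdw = f$sigma_vdw,
                eps_rep = f$eps_rep, ionic_strength = f$ionic_strength,
                dielectric = f$dielectric, temperature = f$temperature,
                viscosity = f$viscosity, z_wall = f$z_wall,
                k_restraint = f$k_restraint, k_wall = f$k_wall,
                r_short = f$r_short, r_medium = f$r_medium,
                contact_form = f$contact_form)
}

#' Integrator configuration from a configuration
#' @param config a \code{gophos_config}.
#' @return A \code{bd_config}.
#' @export
config_integrator <- function(config) {
  i <- config$integrator
  bd_config(timestep_fs = i$timestep_fs,
            list_interval_ps = i$list_interval_ps,
            medium_interval_ps = i$medium_interval_ps,
            tensor_interval_ps = i$tensor_interval_ps,
            snapshot_interval_ps = i$snapshot_interval_ps,
            check_interval_ps = i$check_interval_ps,
            hydrodynamics = i$hydrodynamics,
            noise_scheme = i$noise_scheme, tea_beta = i$tea_beta,
            max_time_ns = i$max_time_ns,
            pairlist_skin_A = i$pairlist_skin_A)
}

#' Create a run manifest
#'
#' Immutable record binding a campaign output to its configuration snapshot,
#' package version, seeds and input hashes, so any output can be regenerated
#' from its manifest alone.
#'
#' @param config configuration list.
#' @param seeds named or plain vector of seeds used.
#' @param inputs named character vector of input descriptions/hashes.
#' @param outputs character vector of produced files.
#' @param path optional JSON file to write.
#' @return The manifest list (invisibly if written).
#' @export
run_manifest <- function(config, seeds, inputs = character(),
                         outputs = character(), path = NULL) {
  man <- list(package = "gophos",
              version = as.character(utils::packageVersion("gophos")),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = unclass(config), seeds = as.list(seeds),
              inputs = as.list(inputs), outputs = as.list(outputs))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(man))
  }
  man
}
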