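#' Run configuration
#'
#' One flat, serialisable structure holding every physical constant and
#' schedule setting that affects results -- no hidden defaults inside code
#' paths.  Round-trips losslessly through YAML.
#'
#' @param system either \code{list(kind = "synthetic", ...)} with
#'   [synthetic_system_spec()] arguments, or
#'   \code{list(kind = "pdb", path = , sidecar = )}
#' @param b_from,b_to,b_by the B ladder
#' @param padding GCMC box padding around the network oxygens (A)
#' @param droplet_radius,restraint_k droplet settings
#' @param cutoff,switch_width,temperature nonbonded settings
#' @param mu_ex,v0 bulk-water reference
#' @param n_repeats independent repeats
#' @param schedule named list of [move_schedule()] overrides
#' @param cluster_cutoff,occupancy_threshold,tpr_threshold analysis settings
#' @param seed master seed
#' @param stages which pipeline stages to run
#' @return an object of class \code{run_config}
#' @export
run_config <- function(system = list(kind = "synthetic", n_sites = 1),
                       b_from = -19, b_to = -7.5, b_by = 0.5,
                       padding = 1, droplet_radius = 30, restraint_k = 1.5,
                       cutoff = 10, switch_width = 0.5, temperature = 298,
                       mu_ex = -6.2, v0 = 30, n_repeats = 3,
                       schedule = list(),
                       cluster_cutoff = 2.4, occupancy_threshold = 0.30,
                       tpr_threshold = 1.5, seed = 1,
                       stages = c("simulate", "titrate", "cluster", "tpr")) {
  cfg <- structure(list(system = system, b_from = b_from, b_to = b_to,
                        b_by = b_by, padding = padding,
                        droplet_radius = droplet_radius,
                        restraint_k = restraint_k, cutoff = cutoff,
                        switch_width = switch_width, temperature = temperature,
                        mu_ex = mu_ex, v0 = v0, n_repeats = n_repeats,
                        schedule = schedule, cluster_cutoff = cluster_cutoff,
                        occupancy_threshold = occupancy_threshold,
                        tpr_threshold = tpr_threshold, seed = seed,
                        stages = stages),
                   class = "run_config")
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$b_from) || is.null(cfg$b_to) || is.null(cfg$b_by) ||
      cfg$b_from >= cfg$b_to)
    stop("config must define an ascending B ladder (b_from < b_to)")
  if (is.null(cfg$seed)) stop("config must carry a seed")
  stopifnot(cfg$n_repeats >= 1, cfg$padding >= 0)
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file
#' @return [read_run_config()]: a \code{run_config};
#'   [write_run_config()]: \code{path}, invisibly
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config a \code{run_config}
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Configuration hash
#'
#' Deterministic hash stamped into every results bundle, so outputs are
#' traceable to the exact configuration and seed that produced them.
#'
#' @param config a \code{run_config}
#' @return 8-hex-digit string
#' @export
config_hash <- function(config) {
  object_hash(unclass(config))
}
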