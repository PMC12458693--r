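#' Run the GCMC water-network pipeline
#'
#' Executes the requested stages -- simulate (B-ladder GCMC), titrate
#' (occupancy curve + network free energy), cluster (hydration sites at the
#' grid point nearest \eqn{B_{equil}}), tpr (comparison against crystal
#' waters) -- and returns a results bundle stamped with the configuration
#' hash, seed and package version.  Stochastic stages derive all randomness
#' from the config seed, so a rerun with the same config is identical.
#'
#' @param config a [run_config()]
#' @param model a \code{water_model}
#' @return an object of class \code{results_bundle}
#' @export
run_pipeline <- function(config, model = tip4p()) {
  config <- validate_run_config(config)
  params <- energy_params(cutoff = config$cutoff,
                          switch_width = config$switch_width,
                          temperature = config$temperature)
  ref <- bulk_water_reference(config$mu_ex, config$v0)

  if (identical(config$system$kind, "pdb")) {
    host <- read_host_pdb(config$system$path, config$system$sidecar)
    if (nrow(host$crystal_water_oxygens) == 0)
      stop("PDB host has no crystallographic waters to define the GCMC region")
    network <- host$crystal_water_oxygens
  } else {
    spec_args <- config$system[setdiff(names(config$system), "kind")]
    spec <- do.call(synthetic_system_spec, spec_args)
    host <- make_cage_host(spec, model, params)
    network <- host$crystal_water_oxygens
  }
  region <- simulation_region(gcmc_box_from_waters(network, config$padding),
                              droplet_radius = config$droplet_radius,
                              restraint_k = config$restraint_k)
  bundle <- list(config = config, config_hash = config_hash(config),
                 seed = config$seed,
                 version = as.character(utils::packageVersion("watnet")),
                 host = host, region = region, params = params, ref = ref)
  class(bundle) <- "results_bundle"

  if (!"simulate" %in% config$stages) return(bundle)
  schedule <- modify_schedule(move_schedule(), config$schedule)
  B <- seq(config$b_from, config$b_to, by = config$b_by)
  b_eq <- equilibrium_b(ref, region, params)
  ladder <- run_gcmc_ladder(host, model, region, params, B,
                            schedule = schedule, seed = config$seed,
                            n_repeats = config$n_repeats,
                            record_frames = TRUE)
  bundle$ladder <- ladder
  bundle$b_equil <- b_eq

  if ("titrate" %in% config$stages) {
    bundle$titration <- occupancy_curve(ladder)
    bundle$network <- gci_binding_free_energy(bundle$titration, region, ref,
                                              params, b_equil = b_eq)
  }
  if ("cluster" %in% config$stages) {
    i_eq <- which.min(abs(B - b_eq))
    trajs <- Filter(function(t) abs(t$B - B[i_eq]) < 1e-9, ladder$trajectories)
    frames <- do.call(rbind, lapply(seq_along(trajs), function(j) {
      f <- trajs[[j]]$frames
      if (nrow(f)) f[, 1] <- f[, 1] + (j - 1) * trajs[[j]]$n_frames
      f
    }))
    n_frames <- sum(vapply(trajs, function(t) t$n_frames, numeric(1)))
    sites <- cluster_water_sites(frames, cutoff = config$cluster_cutoff,
                                 n_frames = n_frames)
    bundle$sites <- filter_by_occupancy(sites, config$occupancy_threshold)
    bundle$sites_b <- B[i_eq]
  }
  if ("tpr" %in% config$stages && !is.null(bundle$sites)) {
    if (nrow(host$crystal_water_oxygens) > 0) {
      bundle$tpr <- true_positive_rate(bundle$sites,
                                       host$crystal_water_oxygens,
                                       config$tpr_threshold)
    }
  }
  bundle
}

#' Human-readable summary of a results bundle
#'
#' Prints whichever sections the bundle contains (titration table, network
#' free energy, hydration-site table, TPR, cycle diagram); missing sections
#' are skipped with a notice.
#'
#' @param bundle a \code{results_bundle} (or a list with any of the same
#'   components)
#' @param ... unused
#' @return \code{bundle}, invisibly
#' @export
report <- function(bundle, ...) {
  cat("== watnet results ==\n")
  if (!is.null(bundle$config_hash))
    cat("config", bundle$config_hash, " seed", bundle$seed,
        " version", bundle$version, "\n")
  if (!is.null(bundle$titration)) {
    cat("\n-- titration (occupancy vs B) --\n")
    print(bundle$titration)
  } else cat("\n[no titration section]\n")
  if (!is.null(bundle$network)) {
    cat("\n-- network binding free energy --\n")
    print(bundle$network)
  }
  if (!is.null(bundle$sites)) {
    cat("\n-- hydration sites (B =", bundle$sites_b, ") --\n")
    print.data.frame(as.data.frame(bundle$sites), row.names = FALSE, digits = 3)
  }
  if (!is.null(bundle$tpr)) {
    cat("\n-- crystal-water comparison --\n")
    print(bundle$tpr)
  }
  if (!is.null(bundle$cycle)) {
    cat("\n-- free-energy cycle --\n")
    print(bundle$cycle)
  }
  invisible(bundle)
}

#' @export
print.results_bundle <- function(x, ...) {
  report(x)
}

#' Export a bundle's numeric artifacts
#'
#' Writes titration curve (TSV), network free energy (JSON), hydration
#' sites (TSV + PDB) and TPR (JSON) into a directory, each stamped with the
#' config hash.
#'
#' @param bundle a \code{results_bundle}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
export_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = bundle$config_hash, seed = bundle$seed,
                version = bundle$version)
  if (!is.null(bundle$titration))
    write.table(as.data.frame(bundle$titration),
                file.path(dir, "titration.tsv"),
                row.names = FALSE, quote = FALSE, sep = "\t")
  if (!is.null(bundle$network))
    jsonlite::write_json(c(stamp, bundle$network[c("dg", "se", "n_equil",
                                                   "b_equil", "method")]),
                         file.path(dir, "network_free_energy.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$sites)) {
    write.table(as.data.frame(bundle$sites), file.path(dir, "sites.tsv"),
                row.names = FALSE, quote = FALSE, sep = "\t")
    write_sites_pdb(bundle$sites, file.path(dir, "sites.pdb"))
  }
  if (!is.null(bundle$tpr))
    jsonlite::write_json(c(stamp, bundle$tpr[c("tp", "fn", "tpr", "threshold")]),
                         file.path(dir, "tpr.json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(dir)
}
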