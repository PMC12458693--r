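#' Softcore parameters
#'
#' \code{delta} softens the Lennard-Jones core, \code{delta_c} the Coulomb
#' interaction; both keep partially decoupled particles finite at zero
#' distance.  \code{delta = 0.2} is the working default for all
#' transformations; \code{delta_c} is per-transformation (2.0-2.5 typical).
#'
#' @param delta LJ softcore parameter (>= 0, default 0.2)
#' @param delta_c Coulomb softcore parameter (>= 0, default 2.0)
#' @return an object of class \code{softcore_params}
#' @export
softcore_params <- function(delta = 0.2, delta_c = 2.0) {
  stopifnot(delta >= 0, delta_c >= 0)
  structure(list(delta = delta, delta_c = delta_c), class = "softcore_params")
}

#' Equally spaced lambda ladder
#' @param n number of windows (default 16), covering 0 and 1
#' @export
lambda_ladder <- function(n = 16) {
  stopifnot(n >= 2)
  seq(0, 1, length.out = n)
}

center_sites <- function(sites) {
  if (nrow(sites) == 0) {
    return(list(frame = matrix(numeric(0), ncol = 6), cog = c(0, 0, 0)))
  }
  m <- site_matrix(sites)
  cog <- colMeans(m[, 1:3, drop = FALSE])
  m[, 1:3] <- sweep(m[, 1:3, drop = FALSE], 2, cog)
  list(frame = m, cog = as.numeric(cog))
}

#' Dual-topology alchemical system
#'
#' Both end-state ligands are present; environment-B interactions are
#' weighted by \eqn{\lambda} and environment-A by \eqn{1-\lambda} through
#' softcore potentials, A-B cross interactions are excluded, and the two
#' copies are tied by a zero-rest-length harmonic "dummy bond" between
#' their centres of geometry with coupled rigid-body moves.
#'
#' @param ligand_a,ligand_b \code{particle_sites} tables in lab coordinates
#'   (an empty table is a null ligand)
#' @param region a \code{simulation_region}
#' @param params an \code{energy_params}
#' @param host optional \code{host_structure}; absent for the bulk leg
#' @param waters optional fixed-N starting waters ([water_matrix()]); their
#'   box membership is preserved during sampling (canonical leg)
#' @param environment \code{"waters-present"}, \code{"waters-absent"} or
#'   \code{"bulk"}
#' @param sc a [softcore_params()]
#' @param dummy_k dummy-bond force constant in kcal/mol/A^2 (default 10)
#' @param com_restraint flat-bottom harmonic holding each copy's centre of
#'   geometry near its starting point: \code{list(k = , radius = )} in
#'   kcal/mol/A^2 and Angstrom.  Keeps a weakly coupled pair from drifting
#'   out of the site (positional restraint, lambda-independent, cancels in
#'   the free-energy difference); \code{k = 0} disables it
#' @return an object of class \code{dual_topology_system}
#' @export
dual_topology_system <- function(ligand_a, ligand_b, region, params,
                                 host = NULL, waters = NULL,
                                 environment = c("waters-present",
                                                 "waters-absent", "bulk"),
                                 sc = softcore_params(), dummy_k = 10,
                                 com_restraint = list(k = 25, radius = 1.0)) {
  environment <- match.arg(environment)
  if (environment == "bulk" && !is.null(host))
    stop("the bulk leg has no host")
  if (environment == "waters-absent" && !is.null(waters) && nrow(waters) > 0)
    stop("waters-absent leg must start with no waters")
  a <- center_sites(ligand_a)
  b <- center_sites(ligand_b)
  # a null ligand keeps the partner's centre so the dummy bond starts at zero
  if (nrow(a$frame) == 0) a$cog <- b$cog
  if (nrow(b$frame) == 0) b$cog <- a$cog
  center <- (a$cog + b$cog) / 2
  structure(list(
    host = host, region = region, params = params,
    lig_a = a$frame, lig_b = b$frame,
    pose_a = c(a$cog, quat_identity()), pose_b = c(b$cog, quat_identity()),
    waters = waters %||% water_matrix(NULL),
    environment = environment, sc = sc, dummy_k = dummy_k,
    lig_restraint = c(center, com_restraint$k %||% 0,
                      com_restraint$radius %||% 0)),
    class = "dual_topology_system")
}

host_matrix_of <- function(system) {
  if (is.null(system$host)) {
    matrix(numeric(0), ncol = 6)
  } else {
    site_matrix(system$host$sites)
  }
}

#' Dual-topology potential at one lambda
#'
#' Full potential of the current configuration: environment terms
#' (host-water, water-water, restraints) plus softcore environment-ligand
#' terms weighted \eqn{(1-\lambda)} for A and \eqn{\lambda} for B, plus the
#' dummy bond.  At \eqn{\lambda = 0} ligand A is fully interacting and B a
#' ghost; at \eqn{\lambda = 1} the mirror case.
#'
#' @param system a [dual_topology_system()]
#' @param lambda coupling coordinate in [0, 1]
#' @param model a \code{water_model}
#' @param waters,pose_a,pose_b optional configuration overrides
#' @return energy in kcal/mol
#' @export
dual_topology_energy <- function(system, lambda, model = tip4p(),
                                 waters = NULL, pose_a = NULL, pose_b = NULL) {
  stopifnot(lambda >= 0, lambda <= 1)
  cpp_dual_topology_energy(
    host_matrix_of(system), unclass(model), params_vector(system$params),
    region_vector(system$region), waters %||% system$waters,
    system$lig_a, system$lig_b,
    pose_a %||% system$pose_a, pose_b %||% system$pose_b,
    lambda, system$sc$delta, system$sc$delta_c, system$dummy_k,
    system$lig_restraint)
}

#' Sampling schedule for an alchemical window
#'
#' @param n_equil equilibration moves per window
#' @param n_production production moves per window
#' @param sample_interval moves between samples
#' @param p_water probability of a water displacement move (the remainder
#'   are coupled ligand rigid-body moves); forced to 0 when the leg has no
#'   waters
#' @param max_translate,max_rotate water move steps (A, rad)
#' @param lig_max_translate,lig_max_rotate ligand move steps (A, rad)
#' @param sample_ligand propose coupled ligand rigid-body moves; set FALSE
#'   for cycle legs so the ligand pose stays identical to the rigid
#'   host-plus-ligand used by the GCMC network legs (see the methods
#'   vignette on cycle consistency)
#' @param swap_interval moves between lambda replica-exchange attempts
#' @return an object of class \code{alch_schedule}
#' @export
alch_schedule <- function(n_equil = 2000, n_production = 20000,
                          sample_interval = 20, p_water = 0.7,
                          max_translate = 0.25, max_rotate = 1.5,
                          lig_max_translate = 0.15, lig_max_rotate = pi / 8,
                          sample_ligand = TRUE, swap_interval = 2000) {
  stopifnot(p_water >= 0, p_water <= 1,
            n_production %% sample_interval == 0)
  structure(list(n_equil = n_equil, n_production = n_production,
                 sample_interval = sample_interval, p_water = p_water,
                 max_translate = max_translate, max_rotate = max_rotate,
                 lig_max_translate = lig_max_translate,
                 lig_max_rotate = lig_max_rotate,
                 sample_ligand = sample_ligand,
                 swap_interval = swap_interval),
            class = "alch_schedule")
}

alch_chunk <- function(system, config, lambda_sim, lambdas, schedule, n_moves,
                       sample_interval, rng_state, model) {
  cpp_alch_chunk(host_matrix_of(system), unclass(model),
                 params_vector(system$params), region_vector(system$region),
                 config$waters, system$lig_a, system$lig_b,
                 config$pose_a, config$pose_b, lambda_sim, lambdas,
                 system$sc$delta, system$sc$delta_c, system$dummy_k,
                 system$lig_restraint,
                 c(config$p_water, 1 - config$p_water),
                 schedule$max_translate, schedule$max_rotate,
                 schedule$lig_max_translate, schedule$lig_max_rotate,
                 as.integer(n_moves), as.integer(sample_interval), rng_state)
}

#' Sample an alchemical leg across a lambda ladder
#'
#' Canonical (fixed-N) Metropolis sampling in every window with
#' replica-exchange swaps between adjacent windows; at each sample the
#' reduced potential is evaluated at every window and stored for MBAR.
#'
#' @param system a [dual_topology_system()]
#' @param lambdas the ladder, e.g. [lambda_ladder()]
#' @param schedule an [alch_schedule()]
#' @param seed master seed (per-window streams are derived from it)
#' @param model a \code{water_model}
#' @param replica_exchange attempt swaps between adjacent windows
#' @return an object of class \code{alchemical_leg}: reduced-potential
#'   matrix \code{u_kn} (rows grouped by source window), per-window counts
#'   \code{n_k}, the ladder, \code{beta}, environment tag, and swap
#'   statistics
#' @export
run_alchemical_leg <- function(system, lambdas = lambda_ladder(),
                               schedule = alch_schedule(), seed = 1,
                               model = tip4p(), replica_exchange = TRUE) {
  stopifnot(length(lambdas) >= 2, !is.unsorted(lambdas),
            abs(lambdas[1]) < 1e-12, abs(lambdas[length(lambdas)] - 1) < 1e-12)
  K <- length(lambdas)
  sample_ligand <- schedule$sample_ligand %||% TRUE
  p_water <- if (!sample_ligand) 1
             else if (nrow(system$waters) == 0) 0
             else schedule$p_water
  configs <- lapply(seq_len(K), function(k) {
    list(waters = system$waters, pose_a = system$pose_a,
         pose_b = system$pose_b, p_water = p_water,
         rng = cpp_rng_create(seed, 5000 + k))
  })
  samples <- vector("list", K)

  # equilibration per window
  for (k in seq_len(K)) {
    res <- alch_chunk(system, configs[[k]], lambdas[k], lambdas, schedule,
                      schedule$n_equil, 0L, configs[[k]]$rng, model)
    configs[[k]]$waters <- res$waters
    configs[[k]]$pose_a <- res$poseA
    configs[[k]]$pose_b <- res$poseB
    configs[[k]]$rng <- res$rng_state
  }

  n_chunks <- if (replica_exchange && K > 1) {
    max(1, ceiling(schedule$n_production / schedule$swap_interval))
  } else 1
  base <- floor(schedule$n_production / n_chunks / schedule$sample_interval) *
    schedule$sample_interval
  chunk_moves <- rep(base, n_chunks)
  chunk_moves[n_chunks] <- chunk_moves[n_chunks] +
    schedule$n_production - sum(chunk_moves)
  swap_att <- swap_acc <- numeric(max(K - 1, 0))

  with_seed(derive_seed(seed, 888), {
    for (ch in seq_len(n_chunks)) {
      for (k in seq_len(K)) {
        res <- alch_chunk(system, configs[[k]], lambdas[k], lambdas, schedule,
                          chunk_moves[ch], schedule$sample_interval,
                          configs[[k]]$rng, model)
        configs[[k]]$waters <- res$waters
        configs[[k]]$pose_a <- res$poseA
        configs[[k]]$pose_b <- res$poseB
        configs[[k]]$rng <- res$rng_state
        samples[[k]] <- rbind(samples[[k]], res$u_kn)
      }
      if (replica_exchange && K > 1 && ch < n_chunks) {
        for (m in seq(1 + ch %% 2, K - 1, by = 2)) {
          nn <- m + 1
          swap_att[m] <- swap_att[m] + 1
          u_m <- reduced_of(system, configs[[m]], lambdas[c(m, nn)], model)
          u_n <- reduced_of(system, configs[[nn]], lambdas[c(m, nn)], model)
          delta <- u_m[2] + u_n[1] - u_m[1] - u_n[2]
          if (log(runif(1)) < -delta) {
            swap_acc[m] <- swap_acc[m] + 1
            keep <- c("waters", "pose_a", "pose_b")
            tmp <- configs[[m]][keep]
            configs[[m]][keep] <- configs[[nn]][keep]
            configs[[nn]][keep] <- tmp
          }
        }
      }
    }
  })

  u_kn <- do.call(rbind, samples)
  structure(list(u_kn = u_kn,
                 n_k = vapply(samples, function(s) nrow(s) %||% 0L, numeric(1)),
                 lambdas = lambdas, beta = system$params$beta,
                 environment = system$environment, seed = seed,
                 swap_attempted = swap_att, swap_accepted = swap_acc),
            class = "alchemical_leg")
}

reduced_of <- function(system, config, lambdas, model) {
  cpp_alch_reduced(host_matrix_of(system), unclass(model),
                   params_vector(system$params), region_vector(system$region),
                   config$waters, system$lig_a, system$lig_b,
                   config$pose_a, config$pose_b, lambdas,
                   system$sc$delta, system$sc$delta_c, system$dummy_k,
                   system$lig_restraint)
}

#' @export
print.alchemical_leg <- function(x, ...) {
  cat("<alchemical_leg>", length(x$lambdas), "windows,",
      nrow(x$u_kn) %||% 0, "samples, environment:", x$environment, "\n")
  invisible(x)
}
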