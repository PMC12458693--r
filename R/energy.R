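#' Nonbonded energy parameters
#'
#' @param cutoff nonbonded cutoff in Angstrom (default 10)
#' @param switch_width width of the energy switching window in Angstrom
#'   (default 0.5, i.e. the last 0.5 A before the cutoff)
#' @param temperature in Kelvin (default 298)
#' @param coulomb_constant in kcal A / (mol e^2)
#' @return an object of class \code{energy_params} with derived \code{kT}
#'   (kcal/mol) and \code{beta} (mol/kcal)
#' @export
energy_params <- function(cutoff = 10, switch_width = 0.5, temperature = 298,
                          coulomb_constant = 332.0637) {
  stopifnot(switch_width > 0, switch_width < cutoff, temperature > 0)
  kT <- k_boltzmann() * temperature
  structure(list(cutoff = cutoff, switch_width = switch_width,
                 temperature = temperature, coulomb_constant = coulomb_constant,
                 kT = kT, beta = 1 / kT),
            class = "energy_params")
}

params_vector <- function(params) {
  c(cutoff = params$cutoff, switch_width = params$switch_width,
    coulomb = params$coulomb_constant, beta = params$beta)
}

#' Energy switching factor
#'
#' CHARMM-style quintic-smooth energy switching applied over the last
#' \code{switch_width} Angstrom before the cutoff: 1 below the switch-on
#' radius, 0 at and beyond the cutoff, continuously differentiable at both
#' joins.
#'
#' @param r distances in Angstrom (vectorised)
#' @param params an \code{energy_params}
#' @return switching factors in [0, 1]
#' @export
switching_factor <- function(r, params = energy_params()) {
  rc <- params$cutoff
  ron <- rc - params$switch_width
  s <- ifelse(r <= ron, 1, ifelse(r >= rc, 0, {
    num <- (rc^2 - r^2)^2 * (rc^2 + 2 * r^2 - 3 * ron^2)
    num / (rc^2 - ron^2)^3
  }))
  as.numeric(s)
}

as_site_vector <- function(s) {
  if (is.data.frame(s)) {
    as.numeric(c(s$x[1], s$y[1], s$z[1], s$sigma[1], s$epsilon[1], s$charge[1]))
  } else {
    stopifnot(length(s) >= 6)
    as.numeric(s[1:6])
  }
}

#' Pairwise site-site energy
#'
#' Lennard-Jones (Lorentz-Berthelot combination) plus Coulomb, multiplied by
#' the switching factor.  Errors on exactly overlapping sites.
#'
#' @param site_a,site_b sites as \code{(x, y, z, sigma, epsilon, charge)}
#'   vectors or single-row \code{particle_sites}
#' @param params an \code{energy_params}
#' @return energy in kcal/mol
#' @export
pair_energy <- function(site_a, site_b, params = energy_params()) {
  cpp_pair_energy(as_site_vector(site_a), as_site_vector(site_b),
                  params_vector(params))
}

#' Softcore pairwise energy for alchemical coupling
#'
#' One-parameter softcore forms scaled by the coupling weight
#' \code{lambda_scale}: finite at zero distance for weights below 1,
#' reducing to [pair_energy()] at weight 1 and vanishing at weight 0.
#'
#' @inheritParams pair_energy
#' @param lambda_scale coupling weight in [0, 1]
#' @param sc a [softcore_params()]
#' @return energy in kcal/mol
#' @export
softcore_pair_energy <- function(site_a, site_b, lambda_scale,
                                 sc = softcore_params(),
                                 params = energy_params()) {
  stopifnot(lambda_scale >= 0, lambda_scale <= 1)
  cpp_softcore_pair_energy(as_site_vector(site_a), as_site_vector(site_b),
                           lambda_scale, sc$delta, sc$delta_c,
                           params_vector(params))
}

#' Droplet restraint energy of one water
#'
#' Half-harmonic: zero inside the droplet radius,
#' \eqn{k (d - R)^2 / 2} outside.
#'
#' @param water a \code{water_molecule}, or a length-3 oxygen position
#' @param region a \code{simulation_region}
#' @return energy in kcal/mol
#' @export
restraint_energy <- function(water, region) {
  o <- if (inherits(water, "water_molecule")) water$oxygen_position else as.numeric(water)
  d <- sqrt(sum((o - region$droplet_center)^2))
  if (d <= region$droplet_radius) return(0)
  0.5 * region$restraint_k * (d - region$droplet_radius)^2
}

#' Total potential energy of a configuration
#'
#' Host-water plus unique water-water pair energies plus droplet restraints.
#' Host-host terms are constant for a rigid host and excluded throughout.
#'
#' @param host a \code{host_structure}
#' @param waters an \code{n x 7} configuration matrix ([water_matrix()])
#' @param model a \code{water_model}
#' @param params an \code{energy_params}
#' @param region a \code{simulation_region}
#' @return energy in kcal/mol (+Inf on hard overlap)
#' @export
total_energy <- function(host, waters, model, params, region) {
  cpp_total_energy(site_matrix(host$sites), waters, unclass(model),
                   params_vector(params), region_vector(region))
}

#' Host-water interaction energy of a single water
#' @inheritParams total_energy
#' @param water a \code{water_molecule}
#' @return energy in kcal/mol (+Inf on hard overlap)
#' @export
host_water_energy <- function(host, water, model, params = energy_params()) {
  cpp_host_water_energy(site_matrix(host$sites), water$oxygen_position,
                        water$orientation, unclass(model), params_vector(params))
}

#' Water-water interaction energy
#' @param water_a,water_b \code{water_molecule}s
#' @inheritParams total_energy
#' @return energy in kcal/mol (+Inf on hard overlap)
#' @export
water_water_energy <- function(water_a, water_b, model, params = energy_params()) {
  cpp_water_water_energy(water_a$oxygen_position, water_a$orientation,
                         water_b$oxygen_position, water_b$orientation,
                         unclass(model), params_vector(params))
}
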