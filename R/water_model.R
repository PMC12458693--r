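#' Rigid water model
#'
#' A rigid 3- or 4-site water model: per-site offsets from the oxygen in the
#' molecular frame, per-site charges, and Lennard-Jones parameters carried by
#' the oxygen site only.  The molecule is rigid; geometry never changes
#' during simulation.
#'
#' @param site_offsets matrix (sites x 3) of displacements from the oxygen in
#'   Angstrom; the first row is the oxygen and must be zero
#' @param site_charges per-site charges in elementary charges; must sum to
#'   zero within 1e-10
#' @param oxygen_lj_sigma,oxygen_lj_epsilon LJ parameters of the oxygen site
#' @param name model name
#' @return an object of class \code{water_model}
#' @seealso [tip4p()]
#' @export
water_model <- function(site_offsets, site_charges, oxygen_lj_sigma,
                        oxygen_lj_epsilon, name = "custom") {
  site_offsets <- as.matrix(site_offsets)
  stopifnot(ncol(site_offsets) == 3,
            nrow(site_offsets) == length(site_charges),
            oxygen_lj_sigma >= 0, oxygen_lj_epsilon >= 0)
  if (any(abs(site_offsets[1, ]) > 1e-12))
    stop("the first site must be the oxygen at the molecular-frame origin")
  if (abs(sum(site_charges)) > 1e-10)
    stop("water model is not charge neutral (|total| > 1e-10 e)")
  structure(list(site_offsets = site_offsets,
                 site_charges = as.numeric(site_charges),
                 oxygen_lj_sigma = oxygen_lj_sigma,
                 oxygen_lj_epsilon = oxygen_lj_epsilon,
                 name = name),
            class = "water_model")
}

#' TIP4P rigid water
#'
#' Standard published TIP4P parameters: O-H 0.9572 A, H-O-H 104.52 deg,
#' M site 0.15 A along the bisector, q_H = +0.52 e, q_M = -1.04 e,
#' sigma_O = 3.15365 A, epsilon_O = 0.1550 kcal/mol.  The bisector points
#' along +z in the molecular frame with the hydrogens in the xz plane.
#'
#' @return a \code{water_model}
#' @export
tip4p <- function() {
  half <- (104.52 / 2) * pi / 180
  oh <- 0.9572
  off <- rbind(O = c(0, 0, 0),
               H1 = c(oh * sin(half), 0, oh * cos(half)),
               H2 = c(-oh * sin(half), 0, oh * cos(half)),
               M = c(0, 0, 0.15))
  water_model(off, c(0, 0.52, 0.52, -1.04), 3.15365, 0.1550, name = "tip4p")
}

#' Non-interacting "water" for ideal-gas reference runs
#'
#' Same geometry as TIP4P but all charges and LJ wells zero, so the grand
#' canonical ideal-gas law \eqn{\langle N \rangle = e^B} holds exactly.
#'
#' @return a \code{water_model}
#' @export
ideal_water_model <- function() {
  m <- tip4p()
  water_model(m$site_offsets, c(0, 0, 0, 0), m$oxygen_lj_sigma, 0,
              name = "ideal")
}

#' A single rigid water molecule
#'
#' @param oxygen_position length-3 oxygen coordinates (Angstrom, lab frame)
#' @param orientation unit quaternion (w, x, y, z) mapping the molecular
#'   frame to the lab frame; checked to unit norm within 1e-9
#' @return an object of class \code{water_molecule}
#' @export
water_molecule <- function(oxygen_position, orientation = quat_identity()) {
  stopifnot(length(oxygen_position) == 3, all(is.finite(oxygen_position)),
            length(orientation) == 4)
  if (abs(sqrt(sum(orientation^2)) - 1) > 1e-9)
    stop("orientation is not a unit quaternion (norm deviates by > 1e-9)")
  structure(list(oxygen_position = as.numeric(oxygen_position),
                 orientation = as.numeric(orientation)),
            class = "water_molecule")
}

#' Lab-frame site coordinates of a water molecule
#'
#' @param water a \code{water_molecule}
#' @param model a \code{water_model}
#' @return matrix (sites x 3) of lab coordinates
#' @export
water_sites <- function(water, model) {
  cpp_water_sites(water$oxygen_position, water$orientation, unclass(model))
}

#' Assemble a set of waters as a configuration matrix
#'
#' The engine represents a variable-size water set as an \code{n x 7} matrix:
#' oxygen x, y, z followed by the orientation quaternion (w, x, y, z).
#'
#' @param oxygens matrix (n x 3) of oxygen positions
#' @param quats matrix (n x 4) of orientations; identity if omitted
#' @return an \code{n x 7} configuration matrix
#' @export
water_matrix <- function(oxygens, quats = NULL) {
  if (is.null(oxygens) || length(oxygens) == 0)
    return(matrix(numeric(0), ncol = 7,
                  dimnames = list(NULL, c("x", "y", "z", "qw", "qx", "qy", "qz"))))
  oxygens <- matrix(as.numeric(oxygens), ncol = 3)
  n <- nrow(oxygens)
  if (is.null(quats)) quats <- matrix(rep(quat_identity(), n), ncol = 4, byrow = TRUE)
  quats <- matrix(as.numeric(quats), ncol = 4)
  stopifnot(nrow(quats) == n)
  out <- cbind(oxygens, quats)
  colnames(out) <- c("x", "y", "z", "qw", "qx", "qy", "qz")
  out
}
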