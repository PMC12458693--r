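#' Rigid interaction sites
#'
#' A table of rigid point sites carrying Lennard-Jones and point-charge
#' parameters.  Parametrisation (atom typing, charge derivation) is out of
#' scope: sites arrive numeric.
#'
#' @param position matrix (n x 3) of coordinates in Angstrom
#' @param lj_sigma,lj_epsilon LJ parameters (A, kcal/mol), recycled
#' @param charge charges in elementary charges, recycled
#' @param label free-text labels, recycled
#' @return a data frame of class \code{particle_sites} with columns
#'   \code{x, y, z, sigma, epsilon, charge, label}
#' @export
particle_sites <- function(position, lj_sigma = 0, lj_epsilon = 0,
                           charge = 0, label = "site") {
  position <- matrix(as.numeric(position), ncol = 3)
  n <- nrow(position)
  if (!all(is.finite(position))) stop("site positions must be finite")
  df <- data.frame(x = position[, 1], y = position[, 2], z = position[, 3],
                   sigma = rep_len(as.numeric(lj_sigma), n),
                   epsilon = rep_len(as.numeric(lj_epsilon), n),
                   charge = rep_len(as.numeric(charge), n),
                   label = rep_len(as.character(label), n),
                   stringsAsFactors = FALSE)
  if (any(df$sigma < 0) || any(df$epsilon < 0))
    stop("lj_sigma and lj_epsilon must be >= 0")
  class(df) <- c("particle_sites", "data.frame")
  df
}

site_matrix <- function(sites) {
  as.matrix(sites[, c("x", "y", "z", "sigma", "epsilon", "charge")])
}

rbind_sites <- function(...) {
  parts <- Filter(function(s) !is.null(s) && nrow(s) > 0, list(...))
  if (length(parts) == 0) return(particle_sites(matrix(numeric(0), ncol = 3))[0, ])
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("particle_sites", "data.frame")
  out
}

#' Rigid host structure
#'
#' The fixed environment a water network binds into: interaction sites plus
#' (optionally) crystallographic water oxygen positions kept for evaluation
#' only -- they never enter the energy.
#'
#' @param sites a \code{particle_sites} table (nonempty)
#' @param crystal_water_oxygens matrix (m x 3) of crystallographic water
#'   oxygen coordinates, or NULL
#' @return an object of class \code{host_structure}
#' @export
host_structure <- function(sites, crystal_water_oxygens = NULL) {
  if (is.null(sites) || nrow(sites) == 0)
    stop("host must have at least one interaction site")
  cw <- if (is.null(crystal_water_oxygens)) {
    matrix(numeric(0), ncol = 3)
  } else {
    matrix(as.numeric(crystal_water_oxygens), ncol = 3)
  }
  structure(list(sites = sites, crystal_water_oxygens = cw, rigid = TRUE),
            class = "host_structure")
}

#' @export
print.host_structure <- function(x, ...) {
  cat("<host_structure>", nrow(x$sites), "sites,",
      nrow(x$crystal_water_oxygens), "crystal waters\n")
  invisible(x)
}
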