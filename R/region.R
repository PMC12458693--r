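#' GCMC sampling box from water oxygen positions
#'
#' Axis-aligned bounding box around a set of oxygen coordinates with uniform
#' padding on every side, the convention used to define the insertion region
#' around a crystallographic water network.
#'
#' @param oxygen_positions matrix (n x 3) of coordinates in Angstrom (n >= 1)
#' @param padding padding in Angstrom (>= 0), default 1
#' @return an object of class \code{gcmc_box}: list with \code{min},
#'   \code{max} corners and \code{volume} in Angstrom^3
#' @export
gcmc_box_from_waters <- function(oxygen_positions, padding = 1) {
  if (is.null(oxygen_positions) || length(oxygen_positions) == 0)
    stop("need at least one oxygen position to define a GCMC box")
  pos <- matrix(as.numeric(oxygen_positions), ncol = 3)
  stopifnot(padding >= 0)
  lo <- apply(pos, 2, min) - padding
  hi <- apply(pos, 2, max) + padding
  vol <- prod(hi - lo)
  if (vol <= 0)
    stop("GCMC box has zero volume; increase padding or supply spread positions")
  structure(list(min = lo, max = hi, volume = vol), class = "gcmc_box")
}

#' Explicit GCMC box from corners
#' @param min,max length-3 corners in Angstrom
#' @export
gcmc_box <- function(min, max) {
  min <- as.numeric(min); max <- as.numeric(max)
  vol <- prod(max - min)
  if (!all(max > min)) stop("GCMC box must have max > min on every axis")
  structure(list(min = min, max = max, volume = vol), class = "gcmc_box")
}

#' Simulation region: solvent droplet plus GCMC box
#'
#' The droplet is a sphere of solvent held together by a half-harmonic
#' restraint acting on oxygens outside its radius (no periodic boundaries);
#' the GCMC box is where insertions and deletions happen and must lie
#' entirely inside the droplet.
#'
#' @param box a \code{gcmc_box}
#' @param droplet_center length-3 centre; defaults to the box centre
#' @param droplet_radius radius in Angstrom (default 30)
#' @param restraint_k half-harmonic force constant in kcal/mol/A^2
#'   (default 1.5); energy is \eqn{k (d-R)^2 / 2} outside the radius
#' @return an object of class \code{simulation_region}
#' @export
simulation_region <- function(box, droplet_center = NULL, droplet_radius = 30,
                              restraint_k = 1.5) {
  stopifnot(inherits(box, "gcmc_box"))
  center <- droplet_center %||% ((box$min + box$max) / 2)
  corners <- as.matrix(expand.grid(x = c(box$min[1], box$max[1]),
                                   y = c(box$min[2], box$max[2]),
                                   z = c(box$min[3], box$max[3])))
  d <- sqrt(rowSums(sweep(corners, 2, center)^2))
  if (any(d > droplet_radius))
    stop("GCMC box extends outside the droplet sphere")
  structure(list(droplet_center = as.numeric(center),
                 droplet_radius = droplet_radius,
                 restraint_k = restraint_k,
                 gcmc_box = box),
            class = "simulation_region")
}

region_vector <- function(region) {
  c(region$droplet_center, region$droplet_radius, region$restraint_k,
    region$gcmc_box$min, region$gcmc_box$max)
}

#' Is an oxygen inside the GCMC box?
#'
#' Membership uses the oxygen position only and a closed box on all sides:
#' a water occupies the region iff its oxygen is inside.
#'
#' @param points matrix (n x 3) of oxygen positions
#' @param region a \code{simulation_region} or \code{gcmc_box}
#' @return logical vector
#' @export
in_gcmc_box <- function(points, region) {
  box <- if (inherits(region, "simulation_region")) region$gcmc_box else region
  pts <- matrix(as.numeric(points), ncol = 3)
  pts[, 1] >= box$min[1] & pts[, 1] <= box$max[1] &
    pts[, 2] >= box$min[2] & pts[, 2] <= box$max[2] &
    pts[, 3] >= box$min[3] & pts[, 3] <= box$max[3]
}
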