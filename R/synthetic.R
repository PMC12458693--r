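#' Specification of a synthetic cage system
#'
#' Describes a rigid polar cavity holding a small cooperative water network
#' (designed hydration sites built from tripods of partial charges) and an
#' ordered ligand series that sequentially occludes sites, optionally adding
#' hydrogen-bond-like polar contacts to surviving sites.  Desk-scale
#' stand-in for a prepared binding-site complex.
#'
#' @param n_sites number of designed water sites (1-7)
#' @param site_positions matrix (n x 3) in Angstrom; default: a linear
#'   chain along x with 4.5 A spacing centred at the origin
#' @param well_depths target well depth per site in kcal/mol (negative),
#'   recycled; default -12
#' @param cage_radius distance from each site to its tripod particles in
#'   Angstrom (default 2.7)
#' @param ligand_series ordered list of occlusion specs; each element is a
#'   list with \code{blocks} (integer site indices occluded by that
#'   compound; later compounds must block supersets) and optional
#'   \code{polar} (named numeric: surviving-site index -> contact charge
#'   in e; positive charges act as hydrogen-bond-donor-like contacts that
#'   stabilise the caged water, whose solvent-exposed face is the oxygen)
#' @param occluder_charge charge on each occluding body (default -0.12 e,
#'   a mildly unfavourable replacement for a hydrogen-bonding neighbour:
#'   it repels the oxygen-side face the remaining waters expose)
#' @param polar_distance distance of a polar contact from its target site
#'   (default 2.9 A)
#' @param seed deterministic-build seed
#' @return an object of class \code{synthetic_system_spec}
#' @export
synthetic_system_spec <- function(n_sites = 3, site_positions = NULL,
                                  well_depths = -12, cage_radius = 2.7,
                                  ligand_series = list(),
                                  occluder_charge = -0.12,
                                  polar_distance = 2.9, seed = 1) {
  stopifnot(n_sites >= 1, n_sites <= 7)
  if (is.null(site_positions)) {
    xs <- (seq_len(n_sites) - (n_sites + 1) / 2) * 4.5
    site_positions <- cbind(xs, 0, 0)
  }
  site_positions <- matrix(as.numeric(site_positions), ncol = 3)
  stopifnot(nrow(site_positions) == n_sites)
  if (n_sites > 1) {
    dmin <- min(dist(site_positions))
    if (dmin < 3) stop("designed sites must be at least 3 A apart (closest: ",
                       round(dmin, 2), " A)")
  }
  well_depths <- rep_len(well_depths, n_sites)
  stopifnot(all(well_depths < 0))
  prev <- integer(0)
  for (i in seq_along(ligand_series)) {
    ls <- ligand_series[[i]]
    blocks <- as.integer(ls$blocks %||% integer(0))
    if (length(blocks) && (min(blocks) < 1 || max(blocks) > n_sites))
      stop("compound ", i, " occludes a nonexistent site")
    if (!all(prev %in% blocks))
      stop("occlusion specs must be nested: compound ", i,
           " must block a superset of compound ", i - 1)
    prev <- blocks
    pol <- ls$polar %||% numeric(0)
    if (length(pol)) {
      idx <- as.integer(names(pol))
      if (anyNA(idx) || any(idx < 1) || any(idx > n_sites))
        stop("polar contact names must be valid site indices")
      if (any(idx %in% blocks))
        stop("polar contacts must target surviving (non-blocked) sites")
    }
  }
  structure(list(n_sites = n_sites, site_positions = site_positions,
                 well_depths = well_depths, cage_radius = cage_radius,
                 ligand_series = ligand_series,
                 occluder_charge = occluder_charge,
                 polar_distance = polar_distance, seed = seed),
            class = "synthetic_system_spec")
}

tripod_directions <- function(axis_sign, twist) {
  alpha <- 25 * pi / 180
  phi <- c(90, 210, 330) * pi / 180 + twist
  t(vapply(phi, function(p) {
    c(sin(alpha) * cos(p), sin(alpha) * sin(p), axis_sign * cos(alpha))
  }, numeric(3)))
}

#' Locate and measure the energy minimum of a water near a position
#'
#' Scans a deterministic rotation set at \code{start}, then relaxes
#' position and orientation by Nelder-Mead.  Used to verify (and tune)
#' designed hydration sites.
#'
#' @param host a \code{host_structure}
#' @param start length-3 starting position
#' @param model a \code{water_model}
#' @param params an \code{energy_params}
#' @param n_orientations size of the orientation scan (default 96)
#' @param relax relax the position as well as the orientation
#' @param max_shift positional relaxation is confined to the local basin: a
#'   steep quadratic penalty activates beyond this offset from \code{start}
#'   (Angstrom), so the measurement cannot slide into a neighbouring site's
#'   well
#' @return list with \code{energy} (kcal/mol), \code{position},
#'   \code{orientation}
#' @export
site_well_minimum <- function(host, start, model = tip4p(),
                              params = energy_params(),
                              n_orientations = 96, relax = TRUE,
                              max_shift = 0.7) {
  hm <- site_matrix(host$sites)
  pv <- params_vector(params)
  quats <- super_fibonacci_rotations(n_orientations)
  e0 <- vapply(seq_len(n_orientations), function(i) {
    cpp_host_water_energy(hm, start, quats[i, ], unclass(model), pv)
  }, numeric(1))
  best <- which.min(e0)
  q0 <- quats[best, ]
  obj <- function(par) {
    pos <- start + if (relax) par[1:3] else c(0, 0, 0)
    rot <- par[4:6]
    ang <- sqrt(sum(rot^2))
    q <- if (ang < 1e-12) q0 else quat_multiply(quat_from_axis_angle(rot, ang), q0)
    q <- q / sqrt(sum(q^2))
    e <- cpp_host_water_energy(hm, pos, q, unclass(model), pv)
    off <- sqrt(sum((pos - start)^2))
    pen <- if (off > max_shift) 500 * (off - max_shift)^2 else 0
    if (!is.finite(e)) 1e6 else e + pen
  }
  fit <- optim(rep(0, 6), obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
  rot <- fit$par[4:6]
  ang <- sqrt(sum(rot^2))
  q <- if (ang < 1e-12) q0 else quat_multiply(quat_from_axis_angle(rot, ang), q0)
  list(energy = fit$value,
       position = start + if (relax) fit$par[1:3] else c(0, 0, 0),
       orientation = q / sqrt(sum(q^2)))
}

#' Build a synthetic cage host
#'
#' Each designed site gets a tripod of three partial charges at
#' \code{cage_radius} (plus soft LJ bodies preventing collapse); tripod
#' charges are tuned by bisection so that the relaxed well depth for a
#' water at each site hits the requested value within 0.2 kcal/mol, with
#' all other tripods present (passes repeat until self-consistent).
#' Tripod axes alternate between +z and -z along the site chain.  The
#' designed positions are stored as crystallographic water oxygens for
#' downstream evaluation.  Deterministic in \code{spec$seed}.
#'
#' @param spec a [synthetic_system_spec()]
#' @param model a \code{water_model}
#' @param params an \code{energy_params}
#' @param verify check that each relaxed minimum sits within 0.5 A of its
#'   designed position (build-time contract)
#' @return a \code{host_structure} with the spec attached as attribute
#'   \code{"spec"}
#' @export
make_cage_host <- function(spec, model = tip4p(), params = energy_params(),
                           verify = TRUE) {
  stopifnot(inherits(spec, "synthetic_system_spec"))
  n <- spec$n_sites
  twists <- with_seed(spec$seed, runif(n, 0, 0.3))
  # per site: three +q donors at cage_radius plus a -3q compensator on the
  # tripod axis, so each cage unit is net neutral and neighbouring sites do
  # not feel a monopole field (keeps well depths independently tunable)
  tripods <- lapply(seq_len(n), function(i) {
    ax <- if (i %% 2 == 1) 1 else -1
    dirs <- tripod_directions(ax, twists[i])
    rbind(sweep(dirs * spec$cage_radius, 2, spec$site_positions[i, ], "+"),
          spec$site_positions[i, ] + c(0, 0, ax * 2.5 * spec$cage_radius))
  })
  q <- rep(0.3, n)
  host_of <- function(q) {
    pos <- do.call(rbind, tripods)
    host_structure(particle_sites(pos, lj_sigma = 2.6, lj_epsilon = 0.30,
                                  charge = c(rbind(q, q, q, -3 * q)),
                                  label = "cage"),
                   crystal_water_oxygens = spec$site_positions)
  }
  depth_of <- function(host, i) {
    site_well_minimum(host, spec$site_positions[i, ], model, params,
                      n_orientations = 64)$energy
  }
  for (pass in 1:6) {
    worst <- 0
    for (i in seq_len(n)) {
      lo <- 0; hi <- 1.0
      target <- spec$well_depths[i]
      for (it in 1:18) {
        mid <- (lo + hi) / 2
        qi <- q; qi[i] <- mid
        d <- depth_of(host_of(qi), i)
        if (d > target) lo <- mid else hi <- mid
      }
      q[i] <- (lo + hi) / 2
      worst <- max(worst, abs(depth_of(host_of(q), i) - target))
    }
    if (worst <= 0.2) break
  }
  if (worst > 0.2)
    stop("could not tune tripod charges to the requested well depths ",
         "(worst deviation ", round(worst, 2), " kcal/mol)")
  host <- host_of(q)
  if (verify) {
    for (i in seq_len(n)) {
      m <- site_well_minimum(host, spec$site_positions[i, ], model, params)
      off <- sqrt(sum((m$position - spec$site_positions[i, ])^2))
      if (off > 0.5)
        stop("designed site ", i, " relaxed ", round(off, 2),
             " A away from its requested position")
    }
  }
  attr(host, "spec") <- spec
  attr(host, "tripod_charges") <- q
  host
}

#' Build the ligand series of a synthetic system
#'
#' Compound k carries one occluding body (soft LJ sphere with a small
#' negative charge) at each site it blocks, plus optional polar contact
#' particles near named surviving sites (positive, hydrogen-bond-donor-like
#' charges emulating scaffold atoms that make new interactions with the
#' remaining waters).  An empty \code{blocks} gives a null ligand (no
#' sites), standing for the parent compound.
#'
#' @param spec a [synthetic_system_spec()] with a nonempty
#'   \code{ligand_series}
#' @return list of \code{particle_sites} tables, one per compound
#' @export
make_ligand_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_system_spec"))
  lapply(spec$ligand_series, function(ls) {
    blocks <- as.integer(ls$blocks %||% integer(0))
    parts <- list()
    if (length(blocks) > 0) {
      parts <- c(parts, list(particle_sites(
        spec$site_positions[blocks, , drop = FALSE],
        lj_sigma = 3.2, lj_epsilon = 0.15,
        charge = spec$occluder_charge, label = "occluder")))
    }
    pol <- ls$polar %||% numeric(0)
    if (length(pol) > 0) {
      idx <- as.integer(names(pol))
      pos <- t(vapply(seq_along(idx), function(j) {
        p <- spec$site_positions[idx[j], ]
        dir <- if (length(blocks) > 0) {
          bp <- spec$site_positions[blocks, , drop = FALSE]
          nb <- bp[which.min(rowSums(sweep(bp, 2, p)^2)), ]
          (nb - p) / sqrt(sum((nb - p)^2))
        } else {
          c(0, 0, if (idx[j] %% 2 == 1) -1 else 1) # opposite the tripod
        }
        p + spec$polar_distance * dir
      }, numeric(3)))
      parts <- c(parts, list(particle_sites(
        pos, lj_sigma = 3.0, lj_epsilon = 0.10,
        charge = as.numeric(pol), label = "polar_contact")))
    }
    if (length(parts) == 0) {
      particle_sites(matrix(numeric(0), ncol = 3))
    } else {
      do.call(rbind_sites, parts)
    }
  })
}

#' Merge a ligand into a host
#'
#' The combined rigid environment used for GCMC legs in the presence of a
#' compound.  Crystal waters of blocked sites are dropped from the
#' evaluation set.
#'
#' @param host a \code{host_structure} from [make_cage_host()]
#' @param ligand a \code{particle_sites} table from [make_ligand_series()]
#' @param blocked integer site indices occluded by this ligand (their
#'   crystal waters are removed)
#' @return a \code{host_structure}
#' @export
host_with_ligand <- function(host, ligand, blocked = integer(0)) {
  cw <- host$crystal_water_oxygens
  if (length(blocked) > 0) cw <- cw[-blocked, , drop = FALSE]
  out <- host_structure(rbind_sites(host$sites, ligand), cw)
  attr(out, "spec") <- attr(host, "spec")
  out
}

#' Planted-site synthetic trajectory
#'
#' Fixture generator for hydration-site clustering: each frame includes
#' each site independently with its stated probability, jittered by an
#' isotropic Gaussian.  Deterministic in \code{seed}.
#'
#' @param sites matrix (n x 3) of site positions
#' @param occupancies per-site inclusion probabilities in [0, 1]
#' @param jitter isotropic Gaussian standard deviation in Angstrom
#' @param n_frames number of frames
#' @param seed RNG seed
#' @return a frames matrix (columns \code{frame, x, y, z}) with attribute
#'   \code{n_frames}
#' @export
planted_trajectory <- function(sites, occupancies, jitter, n_frames, seed = 1) {
  sites <- matrix(as.numeric(sites), ncol = 3)
  occupancies <- rep_len(occupancies, nrow(sites))
  stopifnot(all(occupancies >= 0), all(occupancies <= 1), n_frames >= 0)
  out <- with_seed(seed, {
    rows <- list()
    for (f in seq_len(n_frames)) {
      present <- which(runif(nrow(sites)) < occupancies)
      if (length(present) > 0) {
        pts <- sites[present, , drop = FALSE] +
          matrix(rnorm(3 * length(present), sd = jitter), ncol = 3)
        rows[[length(rows) + 1]] <- cbind(frame = f, pts)
      }
    }
    do.call(rbind, rows) %||% matrix(numeric(0), ncol = 4)
  })
  colnames(out) <- c("frame", "x", "y", "z")
  attr(out, "n_frames") <- n_frames
  out
}
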