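#' Exact grand-partition reference by grid enumeration
#'
#' Computes the grand partition function of waters in the GCMC box by
#' Riemann sums over a position grid times a deterministic low-discrepancy
#' orientation set, for occupancies N = 0..\code{max_n}:
#' \deqn{\Xi(B) = \sum_N e^{BN} \zeta_N,}
#' where \eqn{\zeta_N} is the configurational integral over N-water
#' placements (host-water and water-water Boltzmann factors) normalised by
#' \eqn{V^N N!} -- the same Adams normalisation the sampling engine uses,
#' so engine and oracle are directly comparable.  Returns exact
#' \eqn{\langle N \rangle(B)}, \eqn{\ln \Xi(B)} and the occupancy
#' distribution P(N).
#'
#' Water-water terms are enumerated exactly up to N = 3 over the states
#' covering \eqn{1 - }\code{tail_drop} of the one-body weight; dropped
#' low-weight states and any N > 3 enter through a non-interacting
#' completion (refinement-checked via \code{tail_drop}, the grid step and
#' the orientation count).  Enumeration guards error out rather than
#' silently truncating.
#'
#' @param host a \code{host_structure}
#' @param region a \code{simulation_region}
#' @param B vector of B values to evaluate
#' @param model a \code{water_model}
#' @param params an \code{energy_params}
#' @param max_n highest occupancy enumerated
#' @param spatial_step grid spacing in Angstrom (default 0.25)
#' @param n_orientations orientation-set size (default 256)
#' @param tail_drop one-body weight fraction allowed to drop from exact
#'   pair/triple enumeration (default 1e-3)
#' @param guard_states maximum kept states for pair enumeration
#' @return an object of class \code{oracle_result}
#' @export
grid_oracle <- function(host, region, B, model = tip4p(),
                        params = energy_params(), max_n = 3,
                        spatial_step = 0.25, n_orientations = 256,
                        tail_drop = 1e-3, guard_states = 60000) {
  box <- region$gcmc_box
  pts <- grid_points(box, spatial_step)
  quats <- super_fibonacci_rotations(n_orientations)
  res <- cpp_grid_oracle(site_matrix(host$sites), unclass(model),
                         params_vector(params), pts, quats,
                         as.numeric(B), as.integer(max_n), tail_drop,
                         guard_states)
  res$params <- params
  res$spatial_step <- spatial_step
  res$n_orientations <- n_orientations
  class(res) <- "oracle_result"
  res
}

grid_points <- function(box, step) {
  axes <- lapply(1:3, function(a) {
    ext <- box$max[a] - box$min[a]
    n <- max(1L, round(ext / step))
    box$min[a] + (seq_len(n) - 0.5) * ext / n
  })
  as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]]))
}

#' @export
print.oracle_result <- function(x, ...) {
  cat("<oracle_result>", length(x$B), "B values; states kept",
      x$n_kept, "of", x$n_states,
      sprintf("(dropped weight %.2g)\n", x$weight_dropped))
  invisible(x)
}

#' Exact network binding free energy from the oracle
#'
#' \eqn{-kT [\ln \Xi(B_{equil}) - \ln \Xi(B_{ref})]} with \eqn{B_{ref}} in
#' the empty-region limit: the same quantity grand canonical integration
#' estimates from sampled titration curves (the bulk-reference corrections
#' cancel at \eqn{B_{equil}}; see the methods vignette).  \eqn{\ln \Xi} is
#' spline-interpolated between evaluated B values.
#'
#' @param oracle an \code{oracle_result}
#' @param b_equil equilibrium B value
#' @param b_ref reference (empty-limit) B; defaults to the lowest
#'   evaluated B
#' @return free energy in kcal/mol
#' @export
oracle_binding_free_energy <- function(oracle, b_equil, b_ref = NULL) {
  b_ref <- b_ref %||% min(oracle$B)
  f <- splinefun(oracle$B, oracle$ln_xi, method = "natural")
  -oracle$params$kT * (f(b_equil) - f(b_ref))
}

#' Occupancy distribution P(N) at one B value
#'
#' @param oracle an \code{oracle_result}
#' @param B one of the evaluated B values
#' @return numeric vector P(0..max_n)
#' @export
oracle_pn <- function(oracle, B) {
  i <- which(abs(oracle$B - B) < 1e-9)
  if (length(i) != 1) stop("B = ", B, " was not evaluated by this oracle")
  p <- oracle$p_n[, i]
  names(p) <- 0:(length(p) - 1)
  p
}
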