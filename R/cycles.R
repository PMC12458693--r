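#' A free-energy value with uncertainty
#'
#' Light container for one leg of a cycle.
#'
#' @param dg free energy in kcal/mol
#' @param se uncertainty in kcal/mol (default 0)
#' @param label optional transformation label (used to check that two legs
#'   describe the same transformation)
#' @return an object of class \code{free_energy}
#' @export
free_energy <- function(dg, se = 0, label = NULL) {
  stopifnot(is.finite(dg), se >= 0)
  structure(list(dg = dg, se = se, label = label), class = "free_energy")
}

as_free_energy <- function(x) {
  if (inherits(x, "free_energy")) return(x)
  if (inherits(x, "network_free_energy")) return(free_energy(x$dg, x$se))
  if (is.list(x) && !is.null(x$dg)) return(free_energy(x$dg, x$se %||% 0, x$label))
  if (is.numeric(x) && length(x) == 1) return(free_energy(x))
  stop("cannot interpret this object as a free energy")
}

#' Thermodynamic cycle: two alchemical legs and two network legs
#'
#' Orientation convention (fixed here and printed in every report): the
#' horizontal legs are the alchemical transformation A -> B computed with
#' the retained water set present (\code{wet}, top) and absent (\code{dry},
#' bottom); the vertical legs are the binding free energies of the retained
#' water network in the presence of compound A (\code{network_a}) and of
#' compound B (\code{network_b}).  Traversing
#' dry-A -> wet-A -> wet-B -> dry-B -> dry-A gives the signed closure sum
#' \eqn{\Delta G_{net,A} + \Delta G_{wet} - \Delta G_{net,B} - \Delta G_{dry}}.
#'
#' All four legs must share temperature and the same retained water set
#' (the displaced water, if any, is excluded from both network legs; pass
#' the retained-set size explicitly).
#'
#' @param wet,dry alchemical legs as [free_energy()] (or anything
#'   [mbar_free_energy()] returned)
#' @param network_a,network_b \code{network_free_energy} objects (or
#'   \code{free_energy})
#' @param n_retained size of the retained (common) water set
#' @return an object of class \code{free_energy_cycle}
#' @export
free_energy_cycle <- function(wet, dry, network_a, network_b, n_retained = NA) {
  legs <- list(wet = as_free_energy(wet), dry = as_free_energy(dry),
               network_a = as_free_energy(network_a),
               network_b = as_free_energy(network_b))
  if (inherits(network_a, "network_free_energy") &&
      inherits(network_b, "network_free_energy") &&
      abs(network_a$b_equil - network_b$b_equil) > 1e-9)
    stop("network legs were computed at different B_equil")
  structure(c(legs, list(n_retained = n_retained)), class = "free_energy_cycle")
}

#' Cycle closure error
#'
#' Absolute value of the signed sum of the four legs around the cycle; zero
#' for perfectly consistent, converged simulations.  The uncertainty is the
#' root-sum-square of the leg uncertainties.
#'
#' @param cycle a [free_energy_cycle()]
#' @return list with \code{value} (kcal/mol, >= 0) and \code{se}
#' @export
closure_error <- function(cycle) {
  stopifnot(inherits(cycle, "free_energy_cycle"))
  signed <- cycle$wet$dg + cycle$network_a$dg - cycle$dry$dg - cycle$network_b$dg
  se <- sqrt(cycle$wet$se^2 + cycle$dry$se^2 +
               cycle$network_a$se^2 + cycle$network_b$se^2)
  list(value = abs(signed), signed = signed, se = se)
}

#' Net effect of the water network on a transformation
#'
#' \eqn{\Delta G_{wet} - \Delta G_{dry}}: positive means the network
#' opposes the transformation (it is more favourable with the waters
#' removed).  By the cycle identity this equals the difference of the two
#' network legs up to the closure error.
#'
#' @param cycle a [free_energy_cycle()]
#' @return list with \code{dg}, \code{se} and the sign convention note
#' @export
solvent_contribution <- function(cycle) {
  stopifnot(inherits(cycle, "free_energy_cycle"))
  list(dg = cycle$wet$dg - cycle$dry$dg,
       se = sqrt(cycle$wet$se^2 + cycle$dry$se^2),
       convention = "positive = network opposes the A->B transformation")
}

#' Relative binding free energy from bound and solvent legs
#'
#' \eqn{\Delta\Delta G_{bind} = \Delta G_{bound} - \Delta G_{solvent}} for
#' the same transformation sampled in the complex and in bulk solvent.
#'
#' @param leg_bound,leg_solvent [free_energy()] values (labels, when
#'   present, must match)
#' @return list with \code{ddg} and \code{se} (kcal/mol)
#' @export
relative_binding_free_energy <- function(leg_bound, leg_solvent) {
  b <- as_free_energy(leg_bound); s <- as_free_energy(leg_solvent)
  if (!is.null(b$label) && !is.null(s$label) && !identical(b$label, s$label))
    stop("legs describe different transformations: ", b$label, " vs ", s$label)
  list(ddg = b$dg - s$dg, se = sqrt(b$se^2 + s$se^2))
}

#' @export
print.free_energy_cycle <- function(x, ...) {
  fmt <- function(l) sprintf("%+.2f +/- %.2f", l$dg, l$se)
  cl <- closure_error(x)
  cat("<free_energy_cycle>  (kcal/mol)\n")
  cat(sprintf("   A(wet) --- %s ---> B(wet)\n", fmt(x$wet)))
  cat(sprintf("     ^                              ^\n"))
  cat(sprintf("  %s (net A)     %s (net B)\n", fmt(x$network_a), fmt(x$network_b)))
  cat(sprintf("     |        [closure %.2f]        |\n", cl$value))
  cat(sprintf("   A(dry) --- %s ---> B(dry)\n", fmt(x$dry)))
  cat("  convention: closure = |wet + net_A - dry - net_B|\n")
  invisible(x)
}
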