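test_that("softcore potentials hit both endpoint limits and stay finite", {
  a <- c(0, 0, 0, 3.0, 0.2, 0.3)
  b <- c(3.2, 0, 0, 3.1, 0.15, -0.4)
  sc <- softcore_params(0.2, 2.0)
  expect_equal(softcore_pair_energy(a, b, 1, sc, P298),
               pair_energy(a, b, P298), tolerance = 1e-10)
  expect_identical(softcore_pair_energy(a, b, 0, sc, P298), 0)
  # finite at r = 0 for any lambda_scale < 1
  b0 <- c(0, 0, 0, 3.1, 0.15, -0.4)
  for (w in c(0.1, 0.5, 0.9)) {
    e <- softcore_pair_energy(a, b0, w, sc, P298)
    expect_true(is.finite(e))
    # closed form with (r/sigma)^6 = 0
    sig <- (3.0 + 3.1) / 2; eps <- sqrt(0.2 * 0.15)
    lj <- 4 * eps * w * (1 / (0.2 * (1 - w))^2 - 1 / (0.2 * (1 - w)))
    cou <- 332.0637 * 0.3 * (-0.4) * w / sqrt(2.0 * (1 - w))
    expect_equal(e, lj + cou, tolerance = 1e-9)
  }
})

test_that("softcore LJ core is continuous and monotone in the coupling weight", {
  a <- c(0, 0, 0, 3.0, 0.2, 0)
  for (r in c(0.5, 1.5, 2.5)) { # inside the repulsive core (r < sigma)
    b <- c(r, 0, 0, 3.0, 0.2, 0)
    w <- seq(0.01, 1, by = 0.01)
    e <- vapply(w, function(wi) softcore_pair_energy(a, b, wi,
                                                     softcore_params(), P298),
                numeric(1))
    expect_true(all(is.finite(e)))
    expect_true(all(diff(e) > 0))
  }
})

test_that("MBAR solves identical windows exactly and the harmonic closed form", {
  # two identical states: dG = 0 exactly
  set.seed(4)
  u <- matrix(rexp(400), ncol = 2)
  u[, 2] <- u[, 1]
  fit <- mbar(u, c(100, 100))
  expect_equal(fit$f[2], 0, tolerance = 1e-12)

  # harmonic wells k and 4k at 298 K: dG = kT/2 ln 4
  set.seed(1)
  kT <- P298$kT; n <- 20000
  x <- c(rnorm(n, 0, sqrt(kT / 1)), rnorm(n, 0, sqrt(kT / 4)))
  u_kn <- cbind(P298$beta * 1 / 2 * x^2, P298$beta * 4 / 2 * x^2)
  fit <- mbar(u_kn, c(n, n))
  expect_equal((fit$f[2] - fit$f[1]) * kT, kT / 2 * log(4), tolerance = 0.02)
  expect_true(fit$converged)
})

test_that("two-window MBAR coincides with the Bennett acceptance ratio", {
  set.seed(2)
  n <- 3000
  x <- c(rnorm(n, 0, 1), rnorm(n, 0.8, 1.3))
  u_kn <- cbind(x^2 / 2, (x - 0.8)^2 / (2 * 1.3^2) + 0.6 * x)
  fit <- mbar(u_kn, c(n, n), tol = 1e-12)
  w_f <- u_kn[1:n, 2] - u_kn[1:n, 1]
  w_r <- u_kn[n + 1:n, 1] - u_kn[n + 1:n, 2]
  expect_equal(fit$f[2] - fit$f[1], bar_free_energy(w_f, w_r),
               tolerance = 1e-6)
})

test_that("MBAR matches a brute-force partition-function ratio on discrete states", {
  # enumerable two-state system: microstates j = 1..6 with fixed reduced
  # energies; exact dF from the partition sums, samples drawn exactly
  u0 <- c(0.0, 0.7, 1.5, 2.2, 3.0, 4.0)
  u1 <- c(2.5, 1.2, 0.4, 0.9, 1.8, 2.6)
  exact <- -log(sum(exp(-u1))) + log(sum(exp(-u0)))
  set.seed(6)
  n <- 60000
  j0 <- sample(6, n, replace = TRUE, prob = exp(-u0))
  j1 <- sample(6, n, replace = TRUE, prob = exp(-u1))
  u_kn <- rbind(cbind(u0[j0], u1[j0]), cbind(u0[j1], u1[j1]))
  fit <- mbar(u_kn, c(n, n))
  expect_lt(abs((fit$f[2] - fit$f[1]) - exact), 0.02)
})

test_that("MBAR warns and flags divergence when windows share no overlap", {
  u_kn <- rbind(cbind(rep(0, 50), rep(500, 50)),
                cbind(rep(500, 50), rep(0, 50)))
  expect_warning(fit <- mbar(u_kn, c(50, 50), max_iter = 200), "overlap")
  expect_true(fit$divergent)
})

test_that("dual-topology endpoints equal single-ligand references", {
  spec <- synthetic_system_spec(n_sites = 1, well_depths = -10, seed = 4)
  host <- make_cage_host(spec, verify = FALSE)
  reg <- simulation_region(gcmc_box_from_waters(host$crystal_water_oxygens, 1))
  ligA <- particle_sites(matrix(c(0, 3.5, 0), 1), 3.0, 0.15, 0.1)
  ligB <- particle_sites(matrix(c(0.4, 3.6, 0), 1), 3.3, 0.2, -0.25)
  wat <- water_matrix(matrix(c(0, 0.1, 0), 1))
  # dummy bond off so the endpoint equals the bare single-ligand reference
  # (the bond is a constant offset fixed by the two centres of geometry)
  sys <- dual_topology_system(ligA, ligB, reg, P298, host = host,
                              waters = wat, dummy_k = 0,
                              com_restraint = list(k = 0, radius = 0))
  sysA <- dual_topology_system(ligA, ligA, reg, P298, host = host,
                               waters = wat, dummy_k = 0,
                               com_restraint = list(k = 0, radius = 0))
  sysB <- dual_topology_system(ligB, ligB, reg, P298, host = host,
                               waters = wat, dummy_k = 0,
                               com_restraint = list(k = 0, radius = 0))
  expect_equal(dual_topology_energy(sys, 0), dual_topology_energy(sysA, 0),
               tolerance = 1e-10)
  expect_equal(dual_topology_energy(sys, 1), dual_topology_energy(sysB, 1),
               tolerance = 1e-10)
  expect_error(dual_topology_system(ligA, ligB, reg, P298,
                                    environment = "bulk", host = host),
               "no host")
})

test_that("legs are reproducible, empty at zero production, and swap freely
           when all windows share one potential", {
  spec <- synthetic_system_spec(n_sites = 1, well_depths = -10, seed = 4)
  host <- make_cage_host(spec, verify = FALSE)
  reg <- simulation_region(gcmc_box_from_waters(host$crystal_water_oxygens, 1))
  lig <- particle_sites(matrix(c(0, 3.5, 0), 1), 3.0, 0.15, 0.1)
  sysN <- dual_topology_system(lig, lig, reg, P298, host = host,
                               environment = "waters-absent")
  sch <- alch_schedule(n_equil = 200, n_production = 2000, sample_interval = 10,
                       swap_interval = 500)
  leg1 <- run_alchemical_leg(sysN, lambda_ladder(4), sch, seed = 8)
  leg2 <- run_alchemical_leg(sysN, lambda_ladder(4), sch, seed = 8)
  expect_identical(leg1$u_kn, leg2$u_kn)
  # identical ligands: every window has the same potential -> swaps certain
  expect_equal(leg1$swap_accepted, leg1$swap_attempted)
  # null transformation estimates zero
  expect_equal(mbar_free_energy(leg1, n_boot = 0)$dg, 0, tolerance = 1e-9)
  # zero production
  leg0 <- run_alchemical_leg(sysN, lambda_ladder(4),
                             alch_schedule(n_equil = 100, n_production = 0,
                                           sample_interval = 10), seed = 8)
  expect_equal(nrow(leg0$u_kn), 0)
})
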