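fake_traj <- function(B, N, repeat_id = 1) {
  structure(list(N = N, U = numeric(length(N)),
                 frames = matrix(numeric(0), ncol = 4),
                 n_frames = length(N), B = B, repeat_id = repeat_id),
            class = "gcmc_trajectory")
}

test_that("occupancy curves pool repeats with the stated standard error", {
  tr <- list(fake_traj(-2, rep(5, 100)), fake_traj(-1, rep(5, 100)))
  cv <- occupancy_curve(tr)
  expect_equal(cv$mean, c(5, 5))
  expect_equal(cv$se, c(0, 0))

  tr3 <- list(fake_traj(-1, rep(4, 10), 1), fake_traj(-1, rep(5, 10), 2),
              fake_traj(-1, rep(6, 10), 3))
  cv3 <- occupancy_curve(tr3)
  expect_equal(cv3$mean, 5)
  expect_equal(cv3$se, 1 / sqrt(3), tolerance = 1e-12)

  expect_error(occupancy_curve(list(fake_traj(-1, 1:5, 1),
                                    fake_traj(-2, 1:5, 2))), "mismatched")
})

test_that("equilibrium B follows beta*mu_ex + ln(V/V0)", {
  reg240 <- simulation_region(gcmc_box(c(0, 0, 0), c(10, 6, 4))) # V = 240
  b240 <- equilibrium_b(bulk_water_reference(-6.2, 30), reg240, P298)
  expect_equal(b240, -6.2 / P298$kT + log(240 / 30), tolerance = 1e-12)
  expect_equal(b240, -8.39, tolerance = 0.01) # -6.2/0.59219 + ln 8
  reg <- simulation_region(gcmc_box(c(0, 0, 0), c(2, 2, 2))) # V = 8
  b <- equilibrium_b(bulk_water_reference(-6.2, 30), reg, P298)
  expect_equal(b, -6.2 / P298$kT + log(8 / 30), tolerance = 1e-12)
  # mu_ex = 0 and V = V0 -> 0
  reg30 <- simulation_region(gcmc_box(c(0, 0, 0), c(30, 1, 1) * c(1, 1, 1)),
                             droplet_radius = 40)
  expect_equal(equilibrium_b(bulk_water_reference(0, 30), reg30, P298), 0)
  # doubling the box volume raises B_equil by ln 2
  reg2 <- simulation_region(gcmc_box(c(0, 0, 0), c(4, 2, 2)), droplet_radius = 30)
  expect_equal(equilibrium_b(bulk_water_reference(), reg2, P298) -
                 equilibrium_b(bulk_water_reference(), reg, P298),
               log(2), tolerance = 1e-12)
})

test_that("ideal-gas grand-potential integral matches the analytic value", {
  B <- seq(-6, 0, by = 0.05)
  cv <- titration_curve(B, exp(B))
  got <- grand_potential_change(cv, -5, 0, P298)
  expect_equal(got, -P298$kT * (exp(0) - exp(-5)), tolerance = 0.002 * 0.59)
})

test_that("GCI demands an empty low-B limit and coverage of B_equil", {
  reg <- simulation_region(gcmc_box(c(0, 0, 0), c(2, 2, 2)))
  ref <- bulk_water_reference()
  B <- seq(-19, -7.5, by = 0.5)
  # curve that never empties
  cv_bad <- titration_curve(B, 0.5 + 0 * B)
  expect_error(gci_binding_free_energy(cv_bad, reg, ref, P298), "lowest B")
  # curve that stops below B_equil
  Bshort <- seq(-19, -15, by = 0.5)
  cv_short <- titration_curve(Bshort, exp(Bshort - -17) / (1 + exp(Bshort - -17)))
  expect_error(gci_binding_free_energy(cv_short, reg, ref, P298), "extend the ladder")
  # flat zero curve: empty network flagged, zero integral
  cv0 <- titration_curve(B, 0 * B)
  nfe <- gci_binding_free_energy(cv0, reg, ref, P298)
  expect_true(nfe$empty)
  expect_equal(nfe$n_equil, 0)
  expect_equal(nfe$dg, 0)
})

test_that("trapezoid and logistic integration agree on dense smooth curves", {
  reg <- simulation_region(gcmc_box(c(0, 0, 0), c(2, 2, 2)))
  ref <- bulk_water_reference()
  B <- seq(-19, -7.5, by = 0.1)
  occ <- 1 / (1 + exp(-(B + 14)))
  occ3 <- cbind(occ, occ, occ)
  cv <- titration_curve(B, occ3)
  g1 <- gci_binding_free_energy(cv, reg, ref, P298, method = "trapezoid")
  g2 <- gci_binding_free_energy(cv, reg, ref, P298, method = "logistic")
  expect_equal(g1$method, "trapezoid")
  expect_equal(g2$method, "logistic")
  expect_lt(abs(g1$dg - g2$dg), 0.05)
})

test_that("a host with no attractive sites gives no spurious stabilization", {
  # purely repulsive "host": LJ body in the middle of the box
  host <- host_structure(particle_sites(matrix(c(1, 1, 1), 1),
                                        lj_sigma = 3.2, lj_epsilon = 0.2))
  reg <- simulation_region(gcmc_box(c(0, 0, 0), c(2, 2, 2)))
  lad <- run_gcmc_ladder(host, tip4p(), reg, P298, b_ladder(),
                         schedule = move_schedule(n_production = 20000,
                                                  sample_interval = 50,
                                                  n_equil_region = 2000,
                                                  n_equil_all = 0),
                         seed = 3, n_repeats = 2)
  nfe <- gci_binding_free_energy(occupancy_curve(lad), reg,
                                 bulk_water_reference(), P298)
  expect_gte(nfe$dg, 0)
})

test_that("relative network stability propagates errors and signs", {
  a <- structure(list(dg = -14.5, se = 0.6, b_equil = -8), class = "network_free_energy")
  b <- structure(list(dg = -8.5, se = 0.8, b_equil = -8), class = "network_free_energy")
  d <- relative_network_stability(a, b)
  expect_equal(d$ddg, 6.0)
  expect_equal(d$se, 1.0)
  # a = b -> 0 with pooled error
  d0 <- relative_network_stability(a, a)
  expect_equal(d0$ddg, 0)
  expect_equal(d0$se, sqrt(2) * 0.6)
  b2 <- structure(list(dg = -8.5, se = 0.8, b_equil = -9), class = "network_free_energy")
  expect_error(relative_network_stability(a, b2), "different B_equil")
})
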