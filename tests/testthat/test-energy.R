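test_that("pair energy reproduces hand-computed LJ and Coulomb values", {
  # LJ minimum: equal sigmas, eps 0.2, r = 2^(1/6) sigma -> -eps
  a <- c(0, 0, 0, 3.0, 0.2, 0)
  b <- c(2^(1 / 6) * 3.0, 0, 0, 3.0, 0.2, 0)
  expect_equal(pair_energy(a, b, P298), -0.2, tolerance = 1e-12)
  # bare Coulomb at 3 A, inside the switch-free zone
  a <- c(0, 0, 0, 0, 0, 0.52)
  b <- c(3, 0, 0, 0, 0, -1.04)
  expect_equal(pair_energy(a, b, P298), 332.0637 * 0.52 * (-1.04) / 3,
               tolerance = 1e-12)
  # beyond cutoff -> exactly zero
  expect_identical(pair_energy(c(0, 0, 0, 3, 0.2, 0.5),
                               c(10.5, 0, 0, 3, 0.2, 0.5), P298), 0)
  expect_error(pair_energy(a, a, P298), "zero distance")
  # symmetry
  a <- c(0.3, -1, 2, 3.1, 0.12, 0.3); b <- c(2.5, 0.4, 1.2, 2.8, 0.2, -0.2)
  expect_equal(pair_energy(a, b, P298), pair_energy(b, a, P298),
               tolerance = 1e-12)
})

test_that("switching factor is 1/0 at the joins and smooth in between", {
  expect_equal(switching_factor(c(0, 9.5), P298), c(1, 1))
  expect_equal(switching_factor(c(10, 12), P298), c(0, 0))
  mid <- switching_factor(9.75, P298)
  expect_gt(mid, 0); expect_lt(mid, 1)
  # monotone decrease over the window, matching the compiled path
  r <- seq(9.5, 10, by = 0.01)
  s <- switching_factor(r, P298)
  expect_true(all(diff(s) <= 0))
  s_cpp <- vapply(r, function(ri) ref_switch(ri, P298), numeric(1))
  expect_equal(s, s_cpp, tolerance = 1e-12)
  # approximately C1 at both joins (finite-difference slope -> 0)
  eps <- 1e-6
  expect_lt(abs(switching_factor(9.5 + eps, P298) - 1) / eps, 1e-3)
  expect_lt(abs(switching_factor(10 - eps, P298)) / eps, 1e-3)
})

test_that("droplet restraint follows the half-harmonic k(d-R)^2/2 convention", {
  reg <- simulation_region(gcmc_box(c(-1, -1, -1), c(1, 1, 1)),
                           droplet_radius = 30, restraint_k = 1.5)
  expect_equal(restraint_energy(c(25, 0, 0), reg), 0)
  expect_equal(restraint_energy(c(31, 0, 0), reg), 0.75)
  expect_equal(restraint_energy(c(32, 0, 0), reg), 3.0)
})

test_that("compiled total energy matches the pure-R brute-force oracle", {
  m <- tip4p()
  spec <- synthetic_system_spec(n_sites = 1, well_depths = -6, seed = 8)
  host <- make_cage_host(spec, verify = FALSE)
  box <- gcmc_box(c(-3, -3, -3), c(3, 3, 3))
  reg <- simulation_region(gcmc_box(c(-1, -1, -1), c(1, 1, 1)),
                           droplet_radius = 5, restraint_k = 1.5)
  for (seed in 1:5) {
    w <- rand_waters(6, box, seed)
    expect_equal(total_energy(host, w, m, P298, reg),
                 ref_total_energy(host, w, m, P298, reg), tolerance = 1e-8)
  }
})

test_that("energy is invariant under global translation and rotation", {
  m <- tip4p()
  host <- host_structure(particle_sites(rbind(c(0, 0, 0), c(2.8, 0.5, -0.3)),
                                        lj_sigma = 3.0, lj_epsilon = 0.2,
                                        charge = c(0.3, -0.3)))
  box <- gcmc_box(c(-4, -4, -4), c(4, 4, 4))
  reg <- simulation_region(gcmc_box(c(-1, -1, -1), c(1, 1, 1)),
                           droplet_radius = 6)
  w <- rand_waters(5, gcmc_box(c(-3, -3, -3), c(3, 3, 3)), 42)
  e0 <- total_energy(host, w, m, P298, reg)

  shift <- c(11.3, -7.2, 4.4)
  host_t <- host_structure(particle_sites(
    t(t(rbind(c(0, 0, 0), c(2.8, 0.5, -0.3))) + shift),
    lj_sigma = 3.0, lj_epsilon = 0.2, charge = c(0.3, -0.3)))
  w_t <- w; w_t[, 1:3] <- sweep(w[, 1:3], 2, shift, "+")
  reg_t <- simulation_region(gcmc_box(c(-1, -1, -1) + shift,
                                      c(1, 1, 1) + shift),
                             droplet_center = reg$droplet_center + shift,
                             droplet_radius = 6)
  expect_equal(total_energy(host_t, w_t, m, P298, reg_t), e0, tolerance = 1e-8)

  # rotation about the droplet centre (origin)
  qr <- random_rotations(1)[1, ]
  R <- quat_to_matrix(qr)
  host_r <- host_structure(particle_sites(
    rbind(c(0, 0, 0), c(2.8, 0.5, -0.3)) %*% t(R),
    lj_sigma = 3.0, lj_epsilon = 0.2, charge = c(0.3, -0.3)))
  w_r <- w
  w_r[, 1:3] <- w[, 1:3] %*% t(R)
  for (i in seq_len(nrow(w))) w_r[i, 4:7] <- quat_multiply(qr, w[i, 4:7])
  expect_equal(total_energy(host_r, w_r, m, P298, reg), e0, tolerance = 1e-8)
})

test_that("per-molecule cutoff switches a whole water at once", {
  # a water just inside vs just outside the O-O cutoff: all site-site terms
  # vanish together even though individual sites straddle 10 A
  m <- tip4p()
  wa <- water_molecule(c(0, 0, 0))
  wb_in <- water_molecule(c(9.99, 0, 0))
  wb_out <- water_molecule(c(10.01, 0, 0))
  expect_identical(water_water_energy(wa, wb_out, m, P298), 0)
  expect_true(abs(water_water_energy(wa, wb_in, m, P298)) >= 0) # defined, finite
})
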