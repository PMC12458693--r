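ideal_setup <- function(B, seed = 7) {
  reg <- simulation_region(gcmc_box(c(0, 0, 0), c(2, 2, 2)))
  gcmc_state(null_host(), ideal_water_model(), reg, P298, B = B, seed = seed)
}

test_that("move schedules validate probabilities and sampling interval", {
  expect_error(move_schedule(p_insert = 0.5, p_delete = 0.5,
                             p_displace_region = 0.2, p_displace_bulk = 0),
               "sum to 1")
  expect_error(move_schedule(n_production = 1000, sample_interval = 300),
               "divide")
  expect_equal(length(b_ladder()), 24)
  expect_equal(range(b_ladder()), c(-19, -7.5))
})

test_that("trajectories are bit-identical under the same seed", {
  sch <- move_schedule(n_production = 5000, sample_interval = 10,
                       n_equil_region = 500, n_equil_all = 100)
  t1 <- run_gcmc(ideal_setup(0, seed = 3), sch)
  t2 <- run_gcmc(ideal_setup(0, seed = 3), sch)
  expect_identical(t1$N, t2$N)
  expect_identical(t1$U, t2$U)
  expect_identical(t1$frames, t2$frames)
  t3 <- run_gcmc(ideal_setup(0, seed = 4), sch)
  expect_false(identical(t1$N, t3$N))
})

test_that("zero production moves yield an empty trajectory without error", {
  sch <- move_schedule(n_production = 0, sample_interval = 10,
                       n_equil_region = 100, n_equil_all = 0)
  tr <- run_gcmc(ideal_setup(0), sch)
  expect_length(tr$N, 0)
  expect_length(tr$U, 0)
  expect_equal(nrow(tr$frames), 0)
})

test_that("region count never goes negative and frames stay inside the box", {
  sch <- move_schedule(n_production = 20000, sample_interval = 50,
                       n_equil_region = 1000, n_equil_all = 500)
  tr <- run_gcmc(ideal_setup(-1, seed = 5), sch)
  expect_true(all(tr$N >= 0))
  expect_true(all(in_gcmc_box(tr$frames[, c("x", "y", "z")],
                              gcmc_box(c(0, 0, 0), c(2, 2, 2)))))
})

test_that("incremental energy bookkeeping agrees with full recomputation", {
  m <- tip4p()
  spec <- synthetic_system_spec(n_sites = 1, well_depths = -8, seed = 6)
  host <- make_cage_host(spec, verify = FALSE)
  reg <- simulation_region(gcmc_box_from_waters(host$crystal_water_oxygens, 1))
  st <- gcmc_state(host, m, reg, P298, B = -9, seed = 12)
  sch <- move_schedule(n_production = 20000, sample_interval = 100,
                       n_equil_region = 2000, n_equil_all = 0)
  tr <- run_gcmc(st, sch, check_energy = TRUE)
  expect_lt(tr$max_drift, 1e-6)
  # recorded running energy matches an independent recomputation at the end
  fs <- tr$final_state
  expect_equal(fs$u_total, total_energy(host, fs$waters, m, P298, reg),
               tolerance = 1e-7)
})

test_that("mean occupancy is nondecreasing in B for an interacting system", {
  m <- tip4p()
  spec <- synthetic_system_spec(n_sites = 1, well_depths = -8, seed = 6)
  host <- make_cage_host(spec, verify = FALSE)
  reg <- simulation_region(gcmc_box_from_waters(host$crystal_water_oxygens, 1))
  lad <- run_gcmc_ladder(host, m, reg, P298, seq(-16, -6, by = 2),
                         schedule = move_schedule(n_production = 30000,
                                                  sample_interval = 50,
                                                  n_equil_region = 3000,
                                                  n_equil_all = 0),
                         seed = 2, n_repeats = 2)
  cv <- occupancy_curve(lad)
  # allow tiny sampling wiggles but require a clearly monotone rise
  expect_true(all(diff(cv$mean) > -0.05))
  expect_gt(cv$mean[nrow(cv)], cv$mean[1] + 0.5)
})

test_that("replica-exchange swap rule follows exp[(Bm-Bn)(Nn-Nm)]", {
  reg <- simulation_region(gcmc_box(c(0, 0, 0), c(2, 2, 2)))
  mk <- function(B, n) {
    ox <- matrix(rep(seq(0.2, 1.8, length.out = max(n, 1)), each = 3),
                 ncol = 3, byrow = TRUE)[seq_len(n), , drop = FALSE]
    gcmc_state(null_host(), ideal_water_model(), reg, P298, B = B,
               waters = if (n > 0) water_matrix(ox) else NULL)
  }
  # equal N: exponent 0 -> always swap
  set.seed(1)
  sw <- replica_exchange_sweep(list(mk(-1, 2), mk(-0.5, 2)), parity = 0)
  expect_equal(sw$accepted[1], 1)
  # (Bm - Bn)(Nn - Nm) = (-0.5)(+2) = -1 -> acceptance e^-1
  set.seed(42)
  acc <- replicate(3000, {
    replica_exchange_sweep(list(mk(-1, 0), mk(-0.5, 2)), parity = 0)$accepted[1]
  })
  expect_equal(mean(acc), exp(-1), tolerance = 0.06)
  # exponent (-0.5)(-2) = +1 -> certain acceptance (capped)
  set.seed(7)
  sw2 <- replica_exchange_sweep(list(mk(-1, 2), mk(-0.5, 0)), parity = 0)
  expect_equal(sw2$accepted[1], 1)
  # configurations actually exchange
  st <- list(mk(-1, 2), mk(-0.5, 2))
  set.seed(3)
  sw3 <- replica_exchange_sweep(st, parity = 0)
  expect_equal(sw3$states[[1]]$n_region, 2)
  expect_equal(sw3$states[[2]]$waters, st[[1]]$waters)
  # single replica: no-op
  expect_length(replica_exchange_sweep(list(mk(0, 1)))$attempted, 0)
  expect_error(replica_exchange_sweep(list(mk(0, 1), mk(-1, 1))),
               "strictly increasing")
})

test_that("displacement moves cannot carry an oxygen across the box boundary", {
  # a single region water in a box with nothing outside: after many
  # displacement-only moves it is still in the box and N is unchanged
  reg <- simulation_region(gcmc_box(c(0, 0, 0), c(2, 2, 2)))
  st <- gcmc_state(null_host(), ideal_water_model(), reg, P298, B = 0,
                   seed = 9, waters = water_matrix(matrix(c(1.9, 1.9, 1.9), 1)))
  sch <- move_schedule(n_production = 5000, sample_interval = 10,
                       n_equil_region = 0, n_equil_all = 0,
                       p_insert = 0, p_delete = 0, p_displace_region = 1,
                       p_displace_bulk = 0, max_translate = 1.0)
  tr <- run_gcmc(st, sch)
  expect_true(all(tr$N == 1))
  expect_true(all(in_gcmc_box(tr$frames[, c("x", "y", "z")], reg)))
})
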