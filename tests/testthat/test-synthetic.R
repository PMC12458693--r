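test_that("system specs validate geometry and occlusion nesting", {
  expect_error(synthetic_system_spec(n_sites = 2,
                                     site_positions = rbind(c(0, 0, 0),
                                                            c(2, 0, 0))),
               "3 A apart")
  expect_error(synthetic_system_spec(ligand_series = list(list(blocks = 9L))),
               "nonexistent")
  expect_error(synthetic_system_spec(
    ligand_series = list(list(blocks = 1L), list(blocks = 2L))), "nested")
  expect_error(synthetic_system_spec(
    ligand_series = list(list(blocks = 1L, polar = c("1" = 0.3)))),
    "surviving")
  expect_silent(synthetic_system_spec(
    ligand_series = list(list(blocks = integer(0)),
                         list(blocks = 1L, polar = c("2" = 0.3)))))
})

test_that("cage hosts hit their designed depths near the designed positions", {
  spec <- synthetic_system_spec(n_sites = 2, well_depths = c(-10, -12), seed = 3)
  host <- make_cage_host(spec)
  for (i in 1:2) {
    mm <- site_well_minimum(host, spec$site_positions[i, ])
    expect_equal(mm$energy, spec$well_depths[i], tolerance = 0.25)
    expect_lt(sqrt(sum((mm$position - spec$site_positions[i, ])^2)), 0.5)
  }
  expect_equal(host$crystal_water_oxygens, spec$site_positions)
  # deterministic from the seed
  host2 <- make_cage_host(spec)
  expect_identical(host$sites, host2$sites)
})

test_that("adjacent designed sites allow attractive water-water contacts", {
  spec <- synthetic_system_spec(n_sites = 2)
  m <- tip4p()
  q <- super_fibonacci_rotations(40)
  e <- Inf
  for (i in 1:40) for (j in 1:40) {
    e <- min(e, water_water_energy(
      water_molecule(spec$site_positions[1, ], q[i, ] / sqrt(sum(q[i, ]^2))),
      water_molecule(spec$site_positions[2, ], q[j, ] / sqrt(sum(q[j, ]^2))),
      m, P298))
  }
  expect_lt(e, -1) # cooperativity is possible by construction
})

test_that("ligand series build occluders and stabilising polar contacts", {
  series <- list(list(blocks = integer(0)),
                 list(blocks = 1L),
                 list(blocks = 1L, polar = c("2" = 0.3)))
  spec <- synthetic_system_spec(n_sites = 2, well_depths = -10,
                                ligand_series = series, seed = 7)
  host <- make_cage_host(spec)
  ligs <- make_ligand_series(spec)
  expect_length(ligs, 3)
  expect_equal(nrow(ligs[[1]]), 0)
  expect_equal(nrow(ligs[[2]]), 1)
  expect_equal(nrow(ligs[[3]]), 2)
  expect_setequal(ligs[[3]]$label, c("occluder", "polar_contact"))
  # polar contact strengthens binding at the named surviving site
  d_without <- site_well_minimum(host_with_ligand(host, ligs[[2]], 1L),
                                 spec$site_positions[2, ])$energy
  d_with <- site_well_minimum(host_with_ligand(host, ligs[[3]], 1L),
                              spec$site_positions[2, ])$energy
  expect_lt(d_with, d_without)
  # blocked sites lose their crystal waters
  expect_equal(nrow(host_with_ligand(host, ligs[[2]], 1L)$crystal_water_oxygens), 1)
  # empty series -> empty list
  expect_length(make_ligand_series(synthetic_system_spec(n_sites = 2)), 0)
})

test_that("grid oracle reproduces the ideal-gas law and the max_n = 0 limit", {
  reg <- simulation_region(gcmc_box(c(0, 0, 0), c(2, 2, 2)))
  orc <- grid_oracle(null_host(), reg, B = c(-2, -1, 0, 1),
                     model = ideal_water_model(), max_n = 9,
                     spatial_step = 0.4, n_orientations = 8)
  expect_equal(orc$mean_n, exp(c(-2, -1, 0, 1)), tolerance = 0.02)
  orc0 <- grid_oracle(null_host(), reg, B = 0, model = ideal_water_model(),
                      max_n = 0, spatial_step = 0.4, n_orientations = 8)
  expect_equal(orc0$mean_n, 0)
  expect_equal(orc0$ln_xi, 0)
})

test_that("oracle is self-consistent: -kT d(ln Xi) equals the <N> integral", {
  spec <- synthetic_system_spec(n_sites = 1, well_depths = -8, seed = 6)
  host <- make_cage_host(spec, verify = FALSE)
  reg <- simulation_region(gcmc_box_from_waters(host$crystal_water_oxygens, 1))
  B <- seq(-14, -8, by = 0.25)
  orc <- grid_oracle(host, reg, B, max_n = 2, spatial_step = 0.3,
                     n_orientations = 96)
  lhs <- -P298$kT * (orc$ln_xi[length(B)] - orc$ln_xi[1])
  # trapezoid of the oracle's own <N> over the same range
  rhs <- -P298$kT * sum(diff(B) * (head(orc$mean_n, -1) + orc$mean_n[-1]) / 2)
  expect_equal(lhs, rhs, tolerance = 0.01)
})

test_that("a deeper well shifts the occupancy sigmoid to lower B", {
  reg_of <- function(h) simulation_region(gcmc_box_from_waters(
    h$crystal_water_oxygens, 1))
  B <- seq(-18, -6, by = 0.5)
  mids <- vapply(c(-8, -12), function(depth) {
    spec <- synthetic_system_spec(n_sites = 1, well_depths = depth, seed = 6)
    host <- make_cage_host(spec, verify = FALSE)
    orc <- grid_oracle(host, reg_of(host), B, max_n = 2, spatial_step = 0.3,
                       n_orientations = 96)
    B[which.min(abs(orc$mean_n - 0.5))]
  }, numeric(1))
  expect_lt(mids[2], mids[1] - 3) # ~ beta * ddepth * kT in B units
})
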