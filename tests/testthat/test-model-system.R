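test_that("tip4p satisfies the rigid-water model contracts", {
  m <- tip4p()
  expect_equal(sum(m$site_charges), 0, tolerance = 1e-12)
  expect_equal(m$site_offsets[1, ], c(0, 0, 0))
  # O-H bond lengths and H-O-H angle
  oh <- sqrt(rowSums(m$site_offsets[2:3, ]^2))
  expect_equal(oh, c(0.9572, 0.9572), tolerance = 1e-12, ignore_attr = TRUE)
  cosang <- sum(m$site_offsets[2, ] * m$site_offsets[3, ]) / prod(oh)
  expect_equal(acos(cosang) * 180 / pi, 104.52, tolerance = 1e-9)
  expect_equal(sqrt(sum(m$site_offsets[4, ]^2)), 0.15)
  expect_error(water_model(m$site_offsets, c(0, 0.5, 0.5, -1.04), 3.15, 0.155),
               "neutral")
})

test_that("rigid-body transforms preserve intramolecular distances", {
  m <- tip4p()
  d0 <- dist(m$site_offsets)
  for (i in 1:20) {
    q <- random_rotations(1)[1, ]
    w <- water_molecule(runif(3, -5, 5), q)
    s <- water_sites(w, m)
    expect_lt(max(abs(dist(s) - d0)), 1e-9)
    # proper rotation
    expect_equal(det(quat_to_matrix(q)), 1, tolerance = 1e-9)
  }
})

test_that("water_molecule rejects invalid orientations", {
  expect_error(water_molecule(c(0, 0, 0), c(1, 1, 0, 0)), "unit quaternion")
  expect_error(water_molecule(c(Inf, 0, 0)), "finite")
})

test_that("gcmc_box_from_waters implements min/max corners with padding", {
  b <- gcmc_box_from_waters(rbind(c(0, 0, 0), c(2, 0, 0)), padding = 1)
  expect_equal(b$min, c(-1, -1, -1))
  expect_equal(b$max, c(3, 1, 1))
  expect_equal(b$volume, 16) # 4 x 2 x 2 from the stated corners
  b1 <- gcmc_box_from_waters(matrix(c(5, 5, 5), 1), padding = 1)
  expect_equal(b1$max - b1$min, c(2, 2, 2))
  expect_equal(b1$volume, 8)
  expect_error(gcmc_box_from_waters(matrix(c(1, 1, 1), 1), padding = 0),
               "zero volume")
  expect_error(gcmc_box_from_waters(NULL), "at least one")
})

test_that("box membership is closed, oxygen-based and translation-consistent", {
  b <- gcmc_box(c(0, 0, 0), c(2, 2, 2))
  reg <- simulation_region(b)
  pts <- rbind(c(0, 0, 0), c(2, 2, 2), c(1, 1, 1), c(2.001, 1, 1), c(-0.001, 1, 1))
  expect_equal(in_gcmc_box(pts, reg), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  shift <- c(3.7, -1.2, 0.4)
  b2 <- gcmc_box(b$min + shift, b$max + shift)
  expect_equal(in_gcmc_box(sweep(pts, 2, shift, "+"), b2), in_gcmc_box(pts, b))
})

test_that("simulation region enforces the box-inside-droplet invariant", {
  b <- gcmc_box(c(-2, -2, -2), c(2, 2, 2))
  expect_silent(simulation_region(b, droplet_radius = 30))
  expect_error(simulation_region(b, droplet_center = c(40, 0, 0),
                                 droplet_radius = 30), "outside the droplet")
})

test_that("hosts must carry at least one site and keep crystal waters apart", {
  s <- particle_sites(matrix(c(0, 0, 0), 1), 3, 0.1, 0.5)
  h <- host_structure(s, crystal_water_oxygens = rbind(c(1, 1, 1)))
  expect_equal(nrow(h$crystal_water_oxygens), 1)
  expect_true(h$rigid)
  expect_error(host_structure(s[0, ]), "at least one")
  expect_error(particle_sites(matrix(c(0, 0, 0), 1), lj_sigma = -1), ">= 0")
})
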