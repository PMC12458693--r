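test_that("single observations and sub-cutoff pairs cluster as expected", {
  one <- cluster_water_sites(rbind(c(1, 0.5, 0.5, 0.5)), cutoff = 2.4)
  expect_equal(nrow(one), 1)
  expect_equal(one$occupancy, 1.0)
  expect_equal(unlist(one[1, c("x", "y", "z")], use.names = FALSE), c(0.5, 0.5, 0.5))
  # two points 1.0 A apart in one frame merge below the cutoff
  two <- cluster_water_sites(rbind(c(1, 0, 0, 0), c(1, 1, 0, 0)), cutoff = 2.4)
  expect_equal(nrow(two), 1)
  expect_equal(two$occupancy, 1.0)
  expect_equal(two$n_members, 2L)
  expect_equal(two$x, 0.5)
  # empty input
  expect_equal(nrow(cluster_water_sites(matrix(numeric(0), ncol = 4),
                                        n_frames = 10)), 0)
})

test_that("planted two-site fixtures are recovered with their occupancies", {
  sites <- rbind(c(0, 0, 0), c(5, 0, 0))
  fr <- planted_trajectory(sites, c(0.9, 0.5), jitter = 0.3,
                           n_frames = 2000, seed = 11)
  cl <- cluster_water_sites(fr, cutoff = 2.4, n_frames = 2000)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$occupancy[1], 0.9, tolerance = 0.05)
  expect_equal(cl$occupancy[2], 0.5, tolerance = 0.05)
  expect_lt(sqrt(sum((unlist(cl[1, c("x", "y", "z")]) - sites[1, ])^2)), 0.1)
  expect_lt(sqrt(sum((unlist(cl[2, c("x", "y", "z")]) - sites[2, ])^2)), 0.1)
  # clusters come sorted by occupancy, descending
  expect_true(!is.unsorted(rev(cl$occupancy)))
})

test_that("clustering is invariant to frame order and rigid motions", {
  sites <- rbind(c(0, 0, 0), c(4, 1, -1))
  fr <- planted_trajectory(sites, c(0.8, 0.6), jitter = 0.25,
                           n_frames = 300, seed = 5)
  cl <- cluster_water_sites(fr, n_frames = 300)
  # frame order permuted
  fr_perm <- fr[sample(nrow(fr)), , drop = FALSE]
  cl_perm <- cluster_water_sites(fr_perm, n_frames = 300)
  expect_equal(cl_perm$occupancy, cl$occupancy)
  expect_equal(as.matrix(cl_perm[, 1:3]), as.matrix(cl[, 1:3]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # rigid motion moves centroids identically, occupancies unchanged
  q <- random_rotations(1)[1, ]
  R <- quat_to_matrix(q); shift <- c(3, -2, 7)
  fr_rot <- fr
  fr_rot[, 2:4] <- sweep(fr[, 2:4] %*% t(R), 2, shift, "+")
  cl_rot <- cluster_water_sites(fr_rot, n_frames = 300)
  expect_equal(cl_rot$occupancy, cl$occupancy)
  expect_equal(as.matrix(cl_rot[, 1:3]),
               sweep(as.matrix(cl[, 1:3]) %*% t(R), 2, shift, "+"),
               tolerance = 1e-8, ignore_attr = TRUE)
  # TPR is unchanged under the same motion
  t0 <- true_positive_rate(cl, sites, 1.5)
  t1 <- true_positive_rate(cl_rot, sweep(sites %*% t(R), 2, shift, "+"), 1.5)
  expect_equal(t1$tpr, t0$tpr)
})

test_that("the occupancy filter keeps the 30% boundary inclusively", {
  cl <- data.frame(x = 1:3, y = 0, z = 0,
                   occupancy = c(0.95, 0.30, 0.29), n_members = c(9L, 3L, 2L))
  attr(cl, "members") <- list(1, 2, 3)
  class(cl) <- c("water_sites", "data.frame")
  kept <- filter_by_occupancy(cl, 0.30)
  expect_equal(kept$occupancy, c(0.95, 0.30))
  expect_equal(nrow(filter_by_occupancy(cl, 0)), 3)
  expect_equal(filter_by_occupancy(cl, 1.0)$occupancy, numeric(0))
})

test_that("TPR counts per crystal site with an inclusive threshold", {
  crystal <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0), c(15, 0, 0))
  pred <- rbind(c(0.4, 0, 0), c(5.2, 0.3, 0), c(10, 1, 1)) # misses the 4th
  cmp <- true_positive_rate(pred, crystal, 1.5)
  expect_equal(cmp$tp, 3)
  expect_equal(cmp$fn, 1)
  expect_equal(cmp$tpr, 0.75)
  # exact placement on every site
  expect_equal(true_positive_rate(crystal, crystal, 1.5)$tpr, 1.0)
  # a prediction at exactly 1.5 A counts (inclusive)
  expect_equal(true_positive_rate(rbind(c(1.5, 0, 0)), rbind(c(0, 0, 0)), 1.5)$tp, 1)
  # one prediction may satisfy several crystal sites
  expect_equal(true_positive_rate(rbind(c(0.5, 0, 0)),
                                  rbind(c(0, 0, 0), c(1, 0, 0)), 1.5)$tpr, 1.0)
  expect_error(true_positive_rate(pred, matrix(numeric(0), ncol = 3), 1.5),
               "undefined")
  # no predictions: all false negatives
  expect_equal(true_positive_rate(matrix(numeric(0), ncol = 3), crystal, 1.5)$tpr, 0)
})

test_that("planted trajectories honour their occupancy and determinism", {
  sites <- matrix(c(0, 0, 0), 1)
  f0 <- planted_trajectory(sites, 1.0, jitter = 0, n_frames = 50, seed = 1)
  expect_equal(nrow(f0), 50)
  expect_true(all(f0[, 2:4] == 0))
  f1 <- planted_trajectory(sites, 0.5, jitter = 0.1, n_frames = 10000, seed = 2)
  expect_equal(nrow(f1) / 10000, 0.5, tolerance = 0.015 * 3)
  expect_identical(planted_trajectory(sites, 0.5, 0.1, 100, seed = 9),
                   planted_trajectory(sites, 0.5, 0.1, 100, seed = 9))
  expect_equal(nrow(planted_trajectory(sites, 0.5, 0.1, 0, seed = 1)), 0)
})
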