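nfe <- function(dg, se, beq = -10) {
  structure(list(dg = dg, se = se, b_equil = beq), class = "network_free_energy")
}

test_that("closure error implements |wet + net_A - dry - net_B|", {
  cyc0 <- free_energy_cycle(free_energy(0), free_energy(0),
                            free_energy(0), free_energy(0))
  expect_equal(closure_error(cyc0)$value, 0)
  # constructed consistent cycle
  cyc <- free_energy_cycle(free_energy(-3.0), free_energy(-9.0),
                           nfe(-14.5, 0), nfe(-8.5, 0))
  expect_equal(closure_error(cyc)$value, 0)
  # perturbing one leg by 0.3 moves the closure by 0.3
  cyc2 <- free_energy_cycle(free_energy(-3.0), free_energy(-8.7),
                            nfe(-14.5, 0), nfe(-8.5, 0))
  expect_equal(closure_error(cyc2)$value, 0.3, tolerance = 1e-12)
  # error propagation is root-sum-square
  cyc3 <- free_energy_cycle(free_energy(-3, 0.3), free_energy(-9, 0.4),
                            nfe(-14.5, 0.6), nfe(-8.5, 0.8))
  expect_equal(closure_error(cyc3)$se, sqrt(0.3^2 + 0.4^2 + 0.6^2 + 0.8^2))
  expect_error(free_energy_cycle(free_energy(0), free_energy(0),
                                 nfe(-1, 0, beq = -10), nfe(-1, 0, beq = -9)),
               "different B_equil")
})

test_that("solvent contribution equals wet minus dry with the documented sign", {
  cyc <- free_energy_cycle(free_energy(-3.0, 0.3), free_energy(-9.0, 0.4),
                           nfe(-14.5, 0), nfe(-8.5, 0))
  sc <- solvent_contribution(cyc)
  expect_equal(sc$dg, 6.0)  # network opposes the transformation
  expect_equal(sc$se, 0.5)
  expect_match(sc$convention, "opposes")
  # wet = dry -> 0
  cyc0 <- free_energy_cycle(free_energy(-2), free_energy(-2),
                            nfe(-5, 0), nfe(-5, 0))
  expect_equal(solvent_contribution(cyc0)$dg, 0)
  # cycle identity: wet - dry = net_B - net_A exactly when closure is zero
  expect_equal(sc$dg, cyc$network_b$dg - cyc$network_a$dg,
               tolerance = 1e-12)
})

test_that("relative binding free energy subtracts the solvent leg", {
  b <- free_energy(-2.0, 0.3, label = "A->B")
  s <- free_energy(-1.0, 0.4, label = "A->B")
  d <- relative_binding_free_energy(b, s)
  expect_equal(d$ddg, -1.0)
  expect_equal(d$se, 0.5)
  expect_equal(relative_binding_free_energy(b, b)$ddg, 0)
  s2 <- free_energy(-1.0, 0.4, label = "B->C")
  expect_error(relative_binding_free_energy(b, s2), "different transformations")
})

test_that("cycle reports render the four legs and the closure box", {
  cyc <- free_energy_cycle(free_energy(-3.0, 0.1), free_energy(-9.0, 0.1),
                           nfe(-14.5, 0.6), nfe(-8.5, 0.8))
  out <- capture.output(print(cyc))
  expect_true(any(grepl("closure", out)))
  expect_true(any(grepl("-14.50", out)))
  expect_true(any(grepl("convention", out)))
})
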