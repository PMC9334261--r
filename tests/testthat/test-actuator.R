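test_that("total potential is minimized at the symmetry point of a free symmetric device", {
  sym <- actuator_model(geometry = geometry_map(30), protein = protein_spring(0))
  eq <- solve_equilibrium(sym)
  expect_true(eq$converged)
  expect_equal(eq$x_eq, 15, tolerance = 1e-8)
  expect_equal(eq$force_on_protein, 0)

  # finite-difference derivative of the potential vanishes at the minimizer
  h <- 1e-3
  fd <- (total_potential(sym, eq$x_eq + h) - total_potential(sym, eq$x_eq - h)) / (2 * h)
  expect_lt(abs(fd), 1e-6)

  expect_error(total_potential(sym, -5), "admissible")
  expect_error(total_potential(sym, 100), "admissible")
})

test_that("a very stiff protein spring pins the piston at its rest position", {
  m <- actuator_model(protein = protein_spring(1e4, rest_position = 10))
  eq <- solve_equilibrium(m)
  expect_true(eq$converged)
  expect_equal(eq$x_eq, 10, tolerance = 1e-3)
})

test_that("calibrated default device reproduces the published force span", {
  soft <- solve_equilibrium(actuator_model(protein = protein_spring(0.1)))
  stiff <- solve_equilibrium(actuator_model(protein = protein_spring(20)))
  expect_true(soft$converged && stiff$converged)
  expect_lt(abs(soft$force_on_protein - 1.6), 0.3)
  expect_lt(abs(stiff$force_on_protein - 30), 5)
  expect_lt(soft$residual, 1e-6)
  expect_lt(stiff$residual, 1e-6)

  free <- solve_equilibrium(actuator_model(protein = protein_spring(0)))
  expect_equal(free$force_on_protein, 0)
})

test_that("equilibrium force grows and x_eq shrinks monotonically with protein stiffness", {
  grid <- 10^seq(log10(0.01), log10(100), length.out = 50)
  prof <- force_vs_kprotein(actuator_model(), grid)
  expect_equal(nrow(prof), 50)
  expect_true(all(prof$converged))
  expect_true(all(prof$residual < 1e-6))
  expect_true(all(diff(prof$force_pN) > 0))
  expect_true(all(diff(prof$x_eq) < 0))

  # vanishing stiffness recovers the free minimizer of the connector potential
  free <- solve_equilibrium(actuator_model(protein = protein_spring(0)))
  at_zero <- force_vs_kprotein(actuator_model(), 0)
  expect_equal(at_zero$x_eq, free$x_eq, tolerance = 1e-9)
  expect_identical(at_zero$force_pN, 0)

  expect_error(force_vs_kprotein(actuator_model(), c(1, 0.5)), "sorted")
  expect_error(force_vs_kprotein(actuator_model(), c(-1, 2)), "non-negative")
})

test_that("geometry calibration is self-consistent and responds to scaled targets", {
  g <- calibrate_geometry(actuator_model())
  cal <- attr(g, "calibration")
  expect_lt(max(abs(cal$residuals)), 0.1)
  expect_equal(g$span_D, calibrated_geometry()$span_D, tolerance = 1e-4)

  # re-evaluating the calibrated model returns the anchor forces
  m <- actuator_model(geometry = g)
  f <- vapply(c(0.1, 20), function(k) {
    m$protein <- protein_spring(k)
    solve_equilibrium(m)$force_on_protein
  }, numeric(1))
  expect_lt(max(abs(f - c(1.6, 30))), 0.1)

  # doubling both target forces demands a wider span
  g2 <- calibrate_geometry(
    actuator_model(),
    targets = data.frame(k_protein = c(0.1, 20), force = c(3.2, 60)),
    max_residual = 5
  )
  expect_gt(g2$span_D, g$span_D)

  expect_error(
    calibrate_geometry(actuator_model(),
                       targets = data.frame(k_protein = 0.1, force = 1.6)),
    "two"
  )
})

test_that("remote modes bracket the contour length", {
  rigid <- actuator_model(top = polymer_spec(97, "double"),
                          mode = "remote_ds_rigid",
                          protein = protein_spring(0.5))
  eq_r <- solve_equilibrium(rigid)
  expect_equal(eq_r$x_eq, 32.98)
  expect_equal(eq_r$force_on_protein, 0.5 * eq_r$x_eq)
  expect_equal(eq_r$residual, 0)

  # effective-stiffness mode: taut antagonistic springs hold it below contour
  eff <- actuator_model(top = polymer_spec(97, "double"),
                        mode = "remote_ds_effective",
                        geometry = geometry_map(20))
  eq_e <- solve_equilibrium(eff)
  expect_true(eq_e$converged)
  expect_lt(eq_e$x_eq, 32.98)
  bottom_ext <- eq_e$x_eq - 20
  expect_gt(bottom_ext, 0) # bottom springs are indeed taut at equilibrium

  expect_error(
    actuator_model(top = polymer_spec(97, "single"), mode = "remote_ds_rigid"),
    "double-stranded"
  )
})

test_that("anticipated extension follows the double-stranded contour, rounded to nm", {
  expect_identical(predict_anticipated_extension(c(30, 60, 97)), c(10, 20, 33))
  expect_equal(predict_anticipated_extension(50), round(50 * 0.34))
  expect_error(predict_anticipated_extension(-2), "positive")
})

test_that("hairpin benchmark force and opening probability behave as a two-state system", {
  hp <- hairpin_force()
  expect_equal(hp$force_pN, 8.0 * 5.3)
  expect_identical(hp$force_2sf, 42)
  expect_true(hp$exceeds_f_half)

  expect_false(hairpin_force(deformation = 0)$exceeds_f_half)
  expect_equal(hairpin_force(deformation = 0)$force_pN, 0)
  expect_equal(hairpin_force(k_eff = 3.0)$force_pN, 15.9, tolerance = 1e-6)

  expect_equal(hairpin_open_probability(20), 0.5)
  expect_gt(hairpin_open_probability(42), 0.99)
  f <- seq(0, 30, by = 1) # below numeric saturation of the logistic
  expect_true(all(diff(hairpin_open_probability(f)) > 0))
})

test_that("membrane indentation and positioning precision follow their closed forms", {
  expect_equal(membrane_indentation(10), 1.0)
  expect_equal(membrane_indentation(0), 0)
  expect_equal(effective_distance(17.7, 5), 17.2)
  expect_equal(effective_distance(0.5, 100), 0) # floored at zero

  th <- thermal_state()
  expect_equal(positioning_sd(1, 1), sqrt(th$kBT), tolerance = 1e-12)
  expect_equal(positioning_sd(1, 1), 2.02, tolerance = 2e-3)
  expect_equal(positioning_sd(4, 1), positioning_sd(1, 1) / 2)
  # six parallel connectors at the device-level stiffness of 8 pN/nm
  expect_equal(positioning_sd(6, 8 / 6), sqrt(th$kBT / 8))
  expect_equal(positioning_sd(6, 8 / 6), 0.71, tolerance = 1e-2)
  expect_error(positioning_sd(0, 1), "at least 1")
})
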