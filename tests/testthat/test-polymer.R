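test_that("Marko-Siggia force matches direct evaluation, zero limit and divergence", {
  ss <- polymer_spec(97)
  expect_equal(ss$contour_length, 61.11)
  expect_equal(wlc_force(ss, 0), 0)

  # direct formula evaluation as independent oracle, at several extensions
  for (z in c(1, 10, 30, 55)) {
    expect_equal(wlc_force(ss, z), oracle_ms_force(z, 61.11, 1, oracle_kBT),
                 tolerance = 1e-12)
  }
  expect_equal(wlc_force(ss, 30), 4.93, tolerance = 2e-3)

  # monotone and divergent toward the contour length
  zs <- seq(0, 0.999999 * ss$contour_length, length.out = 200)
  expect_true(all(diff(wlc_force(ss, zs)) > 0))
  expect_gt(wlc_force(ss, 0.999999 * ss$contour_length), 1e4)

  expect_error(wlc_force(ss, -1), "non-negative")
  expect_error(wlc_force(ss, 61.11), "contour length")
  expect_error(wlc_force(ss, 100), "contour length")
})

test_that("force-extension inversion round-trips across the working force range", {
  th <- thermal_state()
  for (spec in list(polymer_spec(97), polymer_spec(97, "double"))) {
    expect_equal(wlc_extension_at_force(spec, 0), 0)
    forces <- 10^seq(-3, 2, length.out = 21)
    z <- wlc_extension_at_force(spec, forces)
    expect_true(all(z > 0 & z < spec$contour_length))
    expect_lt(max(abs(wlc_force(spec, z) - forces)), 1e-6)
  }
  expect_error(wlc_extension_at_force(polymer_spec(97), -1), "non-negative")

  # 97-bp dsDNA at 5 pN: independent bisection on the direct formula
  ds <- polymer_spec(97, "double")
  oracle <- uniroot(
    function(z) oracle_ms_force(z, ds$contour_length, 50, oracle_kBT) - 5,
    c(0, ds$contour_length * (1 - 1e-9)), tol = 1e-12
  )$root
  expect_equal(wlc_extension_at_force(ds, 5), oracle, tolerance = 1e-8)
  expect_equal(oracle / ds$contour_length, 0.936, tolerance = 1e-3)
})

test_that("elastic energy is the antiderivative of the force", {
  ss <- polymer_spec(97)
  expect_equal(wlc_energy(ss, 0), 0)

  # adaptive quadrature of the force as independent oracle
  quad <- integrate(function(z) wlc_force(ss, z), 0, 30, rel.tol = 1e-12)$value
  expect_equal(wlc_energy(ss, 30), quad, tolerance = 1e-6 / quad)

  # central-difference derivative recovers the force
  h <- 1e-3
  fd <- (wlc_energy(ss, 20 + h) - wlc_energy(ss, 20 - h)) / (2 * h)
  expect_equal(fd, wlc_force(ss, 20), tolerance = 1e-4 / wlc_force(ss, 20))

  # convexity: energy increments accelerate
  zs <- seq(0, 55, by = 0.5)
  expect_true(all(diff(diff(wlc_energy(ss, zs))) > 0))
})

test_that("analytic stiffness matches the closed form at zero and finite differences", {
  ss <- polymer_spec(97)
  th <- thermal_state()
  expect_equal(wlc_stiffness(ss, 0),
               th$kBT / ss$persistence_length * 3 / (2 * ss$contour_length),
               tolerance = 1e-12)
  expect_equal(wlc_stiffness(ss, 0), 0.100, tolerance = 5e-3)

  h <- 1e-4
  fd <- (wlc_force(ss, 25 + h) - wlc_force(ss, 25 - h)) / (2 * h)
  expect_equal(wlc_stiffness(ss, 25), fd, tolerance = 1e-4)

  zs <- seq(0, 55, by = 1)
  expect_true(all(diff(wlc_stiffness(ss, zs)) > 0))
})

test_that("entropic-spring linear limit holds for small relative extension", {
  th <- thermal_state()
  for (spec in list(polymer_spec(97), polymer_spec(97, "double"))) {
    zs <- seq(0.005, 0.09, by = 0.005) * spec$contour_length
    f <- wlc_force(spec, zs)
    lin <- 3 * th$kBT / (2 * spec$persistence_length * spec$contour_length) * zs
    expect_lt(max(abs(f - lin) / f), 0.05)
  }
})

test_that("polymer and thermal constructors apply defaults and validate input", {
  ss <- polymer_spec(97)
  expect_equal(ss$persistence_length, 1)
  expect_equal(ss$rise_per_unit, 0.63)
  ds <- polymer_spec(97, "double")
  expect_equal(ds$persistence_length, 50)
  expect_equal(ds$contour_length, 32.98)

  custom <- polymer_spec(50, "single", rise_per_unit = 0.7, persistence_length = 1.5)
  expect_equal(custom$contour_length, 35)
  expect_error(polymer_spec(0), "positive")
  expect_error(polymer_spec(97, persistence_length = -1), "positive")

  th <- thermal_state()
  expect_equal(th$temperature, 296.15)
  expect_equal(th$kBT, 0.0138065 * 296.15)
  expect_error(thermal_state(-3), "positive")

  prof <- wlc_profile(ss)
  expect_named(prof, c("extension_nm", "force_pN", "stiffness_pN_per_nm"))
  expect_equal(prof$force_pN, wlc_force(ss, prof$extension_nm))
})
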