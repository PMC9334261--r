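test_that("bead calibration recovers an exact log-log line and rejects degenerate input", {
  beads <- data.frame(mfi = c(1e2, 1e3, 1e4), molecules_per_bead = c(1e2, 1e3, 1e4))
  line <- fit_bead_calibration(beads)
  expect_equal(line$slope, 1, tolerance = 1e-12)
  expect_equal(line$intercept, 0, tolerance = 1e-12)
  expect_equal(line$r_squared, 1, tolerance = 1e-12)

  expect_error(fit_bead_calibration(data.frame(mfi = 100, molecules_per_bead = 100)),
               "two")
  expect_error(
    fit_bead_calibration(data.frame(mfi = c(100, 100), molecules_per_bead = c(100, 200))),
    "distinct"
  )
  expect_error(
    fit_bead_calibration(data.frame(mfi = c(-1, 10), molecules_per_bead = c(1, 2))),
    "positive"
  )
})

test_that("bead calibration recovers the generating slope from noisy populations", {
  sim <- gen_bead_table(cv = 0.05, slope = 1, intercept = 0, seed = 14)
  line <- fit_bead_calibration(sim$beads)
  slope_se <- tidy(line)$std.error[tidy(line)$term == "slope"]
  expect_lt(abs(line$slope - 1), 3 * slope_se)
  expect_gt(line$r_squared, 0.99)
})

test_that("MFI-to-count conversion inverts the calibration line", {
  line <- fit_bead_calibration(
    data.frame(mfi = c(1e2, 1e3, 1e4), molecules_per_bead = c(1e2, 1e3, 1e4))
  )
  expect_equal(count_from_mfi(line, 1e4), 1e4, tolerance = 1e-9)
  expect_equal(count_from_mfi(line, 1500, background_mfi = 500), 1000,
               tolerance = 1e-9)
  expect_error(count_from_mfi(line, 100, background_mfi = 100), "background")
  expect_error(count_from_mfi(line, 50, background_mfi = 100), "background")
})

test_that("noise-free calibration pipeline reproduces counts exactly, noisy one nearly", {
  exact <- gen_bead_table(cv = 0, true_count = 9200, seed = 5)
  line <- fit_bead_calibration(exact$beads)
  expect_equal(mean(count_from_mfi(line, exact$cell_mfi)), 9200, tolerance = 1e-9)

  # bias < 1% across seeded replicate experiments at cv 5%
  counts <- vapply(1:100, function(s) {
    sim <- gen_bead_table(cv = 0.05, true_count = 9200, seed = 1000 + s)
    mean(count_from_mfi(fit_bead_calibration(sim$beads), sim$cell_mfi))
  }, numeric(1))
  expect_lt(abs(mean(counts) / 9200 - 1), 0.01)
})

test_that("LRET reduction subtracts background and scales ratios per condition", {
  plate <- tibble::tibble(
    well = c("B1", "C1"),
    condition = c("background", "treated"),
    donor_620 = c(1, 1),
    acceptor_665 = c(1, 2)
  )
  out <- lret_ratio(plate)
  expect_equal(out$response, 1e4)

  same <- lret_ratio(tibble::tibble(
    condition = c("background", "treated"),
    donor_620 = c(2, 2), acceptor_665 = c(3, 3)
  ))
  expect_equal(same$response, 0)

  # invariance to a common per-well intensity factor
  plate2 <- dplyr::mutate(plate,
                          donor_620 = donor_620 * c(7, 0.3),
                          acceptor_665 = acceptor_665 * c(7, 0.3))
  expect_equal(lret_ratio(plate2)$response, out$response)

  bad <- dplyr::mutate(plate, donor_620 = c(1, 0))
  expect_error(lret_ratio(bad), "well C1")
  expect_error(lret_ratio(dplyr::filter(plate, condition == "treated")),
               "background")
})

test_that("trace idealization is exact on a noiseless square wave", {
  blocks <- rep(c(4, 16, 4, 16), each = 50)
  trace <- tibble::tibble(time_s = seq_along(blocks) / 1000, current_pA = blocks)
  seg <- segment_trace(trace)
  expect_false(seg$single_state)
  expect_equal(seg$states$mean_pA, c(4, 16))
  expect_equal(seg$states$sd_pA, c(0, 0))
  expect_equal(seg$n_transitions, 3L)
  expect_equal(as.character(seg$data$state),
               ifelse(blocks == 4, "closed", "open"))
})

test_that("degenerate traces are reported as single-state", {
  flat <- tibble::tibble(time_s = (1:200) / 1000, current_pA = rep(5, 200))
  seg <- segment_trace(flat)
  expect_true(seg$single_state)
  expect_equal(seg$n_transitions, 0L)
  expect_equal(seg$states$mean_pA, 5)

  # single-level noisy trace: unimodal, no genuine second level
  noisy <- gen_trace(duration_s = 2, dwell_means_s = c(closed = 1e6, open = 1),
                     seed = 3)
  seg2 <- segment_trace(noisy)
  expect_true(seg2$single_state)
  expect_equal(seg2$n_transitions, 0L)

  expect_error(segment_trace(tibble::tibble(time_s = 1:50 / 1e3,
                                            current_pA = rnorm(50))), "100")
  expect_error(
    segment_trace(tibble::tibble(time_s = c(1:99, 200) / 1e3,
                                 current_pA = rnorm(100))),
    "uniform"
  )
})

test_that("segmentation recovers the open-state level from a noisy Markov trace", {
  trace <- gen_trace(duration_s = 60, seed = 42)
  seg <- segment_trace(trace)
  expect_false(seg$single_state)
  open <- seg$states[seg$states$state == "open", ]
  closed <- seg$states[seg$states$state == "closed", ]
  expect_lt(abs(open$mean_pA - 16), 3 * open$sd_pA / sqrt(open$n_samples))
  expect_lt(abs(closed$mean_pA - 4), 3 * closed$sd_pA / sqrt(closed$n_samples))
  expect_true(closed$mean_pA < open$mean_pA)
  expect_equal(sum(seg$states$n_samples), nrow(trace))
  expect_true(all(seg$dwells$n_samples >= 5) || length(seg$dwells$n_samples) == 1)

  # >= 99% correct assignment at 3x separation-to-noise
  truth <- attr(trace, "state_true")
  acc <- mean(as.character(seg$data$state) == as.character(truth))
  expect_gte(acc, 0.99)
})

test_that("tidy and glance methods expose fitted-object summaries as tibbles", {
  eq <- solve_equilibrium(actuator_model(protein = protein_spring(0.1)))
  expect_named(tidy(eq), c("x_eq", "force_on_protein", "residual", "converged"))
  expect_equal(glance(eq)$k_protein, 0.1)

  line <- fit_bead_calibration(
    data.frame(mfi = c(1e2, 1e3, 1e4), molecules_per_bead = c(2e2, 2e3, 2e4))
  )
  expect_equal(nrow(tidy(line)), 2)
  expect_equal(glance(line)$r.squared, 1, tolerance = 1e-12)

  seg <- segment_trace(gen_trace(duration_s = 2, seed = 1))
  expect_true(all(c("state", "mean_pA", "occupancy") %in% names(tidy(seg))))
  expect_equal(glance(seg)$n_samples, 2000)
})
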