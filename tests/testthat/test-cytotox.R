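test_that("endpoint viability is the treated/vehicle percent at endpoint", {
  plate <- toy_plate(treated_factor = 0.5)
  via <- endpoint_viability(plate)
  expect_equal(nrow(via), 1L)
  expect_equal(via$percent_of_control, 50, tolerance = 1e-9)

  # treated identical to vehicle reads 100%
  same <- toy_plate(treated_factor = 1)
  expect_equal(endpoint_viability(same)$percent_of_control, 100,
               tolerance = 1e-9)

  # fluorescence readout uses raw per-well signals
  flu <- data.frame(well = c("A01", "A02", "B01", "B02"),
                    signal = c(2000, 2000, 1000, 1000))
  vf <- endpoint_viability(plate, readout = "fluorescence",
                           fluorescence = flu)
  expect_equal(vf$percent_of_control, 50)
  zero <- data.frame(well = c("A01", "A02", "B01", "B02"),
                     signal = c(0, 0, 10, 10))
  expect_error(endpoint_viability(plate, readout = "fluorescence",
                                  fluorescence = zero), "not positive")
  expect_error(endpoint_viability(plate, endpoint_time = 3.33), "grid")
})

test_that("cross-readout correlation is Pearson r x 100 with guards", {
  x <- data.frame(compound_id = "a", concentration_uM = c(1, 10, 100),
                  percent_of_control = c(90, 60, 20))
  y <- x
  expect_equal(cross_readout_correlation(x, y)$correlation_pct, 100)
  anti <- x
  anti$percent_of_control <- 200 - x$percent_of_control
  expect_equal(cross_readout_correlation(x, anti)$correlation_pct, -100)
  expect_true(is.na(cross_readout_correlation(x[1:2, ], y[1:2, ])$correlation_pct))
  const <- x
  const$percent_of_control <- 50
  expect_true(is.na(cross_readout_correlation(x, const)$correlation_pct))
})

test_that("shared-latent dual readouts correlate near-perfectly", {
  dr <- simulate_dual_readout(n_compounds = 50, noise_sd = 0.05, seed = 3)
  imp <- data.frame(compound_id = dr$compound_id,
                    concentration_uM = dr$concentration_uM,
                    percent_of_control = dr$impedance_pct)
  flu <- data.frame(compound_id = dr$compound_id,
                    concentration_uM = dr$concentration_uM,
                    percent_of_control = dr$fluorescence_pct)
  expect_gte(cross_readout_correlation(imp, flu)$correlation_pct, 95)
})

test_that("the two-point bracketing fit solves the worked example", {
  r <- compute_lc50(c(1, 10), c(80, 20))
  expect_equal(r$slope_a, -20 / 3)
  expect_equal(r$intercept_b, 260 / 3)
  expect_equal(r$lc50, 5.5)
  expect_identical(r$flag, "ok")
  expect_equal(r$bracketing_pair$concentration_uM, c(1, 10))
  # LC50 lies within the bracketing doses and the viabilities straddle 50
  expect_true(r$lc50 >= 1 && r$lc50 <= 10)
})

test_that("exactly-linear viability recovers the analytic crossing", {
  set.seed(41)
  for (i in 1:50) {
    doses <- sort(runif(5, 0.1, 120))
    beta <- -runif(1, 0.5, 2)
    alpha <- runif(1, 60, 140)
    v <- alpha + beta * doses
    true_cross <- (50 - alpha) / beta
    r <- compute_lc50(doses, v)
    if (v[1] < 50) {
      expect_identical(r$flag, "< lowest dose")
    } else if (all(v > 50)) {
      expect_identical(r$flag, "> top dose")
    } else if (r$flag == "exact") {
      expect_equal(r$lc50, true_cross, tolerance = 1e-9)
    } else {
      expect_equal(r$lc50, true_cross, tolerance = 1e-9)
    }
  }
})

test_that("LC50 boundary cases follow the bracketing conventions", {
  exact <- compute_lc50(c(1, 5, 25), c(80, 50, 10))
  expect_identical(exact$flag, "exact")
  expect_equal(exact$lc50, 5)

  high <- compute_lc50(c(1, 10, 100, 1000), c(95, 90, 80, 70))
  expect_identical(high$flag, "> top dose")
  expect_true(is.na(high$lc50))

  low <- compute_lc50(c(1, 10, 100), c(40, 30, 10))
  expect_identical(low$flag, "< lowest dose")
  expect_true(is.na(low$lc50))

  expect_error(compute_lc50(c(1, 1, 10), c(80, 70, 20)), "duplicate doses")
  expect_error(compute_lc50(5, 50), "at least 2")

  # nearest-to-50 straddle wins; ties go to the lowest doses
  multi <- compute_lc50(c(1, 2, 4, 8), c(90, 55, 45, 20))
  expect_equal(multi$bracketing_pair$concentration_uM, c(2, 4))
  tie <- compute_lc50(c(1, 2, 4, 8), c(60, 40, 60, 40))
  expect_equal(tie$bracketing_pair$concentration_uM, c(1, 2))

  # log-scale option fits on log10(dose)
  lg <- compute_lc50(c(1, 100), c(80, 20), log_scale = TRUE)
  expect_equal(lg$lc50, 10, tolerance = 1e-9)
})

test_that("zero-noise dual readouts give identical LC50s", {
  dr <- simulate_dual_readout(n_compounds = 12, noise_sd = 0, seed = 9)
  for (cid in unique(dr$compound_id)) {
    sub <- dr[dr$compound_id == cid, ]
    ri <- compute_lc50(sub$concentration_uM, sub$impedance_pct)
    rf <- compute_lc50(sub$concentration_uM, sub$fluorescence_pct)
    expect_identical(ri$flag, rf$flag)
    if (ri$flag %in% c("ok", "exact")) expect_equal(ri$lc50, rf$lc50)
  }
})

test_that("the plate-level cytotoxicity report ties the pieces together", {
  sim <- simulate_plate(simulation_design(noise_sd = 0.01),
                        list(tox = archetype_params("cytotoxic",
                                                    potency = 5)),
                        seed = 13)
  plate <- sim$plate
  # fluorescence endpoint proportional to the normalized endpoint CI
  np <- normalize_plate(plate)
  endpoint <- np$values[nrow(np$values), ]
  flu <- data.frame(well = names(endpoint), signal = 1000 * endpoint)
  rpt <- cytotox_report(plate, fluorescence = flu)
  expect_equal(rpt$correlation_pct, 100)
  expect_setequal(rpt$lc50$readout, c("impedance", "fluorescence"))
  imp_pct <- rpt$viability[rpt$viability$readout == "impedance",
                           "percent_of_control"]
  expect_true(all(diff(imp_pct) < 0))  # monotone dose response
  lc <- rpt$lc50[rpt$lc50$readout == "impedance", ]
  expect_true(lc$lc50_uM > 0.1 && lc$lc50_uM < 100)
})
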