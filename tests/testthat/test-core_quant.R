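test_that("percent inhibition anchors at the controls and evaluates Eq-style midpoints", {
  ctl <- control_set(positive_values = c(1000, 1000), negative_values = c(200, 200))
  expect_equal(percent_inhibition(1000, ctl), 0)
  expect_equal(percent_inhibition(200, ctl), 100)
  expect_equal(percent_inhibition(600, ctl), 50)
  # unclipped beyond the control window
  expect_lt(percent_inhibition(1200, ctl), 0)
  expect_gt(percent_inhibition(0, ctl), 100)
})

test_that("percent inhibition is invariant under joint positive affine transforms", {
  set.seed(11)
  for (i in 1:20) {
    pos <- rnorm(6, 1000, 30); neg <- rnorm(6, 100, 10)
    a_i <- runif(1, 0, 1200)
    a <- runif(1, 0.1, 50); b <- runif(1, -200, 200)
    base <- percent_inhibition(a_i, control_set(pos, neg))
    trans <- percent_inhibition(a * a_i + b, control_set(a * pos + b, a * neg + b))
    expect_equal(trans, base, tolerance = 1e-10)
  }
})

test_that("degenerate controls fail loudly with the control-set label", {
  ctl <- control_set(c(5, 5), c(5, 5), label = "plate-7")
  expect_error(percent_inhibition(3, ctl), "plate-7")
  expect_error(z_prime(ctl), "plate-7")
})

test_that("percent quench anchors at max and zero and rejects non-positive controls", {
  ctl <- control_set(c(800, 800), c(10, 10))
  expect_equal(percent_quench(800, ctl), 0)
  expect_equal(percent_quench(0, ctl), 100)
  expect_equal(percent_quench(200, ctl), 75)
  bad <- control_set(c(-5, -5), c(0, 0))
  expect_error(percent_quench(1, bad), "non-positive")
})

test_that("Z' matches hand evaluation, is scale-invariant, symmetric and capped at 1", {
  pos <- c(990, 1010); neg <- c(80, 120)  # means 1000/100, SDs ~14.1/28.3
  zp <- z_prime(control_set(pos, neg))
  expect_equal(zp, 1 - (3 * sd(pos) + 3 * sd(neg)) / 900)
  # symmetry under swapping arms
  expect_equal(z_prime(control_set(neg, pos)), zp)
  # affine invariance (positive scale)
  expect_equal(z_prime(control_set(3 * pos + 7, 3 * neg + 7)), zp,
               tolerance = 1e-12)
  # noiseless limit
  expect_equal(z_prime(control_set(c(10, 10), c(1, 1))), 1)
  set.seed(2)
  for (i in 1:15) {
    z <- z_prime(control_set(rnorm(8, 100, 20), rnorm(8, 60, 20)))
    expect_lte(z, 1)
  }
})

test_that("signal-to-background is the control-mean ratio and rejects blank-only background", {
  expect_equal(signal_to_background(control_set(c(5, 5), c(5, 5))), 1)
  expect_equal(signal_to_background(control_set(c(1200, 1200), c(1, 1))), 1200)
  expect_error(signal_to_background(control_set(c(10, 10), c(0, 0))), "background")
})

test_that("4PL fit round-trips noiseless curves across hill slopes", {
  conc <- 10^seq(-9, -5.5, length.out = 12)
  for (hill in c(0.5, 1, 2)) {
    y <- 0 + (100 - 0) / (1 + (1e-7 / conc)^hill)
    fit <- fit_4pl(dose_response_series(conc, y, "percent_inhibition"))
    expect_true(fit$converged)
    expect_equal(fit$ic50, 1e-7, tolerance = 1e-6)
    expect_equal(fit$hill, hill, tolerance = 1e-6)
    expect_equal(fit$top, 100, tolerance = 1e-6)
    expect_equal(fit$bottom, 0, tolerance = 1e-4)
  }
})

test_that("4PL flags flat series instead of fabricating parameters", {
  conc <- 10^seq(-9, -6, length.out = 8)
  fit <- fit_4pl(dose_response_series(conc, rep(50, 8), "percent_inhibition"))
  expect_false(fit$converged)
  expect_true(is.na(fit$ic50))
})

test_that("4PL recovers a simulated displacement IC50 within 3 SE at 2% noise", {
  kd_c <- calibrate_competitor_kd(15e-9, 30e-9, 250e-9, 117.5e-9)
  spec <- equilibrium_spec(15e-9, 30e-9, 250e-9, kd_competitor = kd_c)
  grid <- 117.5e-9 * 2^seq(-5.5, 5.5, by = 1)
  sim <- simulate_displacement_plate("alpha", spec, grid, noise_cv = 0.02,
                                     seed = 101)
  fit <- analyze_displacement_plate(sim$plate)
  expect_true(fit$converged)
  expect_lt(abs(fit$ic50 - 117.5e-9), 3 * fit$se[["ic50"]] + 0.02 * 117.5e-9)
})

test_that("hook detection returns none on monotone lines and locates the capacity hook", {
  pep <- c(1, 2, 5, 10, 20, 50, 100, 200, 500) * 1e-9
  mono <- titration_matrix(c(1e-9, 2e-9), pep,
                           rbind(seq(1, 9), seq(2, 18, by = 2)))
  expect_true(all(is.na(hook_point(mono, "cols")$hook_concentration)))
  sim <- simulate_alpha_matrix(alpha_bead_model(donor_capacity = 50e-9),
                               protein_concentrations = c(5, 15, 50) * 1e-9,
                               peptide_concentrations = pep,
                               kd = 250e-9, seed = 31)
  hp <- hook_point(sim$matrix, axis = "cols")
  # detected hook within one grid step of the 50 nM donor capacity
  idx_cap <- which.min(abs(pep - 50e-9))
  for (h in hp$hook_concentration) {
    expect_true(!is.na(h))
    expect_lte(abs(which(pep == h) - idx_cap), 1)
  }
})

test_that("dose-response series validates its invariants", {
  expect_error(dose_response_series(c(1e-9, 1e-9, 2e-9, 3e-9), 1:4,
                                    "raw_signal"), "ascending")
  expect_error(dose_response_series(c(0, 1e-9, 2e-9, 3e-9), 1:4,
                                    "raw_signal"), "positive")
  expect_error(dose_response_series(c(1e-9, 2e-9), 1:3, "raw_signal"),
               "one entry per concentration")
})
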