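paper_rates <- list(ka = 9.43e4, kd = 1.35e-3)

test_that("Langmuir closed forms match hand-computed anchor values", {
  # k_obs = 9.43e4 * 1e-7 + 1.35e-3 = 0.010780; R_eq = 0.874768...
  with(paper_rates, {
    kobs <- ka * 1e-7 + kd
    req <- ka * 1e-7 / kobs
    expect_equal(model_association(120, ka, kd, 1e-7, 1),
                 req * (1 - exp(-kobs * 120)), tolerance = 1e-12)
    expect_equal(model_association(120, ka, kd, 1e-7, 1), 0.634835307,
                 tolerance = 1e-8)
    expect_equal(model_dissociation(500, kd, 1), exp(-0.675), tolerance = 1e-12)
    expect_equal(model_dissociation(500, kd, 1), 0.509156421,
                 tolerance = 1e-8)
  })
  expect_equal(model_association(0, 1e5, 1e-3, 1e-7, 1.5), 0)
  expect_equal(model_association(Inf, 1e5, 1e-3, 1e-7, 1.5),
               1.5 * 1e-2 / (1e-2 + 1e-3))
})

test_that("K_D from rates reproduces the two characterized values", {
  expect_equal(kd_from_rates(9.43e4, 1.35e-3) * 1e9, 14.3160127, tolerance = 1e-6)
  expect_equal(kd_from_rates(6.54e4, 8.63e-4) * 1e9, 13.1957187, tolerance = 1e-6)
  expect_error(kd_from_rates(0, 1e-3), "positive")
})

test_that("sensorgram container enforces phase ordering", {
  expect_error(sensorgram(1:4, rep(0, 4),
                          c("association", "baseline", "baseline",
                            "dissociation"), 1e-7),
               "ordered")
  expect_error(sensorgram(1:4, rep(0, 4),
                          c("baseline", "association", "baseline",
                            "dissociation"), 1e-7),
               "contiguous")
  sg <- sensorgram(1:4, rep(0, 4),
                   c("baseline", "association", "association",
                     "dissociation"), 1e-7)
  expect_s3_class(sg, "sensorgram")
})

test_that("reference subtraction removes a shared drift exactly", {
  sim <- simulate_bli(9.43e4, 1.35e-3, 1.2, c(50e-9, 100e-9),
                      noise_sd = 0, drift = 0.002, seed = 1)
  corrected <- reference_subtract(sim$sensorgrams[[1]], sim$reference)
  clean <- simulate_bli(9.43e4, 1.35e-3, 1.2, 50e-9,
                        noise_sd = 0, drift = 0, seed = 1)$sensorgrams[[1]]
  expect_equal(corrected$response, clean$response, tolerance = 1e-10)
  expect_true(corrected$reference_subtracted)
})

test_that("rezero_association zeroes the late baseline and restarts the clock", {
  sim <- simulate_bli(9.43e4, 1.35e-3, 1.2, 100e-9, noise_sd = 0, seed = 1)
  rz <- rezero_association(sim$sensorgrams[[1]])
  expect_equal(min(rz$time[rz$phase == "association"]), 0)
  ib <- which(rz$phase == "baseline")
  expect_equal(mean(rz$response[ib[rz$time[ib] >= -5]]), 0, tolerance = 1e-12)
})

test_that("global fit recovers noiseless rates to near machine precision", {
  truth <- list(ka = 9.43e4, kd = 1.35e-3, rmax = 1.2)
  sim <- simulate_bli(truth$ka, truth$kd, truth$rmax,
                      c(12.5, 25, 50, 100, 200) * 1e-9,
                      noise_sd = 0, seed = 1)
  fit <- global_fit_1to1(sim$sensorgrams)
  expect_equal(fit$ka, truth$ka, tolerance = 1e-8)
  expect_equal(fit$kd_rate, truth$kd, tolerance = 1e-8)
  expect_equal(fit$rmax[1], truth$rmax, tolerance = 1e-8)
  expect_equal(fit$kd_eq * 1e9, 14.3160127, tolerance = 1e-6)
  expect_true(fit$kd_reliable)
  expect_length(fit$low_decay_curves, 0)
})

test_that("global fit stays accurate at instrument-level noise with drift plus referencing", {
  sim <- simulate_bli(9.43e4, 1.35e-3, 1.2, c(12.5, 25, 50, 100, 200) * 1e-9,
                      noise_sd = 0.01, drift = 0.001, seed = 42)
  sgs <- lapply(sim$sensorgrams, reference_subtract, reference = sim$reference)
  fit <- global_fit_1to1(sgs)
  expect_equal(fit$ka, 9.43e4, tolerance = 0.05)
  expect_equal(fit$kd_rate, 1.35e-3, tolerance = 0.05)
  expect_equal(fit$kd_eq, 14.316e-9, tolerance = 0.08)
})

test_that("slow dissociation trips the low-decay flag", {
  # kd = 1e-5/s over 120 s: ~0.1% decay, far below the 5% floor
  sim <- simulate_bli(1e5, 1e-5, 1.0, c(50, 100) * 1e-9,
                      noise_sd = 0, seed = 1)
  fit <- global_fit_1to1(sim$sensorgrams)
  expect_equal(sort(fit$low_decay_curves), 1:2)
  expect_false(fit$kd_reliable)
})

test_that("local dissociation fit matches the generating rate", {
  sim <- simulate_bli(9.43e4, 1.35e-3, 1.2, 100e-9, noise_sd = 0, seed = 1)
  ft <- fit_dissociation(sim$sensorgrams[[1]])
  expect_equal(ft$kd_rate, 1.35e-3, tolerance = 1e-6)
  expect_gt(ft$decay_fraction, 0.05)
})

test_that("report-point displacement reads 0% for identical traces and scales linearly", {
  sim <- simulate_bli(9.43e4, 1.35e-3, 1.2, 100e-9, noise_sd = 0, seed = 1)
  ctl <- sim$sensorgrams[[1]]
  expect_equal(report_point_displacement(ctl, ctl), 0, tolerance = 1e-12)
  half <- ctl; half$response <- ctl$response / 2
  expect_equal(report_point_displacement(half, ctl), 50, tolerance = 1e-9)
})

test_that("dissociation shift and regeneration QC behave", {
  expect_equal(dissociation_shift(2.7e-3, 1.35e-3), 2)
  qc <- regeneration_qc(c(1.00, 0.99, 1.01, 1.00, 0.98))
  expect_true(qc$stable)
  expect_lt(qc$cv, 2)
  bad <- regeneration_qc(c(1.0, 0.98, 0.5, 0.3))
  expect_false(bad$stable)
  expect_lt(bad$usable_cycles, 4)
})
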