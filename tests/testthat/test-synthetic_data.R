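test_that("simulators are deterministic in their seed and leave the RNG untouched", {
  spec <- equilibrium_spec(15e-9, 30e-9, 250e-9, kd_competitor = 100e-9)
  grid <- 10^seq(-8, -5, length.out = 8)
  set.seed(999); before <- runif(1)
  set.seed(999)
  a <- simulate_displacement_plate("alpha", spec, grid, seed = 5)
  after <- runif(1)
  expect_equal(after, before)   # global stream unchanged by the simulator
  b <- simulate_displacement_plate("alpha", spec, grid, seed = 5)
  expect_equal(a$plate, b$plate)
  c <- simulate_displacement_plate("alpha", spec, grid, seed = 6)
  expect_false(isTRUE(all.equal(a$plate$signal, c$plate$signal)))
})

test_that("lnorm noise has unit mean and the requested CV", {
  set.seed(1)
  x <- readerscreen:::lnorm_noise(2e5, 0.05)
  expect_equal(mean(x), 1, tolerance = 1e-3)
  expect_equal(sd(x), 0.05, tolerance = 0.02)
  expect_identical(readerscreen:::lnorm_noise(3, 0), rep(1, 3))
})

test_that("sim_truth carries the generating parameters through every simulator", {
  spec <- equilibrium_spec(15e-9, 30e-9, 250e-9, kd_competitor = 100e-9)
  sim <- simulate_displacement_plate("alpha", spec, 10^seq(-8, -5, length.out = 6),
                                     seed = 2)
  expect_s3_class(sim$truth, "sim_truth")
  expect_equal(sim$truth$seed, 2)
  expect_gt(sim$truth$half_displacement_dose, 0)
  expect_equal(sim$truth$spec$kd_competitor, 100e-9)
})

test_that("noiseless alpha plate analysis reproduces the theoretical half-displacement dose", {
  kd_c <- calibrate_competitor_kd(15e-9, 30e-9, 250e-9, 117.5e-9)
  spec <- equilibrium_spec(15e-9, 30e-9, 250e-9, kd_competitor = kd_c)
  grid <- 117.5e-9 * 2^seq(-5.5, 5.5, by = 1)
  sim <- simulate_displacement_plate("alpha", spec, grid, noise_cv = 0, seed = 1)
  fit <- analyze_displacement_plate(sim$plate)
  expect_true(fit$converged)
  expect_equal(fit$ic50, sim$truth$half_displacement_dose, tolerance = 0.02)
})

test_that("alpha matrix hook appears on the peptide axis but not on the protein axis", {
  model <- alpha_bead_model(donor_capacity = 50e-9, acceptor_capacity = 1e-6,
                            noise_cv = 0)
  pep <- c(1, 5, 10, 25, 50, 100, 250, 500) * 1e-9
  prot <- c(1, 5, 15, 50, 150, 500) * 1e-9
  sim <- simulate_alpha_matrix(model, prot, pep, kd = 250e-9, seed = 1)
  hooked <- hook_point(sim$matrix, axis = "cols")
  expect_true(any(!is.na(hooked$hook_concentration)))
  # protein never exceeds the 1 uM acceptor capacity: no hook along rows
  unhooked <- hook_point(sim$matrix, axis = "rows")
  expect_true(all(is.na(unhooked$hook_concentration)))
})

test_that("FP titration plate carries all four roles with shared dose grids", {
  refs <- paper_fp_refs()
  sim <- simulate_fp_titration(refs, 31e-9, fp_receptor_grid(), 1e-9, seed = 1)
  roles <- table(sim$plate$role)
  expect_setequal(names(roles),
                  c("sample", "saturated_competitor", "protein_only",
                    "probe_only"))
  samp <- sort(unique(sim$plate$conc_M[sim$plate$role == "sample"]))
  bg <- sort(unique(sim$plate$conc_M[sim$plate$role == "protein_only"]))
  expect_equal(samp, bg)
  # default nonspecific slope contributes 5 mP at the top dose
  expect_equal(sim$truth$nonspecific_slope * max(fp_receptor_grid()), 5,
               tolerance = 1e-10)
})

test_that("noiseless FP plate round-trips the probe K_D through the analyzer", {
  refs <- paper_fp_refs()
  sim <- simulate_fp_titration(refs, 31e-9, fp_receptor_grid(), 1e-9,
                               nonspecific_slope = 0, noise_mp = 0, seed = 1)
  res <- analyze_fp_titration(sim$plate, refs$g_factor, mode = "depletion",
                              probe_total = 1e-9)
  expect_equal(res$fit$kd, 31e-9, tolerance = 1e-3)
})

test_that("FTSA simulator produces monotone Tm shifts with ligand dose", {
  p <- thermo_params(54, 420, 3.88e-6, kb_t0 = 1 / 380e-9)
  sim <- simulate_ftsa(p, c(0, 2e-6, 10e-6, 50e-6), noise_cv = 0, seed = 1)
  expect_length(sim$curves, 4)
  tms <- vapply(lapply(sim$curves, fit_melt_curve),
                function(f) f$tm, numeric(1))
  expect_true(all(diff(tms) > 0))
  expect_equal(sim$truth$kd, 380e-9, tolerance = 1e-12)
})

test_that("BLI simulator matches the closed-form model when noiseless", {
  sim <- simulate_bli(9.43e4, 1.35e-3, 1.0, 100e-9, noise_sd = 0, seed = 1)
  sg <- sim$sensorgrams[[1]]
  ia <- which(sg$phase == "association")
  t_local <- sg$time[ia] - 30   # baseline lasts 30 s
  expect_equal(sg$response[ia],
               model_association(t_local, 9.43e4, 1.35e-3, 100e-9, 1.0),
               tolerance = 1e-12)
  expect_true(all(sg$response[sg$phase == "baseline"] == 0))
})

test_that("CETSA simulator places midpoints at the programmed temperatures", {
  sim <- simulate_cetsa(54.4, 5.9, noise_cv = 0, seed = 1)
  fc <- fit_tagg(normalize_cetsa(sim$control))
  ft <- fit_tagg(normalize_cetsa(sim$treated))
  expect_equal(fc$t_agg, 54.4, tolerance = 1e-4)
  expect_equal(ft$t_agg, 60.3, tolerance = 1e-4)
  expect_equal(sim$truth$grid, seq(40, 73, by = 3))
})
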