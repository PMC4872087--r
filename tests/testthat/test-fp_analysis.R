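test_that("mP formula matches hand-computed values and bounds", {
  # hand value: i_s = 1000, i_p = 500, g = 0.91 ->
  # (1000 - 455)/(1000 + 455)*1000 = 374.5704...
  expect_equal(mp_from_intensities(1000, 500, 0.91), 545 / 1455 * 1000,
               tolerance = 1e-12)
  expect_equal(mp_from_intensities(1000, 500, 0.91), 374.570446735395,
               tolerance = 1e-10)
  expect_equal(mp_from_intensities(500, 500, 1), 0)
  expect_equal(mp_from_intensities(1000, 0, 1), 1000)
  expect_error(mp_from_intensities(1, 1, -0.5), "positive")
})

test_that("intensities_from_mp is the exact inverse of the mP/total pair", {
  set.seed(5)
  for (i in 1:50) {
    mp <- runif(1, -200, 600); tot <- runif(1, 1e3, 1e5)
    g <- runif(1, 0.7, 1.3)
    ii <- intensities_from_mp(mp, tot, g)
    expect_equal(mp_from_intensities(ii$i_s, ii$i_p, g), mp, tolerance = 1e-9)
    expect_equal(total_intensity(ii$i_s, ii$i_p), tot, tolerance = 1e-9)
  }
})

test_that("G-factor calibration pins the free probe to the target mP", {
  g <- calibrate_g_factor(i_s = 1050, i_p = 1100, target_mp = 25)
  expect_equal(g, 1050 * 975 / (1100 * 1025), tolerance = 1e-12)
  expect_equal(mp_from_intensities(1050, 1100, g), 25, tolerance = 1e-10)
  # the common working value ~0.91 arises from near-equal channels
  expect_equal(round(calibrate_g_factor(980, 1024, 25), 4), 0.9103)
})

test_that("probe linearity reports R^2 = 1 for exact lines and 0 for constants", {
  conc <- c(1, 2, 5, 10, 20) * 1e-9
  # suppressWarnings: summary.lm warns on numerically perfect fits
  lin <- suppressWarnings(probe_linearity(conc, 3e11 * conc + 50))
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)
  expect_equal(lin$slope, 3e11, tolerance = 1e-3)
  expect_equal(lin$intercept, 50, tolerance = 1e-6)
  flat <- suppressWarnings(probe_linearity(conc, rep(100, 5)))
  expect_equal(flat$r_squared, 0)
})

test_that("the specific-binding chain matches a hand-worked example and its identities", {
  refs <- polarization_references(25, 225, 0.91)
  # P_M = 150, P_I = 45: F_B = 125/200 = 0.625; P_NS = 20*0.375 = 7.5;
  # P_S = 142.5
  pts <- specific_polarization(150, 45, refs)
  expect_equal(pts$f_b, 0.625)
  expect_equal(pts$p_ns, 7.5)
  expect_equal(pts$p_s, 142.5)
  # identity: P_S + P_NS = P_M always
  set.seed(9)
  p_m <- runif(20, 25, 225); p_i <- runif(20, 25, 80)
  chain <- specific_polarization(p_m, p_i, refs)
  expect_equal(chain$p_s + chain$p_ns, chain$p_m, tolerance = 1e-12)
  # no nonspecific signal (P_I = P_D*) leaves P_M untouched
  clean <- specific_polarization(p_m, rep(25, 20), refs)
  expect_equal(clean$p_s, p_m, tolerance = 1e-12)
})

test_that("channel-wise background correction commutes with the simulator's addition", {
  refs <- paper_fp_refs()
  ii <- intensities_from_mp(120, 1e4, refs$g_factor)
  bg <- 350
  corr <- fp_background_correct(ii$i_s + bg, ii$i_p + bg, bg, bg)
  expect_equal(mp_from_intensities(corr$i_s, corr$i_p, refs$g_factor), 120,
               tolerance = 1e-10)
})

test_that("fit_probe_kd round-trips noiseless points in both modes", {
  refs <- paper_fp_refs()
  kd <- 31e-9; probe <- 1e-9
  grid <- fp_receptor_grid()
  fb <- vapply(grid, function(r) {
    st <- solve_1to1(equilibrium_spec(r, probe, kd))
    st$receptor_probe / probe
  }, numeric(1))
  p_m <- refs$p_dstar + fb * (refs$p_dstar_r - refs$p_dstar)
  pts <- specific_polarization(p_m, rep(refs$p_dstar, length(grid)), refs,
                               receptor_total = grid)
  dep <- fit_probe_kd(pts, mode = "depletion", probe_total = probe,
                      refs = refs)
  expect_true(dep$converged)
  expect_equal(dep$kd, kd, tolerance = 1e-6)
  # total mode on a probe far below kd is nearly depletion-free
  tot <- fit_probe_kd(pts, mode = "total", refs = refs)
  expect_true(tot$converged)
  expect_equal(tot$kd, kd, tolerance = 0.05)
})

test_that("depletion mode corrects the bias that total mode incurs at high probe", {
  refs <- paper_fp_refs()
  kd <- 31e-9; probe <- 60e-9   # probe ~2x kd: strong depletion
  grid <- fp_receptor_grid(0.5e-9, 2e-6, 15)
  fb <- vapply(grid, function(r) {
    st <- solve_1to1(equilibrium_spec(r, probe, kd))
    st$receptor_probe / probe
  }, numeric(1))
  p_m <- refs$p_dstar + fb * (refs$p_dstar_r - refs$p_dstar)
  pts <- specific_polarization(p_m, rep(refs$p_dstar, length(grid)), refs,
                               receptor_total = grid)
  dep <- fit_probe_kd(pts, mode = "depletion", probe_total = probe,
                      refs = refs)
  tot <- fit_probe_kd(pts, mode = "total", refs = refs)
  expect_equal(dep$kd, kd, tolerance = 1e-4)
  expect_gt(abs(tot$kd - kd) / kd, 0.2)   # total mode visibly biased here
})

test_that("full FP titration pipeline recovers a 31 nM probe K_D from a simulated plate", {
  refs <- paper_fp_refs()
  sim <- simulate_fp_titration(refs, kd = 31e-9,
                               receptor_grid = fp_receptor_grid(),
                               probe_total = 1e-9, seed = 7)
  res <- analyze_fp_titration(sim$plate, g_factor = refs$g_factor)
  expect_true(res$fit$converged)
  expect_true(res$fit$reliable)
  expect_equal(res$fit$kd, 31e-9, tolerance = 0.15)
  # references recovered close to the generating ones
  expect_equal(res$refs$p_dstar, 25, tolerance = 0.05)
})

test_that("fp_displacement_ic50 converts raw mP series through controls", {
  refs <- paper_fp_refs()
  kd_c <- calibrate_competitor_kd(1e-7, 1e-8, 31e-9, 200e-9)
  spec <- equilibrium_spec(1e-7, 1e-8, 31e-9, kd_competitor = kd_c)
  grid <- 200e-9 * 2^seq(-5, 5)
  sim <- simulate_displacement_plate("fp", spec, grid, refs = refs,
                                     noise_cv = 0.5, seed = 3)
  plate <- sim$plate
  plate$signal <- mp_from_intensities(plate$i_s, plate$i_p, refs$g_factor)
  ctl <- control_set(plate$signal[plate$role == "positive"],
                     plate$signal[plate$role == "negative"])
  samp <- plate[plate$role == "sample", ]
  reps <- lapply(grid, function(d) samp$signal[samp$conc_M == d])
  fit <- fp_displacement_ic50(dose_response_series(grid, reps, "raw_signal"),
                              ctl)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 200e-9, tolerance = 0.1)
})
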