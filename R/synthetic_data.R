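# Seeded generative models for every assay readout. Each simulator emits the
# canonical table of its consuming module plus a `sim_truth` record of the
# generating parameters, so analyzer/simulator pairs can be tested for
# parameter recovery end to end. All simulators are deterministic given
# their seed and leave the caller's RNG state untouched.

#' Ground-truth record attached to simulated data
#'
#' @param ... Named generating parameters (equilibrium spec, rates,
#'   thermodynamic parameters, noise levels, ...).
#' @param seed The seed the dataset was generated from.
#' @return Object of class `sim_truth`.
#' @export
sim_truth <- function(seed, ...) {
  structure(c(list(seed = seed, schema = "sim_truth/1"), list(...)),
            class = "sim_truth")
}

#' Alpha bead model
#'
#' Signal mechanism for the bead-proximity assay: the Alpha signal is
#' proportional to the concentration of ternary donor-complex-acceptor
#' bridges. Each bead species has a finite binding capacity; once the total
#' of its analyte exceeds that capacity, the captured fraction is diluted by
#' `capacity/total`, which produces the hook effect.
#'
#' @param donor_capacity Maximal biotin-peptide captured by donor beads,
#'   molar.
#' @param acceptor_capacity Maximal His-protein captured by acceptor beads,
#'   molar.
#' @param signal_gain Signal counts per molar complex.
#' @param background Background counts.
#' @param noise_cv Multiplicative (log-normal) noise CV.
#' @export
alpha_bead_model <- function(donor_capacity = 50e-9,
                             acceptor_capacity = 1e-6,
                             signal_gain = 1e12, background = 500,
                             noise_cv = 0.05) {
  assert_that(donor_capacity > 0 && acceptor_capacity > 0,
              "bead capacities must be positive")
  structure(list(donor_capacity = donor_capacity,
                 acceptor_capacity = acceptor_capacity,
                 signal_gain = signal_gain, background = background,
                 noise_cv = noise_cv),
            class = "alpha_bead_model")
}

# multiplicative log-normal noise with unit mean and given CV
lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate an Alpha cross-titration matrix
#'
#' Protein (rows) x biotin-peptide (cols) grid of Alpha signals under the
#' bead-capacity model: signal = gain * [complex] *
#' min(1, donor_capacity/peptide_total) * min(1, acceptor_capacity/protein_total)
#' + background, with multiplicative log-normal noise. Reproduces a hook on
#' the peptide axis once the peptide exceeds the donor capacity.
#'
#' @param model An [alpha_bead_model()].
#' @param protein_concentrations,peptide_concentrations Ascending molar axes.
#' @param kd Protein-peptide dissociation constant, molar.
#' @param seed RNG seed.
#' @return List with `matrix` (a [titration_matrix()]) and `truth`.
#' @export
simulate_alpha_matrix <- function(model, protein_concentrations,
                                  peptide_concentrations, kd, seed = 1) {
  stopifnot(inherits(model, "alpha_bead_model"))
  with_seed(seed, {
    grid <- outer(protein_concentrations, peptide_concentrations,
                  Vectorize(function(pr, pe) {
                    st <- solve_1to1(equilibrium_spec(pr, pe, kd))
                    st$receptor_probe *
                      min(1, model$donor_capacity / pe) *
                      min(1, model$acceptor_capacity / pr)
                  }))
    noise <- matrix(lnorm_noise(length(grid), model$noise_cv), nrow = nrow(grid))
    signals <- model$signal_gain * grid * noise + model$background
    list(matrix = titration_matrix(protein_concentrations,
                                   peptide_concentrations, signals),
         truth = sim_truth(seed, model = unclass(model), kd = kd,
                           protein_concentrations = protein_concentrations,
                           peptide_concentrations = peptide_concentrations))
  })
}

#' Simulate a displacement plate
#'
#' Generates the canonical long-format plate table for an Alpha or FP
#' displacement experiment from the competitive-equilibrium model, including
#' positive/negative control blocks and blanks.
#'
#' For `assay = "alpha"`, well signals are counts proportional to the
#' bound-probe (bridge) concentration plus background. For `assay = "fp"`,
#' wells carry `i_s`/`i_p` channel intensities built by inverting the mP
#' formula from P = P_D* + F_B (P_D*R - P_D*).
#'
#' @param assay `"alpha"` or `"fp"`.
#' @param spec An [equilibrium_spec()] giving receptor, probe and both
#'   affinities (its `competitor_total` is ignored).
#' @param competitor_grid Ascending molar competitor doses.
#' @param noise_cv Multiplicative noise CV for alpha signals, or additive mP
#'   noise for FP (in mP units).
#' @param n_replicates Wells per dose (default 3).
#' @param n_controls Wells per control block (default 6).
#' @param refs [polarization_references()] (FP only).
#' @param gain,background Alpha signal scale and background.
#' @param total_intensity_ref Per-well total fluorescence intensity (FP).
#' @param seed RNG seed.
#' @return List with `plate` (data.frame), `controls` hint columns, `truth`
#'   (including the theoretical half-displacement dose).
#' @export
simulate_displacement_plate <- function(assay = c("alpha", "fp"), spec,
                                        competitor_grid, noise_cv = NULL,
                                        n_replicates = 3, n_controls = 6,
                                        refs = NULL, gain = 3e12,
                                        background = 400,
                                        total_intensity_ref = 1e4,
                                        seed = 1) {
  assay <- match.arg(assay)
  stopifnot(inherits(spec, "equilibrium_spec"))
  if (is.null(noise_cv)) noise_cv <- if (assay == "alpha") 0.05 else 1
  curve <- displacement_curve(spec, competitor_grid)
  f0 <- solve_1to1(equilibrium_spec(spec$receptor_total, spec$probe_total,
                                    spec$kd_probe))$receptor_probe /
    spec$probe_total
  half_dose <- half_displacement_dose(spec, upper = max(competitor_grid) * 1e4)
  with_seed(seed, {
    if (assay == "alpha") {
      bound_conc <- curve$bound_fraction * spec$probe_total
      mk_rows <- function(conc, b_conc, role, n) {
        mu <- gain * b_conc
        sig <- mu * lnorm_noise(n, noise_cv) + background
        data.frame(role = role, compound_id = if (role == "sample")
          "competitor" else "", conc_M = conc, signal = sig)
      }
      rows <- do.call(rbind, lapply(seq_along(competitor_grid), function(i) {
        mk_rows(competitor_grid[i], bound_conc[i], "sample", n_replicates)
      }))
      pos <- mk_rows(0, f0 * spec$probe_total, "positive", n_controls)
      neg <- mk_rows(0, 0, "negative", n_controls)
      blank <- data.frame(role = "blank", compound_id = "", conc_M = 0,
                          signal = stats::rnorm(n_controls, background,
                                                background * noise_cv))
      plate <- rbind(rows, pos, neg, blank)
      plate$well <- seq_len(nrow(plate))
    } else {
      stopifnot(inherits(refs, "polarization_references"))
      span <- refs$p_dstar_r - refs$p_dstar
      mk_fp_rows <- function(conc, fb, role, n) {
        mp <- refs$p_dstar + fb * span + stats::rnorm(n, 0, noise_cv)
        ii <- intensities_from_mp(mp, total_intensity_ref, refs$g_factor)
        data.frame(role = role, compound_id = if (role == "sample")
          "competitor" else "", conc_M = conc, i_s = ii$i_s, i_p = ii$i_p)
      }
      rows <- do.call(rbind, lapply(seq_along(competitor_grid), function(i) {
        mk_fp_rows(competitor_grid[i], curve$bound_fraction[i], "sample",
                   n_replicates)
      }))
      pos <- mk_fp_rows(0, f0, "positive", n_controls)
      neg <- mk_fp_rows(0, 0, "negative", n_controls)  # probe only
      plate <- rbind(rows, pos, neg)
      plate$well <- seq_len(nrow(plate))
    }
    list(plate = plate,
         truth = sim_truth(seed, assay = assay, spec = unclass(spec),
                           competitor_grid = competitor_grid,
                           noise_cv = noise_cv, zero_dose_bound_fraction = f0,
                           half_displacement_dose = half_dose))
  })
}

#' Analyze a simulated displacement plate to an IC50
#'
#' Convenience chain: build controls from the plate's control blocks,
#' convert sample wells to percent inhibition and fit the 4PL. Works for
#' both assay flavors emitted by [simulate_displacement_plate()].
#'
#' @param plate Plate data.frame.
#' @param g_factor G-factor (FP plates only).
#' @return A `four_pl_fit`.
#' @export
analyze_displacement_plate <- function(plate, g_factor = NULL) {
  is_fp <- "i_s" %in% names(plate)
  if (is_fp) {
    assert_that(!is.null(g_factor), "FP plates need a g_factor")
    plate$signal <- mp_from_intensities(plate$i_s, plate$i_p, g_factor)
  } else if ("blank" %in% plate$role) {
    blank_mean <- mean(plate$signal[plate$role == "blank"])
    plate$signal <- plate$signal - blank_mean
  }
  ctl <- control_set(plate$signal[plate$role == "positive"],
                     plate$signal[plate$role == "negative"],
                     blank_values = plate$signal[plate$role == "blank"])
  samp <- plate[plate$role == "sample", ]
  doses <- sort(unique(samp$conc_M))
  reps <- lapply(doses, function(d) {
    percent_inhibition(samp$signal[samp$conc_M == d], ctl)
  })
  series <- dose_response_series(doses, reps,
                                 response_kind = "percent_inhibition")
  fit_4pl(series)
}

#' Simulate an FP probe titration plate
#'
#' Builds the full FP K_D-determination layout: probe+receptor wells (P_M),
#' protein-only background wells, saturated-competitor wells (P_I),
#' and probe-only reference wells. Well polarizations follow
#' P = P_D* + F_B (P_D*R - P_D*) + nonspecific_slope * receptor, with F_B
#' from the exact 1:1 equilibrium; channel intensities are obtained by
#' inverting the mP formula, and the protein's intrinsic background
#' intensities are added channel-wise so that the analyzer's background
#' correction is exercised.
#'
#' @param refs A [polarization_references()].
#' @param kd True probe-receptor K_D, molar.
#' @param receptor_grid Ascending molar receptor doses.
#' @param probe_total Total probe concentration, molar.
#' @param nonspecific_slope Nonspecific polarization per molar receptor
#'   (mP/M); the default (`NULL`) contributes 5 mP at the top of the
#'   titrated range, the small residual typical of BSA/CHAPS-buffered FP
#'   assays.
#' @param noise_mp Additive polarization noise, mP.
#' @param n_replicates Wells per dose.
#' @param total_intensity_ref Probe total intensity per well.
#' @param bg_intensity_slope Protein background intensity per molar receptor
#'   (per channel).
#' @param seed RNG seed.
#' @return List with `plate` and `truth`.
#' @export
simulate_fp_titration <- function(refs, kd, receptor_grid, probe_total,
                                  nonspecific_slope = NULL, noise_mp = 1,
                                  n_replicates = 3,
                                  total_intensity_ref = 1e4,
                                  bg_intensity_slope = 2e8, seed = 1) {
  stopifnot(inherits(refs, "polarization_references"))
  if (is.null(nonspecific_slope)) {
    nonspecific_slope <- 5 / max(receptor_grid)
  }
  span <- refs$p_dstar_r - refs$p_dstar
  fb <- vapply(receptor_grid, function(r) {
    st <- solve_1to1(equilibrium_spec(r, probe_total, kd))
    st$receptor_probe / probe_total
  }, numeric(1))
  with_seed(seed, {
    mk <- function(role, conc, mp_mean, n, bg = TRUE, noise = noise_mp) {
      mp <- mp_mean + stats::rnorm(n, 0, noise)
      ii <- intensities_from_mp(mp, total_intensity_ref, refs$g_factor)
      bg_i <- if (bg) conc * bg_intensity_slope else 0
      data.frame(role = role, conc_M = conc,
                 i_s = ii$i_s + bg_i, i_p = ii$i_p + bg_i)
    }
    rows <- list()
    for (i in seq_along(receptor_grid)) {
      r <- receptor_grid[i]
      ns <- nonspecific_slope * r
      rows[[length(rows) + 1]] <-
        mk("sample", r, refs$p_dstar + fb[i] * span + ns, n_replicates)
      rows[[length(rows) + 1]] <-
        mk("saturated_competitor", r, refs$p_dstar + ns, n_replicates)
      # protein-only wells: intensities only, polarization content irrelevant
      bg_i <- r * bg_intensity_slope
      rows[[length(rows) + 1]] <- data.frame(
        role = "protein_only", conc_M = r,
        i_s = rep(bg_i, n_replicates), i_p = rep(bg_i, n_replicates))
    }
    rows[[length(rows) + 1]] <-
      mk("probe_only", 0, refs$p_dstar, n_replicates, bg = FALSE)
    plate <- do.call(rbind, rows)
    plate$well <- seq_len(nrow(plate))
    list(plate = plate,
         truth = sim_truth(seed, kd = kd, probe_total = probe_total,
                           receptor_grid = receptor_grid,
                           refs = unclass(refs),
                           nonspecific_slope = nonspecific_slope,
                           noise_mp = noise_mp))
  })
}

#' Simulate FTSA melt curves across ligand doses
#'
#' Per-temperature fluorescence from the two-state unfolding model coupled
#' to ligand binding: F(T) = (F_N(T) + F_U(T) K_app(T)) / (1 + K_app(T)),
#' where K_app(T) = K_U(T) / (1 + K_b(T) [L_free](T)) is the apparent
#' unfolding constant with free ligand from the full three-species
#' equilibrium at each temperature. Linear native/unfolded baselines and an
#' optional exponential post-peak decay (dye dissociating from aggregates)
#' complete the trace; noise is multiplicative.
#'
#' @param params A [thermo_params()] with a finite `kb_t0`.
#' @param ligand_doses Molar doses (include 0 for the reference curve).
#' @param temperatures Temperature grid, deg C.
#' @param f_native,f_unfolded Baseline intercepts (native < unfolded).
#' @param slope_native,slope_unfolded Baseline slopes per deg C.
#' @param decay_tau Post-peak decay constant, deg C; `Inf` disables decay.
#' @param noise_cv Multiplicative noise CV.
#' @param seed RNG seed.
#' @return List with `curves` (list of [melt_curve()]) and `truth`.
#' @export
simulate_ftsa <- function(params, ligand_doses,
                          temperatures = seq(25, 95, by = 0.5),
                          f_native = 100, f_unfolded = 1100,
                          slope_native = 0.5, slope_unfolded = -2,
                          decay_tau = 25, noise_cv = 0.02, seed = 1) {
  stopifnot(inherits(params, "thermo_params"))
  assert_that(is.finite(params$kb_t0) && params$kb_t0 > 0,
              "simulate_ftsa needs a finite kb_t0 (set K_D via kb_t0 = 1/K_D)")
  with_seed(seed, {
    curves <- lapply(ligand_doses, function(lt) {
      k_app <- vapply(temperatures, function(tc) {
        sp <- ftsa_species(tc, params, lt)
        fu <- sp$unfolded_fraction
        fu / (1 - fu)
      }, numeric(1))
      fn <- f_native + slope_native * (temperatures - min(temperatures))
      fu_base <- f_unfolded + slope_unfolded * (temperatures - min(temperatures))
      f <- (fn + fu_base * k_app) / (1 + k_app)
      if (is.finite(decay_tau)) {
        # dye loss from aggregates well past the transition
        frac_unfolded <- k_app / (1 + k_app)
        onset <- suppressWarnings(min(temperatures[frac_unfolded > 0.99]))
        if (is.finite(onset)) {
          over <- pmax(0, temperatures - onset)
          f <- f * exp(-over / decay_tau)
        }
      }
      f <- f * lnorm_noise(length(f), noise_cv)
      melt_curve(temperatures, f, ligand_total = lt,
                 label = sprintf("L=%.3g M", lt))
    })
    list(curves = curves,
         truth = sim_truth(seed, params = unclass(params),
                           ligand_doses = ligand_doses, noise_cv = noise_cv,
                           kd = 1 / params$kb_t0))
  })
}

#' Simulate BLI sensorgrams
#'
#' Piecewise baseline/association/dissociation traces from the 1:1 Langmuir
#' model with additive Gaussian noise and optional linear drift; a paired
#' buffer reference trace carries the same drift so reference subtraction
#' removes it.
#'
#' @param ka,kd_rate True rate constants (1/(M s), 1/s).
#' @param rmax Maximal response, nm.
#' @param concentrations Analyte concentrations, molar.
#' @param phase_durations Named vector: `baseline`, `association`,
#'   `dissociation` durations in seconds.
#' @param dt Sampling interval, seconds.
#' @param noise_sd Additive noise SD, nm.
#' @param drift Linear drift, nm/s.
#' @param seed RNG seed.
#' @return List with `sensorgrams` (list), `reference` (buffer trace) and
#'   `truth`.
#' @export
simulate_bli <- function(ka, kd_rate, rmax, concentrations,
                         phase_durations = c(baseline = 30, association = 120,
                                             dissociation = 120),
                         dt = 0.5, noise_sd = 0.01, drift = 0, seed = 1) {
  assert_that(ka > 0 && kd_rate > 0, "rates must be positive")
  durs <- phase_durations[c("baseline", "association", "dissociation")]
  with_seed(seed, {
    mk_trace <- function(conc) {
      t_b <- seq(0, durs[["baseline"]], by = dt)
      t_a <- seq(dt, durs[["association"]], by = dt)
      t_d <- seq(dt, durs[["dissociation"]], by = dt)
      r_a <- model_association(t_a, ka, kd_rate, conc, rmax)
      r_end <- model_association(durs[["association"]], ka, kd_rate, conc, rmax)
      r_d <- model_dissociation(t_d, kd_rate, r_end)
      time <- c(t_b, durs[["baseline"]] + t_a,
                durs[["baseline"]] + durs[["association"]] + t_d)
      resp <- c(rep(0, length(t_b)), r_a, r_d) + drift * time +
        stats::rnorm(length(time), 0, noise_sd)
      sensorgram(time, resp,
                 c(rep("baseline", length(t_b)),
                   rep("association", length(t_a)),
                   rep("dissociation", length(t_d))),
                 analyte_concentration = conc,
                 run_id = sprintf("c=%.3g M", conc))
    }
    sgs <- lapply(concentrations, mk_trace)
    reference <- mk_trace(0)
    reference$run_id <- "reference"
    list(sensorgrams = sgs, reference = reference,
         truth = sim_truth(seed, ka = ka, kd_rate = kd_rate,
                           kd_eq = kd_rate / ka, rmax = rmax,
                           concentrations = concentrations,
                           noise_sd = noise_sd, drift = drift))
  })
}

#' Simulate a CETSA series pair
#'
#' Control and treated soluble-fraction series from decreasing Boltzmann
#' curves at `t_agg_control` and `t_agg_control + delta`, scaled to
#' blot-like intensity units with multiplicative noise.
#'
#' @param t_agg_control Control aggregation midpoint, deg C.
#' @param delta Programmed shift of the treated series, deg C.
#' @param grid Temperature grid, deg C (default the 12-point 40-73 deg C
#'   gradient in 3 deg C steps).
#' @param steepness Transition steepness, deg C.
#' @param top_intensity,bottom_intensity Intensity scale of the blot bands.
#' @param noise_cv Multiplicative noise CV.
#' @param seed RNG seed.
#' @return List with `control`, `treated` ([cetsa_series()]) and `truth`.
#' @export
simulate_cetsa <- function(t_agg_control, delta, grid = seq(40, 73, by = 3),
                           steepness = 2, top_intensity = 1000,
                           bottom_intensity = 30, noise_cv = 0.05, seed = 1) {
  assert_that(!is.unsorted(grid, strictly = TRUE), "grid must be ascending")
  boltz <- function(tt, t_agg) {
    bottom_intensity + (top_intensity - bottom_intensity) /
      (1 + exp((tt - t_agg) / steepness))
  }
  with_seed(seed, {
    ctl <- boltz(grid, t_agg_control) * lnorm_noise(length(grid), noise_cv)
    trt <- boltz(grid, t_agg_control + delta) *
      lnorm_noise(length(grid), noise_cv)
    list(control = cetsa_series(grid, ctl, "control", "membrane-1"),
         treated = cetsa_series(grid, trt, "treated", "membrane-1"),
         truth = sim_truth(seed, t_agg_control = t_agg_control, delta = delta,
                           grid = grid, steepness = steepness,
                           noise_cv = noise_cv))
  })
}
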