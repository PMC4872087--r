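# Fluorescent thermal shift assay (FTSA/DSF): Boltzmann melting-curve
# fitting, Tm shifts, and K_D estimation from ligand-dose-dependent Tm
# shifts via a coupled two-state-unfolding / 1:1-binding model.
#
# Model. Native protein N binds ligand L (K_b = [NL]/([N][L]), temperature-
# dependent via van't Hoff) and unfolds to U (K_U = [U]/[N], from the
# Gibbs-Helmholtz free energy). At the melting temperature half the protein
# is unfolded: U = N + NL. Eliminating species from the two equilibria and
# the conservation laws gives the total ligand needed to place the midpoint
# at temperature T:
#
#   L_t(T) = (K_U(T) - 1) * ( 1/K_b(T) + M_t / (2 K_U(T)) )
#
# with ΔG_U(T) = ΔH_U (1 - T/T_r) - ΔCp_U [(T_r - T) + T ln(T/T_r)]
# (absolute temperatures; ΔG_U(T_r) = 0 so L_t(T_r) = 0). Inverting L_t
# numerically yields predicted Tm per dose; least squares over the binding
# constant yields K_D = 1/K_b(T_0).

#' Thermodynamic parameters for the Tm-dosing model
#'
#' @param t_r Reference (ligand-free) melting temperature, deg C.
#' @param dh_u Unfolding enthalpy at `t_r`, kJ/mol (> 0).
#' @param dcp_u Unfolding heat-capacity change, kJ/(mol K). Default 8, a
#'   typical value for small single-domain proteins.
#' @param kb_t0 Binding constant at `t0`, 1/M (> 0); K_D = 1/kb_t0. May be
#'   `NA` when the constant is the quantity being fitted.
#' @param dh_b Binding enthalpy, kJ/mol. Default -42 (a typical exothermic
#'   peptide-protein binding enthalpy).
#' @param dcp_b Binding heat-capacity change, kJ/(mol K). Default 0.
#' @param t0 Reference temperature for reporting K_D, deg C. Default 37.
#' @param protein_total Total protein concentration M_t, molar (> 0).
#' @return Object of class `thermo_params`.
#' @export
thermo_params <- function(t_r, dh_u, protein_total, kb_t0 = NA_real_,
                          dcp_u = 8, dh_b = -42, dcp_b = 0, t0 = 37) {
  assert_that(is.numeric(dh_u) && dh_u > 0, "dh_u must be positive (kJ/mol)")
  assert_that(is.na(kb_t0) || kb_t0 > 0, "kb_t0 must be positive (1/M)")
  assert_that(protein_total > 0, "protein_total must be positive (molar)")
  structure(list(t_r = t_r, dh_u = dh_u, dcp_u = dcp_u, kb_t0 = kb_t0,
                 dh_b = dh_b, dcp_b = dcp_b, t0 = t0,
                 protein_total = protein_total),
            class = "thermo_params")
}

# Unfolding equilibrium constant K_U(T); temperatures in deg C.
ku_unfolding <- function(temp_c, params) {
  tk <- c_to_k(temp_c); trk <- c_to_k(params$t_r)
  dg <- params$dh_u * (1 - tk / trk) -
    params$dcp_u * ((trk - tk) + tk * log(tk / trk))
  exp(-dg / (.R_GAS * tk))
}

# Binding constant K_b(T) extrapolated from kb at t0 via integrated
# van't Hoff with constant ΔCp_b.
kb_at_temp <- function(temp_c, params, kb_t0 = params$kb_t0) {
  tk <- c_to_k(temp_c); t0k <- c_to_k(params$t0)
  lnk <- log(kb_t0) -
    (params$dh_b - params$dcp_b * t0k) / .R_GAS * (1 / tk - 1 / t0k) +
    params$dcp_b / .R_GAS * log(tk / t0k)
  exp(lnk)
}

# Total ligand that places the melting midpoint at temp_c.
ligand_total_at_tm <- function(temp_c, params, kb_t0 = params$kb_t0) {
  ku <- ku_unfolding(temp_c, params)
  kb <- kb_at_temp(temp_c, params, kb_t0)
  (ku - 1) * (1 / kb + params$protein_total / (2 * ku))
}

#' Predict the melting temperature at a ligand dose
#'
#' Root-finds the temperature at which the coupled unfolding-binding model
#' places the melting midpoint for the given total ligand concentration.
#' Strictly increasing in the dose; returns `t_r` exactly at zero dose.
#'
#' @param params A [thermo_params()] with a finite `kb_t0`.
#' @param ligand_total Total ligand concentration, molar (vectorized).
#' @param search_width Width of the root bracket above `t_r`, deg C.
#' @return Predicted Tm in deg C.
#' @export
predict_tm <- function(params, ligand_total, search_width = 60) {
  stopifnot(inherits(params, "thermo_params"))
  assert_that(is.finite(params$kb_t0) && params$kb_t0 > 0,
              "predict_tm requires a finite positive kb_t0")
  vapply(ligand_total, function(lt) {
    if (lt == 0) return(params$t_r)
    f <- function(t) ligand_total_at_tm(t, params) - lt
    hi <- params$t_r + search_width
    if (f(hi) < 0) {
      stop(sprintf(paste("no Tm root within %.0f deg C above the reference;",
                         "dose %.3g M exceeds the model's range"),
                   search_width, lt), call. = FALSE)
    }
    stats::uniroot(f, lower = params$t_r, upper = hi, tol = 1e-10)$root
  }, numeric(1))
}

#' Three-species equilibrium at a fixed temperature
#'
#' Independent solver for the native/ligand-bound/unfolded system used to
#' cross-check the Tm-dosing relation: given K_U(T) and K_b(T), solves the
#' conservation laws for N, NL, U and free L and reports the unfolded
#' fraction. At a Tm predicted by [predict_tm()] the unfolded fraction is
#' 1/2 by construction.
#'
#' @param temp_c Temperature, deg C.
#' @param params A [thermo_params()].
#' @param ligand_total Total ligand, molar.
#' @param kb_t0 Binding constant override (1/M).
#' @return List with `n`, `nl`, `u`, `l_free`, `unfolded_fraction`.
#' @export
ftsa_species <- function(temp_c, params, ligand_total,
                         kb_t0 = params$kb_t0) {
  ku <- ku_unfolding(temp_c, params)
  kb <- kb_at_temp(temp_c, params, kb_t0)
  mt <- params$protein_total
  if (ligand_total == 0) {
    n <- mt / (1 + ku)
    return(list(n = n, nl = 0, u = ku * n, l_free = 0,
                unfolded_fraction = ku / (1 + ku)))
  }
  # free ligand balance, monotone in l on [0, ligand_total]
  f <- function(l) {
    n <- mt / (1 + ku + kb * l)
    l + kb * n * l - ligand_total
  }
  l <- stats::uniroot(f, lower = 0, upper = ligand_total,
                      tol = .Machine$double.eps * ligand_total)$root
  n <- mt / (1 + ku + kb * l)
  list(n = n, nl = kb * n * l, u = ku * n, l_free = l,
       unfolded_fraction = ku * n / mt)
}

#' Fit K_D from a Tm dosing series
#'
#' Least-squares over the binding constant `kb_t0` minimizing the squared
#' difference between observed Tms and [predict_tm()] across the dose
#' series. The reference Tm (`t_r`) is taken from the zero-dose point. The
#' reported K_D = 1/kb_t0 refers to temperature `params$t0`.
#'
#' @param series A [tm_dose_series()] (or list with `ligand_totals`, `tms`).
#' @param params A [thermo_params()]; its `kb_t0` is ignored and `t_r` is
#'   replaced by the observed zero-dose Tm.
#' @param shift_floor Smallest maximal Tm shift (deg C) treated as evidence
#'   of binding; below it the result is flagged `non_binder`.
#' @return List with `kd` (molar), `kb_t0`, `kd_se` (crude curvature-based),
#'   `params` (as used), `sse`, `non_binder` flag and `predicted_tms`.
#' @export
fit_kd_from_dosing <- function(series, params, shift_floor = 0.2) {
  stopifnot(inherits(params, "thermo_params"))
  lt <- series$ligand_totals; tm <- series$tms
  assert_that(length(lt) == length(tm), "dose/Tm lengths differ")
  assert_that(length(lt) >= 4, "need >= 4 doses")
  assert_that(any(lt == 0), "series must include the zero-dose reference")
  params$t_r <- mean(tm[lt == 0])
  max_shift <- max(tm) - params$t_r
  if (max_shift < shift_floor) {
    return(list(kd = NA_real_, kb_t0 = NA_real_, kd_se = NA_real_,
                params = params, sse = NA_real_, non_binder = TRUE,
                predicted_tms = rep(params$t_r, length(lt))))
  }
  sse <- function(log10_kb) {
    p <- params; p$kb_t0 <- 10^log10_kb
    pred <- tryCatch(predict_tm(p, lt), error = function(e) NULL)
    if (is.null(pred)) return(1e12)
    sum((tm - pred)^2)
  }
  opt <- stats::optimize(sse, interval = c(0, 12), tol = 1e-7)
  kb <- 10^opt$minimum
  # curvature of SSE in log10 kb -> rough standard error on log10 kb
  h <- 0.05
  d2 <- (sse(opt$minimum + h) - 2 * opt$objective + sse(opt$minimum - h)) / h^2
  n_eff <- max(1, sum(lt > 0) - 1)
  log10_se <- if (is.finite(d2) && d2 > 0) {
    sqrt(2 * opt$objective / n_eff / d2)
  } else NA_real_
  params$kb_t0 <- kb
  list(kd = 1 / kb, kb_t0 = kb,
       kd_se = if (is.na(log10_se)) NA_real_ else (1 / kb) * log(10) * log10_se,
       params = params, sse = opt$objective, non_binder = FALSE,
       predicted_tms = predict_tm(params, lt))
}

#' Tm dosing series
#'
#' @param ligand_totals Molar ligand doses (must include 0).
#' @param tms Fitted melting temperatures, deg C.
#' @export
tm_dose_series <- function(ligand_totals, tms) {
  assert_that(length(ligand_totals) == length(tms), "length mismatch")
  assert_that(any(ligand_totals == 0), "series must include the zero dose")
  structure(list(ligand_totals = as.numeric(ligand_totals),
                 tms = as.numeric(tms)),
            class = "tm_dose_series")
}

#' Estimate the unfolding enthalpy from melt-curve steepness
#'
#' Two-state van't Hoff relation at the midpoint: the logistic steepness s
#' (deg C) of the transition corresponds to ΔH_U = R * Tm^2 / s.
#'
#' @param tm Melting temperature, deg C.
#' @param steepness Fitted transition steepness, deg C.
#' @return Enthalpy in kJ/mol.
#' @export
dh_u_from_steepness <- function(tm, steepness) {
  assert_that(steepness > 0, "steepness must be positive")
  .R_GAS * c_to_k(tm)^2 / steepness
}

#' Melt curve container
#'
#' @param temperatures Ascending temperatures, deg C (>= 20 points).
#' @param fluorescence Dye fluorescence, arbitrary units.
#' @param ligand_total Molar ligand dose of the well.
#' @param label Optional label.
#' @export
melt_curve <- function(temperatures, fluorescence, ligand_total = 0,
                       label = "") {
  assert_that(length(temperatures) == length(fluorescence), "length mismatch")
  assert_that(length(temperatures) >= 20, "need >= 20 temperature points")
  assert_that(!is.unsorted(temperatures), "temperatures must be ascending")
  structure(list(temperatures = as.numeric(temperatures),
                 fluorescence = as.numeric(fluorescence),
                 ligand_total = ligand_total, label = label),
            class = "melt_curve")
}

#' Fit a Boltzmann melting curve
#'
#' Truncates the trace at its global fluorescence maximum (discarding the
#' post-peak decay caused by dye dissociating from aggregates), then fits
#' F(T) = pre(T) + (post(T) - pre(T)) / (1 + exp((tm - T)/steepness)) with
#' linear pre- and post-transition baselines. Flat traces (e.g. dye-only
#' negative controls) yield an explicit no-transition result.
#'
#' @param curve A [melt_curve()].
#' @param min_rise Minimal transition amplitude, as a fraction of the maximum
#'   fluorescence, below which the curve is declared transition-free.
#' @return A `melt_fit` with `tm`, baseline coefficients,
#'   `transition_steepness`, `truncation_temp` and `has_transition`.
#' @export
fit_melt_curve <- function(curve, min_rise = 0.05) {
  stopifnot(inherits(curve, "melt_curve"))
  tt <- curve$temperatures; ff <- curve$fluorescence
  i_max <- which.max(ff)
  keep <- seq_len(i_max)
  t_use <- tt[keep]; f_use <- ff[keep]
  no_transition <- function() {
    structure(list(tm = NA_real_, tm_se = NA_real_,
                   pre_baseline = c(intercept = NA_real_, slope = NA_real_),
                   post_baseline = c(intercept = NA_real_, slope = NA_real_),
                   transition_steepness = NA_real_,
                   truncation_temp = tt[i_max], has_transition = FALSE,
                   label = curve$label),
              class = "melt_fit")
  }
  amp <- diff(range(f_use))
  if (length(t_use) < 10 || amp < min_rise * max(abs(ff), 1)) {
    return(no_transition())
  }
  # initialize: midpoint at half-rise, baselines from the outer 20% of points
  f_norm <- (f_use - min(f_use)) / amp
  tm0 <- t_use[which.min(abs(f_norm - 0.5))]
  n <- length(t_use)
  lo <- seq_len(max(3, floor(0.2 * n)))
  hi <- seq(n - max(3, floor(0.2 * n)) + 1, n)
  pre0 <- stats::coef(stats::lm(f_use[lo] ~ t_use[lo]))
  post0 <- stats::coef(stats::lm(f_use[hi] ~ t_use[hi]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f_use ~ (a1 + b1 * t_use) +
        ((a2 + b2 * t_use) - (a1 + b1 * t_use)) /
        (1 + exp((tm - t_use) / s)),
      start = list(a1 = unname(pre0[1]), b1 = unname(pre0[2]),
                   a2 = unname(post0[1]), b2 = unname(post0[2]),
                   tm = tm0, s = 1),
      lower = c(-Inf, -Inf, -Inf, -Inf, min(t_use), 1e-3),
      upper = c(Inf, Inf, Inf, Inf, max(t_use), 30),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(no_transition())
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) stats::setNames(rep(NA_real_, 6), names(cf)))
  if (cf[["tm"]] <= min(t_use) + 1e-6 || cf[["tm"]] >= max(t_use) - 1e-6) {
    return(no_transition())   # midpoint pinned at the window edge
  }
  structure(list(tm = unname(cf[["tm"]]), tm_se = unname(se[["tm"]]),
                 pre_baseline = c(intercept = unname(cf[["a1"]]),
                                  slope = unname(cf[["b1"]])),
                 post_baseline = c(intercept = unname(cf[["a2"]]),
                                   slope = unname(cf[["b2"]])),
                 transition_steepness = unname(cf[["s"]]),
                 truncation_temp = tt[i_max], has_transition = TRUE,
                 label = curve$label),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  if (!x$has_transition) {
    cat("melt_fit: no transition detected\n")
  } else {
    cat(sprintf("melt_fit: Tm = %.2f deg C (steepness %.2f), truncated at %.1f\n",
                x$tm, x$transition_steepness, x$truncation_temp))
  }
  invisible(x)
}

#' Melting-temperature shift
#'
#' @param sample,reference `melt_fit` objects; both must have a transition.
#' @return sample Tm minus reference Tm, deg C.
#' @export
delta_tm <- function(sample, reference) {
  stopifnot(inherits(sample, "melt_fit"), inherits(reference, "melt_fit"))
  if (!sample$has_transition || !reference$has_transition) {
    stop("delta_tm requires two curves with detected transitions", call. = FALSE)
  }
  sample$tm - reference$tm
}
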