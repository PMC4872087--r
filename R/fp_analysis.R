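# Fluorescence-polarization pipeline: intensity -> mP conversion, G-factor
# calibration, the specific-binding correction chain (F_B, P_NS, P_S), probe
# linearity check, K_D and displacement IC50 fitting.
#
# Channel convention: i_s is the s-plane (perpendicular) intensity, i_p the
# p-plane (parallel) intensity, both blank-corrected.

#' Millipolarization from channel intensities
#'
#' P = (I_S - G * I_P) / (I_S + G * I_P) * 1000 mP.
#'
#' @param i_s,i_p Blank-corrected s- and p-plane intensities (vectorized).
#' @param g Grating (G-) factor of the instrument, > 0.
#' @return Polarization in mP, bounded in (-1000, 1000].
#' @export
mp_from_intensities <- function(i_s, i_p, g) {
  assert_that(is.numeric(g) && all(g > 0), "G-factor must be positive")
  denom <- i_s + g * i_p
  if (any(denom <= 0)) {
    stop("non-positive total intensity I_S + G*I_P; cannot form mP",
         call. = FALSE)
  }
  (i_s - g * i_p) / denom * 1000
}

#' Invert the mP formula to channel intensities
#'
#' Given a polarization and a total intensity (2*I_P + I_S convention),
#' reconstructs the unique (i_s, i_p) pair. Exact inverse of
#' [mp_from_intensities()] / [total_intensity()]; used by the FP simulator.
#'
#' @param mp Polarization in mP (< 1000).
#' @param total Total intensity 2*I_P + I_S.
#' @param g G-factor.
#' @return List with `i_s`, `i_p`.
#' @export
intensities_from_mp <- function(mp, total, g) {
  assert_that(all(mp < 1000), "mP must be < 1000 to invert")
  p <- mp / 1000
  ratio <- g * (1 + p) / (1 - p)   # i_s / i_p
  i_p <- total / (2 + ratio)
  list(i_s = ratio * i_p, i_p = i_p)
}

#' Total fluorescence intensity
#'
#' Default mode is the plain channel sum 2*I_P + I_S used throughout the
#' plate-reader workflow; `"g_weighted"` gives the conventional
#' I_par + 2*G*I_perp (here i_p + 2*g*i_s) as an alternative.
#'
#' @inheritParams mp_from_intensities
#' @param mode `"as_measured"` (default) or `"g_weighted"`.
#' @export
total_intensity <- function(i_s, i_p, mode = c("as_measured", "g_weighted"),
                            g = NULL) {
  mode <- match.arg(mode)
  if (mode == "as_measured") return(2 * i_p + i_s)
  assert_that(!is.null(g), "g_weighted mode requires a G-factor")
  i_p + 2 * g * i_s
}

#' Probe linearity check
#'
#' Ordinary least-squares line through total intensity vs probe
#' concentration; the dilution-series QC that validates the working range of
#' a fluorescent probe.
#'
#' @param concentrations Molar probe concentrations (>= 3).
#' @param totals Total intensities.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
probe_linearity <- function(concentrations, totals) {
  assert_that(length(concentrations) >= 3, "need at least 3 points")
  assert_that(length(concentrations) == length(totals), "length mismatch")
  fit <- stats::lm(totals ~ concentrations)
  # summary.lm's R^2 is numerically unstable when the responses are exactly
  # constant (0/0); define it as zero explained variance in that case
  r2 <- if (stats::var(totals) == 0) 0 else summary(fit)$r.squared
  if (is.nan(r2)) r2 <- 0
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Calibrate the G-factor from a free-probe read
#'
#' Solves mp_from_intensities(i_s, i_p, G) = target_mp for G:
#' G = i_s * (1000 - target) / (i_p * (1000 + target)). The standard
#' procedure anchors the free-probe polarization to a known value
#' (e.g. ~25 mP for fluorescein-labeled peptides).
#'
#' @param i_s,i_p Free-probe channel intensities (i_p > 0).
#' @param target_mp Desired free-probe polarization, |target_mp| < 1000.
#' @return G-factor (dimensionless).
#' @export
calibrate_g_factor <- function(i_s, i_p, target_mp) {
  assert_that(all(i_p > 0), "i_p must be positive")
  assert_that(abs(target_mp) < 1000, "target mP must lie in (-1000, 1000)")
  i_s * (1000 - target_mp) / (i_p * (1000 + target_mp))
}

#' Polarization reference set
#'
#' @param p_dstar Free-probe polarization P_D* (mP).
#' @param p_dstar_r Saturated probe-receptor polarization P_D*R (mP);
#'   must exceed `p_dstar`.
#' @param g_factor Instrument G-factor, > 0.
#' @export
polarization_references <- function(p_dstar, p_dstar_r, g_factor) {
  assert_that(p_dstar_r > p_dstar, "P_D*R must exceed P_D*")
  assert_that(g_factor > 0, "G-factor must be positive")
  structure(list(p_dstar = p_dstar, p_dstar_r = p_dstar_r,
                 g_factor = g_factor),
            class = "polarization_references")
}

#' Specific-binding correction chain
#'
#' Applies, in order: F_B = (P_M - P_D*) / (P_D*R - P_D*);
#' P_NS = (P_I - P_D*) * (1 - F_B); P_S = P_M - P_NS. P_M is the measured
#' (background-corrected) polarization, P_I the polarization with a
#' saturating unlabeled competitor (probe fully displaced, nonspecific
#' binding only).
#'
#' @param p_m,p_i Measured and competitor-saturated polarizations (mP),
#'   vectorized.
#' @param refs A [polarization_references()].
#' @param receptor_total Optional molar receptor doses carried through.
#' @return data.frame with `receptor_total` (if given), `p_m`, `p_i`, `f_b`,
#'   `p_ns`, `p_s`.
#' @export
specific_polarization <- function(p_m, p_i, refs, receptor_total = NULL) {
  stopifnot(inherits(refs, "polarization_references"))
  span <- refs$p_dstar_r - refs$p_dstar
  if (span == 0) stop("P_D*R equals P_D*: reference span is zero", call. = FALSE)
  f_b <- (p_m - refs$p_dstar) / span
  p_ns <- (p_i - refs$p_dstar) * (1 - f_b)
  p_s <- p_m - p_ns
  out <- data.frame(p_m = p_m, p_i = p_i, f_b = f_b, p_ns = p_ns, p_s = p_s)
  if (!is.null(receptor_total)) out <- cbind(receptor_total = receptor_total, out)
  out
}

#' Channel-wise background correction
#'
#' Subtracts protein-only well intensities from probe-well intensities
#' channel by channel, before any mP conversion (polarization is nonlinear in
#' the intensities, so subtraction must happen at intensity level).
#'
#' @param i_s,i_p Probe-well intensities.
#' @param bg_i_s,bg_i_p Matched protein-only background intensities.
#' @return List with corrected `i_s`, `i_p`.
#' @export
fp_background_correct <- function(i_s, i_p, bg_i_s, bg_i_p) {
  list(i_s = i_s - bg_i_s, i_p = i_p - bg_i_p)
}

#' Probe K_D from corrected binding points
#'
#' Fits specific polarization P_S against receptor concentration. The default
#' `"total"` mode fits the one-site hyperbola against TOTAL receptor
#' concentration, exactly as plate-based FP titrations are conventionally
#' plotted. `"depletion"` mode instead fits
#' P_S = Bmax * F_B(R_total; K_D, probe_total) with the bound fraction from
#' the exact 1:1 equilibrium, which removes the ligand-depletion bias that
#' the total-concentration hyperbola incurs when the probe concentration is
#' not far below K_D.
#'
#' Because specific polarization retains the free-probe baseline
#' (P_S -> P_D* as receptor -> 0), the fit is performed on P_S - P_D* when
#' `refs` is supplied, so that the hyperbola's zero matches the data's zero.
#'
#' @param points data.frame from [specific_polarization()] including a
#'   `receptor_total` column (>= 4 rows).
#' @param mode `"total"` (default) or `"depletion"`.
#' @param probe_total Total probe concentration (molar); required for
#'   depletion mode.
#' @param refs Optional [polarization_references()]; when given, `p_dstar`
#'   is subtracted from `p_s` before fitting.
#' @return A `hyperbola_fit` (with `kd`, `bmax`, diagnostics).
#' @export
fit_probe_kd <- function(points, mode = c("total", "depletion"),
                         probe_total = NULL, refs = NULL) {
  mode <- match.arg(mode)
  assert_that(is.data.frame(points) && "receptor_total" %in% names(points) &&
                "p_s" %in% names(points),
              "points must carry receptor_total and p_s columns")
  assert_that(nrow(points) >= 4, "need >= 4 binding points")
  if (!is.null(refs)) {
    stopifnot(inherits(refs, "polarization_references"))
    points$p_s <- points$p_s - refs$p_dstar
  }
  if (mode == "total") {
    return(fit_hyperbola(points$receptor_total, points$p_s))
  }
  assert_that(!is.null(probe_total) && probe_total > 0,
              "depletion mode requires probe_total")
  x <- points$receptor_total; y <- points$p_s
  fb_of <- function(rt, kd) {
    vapply(rt, function(r) {
      st <- solve_1to1(equilibrium_spec(r, probe_total, kd))
      st$receptor_probe / probe_total
    }, numeric(1))
  }
  bmax0 <- max(y)
  kd0 <- x[which.min(abs(y - bmax0 / 2))]
  fit <- minpack.lm::nls.lm(
    par = list(log_kd = log(kd0), bmax = bmax0),
    fn = function(par) y - par$bmax * fb_of(x, exp(par$log_kd)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  kd <- exp(fit$par$log_kd)
  covm <- tryCatch({
    s2 <- fit$deviance / max(1, length(y) - 2)
    s2 * solve(fit$hessian)
  }, error = function(e) matrix(NA_real_, 2, 2))
  kd_se <- kd * sqrt(abs(covm[1, 1]))  # delta method from log scale
  structure(list(kd = kd, bmax = fit$par$bmax,
                 kd_se = kd_se, bmax_se = sqrt(abs(covm[2, 2])),
                 converged = fit$info %in% 1:4, reliable = kd <= 10 * max(x),
                 residual_norm = sqrt(fit$deviance)),
            class = "hyperbola_fit")
}

#' FP displacement IC50
#'
#' Converts polarization signals to percent inhibition against
#' probe+receptor (positive) and probe-only (negative) controls, then fits
#' the four-parameter logistic.
#'
#' @param series A [dose_response_series()]; raw-signal series are converted
#'   to percent inhibition with `controls` first.
#' @param controls A [control_set()] (positive: probe+receptor wells,
#'   negative: probe-only wells).
#' @return A `four_pl_fit`.
#' @export
fp_displacement_ic50 <- function(series, controls) {
  stopifnot(inherits(series, "dose_response_series"))
  if (series$response_kind == "raw_signal") {
    inh <- lapply(series$responses, percent_inhibition, controls = controls)
    series <- dose_response_series(series$concentrations, inh,
                                   response_kind = "percent_inhibition")
  }
  fit_4pl(series)
}

#' Analyze a simulated or measured FP titration plate
#'
#' Runs the full correction chain on a canonical FP plate table (columns
#' `role`, `conc_M`, `i_s`, `i_p`): channel-wise background correction using
#' the protein-only wells, mP conversion, reference extraction (P_D* from
#' probe-only wells, P_D*R from the highest-dose sample wells), the
#' F_B/P_NS/P_S chain, and the K_D fit.
#'
#' @param plate data.frame in the canonical FP layout (see
#'   [simulate_fp_titration()]).
#' @param g_factor Instrument G-factor.
#' @param mode Passed to [fit_probe_kd()].
#' @param probe_total Required for depletion mode.
#' @return List with `points` (corrected binding points), `refs` and `fit`.
#' @export
analyze_fp_titration <- function(plate, g_factor,
                                 mode = c("total", "depletion"),
                                 probe_total = NULL) {
  mode <- match.arg(mode)
  need <- c("role", "conc_M", "i_s", "i_p")
  assert_that(all(need %in% names(plate)),
              paste("plate table must have columns:", paste(need, collapse = ", ")))
  agg <- function(df) {
    out <- stats::aggregate(cbind(i_s, i_p) ~ conc_M, data = df, FUN = mean)
    out[order(out$conc_M), ]
  }
  samples <- agg(plate[plate$role == "sample", ])
  bg <- agg(plate[plate$role == "protein_only", ])
  sat <- agg(plate[plate$role == "saturated_competitor", ])
  probe_only <- plate[plate$role == "probe_only", ]
  assert_that(nrow(samples) > 0 && nrow(bg) > 0 && nrow(sat) > 0 &&
                nrow(probe_only) > 0,
              "plate must contain sample, protein_only, saturated_competitor and probe_only wells")
  assert_that(identical(samples$conc_M, bg$conc_M) &&
                identical(samples$conc_M, sat$conc_M),
              "sample, background and saturated wells must share the dose grid")
  corr_m <- fp_background_correct(samples$i_s, samples$i_p, bg$i_s, bg$i_p)
  corr_i <- fp_background_correct(sat$i_s, sat$i_p, bg$i_s, bg$i_p)
  p_m <- mp_from_intensities(corr_m$i_s, corr_m$i_p, g_factor)
  p_i <- mp_from_intensities(corr_i$i_s, corr_i$i_p, g_factor)
  p_dstar <- mean(mp_from_intensities(probe_only$i_s, probe_only$i_p, g_factor))
  p_dstar_r <- p_m[which.max(samples$conc_M)]
  refs <- polarization_references(p_dstar, p_dstar_r, g_factor)
  points <- specific_polarization(p_m, p_i, refs,
                                  receptor_total = samples$conc_M)
  fit <- fit_probe_kd(points, mode = mode, probe_total = probe_total,
                      refs = refs)
  list(points = points, refs = refs, fit = fit)
}
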