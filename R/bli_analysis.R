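# Biolayer interferometry: 1:1 Langmuir sensorgram model, global
# multi-concentration kinetic fitting, competitive report-point and
# dissociation-shift readouts, and biosensor regeneration QC.

#' 1:1 Langmuir association response
#'
#' R(t) = R_eq (1 - exp(-k_obs t)) with k_obs = ka c + kd and
#' R_eq = rmax c / (c + kd/ka). Monotone non-decreasing in t.
#'
#' @param t Time since association start, seconds (>= 0).
#' @param ka Association rate, 1/(M s).
#' @param kd_rate Dissociation rate, 1/s.
#' @param c Analyte concentration, molar.
#' @param rmax Maximal response, nm.
#' @return Response in nm.
#' @export
model_association <- function(t, ka, kd_rate, c, rmax) {
  assert_that(all(t >= 0), "time must be non-negative")
  kobs <- ka * c + kd_rate
  req <- if (kobs > 0) rmax * ka * c / kobs else 0
  req * (1 - exp(-kobs * t))
}

#' First-order dissociation response
#'
#' R(t) = r0 exp(-kd t).
#'
#' @param t Time since dissociation start, seconds (>= 0).
#' @param kd_rate Dissociation rate, 1/s.
#' @param r0 Response at the start of dissociation, nm.
#' @export
model_dissociation <- function(t, kd_rate, r0) {
  assert_that(all(t >= 0), "time must be non-negative")
  r0 * exp(-kd_rate * t)
}

#' Equilibrium K_D from kinetic rates
#'
#' @param ka Association rate, 1/(M s), > 0.
#' @param kd_rate Dissociation rate, 1/s.
#' @return K_D = kd_rate / ka, molar.
#' @export
kd_from_rates <- function(ka, kd_rate) {
  assert_that(all(ka > 0), "ka must be positive")
  kd_rate / ka
}

#' Sensorgram container
#'
#' @param time Ascending times, seconds.
#' @param response Responses, nm.
#' @param phase Per-point labels among `baseline`, `association`,
#'   `dissociation`; must be contiguous and in that order (baseline
#'   optional).
#' @param analyte_concentration Analyte concentration, molar.
#' @param reference_subtracted Logical flag.
#' @param run_id Optional identifier.
#' @export
sensorgram <- function(time, response, phase, analyte_concentration,
                       reference_subtracted = FALSE, run_id = "") {
  assert_that(length(time) == length(response) &&
                length(time) == length(phase), "length mismatch")
  assert_that(!is.unsorted(time), "time must be ascending")
  phase <- as.character(phase)
  allowed <- c("baseline", "association", "dissociation")
  assert_that(all(phase %in% allowed),
              "phase labels must be baseline/association/dissociation")
  r <- rle(phase)
  assert_that(identical(r$values, intersect(allowed, r$values)),
              "phases must be contiguous and ordered baseline < association < dissociation")
  structure(list(time = as.numeric(time), response = as.numeric(response),
                 phase = phase,
                 analyte_concentration = analyte_concentration,
                 reference_subtracted = isTRUE(reference_subtracted),
                 run_id = run_id),
            class = "sensorgram")
}

phase_idx <- function(sg, ph) which(sg$phase == ph)

#' Reference-subtract a sensorgram
#'
#' Pointwise subtraction of a buffer reference trace; the reference is
#' linearly interpolated when the time grids differ.
#'
#' @param sample,reference `sensorgram` objects with overlapping time ranges.
#' @return The corrected sensorgram with `reference_subtracted = TRUE`.
#' @export
reference_subtract <- function(sample, reference) {
  stopifnot(inherits(sample, "sensorgram"), inherits(reference, "sensorgram"))
  if (max(reference$time) < min(sample$time) ||
      min(reference$time) > max(sample$time)) {
    stop("sample and reference time ranges do not overlap", call. = FALSE)
  }
  ref <- if (identical(sample$time, reference$time)) reference$response else
    stats::approx(reference$time, reference$response, xout = sample$time,
                  rule = 2)$y
  out <- sample
  out$response <- sample$response - ref
  out$reference_subtracted <- TRUE
  out
}

#' Re-zero a sensorgram at the association start
#'
#' Subtracts the mean of the final `window` seconds of the baseline phase and
#' shifts time so the association phase starts at t = 0.
#'
#' @param sg A `sensorgram` containing a baseline phase.
#' @param window Averaging window, seconds.
#' @export
rezero_association <- function(sg, window = 5) {
  stopifnot(inherits(sg, "sensorgram"))
  ib <- phase_idx(sg, "baseline")
  ia <- phase_idx(sg, "association")
  assert_that(length(ia) > 0, "no association phase")
  if (length(ib) > 0) {
    t_end <- max(sg$time[ib])
    late <- ib[sg$time[ib] >= t_end - window]
    sg$response <- sg$response - mean(sg$response[late])
  }
  sg$time <- sg$time - min(sg$time[ia])
  sg
}

# Fraction of signal lost during the dissociation phase.
dissociation_decay_fraction <- function(sg) {
  id <- phase_idx(sg, "dissociation")
  if (length(id) < 2) return(NA_real_)
  r0 <- sg$response[id[1]]
  if (r0 <= 0) return(NA_real_)
  (r0 - sg$response[id[length(id)]]) / r0
}

#' Global 1:1 kinetic fit across concentrations
#'
#' Fits a single (ka, kd, rmax) by least squares jointly over the
#' association and dissociation phases of all sensorgrams; rmax is shared
#' across curves (single loaded or regenerated-equivalent sensor), with an
#' optional per-curve-rmax mode for fresh-sensor runs. Initialization uses
#' the standard two-step seeding: kd from a log-linear fit of late
#' dissociation, ka from the regression of per-curve k_obs on concentration.
#'
#' Curves whose dissociation decays less than `decay_floor` (default 5%)
#' are flagged: their information on kd is weak and the fitted kd is marked
#' unreliable.
#'
#' @param sensorgrams List of `sensorgram` objects at >= 2 distinct analyte
#'   concentrations, reference-subtracted and baseline-re-zeroed (or raw
#'   with a baseline phase, in which case they are re-zeroed here).
#' @param shared_rmax Share rmax across curves (default TRUE).
#' @param decay_floor Minimal dissociation decay fraction.
#' @return A `kinetic_fit` with `ka`, `kd_rate`, `kd_eq` (= kd_rate/ka),
#'   `rmax`, per-curve residual norms, `low_decay_curves` and
#'   `kd_reliable` flags.
#' @export
global_fit_1to1 <- function(sensorgrams, shared_rmax = TRUE,
                            decay_floor = 0.05) {
  assert_that(length(sensorgrams) >= 2, "need sensorgrams at >= 2 concentrations")
  sgs <- lapply(sensorgrams, function(sg) {
    stopifnot(inherits(sg, "sensorgram"))
    if (length(phase_idx(sg, "baseline")) > 0) rezero_association(sg) else sg
  })
  concs <- vapply(sgs, function(s) s$analyte_concentration, numeric(1))
  assert_that(length(unique(concs)) >= 2,
              "need >= 2 distinct analyte concentrations")
  decay <- vapply(sgs, dissociation_decay_fraction, numeric(1))
  low_decay <- which(is.finite(decay) & decay < decay_floor)

  # assemble per-curve phase data with phase-local time; the association
  # clock starts at the end of the baseline phase (the true phase boundary),
  # the dissociation clock at the end of the association phase
  parts <- lapply(seq_along(sgs), function(i) {
    sg <- sgs[[i]]
    ia <- phase_idx(sg, "association"); id <- phase_idx(sg, "dissociation")
    ib <- phase_idx(sg, "baseline")
    assert_that(length(ia) >= 3 && length(id) >= 3,
                "each curve needs association and dissociation points")
    t0a <- if (length(ib) > 0) max(sg$time[ib]) else min(sg$time[ia])
    t_assoc_end <- max(sg$time[ia])
    list(i = i, c = sg$analyte_concentration,
         ta = sg$time[ia] - t0a, ra = sg$response[ia],
         ta_dur = t_assoc_end - t0a,
         td = sg$time[id] - t_assoc_end, rd = sg$response[id])
  })

  # --- seeding ---------------------------------------------------------
  kd0 <- {
    ests <- vapply(parts, function(p) {
      pos <- p$rd > 0.05 * max(p$rd)
      if (sum(pos) < 3) return(NA_real_)
      -stats::coef(stats::lm(log(p$rd[pos]) ~ p$td[pos]))[[2]]
    }, numeric(1))
    m <- stats::median(ests[is.finite(ests) & ests > 0])
    if (is.finite(m) && m > 0) m else 1e-3
  }
  kobs0 <- vapply(parts, function(p) {
    req0 <- max(p$ra)
    frac <- pmin(p$ra / req0, 0.99)
    sel <- p$ta > 0 & frac > 0.05
    if (sum(sel) < 3) return(NA_real_)
    -stats::coef(stats::lm(log(1 - frac[sel]) ~ p$ta[sel] - 1))[[1]]
  }, numeric(1))
  ok <- is.finite(kobs0) & kobs0 > 0
  ka0 <- if (sum(ok) >= 2) {
    max(stats::coef(stats::lm(kobs0[ok] ~ concs[ok]))[[2]], 1)
  } else max(stats::median(kobs0[ok] / concs[ok], na.rm = TRUE), 1)
  rmax0 <- max(vapply(parts, function(p) max(p$ra), numeric(1)))

  # --- global least squares -------------------------------------------
  n_r <- if (shared_rmax) 1L else length(parts)
  resid_fun <- function(par) {
    ka <- exp(par[1]); kd <- exp(par[2]); rmaxes <- par[2 + seq_len(n_r)]
    unlist(lapply(parts, function(p) {
      rmax <- if (shared_rmax) rmaxes[1] else rmaxes[p$i]
      pa <- model_association(p$ta, ka, kd, p$c, rmax)
      r_end <- model_association(p$ta_dur, ka, kd, p$c, rmax)
      pd <- model_dissociation(p$td, kd, r_end)
      c(p$ra - pa, p$rd - pd)
    }))
  }
  fit <- minpack.lm::nls.lm(
    par = c(log(ka0), log(kd0), rep(rmax0, n_r)),
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 400))
  if (!(fit$info %in% 1:4)) {
    stop("global 1:1 fit failed to converge (nls.lm info = ", fit$info, ")",
         call. = FALSE)
  }
  ka <- exp(fit$par[1]); kd_rate <- exp(fit$par[2])
  rmax <- fit$par[2 + seq_len(n_r)]
  covm <- tryCatch({
    dof <- max(1, length(resid_fun(fit$par)) - length(fit$par))
    (fit$deviance / dof) * solve(fit$hessian)
  }, error = function(e) matrix(NA_real_, 2 + n_r, 2 + n_r))
  per_curve <- vapply(parts, function(p) {
    rm_i <- if (shared_rmax) rmax[1] else rmax[p$i]
    pa <- model_association(p$ta, ka, kd_rate, p$c, rm_i)
    r_end <- model_association(p$ta_dur, ka, kd_rate, p$c, rm_i)
    pd <- model_dissociation(p$td, kd_rate, r_end)
    sqrt(sum(c(p$ra - pa, p$rd - pd)^2))
  }, numeric(1))
  structure(list(
    ka = ka, kd_rate = kd_rate, kd_eq = kd_from_rates(ka, kd_rate),
    rmax = rmax,
    ka_se = ka * sqrt(abs(covm[1, 1])), kd_rate_se = kd_rate * sqrt(abs(covm[2, 2])),
    per_curve_residuals = per_curve,
    concentrations = concs,
    low_decay_curves = low_decay,
    kd_reliable = length(low_decay) < length(parts),
    converged = TRUE), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Global 1:1 Langmuir fit\n")
  cat(sprintf("  ka   : %.4g 1/(M s)  (SE %.2g)\n", x$ka, x$ka_se))
  cat(sprintf("  kd   : %.4g 1/s      (SE %.2g)\n", x$kd_rate, x$kd_rate_se))
  cat(sprintf("  K_D  : %.4g M\n", x$kd_eq))
  if (length(x$low_decay_curves) > 0) {
    cat("  note: curves with <5% dissociation decay:",
        paste(x$low_decay_curves, collapse = ", "),
        if (!x$kd_reliable) "- kd unreliable" else "", "\n")
  }
  invisible(x)
}

#' Local dissociation fit for one sensorgram
#'
#' Single-exponential fit of the dissociation phase, used for the
#' competitive dissociation-shift readout where each curve is fitted
#' locally.
#'
#' @param sg A `sensorgram` with a dissociation phase.
#' @return List with `kd_rate`, `r0`, `decay_fraction`.
#' @export
fit_dissociation <- function(sg) {
  stopifnot(inherits(sg, "sensorgram"))
  id <- phase_idx(sg, "dissociation")
  ia <- phase_idx(sg, "association")
  assert_that(length(id) >= 5, "need >= 5 dissociation points")
  t0d <- if (length(ia) > 0) max(sg$time[ia]) else min(sg$time[id])
  td <- sg$time[id] - t0d; rd <- sg$response[id]
  kd0 <- {
    pos <- rd > 0.05 * max(rd)
    est <- if (sum(pos) >= 3)
      -stats::coef(stats::lm(log(rd[pos]) ~ td[pos]))[[2]] else 1e-3
    if (is.finite(est) && est > 0) est else 1e-3
  }
  fit <- minpack.lm::nlsLM(rd ~ r0 * exp(-kd * td),
                           start = list(r0 = max(rd), kd = kd0),
                           lower = c(0, 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(kd_rate = unname(cf[["kd"]]), r0 = unname(cf[["r0"]]),
       decay_fraction = dissociation_decay_fraction(sg))
}

#' Report-point displacement
#'
#' Percent reduction of the sample's binding signal relative to the positive
#' control, read at a report point `time_offset` seconds before the end of
#' the association phase.
#'
#' @param sample,control `sensorgram` objects sharing association timing.
#' @param time_offset Seconds before association end (default 5).
#' @return Percent displacement, 100 * (1 - R_sample/R_control).
#' @export
report_point_displacement <- function(sample, control, time_offset = 5) {
  stopifnot(inherits(sample, "sensorgram"), inherits(control, "sensorgram"))
  t_rp <- function(sg) max(sg$time[phase_idx(sg, "association")]) - time_offset
  r_at <- function(sg, t) stats::approx(sg$time, sg$response, xout = t)$y
  t_s <- t_rp(sample); t_c <- t_rp(control)
  assert_that(abs(t_s - t_c) < 1e-6,
              "sample and control association phases are not aligned")
  rc <- r_at(control, t_c)
  if (!is.finite(rc) || rc <= 0) {
    stop("control response at the report point is non-positive", call. = FALSE)
  }
  100 * (1 - r_at(sample, t_s) / rc)
}

#' Dissociation-rate shift
#'
#' Fold change of the dissociation rate in the presence of a competitor;
#' values above 1 indicate competition.
#'
#' @param kd_sample,kd_control Dissociation rates, 1/s, both > 0.
#' @export
dissociation_shift <- function(kd_sample, kd_control) {
  assert_that(all(kd_sample > 0) && all(kd_control > 0),
              "rates must be positive")
  kd_sample / kd_control
}

#' Regeneration QC across biosensor cycles
#'
#' Coefficient of variation of the association maxima over regeneration
#' cycles; the sensor is `stable` if the overall CV stays within
#' `cv_threshold`. `usable_cycles` is the largest leading run of cycles
#' whose running CV stays within the threshold.
#'
#' @param association_maxima Per-cycle association maxima, nm (>= 2 cycles).
#' @param cv_threshold Percent CV allowed (default 10).
#' @return List with `stable`, `cv` (percent), `usable_cycles`.
#' @export
regeneration_qc <- function(association_maxima, cv_threshold = 10) {
  x <- as.numeric(association_maxima)
  assert_that(length(x) >= 2, "need >= 2 cycles")
  cv <- function(v) 100 * stats::sd(v) / mean(v)
  running <- vapply(2:length(x), function(k) cv(x[1:k]), numeric(1))
  usable <- if (any(running > cv_threshold)) {
    which(running > cv_threshold)[1]   # cycles before the first violation
  } else length(x)
  list(stable = cv(x) <= cv_threshold, cv = cv(x), usable_cycles = usable)
}
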