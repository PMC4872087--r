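# Plate-level quantitation shared by the AlphaLISA and FP displacement
# assays: control statistics, inhibition/quench percentages, Z'-factor,
# four-parameter logistic IC50 fitting and hook-point detection in
# cross-titration matrices.

#' Plate control set
#'
#' Holds the positive-control, negative-control and blank wells of one plate.
#' Control statistics are always derived on demand (see [control_stats()]),
#' never stored, so they cannot go stale.
#'
#' @param positive_values,negative_values Blank-corrected control signals.
#' @param blank_values Raw blank signals (optional, kept for provenance).
#' @param label Optional plate/control-set label used in error messages.
#' @return An object of class `control_set`.
#' @export
control_set <- function(positive_values, negative_values,
                        blank_values = numeric(), label = "controls") {
  assert_that(length(positive_values) >= 1 && length(negative_values) >= 1,
              "both control arms must be non-empty")
  assert_that(all(is.finite(positive_values)) && all(is.finite(negative_values)),
              "control values must be finite")
  structure(list(positive_values = as.numeric(positive_values),
                 negative_values = as.numeric(negative_values),
                 blank_values = as.numeric(blank_values),
                 label = as.character(label)),
            class = "control_set")
}

#' Control statistics
#'
#' @param controls A [control_set()].
#' @return List with `mu_max`, `mu_min` (means of the positive and negative
#'   arm) and `sd_max`, `sd_min`.
#' @export
control_stats <- function(controls) {
  stopifnot(inherits(controls, "control_set"))
  list(mu_max = mean(controls$positive_values),
       mu_min = mean(controls$negative_values),
       sd_max = stats::sd(controls$positive_values),
       sd_min = stats::sd(controls$negative_values))
}

#' Percent inhibition of a displacement signal
#'
#' I = 100 * (1 - (A_i - mu_min) / (mu_max - mu_min)). Values are returned
#' unclipped: negative inhibition and values above 100% are preserved for QC.
#'
#' @param a_i Blank-corrected sample signal(s).
#' @param controls A [control_set()].
#' @return Percent inhibition, vectorized over `a_i`.
#' @export
percent_inhibition <- function(a_i, controls) {
  s <- control_stats(controls)
  if (!is.finite(s$mu_max - s$mu_min) || s$mu_max == s$mu_min) {
    stop("degenerate controls in '", controls$label,
         "': positive and negative means are equal", call. = FALSE)
  }
  100 * (1 - (a_i - s$mu_min) / (s$mu_max - s$mu_min))
}

#' Percent Alpha-signal quench
#'
#' Q = 100 * (1 - A_i / mu_max), the counter-screen statistic for
#' signal-interference (e.g. TruHits-style) wells.
#'
#' @inheritParams percent_inhibition
#' @export
percent_quench <- function(a_i, controls) {
  s <- control_stats(controls)
  if (!(s$mu_max > 0)) {
    stop("non-positive positive-control mean in '", controls$label, "'",
         call. = FALSE)
  }
  100 * (1 - a_i / s$mu_max)
}

#' Z'-factor assay-quality statistic
#'
#' Z' = 1 - (3 SD_max + 3 SD_min) / |mu_max - mu_min|. Always <= 1; equals 1
#' only in the noiseless limit. Invariant under affine rescaling of all
#' signals and under swapping the two control arms.
#'
#' @param controls A [control_set()] with >= 2 values per arm.
#' @export
z_prime <- function(controls) {
  stopifnot(inherits(controls, "control_set"))
  assert_that(length(controls$positive_values) >= 2 &&
                length(controls$negative_values) >= 2,
              "Z' needs at least 2 values per control arm")
  s <- control_stats(controls)
  if (s$mu_max == s$mu_min) {
    stop("identical control means in '", controls$label, "'", call. = FALSE)
  }
  1 - (3 * s$sd_max + 3 * s$sd_min) / abs(s$mu_max - s$mu_min)
}

#' Signal-to-background ratio
#'
#' @param controls A [control_set()] with positive negative-control mean.
#' @return mu_max / mu_min.
#' @export
signal_to_background <- function(controls) {
  s <- control_stats(controls)
  if (!(s$mu_min > 0)) {
    stop("non-positive background (negative-control mean) in '",
         controls$label, "'", call. = FALSE)
  }
  s$mu_max / s$mu_min
}

#' Dose-response series
#'
#' Ascending competitor doses with replicate responses. Replicates are stored
#' as a list of numeric vectors; fitting uses unweighted per-dose means.
#'
#' @param concentrations Strictly positive, strictly ascending molar doses.
#' @param responses Numeric vector (one response per dose), matrix
#'   (doses x replicates) or list of numeric vectors.
#' @param response_kind Either `"raw_signal"` or `"percent_inhibition"`.
#' @return Object of class `dose_response_series`.
#' @export
dose_response_series <- function(concentrations,
                                 responses,
                                 response_kind = c("raw_signal",
                                                   "percent_inhibition")) {
  response_kind <- match.arg(response_kind)
  conc <- as.numeric(concentrations)
  assert_that(all(conc > 0), "concentrations must be strictly positive")
  assert_that(!is.unsorted(conc, strictly = TRUE),
              "concentrations must be strictly ascending")
  if (is.matrix(responses)) {
    responses <- lapply(seq_len(nrow(responses)), function(i) responses[i, ])
  } else if (is.numeric(responses)) {
    responses <- as.list(as.numeric(responses))
  }
  assert_that(length(responses) == length(conc),
              "responses must have one entry per concentration")
  structure(list(concentrations = conc,
                 responses = lapply(responses, as.numeric),
                 response_kind = response_kind),
            class = "dose_response_series")
}

#' @export
print.dose_response_series <- function(x, ...) {
  cat(sprintf("dose_response_series: %d doses (%.3g - %.3g M), kind '%s'\n",
              length(x$concentrations), min(x$concentrations),
              max(x$concentrations), x$response_kind))
  invisible(x)
}

series_means <- function(series) vapply(series$responses, mean, numeric(1))

#' Four-parameter logistic (variable-slope) IC50 fit
#'
#' Fits I(c) = bottom + (top - bottom) / (1 + (ic50/c)^hill) on log10
#' concentration. Initialization: top = max, bottom = min, ic50 at the
#' half-range crossing, hill = 1.
#'
#' @param series A [dose_response_series()] in `percent_inhibition` kind with
#'   >= 4 distinct doses.
#' @return A `four_pl_fit` with `ic50` (molar), `hill`, `top`, `bottom`,
#'   standard errors, 95% confidence half-widths, and flags: `converged`,
#'   `extrapolated` (ic50 outside the titrated range) and `out_of_band`
#'   (ic50 outside `[c_min/10, c_max*10]`). Degenerate (flat) series return a
#'   non-converged fit rather than fabricated parameters.
#' @export
fit_4pl <- function(series) {
  stopifnot(inherits(series, "dose_response_series"))
  assert_that(series$response_kind == "percent_inhibition",
              "fit_4pl expects a percent_inhibition series")
  conc <- series$concentrations
  assert_that(length(unique(conc)) >= 4, "need >= 4 distinct concentrations")
  y <- series_means(series)
  lx <- log10(conc)
  fail <- function(why) {
    structure(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                   bottom = NA_real_, se = c(ic50 = NA_real_, hill = NA_real_,
                                             top = NA_real_, bottom = NA_real_),
                   ci_halfwidth = NULL, converged = FALSE,
                   extrapolated = NA, out_of_band = NA,
                   residual_norm = NA_real_, note = why),
              class = "four_pl_fit")
  }
  if (diff(range(y)) < 1e-9 * max(abs(y), 1)) {
    return(fail("no transition: all responses equal"))
  }
  top0 <- max(y); bot0 <- min(y)
  half <- (top0 + bot0) / 2
  l50 <- tryCatch(stats::approx(y, lx, xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(l50)) l50 <- stats::median(lx)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (l50p - lx))),
      start = list(top = top0, bottom = bot0, l50p = l50, hill = 1),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("nonlinear fit did not converge"))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) stats::setNames(rep(NA_real_, 4), names(cf)))
  ic50 <- 10^cf[["l50p"]]
  # delta-method SE of ic50 from the SE of log10(ic50)
  ic50_se <- ic50 * log(10) * se[["l50p"]]
  structure(list(
    ic50 = ic50, hill = unname(cf[["hill"]]), top = unname(cf[["top"]]),
    bottom = unname(cf[["bottom"]]),
    se = c(ic50 = unname(ic50_se), hill = unname(se[["hill"]]),
           top = unname(se[["top"]]), bottom = unname(se[["bottom"]])),
    ci_halfwidth = c(ic50 = 1.96 * unname(ic50_se),
                     hill = 1.96 * unname(se[["hill"]])),
    converged = TRUE,
    extrapolated = ic50 < min(conc) || ic50 > max(conc),
    out_of_band = ic50 < min(conc) / 10 || ic50 > max(conc) * 10,
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    note = NULL), class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat("Four-parameter logistic fit\n")
  if (!x$converged) {
    cat("  NOT CONVERGED:", x$note %||% "", "\n")
    return(invisible(x))
  }
  cat(sprintf("  IC50   : %.4g M (SE %.2g)\n", x$ic50, x$se[["ic50"]]))
  cat(sprintf("  hill   : %.3f   top: %.2f   bottom: %.2f\n",
              x$hill, x$top, x$bottom))
  if (isTRUE(x$out_of_band)) cat("  WARNING: IC50 far outside titrated range\n")
  else if (isTRUE(x$extrapolated)) cat("  note: IC50 extrapolated beyond range\n")
  invisible(x)
}

#' Cross-titration matrix
#'
#' Blank-corrected signal grid from titrating one binder (rows) against the
#' other (columns), the layout used to locate bead-capacity hook points.
#'
#' @param row_concentrations,col_concentrations Strictly ascending molar axes.
#' @param signals Numeric matrix, `length(row_concentrations)` x
#'   `length(col_concentrations)`.
#' @export
titration_matrix <- function(row_concentrations, col_concentrations, signals) {
  rc <- as.numeric(row_concentrations); cc <- as.numeric(col_concentrations)
  assert_that(is.matrix(signals) &&
                nrow(signals) == length(rc) && ncol(signals) == length(cc),
              "signal grid dimensions must match the concentration axes")
  assert_that(!is.unsorted(rc, strictly = TRUE) &&
                !is.unsorted(cc, strictly = TRUE),
              "concentration axes must be strictly ascending")
  structure(list(row_concentrations = rc, col_concentrations = cc,
                 signals = signals),
            class = "titration_matrix")
}

#' Hook-point detection along one axis of a cross-titration
#'
#' For each line scanned along `axis`, reports the concentration of the raw
#' signal maximum if the signal beyond it drops by more than `drop_threshold`
#' relative to that maximum (the bead-capacity hook effect); `NA` otherwise.
#' No smoothing is applied: the grids are small and smoothing would blur the
#' hook.
#'
#' @param matrix A [titration_matrix()].
#' @param axis `"cols"` scans along the column axis (one line per row);
#'   `"rows"` scans along the row axis (one line per column).
#' @param drop_threshold Relative drop below the maximum that declares a hook.
#' @return data.frame with `line_concentration` (the fixed-axis dose of each
#'   line) and `hook_concentration` (molar, `NA` if no hook).
#' @export
hook_point <- function(matrix, axis = c("cols", "rows"),
                       drop_threshold = 0.10) {
  stopifnot(inherits(matrix, "titration_matrix"))
  axis <- match.arg(axis)
  scan_conc <- if (axis == "cols") matrix$col_concentrations else
    matrix$row_concentrations
  assert_that(length(scan_conc) >= 4,
              "need >= 4 concentrations on the scanned axis")
  lines <- if (axis == "cols") {
    lapply(seq_len(nrow(matrix$signals)), function(i) matrix$signals[i, ])
  } else {
    lapply(seq_len(ncol(matrix$signals)), function(j) matrix$signals[, j])
  }
  fixed_conc <- if (axis == "cols") matrix$row_concentrations else
    matrix$col_concentrations
  hooks <- vapply(lines, function(sig) {
    i_max <- which.max(sig)
    if (i_max == length(sig)) return(NA_real_)
    beyond <- sig[(i_max + 1):length(sig)]
    if (any(beyond < (1 - drop_threshold) * sig[i_max])) scan_conc[i_max]
    else NA_real_
  }, numeric(1))
  data.frame(line_concentration = fixed_conc, hook_concentration = hooks)
}
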