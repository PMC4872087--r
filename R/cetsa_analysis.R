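# Cellular thermal shift assay (CETSA): band-intensity normalization,
# Boltzmann aggregation-curve fitting, apparent T_agg and ligand-induced
# T_agg shifts.

#' CETSA series
#'
#' One immunoblot-quantified melting series: soluble-fraction band
#' intensities across a temperature gradient for one condition on one
#' membrane.
#'
#' @param temperatures Ascending temperatures, deg C (>= 6).
#' @param band_intensities Band intensities, arbitrary units.
#' @param condition_label,membrane_id Identifiers.
#' @param replicate Replicate index.
#' @export
cetsa_series <- function(temperatures, band_intensities,
                         condition_label = "", membrane_id = "",
                         replicate = 1L) {
  assert_that(length(temperatures) == length(band_intensities),
              "length mismatch")
  assert_that(length(temperatures) >= 6, "need >= 6 temperatures")
  assert_that(!is.unsorted(temperatures), "temperatures must be ascending")
  structure(list(temperatures = as.numeric(temperatures),
                 band_intensities = as.numeric(band_intensities),
                 condition_label = condition_label,
                 membrane_id = membrane_id, replicate = replicate),
            class = "cetsa_series")
}

#' Normalize CETSA band intensities
#'
#' Two per-membrane modes: `"min_max"` (default) rescales the highest and
#' lowest intensity on the membrane to 100 and 0%; `"relative_to_lowest_temp"`
#' expresses each intensity relative to the lowest-temperature sample. Both
#' commute with any positive rescaling of the raw intensities, so film
#' exposure does not affect the normalized curve.
#'
#' @param series A [cetsa_series()].
#' @param mode Normalization mode.
#' @return The series with `band_intensities` replaced by percent values and
#'   a `normalization` field set.
#' @export
normalize_cetsa <- function(series,
                            mode = c("min_max", "relative_to_lowest_temp")) {
  stopifnot(inherits(series, "cetsa_series"))
  mode <- match.arg(mode)
  x <- series$band_intensities
  if (mode == "min_max") {
    if (max(x) == min(x)) {
      stop("degenerate intensities on membrane '", series$membrane_id,
           "': max equals min", call. = FALSE)
    }
    series$band_intensities <- 100 * (x - min(x)) / (max(x) - min(x))
  } else {
    ref <- x[which.min(series$temperatures)]
    if (!(ref > 0)) {
      stop("non-positive lowest-temperature reference on membrane '",
           series$membrane_id, "'", call. = FALSE)
    }
    series$band_intensities <- 100 * x / ref
  }
  series$normalization <- mode
  series
}

#' Fit the Boltzmann aggregation curve
#'
#' Fits Y(T) = bottom + (top - bottom) / (1 + exp((T - t_agg)/steepness))
#' (decreasing in temperature for steepness > 0) to a normalized CETSA
#' series and returns the apparent aggregation temperature. Series without a
#' decreasing transition yield an explicit no-transition result; increasing
#' series are rejected as mis-oriented.
#'
#' @param series A normalized [cetsa_series()].
#' @param min_drop Minimal fractional drop of the signal across the series
#'   for a transition to be declared.
#' @return An `aggregation_fit` with `t_agg`, `top`, `bottom`, `steepness`,
#'   `t_agg_se` and `has_transition`.
#' @export
fit_tagg <- function(series, min_drop = 0.2) {
  stopifnot(inherits(series, "cetsa_series"))
  tt <- series$temperatures; yy <- series$band_intensities
  no_transition <- function() {
    structure(list(t_agg = NA_real_, t_agg_se = NA_real_, top = NA_real_,
                   bottom = NA_real_, steepness = NA_real_,
                   has_transition = FALSE,
                   condition_label = series$condition_label),
              class = "aggregation_fit")
  }
  rng <- diff(range(yy))
  if (rng < min_drop * max(abs(yy), 1)) return(no_transition())
  # orientation: soluble fraction must fall with temperature
  if (stats::cor(tt, yy) > 0) {
    stop("series increases with temperature; CETSA aggregation curves must decrease",
         call. = FALSE)
  }
  y_norm <- (yy - min(yy)) / rng
  t0 <- tt[which.min(abs(y_norm - 0.5))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ bottom + (top - bottom) / (1 + exp((tt - t_agg) / s)),
      start = list(top = max(yy), bottom = min(yy), t_agg = t0, s = 2),
      lower = c(-Inf, -Inf, min(tt), 1e-3),
      upper = c(Inf, Inf, max(tt), 30),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(no_transition())
  cf <- stats::coef(fit)
  if (cf[["t_agg"]] <= min(tt) + 1e-6 || cf[["t_agg"]] >= max(tt) - 1e-6) {
    return(no_transition())
  }
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) stats::setNames(rep(NA_real_, 4), names(cf)))
  structure(list(t_agg = unname(cf[["t_agg"]]),
                 t_agg_se = unname(se[["t_agg"]]),
                 top = unname(cf[["top"]]), bottom = unname(cf[["bottom"]]),
                 steepness = unname(cf[["s"]]), has_transition = TRUE,
                 condition_label = series$condition_label),
            class = "aggregation_fit")
}

#' @export
print.aggregation_fit <- function(x, ...) {
  if (!x$has_transition) cat("aggregation_fit: no transition detected\n")
  else cat(sprintf("aggregation_fit: T_agg = %.2f deg C (SE %.2g)\n",
                   x$t_agg, x$t_agg_se))
  invisible(x)
}

#' Ligand-induced T_agg shift
#'
#' Difference between treated and control apparent aggregation temperatures.
#' The shift is reported together with its propagated fit uncertainty;
#' judging significance is left to the user.
#'
#' @param treated,control `aggregation_fit` objects with transitions.
#' @return List with `delta_tagg` (deg C) and `se` (propagated).
#' @export
delta_tagg <- function(treated, control) {
  stopifnot(inherits(treated, "aggregation_fit"),
            inherits(control, "aggregation_fit"))
  if (!treated$has_transition || !control$has_transition) {
    stop("delta_tagg requires two fits with detected transitions",
         call. = FALSE)
  }
  list(delta_tagg = treated$t_agg - control$t_agg,
       se = sqrt(sum(c(treated$t_agg_se, control$t_agg_se)^2, na.rm = TRUE)))
}

#' Average T_agg across replicate membranes
#'
#' Replicate membranes are fitted independently and their apparent T_agg
#' values averaged (no pooled fit).
#'
#' @param series_list List of normalized [cetsa_series()] replicates.
#' @return List with `mean_t_agg`, `sd_t_agg`, `fits`.
#' @export
fit_tagg_replicates <- function(series_list) {
  fits <- lapply(series_list, fit_tagg)
  tags <- vapply(fits, function(f) f$t_agg, numeric(1))
  list(mean_t_agg = mean(tags), sd_t_agg = stats::sd(tags), fits = fits)
}
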