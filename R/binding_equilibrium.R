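# Closed-form and numerical solvers for 1:1 and competitive binding
# equilibria. These are the mechanistic backbone shared by the displacement
# analyses and by every simulator: receptor R binds a labeled probe P with
# dissociation constant kd_probe and, optionally, an unlabeled competitor C
# with kd_competitor. All concentrations are molar.

#' Specify a binding equilibrium
#'
#' Bundles the total concentrations and dissociation constants of a
#' receptor/probe/competitor system. `competitor_total = 0` describes a plain
#' 1:1 receptor-probe equilibrium; `kd_competitor = Inf` an inert competitor.
#'
#' @param receptor_total,probe_total,competitor_total Total (analytical)
#'   concentrations in molar; all must be >= 0.
#' @param kd_probe,kd_competitor Dissociation constants in molar; must be > 0
#'   (`Inf` allowed for the competitor).
#' @return An object of class `equilibrium_spec`.
#' @export
#' @examples
#' equilibrium_spec(1e-7, 1e-8, kd_probe = 31e-9,
#'                  competitor_total = 2.5e-7, kd_competitor = 250e-9)
equilibrium_spec <- function(receptor_total, probe_total, kd_probe,
                             competitor_total = 0, kd_competitor = Inf) {
  assert_that(is.numeric(receptor_total) && receptor_total >= 0,
              "receptor_total must be a non-negative molar concentration")
  assert_that(is.numeric(probe_total) && probe_total >= 0,
              "probe_total must be a non-negative molar concentration")
  assert_that(is.numeric(competitor_total) && competitor_total >= 0,
              "competitor_total must be a non-negative molar concentration")
  assert_that(is.numeric(kd_probe) && kd_probe > 0 && is.finite(kd_probe),
              "kd_probe must be a positive, finite molar constant")
  assert_that(is.numeric(kd_competitor) && kd_competitor > 0,
              "kd_competitor must be positive (Inf allowed)")
  structure(
    list(receptor_total = receptor_total, probe_total = probe_total,
         competitor_total = competitor_total, kd_probe = kd_probe,
         kd_competitor = kd_competitor),
    class = "equilibrium_spec"
  )
}

new_species_state <- function(free_receptor, free_probe, free_competitor,
                              receptor_probe, receptor_competitor) {
  structure(
    list(free_receptor = free_receptor, free_probe = free_probe,
         free_competitor = free_competitor, receptor_probe = receptor_probe,
         receptor_competitor = receptor_competitor),
    class = "species_state"
  )
}

#' Solve a 1:1 binding equilibrium exactly
#'
#' Computes species concentrations for R + P <-> RP from the stable root of
#' the binding quadratic. The returned state satisfies
#' `kd_probe * [RP] = [R_free] * [P_free]` and mass conservation to machine
#' precision.
#'
#' @param spec An [equilibrium_spec()] with `competitor_total = 0`.
#' @return A `species_state` with fields `free_receptor`, `free_probe`,
#'   `free_competitor` (0), `receptor_probe`, `receptor_competitor` (0).
#' @export
solve_1to1 <- function(spec) {
  stopifnot(inherits(spec, "equilibrium_spec"))
  assert_that(spec$competitor_total == 0,
              "solve_1to1 requires competitor_total = 0; use solve_competitive")
  rt <- spec$receptor_total; pt <- spec$probe_total; kd <- spec$kd_probe
  b <- rt + pt + kd
  # numerically stable smaller quadratic root: RP = 2*rt*pt / (b + sqrt(disc))
  disc <- b * b - 4 * rt * pt
  rp <- if (rt == 0 || pt == 0) 0 else 2 * rt * pt / (b + sqrt(max(disc, 0)))
  new_species_state(
    free_receptor = rt - rp,
    free_probe = pt - rp,
    free_competitor = 0,
    receptor_probe = rp,
    receptor_competitor = 0
  )
}

#' Solve a competitive binding equilibrium
#'
#' Solves the coupled equilibria R + P <-> RP (kd_probe) and R + C <-> RC
#' (kd_competitor) under the three conservation laws. The problem is reduced
#' to a single monotone equation in free receptor, bracketed on
#' `[0, receptor_total]` and solved by `uniroot` followed by Newton polishing,
#' so convergence is guaranteed and independent of starting guesses.
#'
#' @param spec An [equilibrium_spec()].
#' @param tol Relative tolerance on the conservation residual.
#' @return A `species_state`.
#' @export
solve_competitive <- function(spec, tol = 1e-12) {
  stopifnot(inherits(spec, "equilibrium_spec"))
  if (spec$competitor_total == 0 || !is.finite(spec$kd_competitor)) {
    out <- solve_1to1(equilibrium_spec(spec$receptor_total, spec$probe_total,
                                       spec$kd_probe))
    out$free_competitor <- spec$competitor_total
    return(out)
  }
  rt <- spec$receptor_total; pt <- spec$probe_total; ct <- spec$competitor_total
  kp <- spec$kd_probe; kc <- spec$kd_competitor
  if (rt == 0) {
    return(new_species_state(0, pt, ct, 0, 0))
  }
  # free-receptor balance: monotone increasing in r on [0, rt]
  f <- function(r) r * (1 + pt / (kp + r) + ct / (kc + r)) - rt
  root <- stats::uniroot(f, lower = 0, upper = rt,
                         tol = .Machine$double.eps * max(rt, 1e-300))$root
  # Newton polish to drive the conservation residual to machine precision
  for (i in 1:6) {
    fr <- f(root)
    dfr <- 1 + pt * kp / (kp + root)^2 + ct * kc / (kc + root)^2
    step <- fr / dfr
    root <- min(max(root - step, 0), rt)
    if (abs(fr) <= tol * rt) break
  }
  r <- root
  rp <- pt * r / (kp + r)
  rc <- ct * r / (kc + r)
  state <- new_species_state(
    free_receptor = r,
    free_probe = pt - rp,
    free_competitor = ct - rc,
    receptor_probe = rp,
    receptor_competitor = rc
  )
  resid <- abs(r + rp + rc - rt) / max(rt, .Machine$double.xmin)
  if (!is.finite(resid) || resid > 1e-8) {
    stop(sprintf("competitive solver failed to conserve receptor (residual %.3e)",
                 resid), call. = FALSE)
  }
  state
}

#' Fit the one-site binding hyperbola
#'
#' Least-squares fit of Y = Bmax * R / (K_D + R) against receptor
#' concentration, the standard saturation-binding model for probe titrations.
#'
#' @param receptor_concentrations Molar concentrations (>= 4 points).
#' @param responses Non-negative responses (e.g. specific polarization P_S).
#' @return A `hyperbola_fit` with `kd` (molar), `bmax`, standard errors and
#'   diagnostics. Data without curvature are flagged via `reliable = FALSE`.
#' @export
fit_hyperbola <- function(receptor_concentrations, responses) {
  x <- as.numeric(receptor_concentrations); y <- as.numeric(responses)
  assert_that(length(x) == length(y), "concentration/response lengths differ")
  assert_that(length(x) >= 4, "at least 4 points are required")
  assert_that(max(y) > 0,
              "responses must contain positive values")
  # small negative values (baseline noise) are tolerated; the model itself
  # is non-negative
  bmax0 <- max(y)
  half <- bmax0 / 2
  kd0 <- x[which.min(abs(y - half))]
  if (kd0 <= 0) kd0 <- stats::median(x[x > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ bmax * x / (kd + x),
                      start = list(bmax = bmax0, kd = kd0),
                      lower = c(0, .Machine$double.xmin),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(kd = NA_real_, bmax = NA_real_, kd_se = NA_real_,
                          bmax_se = NA_real_, converged = FALSE,
                          reliable = FALSE, residual_norm = NA_real_),
                     class = "hyperbola_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 2))
  reliable <- is.finite(cf[["kd"]]) && cf[["kd"]] <= 10 * max(x) &&
    (!is.finite(se[["kd"]]) || se[["kd"]] < cf[["kd"]] * 10)
  # linear (curvature-free) data drive kd to the boundary; flag it
  structure(list(kd = unname(cf[["kd"]]), bmax = unname(cf[["bmax"]]),
                 kd_se = unname(se[["kd"]]), bmax_se = unname(se[["bmax"]]),
                 converged = TRUE, reliable = reliable,
                 residual_norm = sqrt(sum(stats::resid(fit)^2))),
            class = "hyperbola_fit")
}

#' @export
print.hyperbola_fit <- function(x, ...) {
  cat("One-site binding (hyperbola) fit\n")
  cat(sprintf("  K_D  : %.4g M (SE %.2g)\n", x$kd, x$kd_se))
  cat(sprintf("  Bmax : %.4g (SE %.2g)\n", x$bmax, x$bmax_se))
  if (!x$reliable) cat("  WARNING: fit flagged unreliable (no curvature?)\n")
  invisible(x)
}

#' Theoretical displacement curve
#'
#' Bound-probe fraction as a function of competitor dose at fixed receptor,
#' probe and affinities. This is the equilibrium curve underlying every
#' displacement IC50 experiment.
#'
#' @param spec_base An [equilibrium_spec()]; its `competitor_total` is ignored.
#' @param competitor_grid Molar competitor doses.
#' @return A data.frame with `competitor_total`, `bound_fraction` (of probe)
#'   and `percent_bound` (relative to the zero-dose occupancy).
#' @export
displacement_curve <- function(spec_base, competitor_grid) {
  stopifnot(inherits(spec_base, "equilibrium_spec"))
  frac <- vapply(competitor_grid, function(ct) {
    st <- solve_competitive(equilibrium_spec(
      spec_base$receptor_total, spec_base$probe_total, spec_base$kd_probe,
      competitor_total = ct, kd_competitor = spec_base$kd_competitor))
    if (spec_base$probe_total == 0) 0 else st$receptor_probe / spec_base$probe_total
  }, numeric(1))
  zero <- solve_1to1(equilibrium_spec(spec_base$receptor_total,
                                      spec_base$probe_total,
                                      spec_base$kd_probe))
  f0 <- if (spec_base$probe_total == 0) 0 else
    zero$receptor_probe / spec_base$probe_total
  data.frame(competitor_total = as.numeric(competitor_grid),
             bound_fraction = frac,
             percent_bound = if (f0 > 0) 100 * frac / f0 else rep(0, length(frac)))
}

#' Half-displacement dose of the theoretical curve
#'
#' Finds the competitor dose at which the bound-probe fraction falls midway
#' between its zero-dose value and its fully-displaced limit: the apparent
#' IC50 that an ideal (noise-free) displacement experiment would measure.
#'
#' @inheritParams displacement_curve
#' @param upper Upper bracket for the dose search (molar).
#' @return Molar dose.
#' @export
half_displacement_dose <- function(spec_base, upper = 1) {
  stopifnot(inherits(spec_base, "equilibrium_spec"))
  f_at <- function(ct) {
    st <- solve_competitive(equilibrium_spec(
      spec_base$receptor_total, spec_base$probe_total, spec_base$kd_probe,
      competitor_total = ct, kd_competitor = spec_base$kd_competitor))
    st$receptor_probe / spec_base$probe_total
  }
  f0 <- f_at(0)
  finf <- f_at(upper)
  target <- (f0 + finf) / 2
  stats::uniroot(function(lc) f_at(10^lc) - target,
                 lower = -15, upper = log10(upper), tol = 1e-12)$root |>
    (\(lc) 10^lc)()
}
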