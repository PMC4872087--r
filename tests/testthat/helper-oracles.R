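# Independent reference implementations used to cross-check the analytical
# solvers. They deliberately share no code with the package internals.

# 1:1 equilibrium by damped fixed-point iteration on free receptor.
oracle_1to1 <- function(rt, pt, kd, iters = 400) {
  r <- rt
  for (i in seq_len(iters)) {
    p_free <- pt / (1 + r / kd)
    r_new <- rt / (1 + p_free / kd)
    if (r == 0 || r_new == 0) { r <- r_new; next }
    r <- sqrt(r * r_new)          # geometric damping
  }
  rp <- r * (pt / (1 + r / kd)) / kd
  list(free_receptor = r, receptor_probe = rp, free_probe = pt - rp)
}

# Competitive equilibrium by brute-force bisection on free receptor, with
# free probe/competitor eliminated analytically (no Newton, no uniroot; 200
# halvings drive the bracket to machine precision regardless of stiffness).
oracle_competitive <- function(rt, pt, ct, kp, kc, halvings = 200) {
  if (rt == 0) return(list(free_receptor = 0, receptor_probe = 0,
                           receptor_competitor = 0))
  excess <- function(r) {
    p_free <- pt / (1 + r / kp)
    c_free <- ct / (1 + r / kc)
    r * (1 + p_free / kp + c_free / kc) - rt
  }
  lo <- 0; hi <- rt
  for (i in seq_len(halvings)) {
    mid <- (lo + hi) / 2
    if (mid == lo || mid == hi) break
    if (excess(mid) > 0) hi <- mid else lo <- mid
  }
  r <- (lo + hi) / 2
  p_free <- pt / (1 + r / kp)
  c_free <- ct / (1 + r / kc)
  list(free_receptor = r,
       receptor_probe = r * p_free / kp,
       receptor_competitor = r * c_free / kc)
}

# Shared fixture pieces ------------------------------------------------

paper_fp_refs <- function() polarization_references(25, 225, 0.91)

# 15-dose log grid used for FP titrations (0.06 - 750 nM regime).
fp_receptor_grid <- function(lo = 0.06e-9, hi = 750e-9, n = 15) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# Competitor affinity calibrated so the theoretical half-displacement dose
# of the equilibrium model equals a stated apparent IC50.
calibrate_competitor_kd <- function(receptor_total, probe_total, kd_probe,
                                    target_ic50) {
  g <- function(lk) {
    half_displacement_dose(
      equilibrium_spec(receptor_total, probe_total, kd_probe,
                       kd_competitor = 10^lk),
      upper = 1e-2) - target_ic50
  }
  10^stats::uniroot(g, c(-12, -4))$root
}

# Temp CSV path; the session temp dir is discarded when testing ends.
local_csv <- function() tempfile(fileext = ".csv")
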