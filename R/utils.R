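# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so simulators never perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive independent per-assay stream seeds from one global seed, kept well
# inside 32-bit integer range.
fanout_seeds <- function(seed, n) {
  (as.integer(seed) + 99991L * seq_len(n)) %% 2147483562L + 1L
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Parse a concentration string to molar units
#'
#' Accepts a bare number (taken as molar) or a number with an `M`, `mM`,
#' `uM`/`µM`/`μM`, `nM` or `pM` suffix, e.g. `"100 nM"` -> `1e-7`.
#'
#' @param x Character or numeric vector.
#' @return Numeric vector in molar.
#' @export
#' @examples
#' parse_conc(c("250 nM", "10uM", "1e-6"))
parse_conc <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
  vapply(x, function(s) {
    s <- gsub("µ|μ", "u", trimws(s))
    m <- regmatches(s, regexec("^([0-9.eE+-]+)\\s*([munp]?M)?$", s))[[1]]
    if (length(m) == 0L || m[2] == "") {
      stop("cannot parse concentration: '", s, "'", call. = FALSE)
    }
    unit <- if (m[3] == "") "M" else m[3]
    as.numeric(m[2]) * scale[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
}

# Kelvin <-> Celsius; all thermodynamic formulas run in absolute temperature.
c_to_k <- function(t_c) t_c + 273.15
k_to_c <- function(t_k) t_k - 273.15

# Gas constant in kJ/(mol K), matching enthalpies carried in kJ/mol.
.R_GAS <- 8.31446261815324e-3
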