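#' metawham: free-energy methods and collective variables for helix dynamics
#'
#' Internal units are nm, kJ/mol, ps and K throughout; PDB files (Angstrom)
#' are converted at the I/O boundary only. Residue numbers follow author
#' (PDB) numbering verbatim.
#'
#' @keywords internal
"_PACKAGE"

#' Boltzmann constant in kJ mol^-1 K^-1
#'
#' @export
kB <- 0.0083144621

#' Rational switching function
#'
#' `f(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)`, the smooth contact-counting
#' kernel used by the contact-number CVs (`r0 = 0.85` nm) and the
#' alpha-helix RMSD CV (`r0 = 0.08` nm). The singularity at `r = r0` is
#' removable; the analytic limit `n/m` is returned there (a first-order
#' series is used within `|r/r0 - 1| < 1e-6`).
#'
#' @param r distances (same units as `r0`); vectorised.
#' @param r0 switching radius, > 0.
#' @param n,m numerator/denominator exponents, `0 < n < m` (defaults 8, 12).
#' @return numeric vector of the same length as `r`, values in (0, 1] for
#'   `r >= 0`, decreasing in `r`.
#' @export
switching_fn <- function(r, r0, n = 8L, m = 12L) {
  stopifnot(r0 > 0, n > 0, m > n)
  x <- r / r0
  f <- numeric(length(x))
  near <- abs(x - 1) < 1e-6
  if (any(!near)) {
    xx <- x[!near]
    f[!near] <- (1 - xx^n) / (1 - xx^m)
  }
  if (any(near)) {
    # removable singularity: f -> n/m with slope correction (n-m)/2 * (x-1)
    u <- x[near] - 1
    f[near] <- (n / m) * (1 + (n - m) / 2 * u)
  }
  f
}

#' Derivative of the switching function with respect to r
#'
#' @inheritParams switching_fn
#' @return df/dr, same length as `r`.
#' @keywords internal
switching_fn_deriv <- function(r, r0, n = 8L, m = 12L) {
  x <- r / r0
  near <- abs(x - 1) < 1e-6
  d <- numeric(length(x))
  if (any(!near)) {
    xx <- x[!near]
    num <- 1 - xx^n
    den <- 1 - xx^m
    d[!near] <- (-n * xx^(n - 1) * den + m * xx^(m - 1) * num) / den^2 / r0
  }
  if (any(near)) {
    # d/dx at x=1 of the series n/m * (1 + (n-m)/2 (x-1))
    d[near] <- (n / m) * (n - m) / 2 / r0
  }
  d
}
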