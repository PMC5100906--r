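#' Define an analytic potential (or bias) on CV space
#'
#' A `potential_model` bundles an energy function (kJ/mol) and its analytic
#' gradient over a low-dimensional CV space. Potentials and bias terms share
#' this interface, so any of them can be handed to [langevin_run()] or
#' [boltzmann_sampler()].
#'
#' @param energy function of a numeric vector (length = `dimension`)
#'   returning kJ/mol.
#' @param gradient function returning the gradient, kJ/(mol * CV unit).
#' @param dimension dimension of CV space.
#' @param barrier optional known barrier height (kJ/mol) for verification.
#' @param minima optional matrix of known minima (one per row).
#' @return object of class `potential_model`.
#' @export
potential_model <- function(energy, gradient, dimension = 1L,
                            barrier = NULL, minima = NULL) {
  stopifnot(is.function(energy), is.function(gradient), dimension >= 1)
  structure(list(energy = energy, gradient = gradient,
                 dimension = as.integer(dimension),
                 barrier = barrier, minima = minima),
            class = "potential_model")
}

#' @export
print.potential_model <- function(x, ...) {
  cat("potential_model:", x$dimension, "dimensional")
  if (!is.null(x$barrier)) cat(", known barrier", x$barrier, "kJ/mol")
  cat("\n")
  invisible(x)
}

#' Harmonic well
#'
#' `V(x) = 1/2 kappa |x - x0|^2`.
#'
#' @param kappa spring constant, kJ/(mol * unit^2).
#' @param x0 minimum position.
#' @return a [potential_model()].
#' @export
harmonic_potential <- function(kappa, x0 = 0) {
  x0 <- as.numeric(x0)
  potential_model(
    energy = function(x) 0.5 * kappa * sum((x - x0)^2),
    gradient = function(x) kappa * (x - x0),
    dimension = length(x0),
    minima = matrix(x0, nrow = 1)
  )
}

#' Symmetric quartic double well
#'
#' `V(x) = h * ((x/a)^2 - 1)^2`: minima at `x = -a` and `x = +a` with
#' `V = 0`, a barrier of exactly `h` kJ/mol at `x = 0`. The standard truth
#' source for free-energy recovery tests, mirroring the two-minimum profile
#' (barrier around 6.5 kJ/mol) seen along the receptor's difference-RMSD
#' coordinate.
#'
#' @param barrier_height `h`, kJ/mol.
#' @param well_separation `a`, CV units (half-distance between minima).
#' @return a [potential_model()] with known `barrier` and `minima`.
#' @export
double_well_potential <- function(barrier_height = 6.5, well_separation = 1) {
  h <- barrier_height; a <- well_separation
  stopifnot(h > 0, a > 0)
  potential_model(
    energy = function(x) h * ((x[1] / a)^2 - 1)^2,
    gradient = function(x) c(4 * h * x[1] * ((x[1] / a)^2 - 1) / a^2),
    dimension = 1L,
    barrier = h,
    minima = matrix(c(-a, a), ncol = 1)
  )
}

#' Harmonic umbrella restraint as a potential
#'
#' The window bias `E = k (x - C)^2` (no 1/2 factor), as used along the
#' difference-RMSD coordinate with `k = 10` kJ/(mol nm^2).
#'
#' @param center window centre `C` (CV units).
#' @param k force constant, kJ/(mol * unit^2), default 10.
#' @return a [potential_model()].
#' @export
umbrella_potential <- function(center, k = 10) {
  potential_model(
    energy = function(x) k * (x[1] - center)^2,
    gradient = function(x) c(2 * k * (x[1] - center)),
    dimension = 1L
  )
}

#' Sum of potentials
#'
#' @param ... `potential_model` objects of equal dimension.
#' @return a [potential_model()] evaluating their sum.
#' @export
combine_potentials <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1)
  dim <- parts[[1]]$dimension
  stopifnot(all(vapply(parts, function(p) p$dimension, integer(1)) == dim))
  potential_model(
    energy = function(x) sum(vapply(parts, function(p) p$energy(x), numeric(1))),
    gradient = function(x) Reduce(`+`, lapply(parts, function(p) p$gradient(x))),
    dimension = dim
  )
}
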