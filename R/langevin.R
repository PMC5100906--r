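#' Settings for the overdamped Langevin integrator
#'
#' @param dt time step (ps).
#' @param friction friction coefficient `gamma` (amu/ps-like units; the
#'   diffusion constant is `kB T / friction`).
#' @param temperature temperature in K (default 300).
#' @param n_steps number of integration steps.
#' @param stride sampling stride (a frame is recorded every `stride` steps).
#' @param seed integer RNG seed; identical seeds give identical tracks.
#' @return object of class `langevin_spec`.
#' @export
langevin_spec <- function(dt = 0.01, friction = 1, temperature = 300,
                          n_steps = 10000L, stride = 10L, seed = 1L) {
  stopifnot(dt > 0, friction > 0, temperature >= 0, n_steps >= 1, stride >= 1)
  structure(list(dt = dt, friction = friction, temperature = temperature,
                 n_steps = as.integer(n_steps), stride = as.integer(stride),
                 seed = as.integer(seed)),
            class = "langevin_spec")
}

#' Overdamped (Brownian) Langevin sampling on a CV-space potential
#'
#' Euler-Maruyama integration of
#' `dx = -grad(V)/gamma dt + sqrt(2 kB T dt / gamma) xi`,
#' the equilibrium-sampling surrogate for molecular dynamics on the
#' low-dimensional CV spaces used throughout this package. Deterministic
#' under a fixed seed.
#'
#' @param potential a [potential_model()].
#' @param biases list of additional `potential_model` bias terms (umbrella
#'   restraints, walls, ...), each exposing energy and gradient.
#' @param spec a [langevin_spec()].
#' @param x0 starting point (defaults to the first known minimum, or 0).
#' @return object of class `sample_track`: `times` (ps), `positions`
#'   (frames x dimension), `bias_energy` per frame (kJ/mol), and the spec.
#' @export
langevin_run <- function(potential, biases = list(), spec = langevin_spec(),
                         x0 = NULL) {
  d <- potential$dimension
  if (is.null(x0)) {
    x0 <- if (!is.null(potential$minima)) potential$minima[1, ] else rep(0, d)
  }
  stopifnot(length(x0) == d)
  set.seed(spec$seed)
  n_out <- spec$n_steps %/% spec$stride
  pos <- matrix(NA_real_, n_out, d)
  be <- numeric(n_out)
  x <- as.numeric(x0)
  pref <- spec$dt / spec$friction
  noise_sd <- sqrt(2 * kB * spec$temperature * spec$dt / spec$friction)
  noise <- matrix(stats::rnorm(spec$n_steps * d, sd = noise_sd), spec$n_steps, d)
  k_out <- 0L
  for (step in seq_len(spec$n_steps)) {
    g <- potential$gradient(x)
    for (b in biases) g <- g + b$gradient(x)
    if (any(!is.finite(g)))
      stop("non-finite force at step ", step, " (x = ",
           paste(signif(x, 6), collapse = ", "), ")")
    x <- x - pref * g + noise[step, ]
    if (step %% spec$stride == 0L) {
      k_out <- k_out + 1L
      pos[k_out, ] <- x
      be[k_out] <- if (length(biases))
        sum(vapply(biases, function(b) b$energy(x), numeric(1))) else 0
    }
  }
  structure(list(times = seq_len(n_out) * spec$stride * spec$dt,
                 positions = pos, bias_energy = be, spec = spec),
            class = "sample_track")
}

#' @export
print.sample_track <- function(x, ...) {
  cat("sample_track:", nrow(x$positions), "frames,",
      ncol(x$positions), "CV dimension(s), t =",
      signif(utils::tail(x$times, 1), 6), "ps\n")
  invisible(x)
}

#' Exact Boltzmann sampling on a bounded domain
#'
#' Draws i.i.d. samples from `exp(-(V + bias)/kB T)` on a bounded 1-D or
#' 2-D domain by dense-grid inverse-CDF (1-D) or cell-multinomial with
#' in-cell jitter (2-D). Used as the exactly-distributed oracle feeding
#' WHAM windows. Deterministic under the seed.
#'
#' @param potential a [potential_model()].
#' @param bias optional additional `potential_model`.
#' @param temperature K.
#' @param n number of samples.
#' @param seed integer seed.
#' @param lower,upper domain bounds (length 1 or 2).
#' @param grid_n grid resolution per dimension.
#' @return numeric vector (1-D) or `n` x 2 matrix (2-D).
#' @export
boltzmann_sampler <- function(potential, bias = NULL, temperature = 300,
                              n = 1000L, seed = 1L, lower, upper,
                              grid_n = 4096L) {
  d <- potential$dimension
  stopifnot(d %in% c(1L, 2L), length(lower) == d, length(upper) == d,
            all(upper > lower))
  beta <- 1 / (kB * temperature)
  etot <- function(x) potential$energy(x) + if (is.null(bias)) 0 else bias$energy(x)
  set.seed(seed)
  if (d == 1L) {
    xs <- seq(lower, upper, length.out = grid_n)
    E <- vapply(xs, etot, numeric(1))
    w <- exp(-beta * (E - min(E)))
    # trapezoid CDF, inverse by linear interpolation
    cdf <- c(0, cumsum((w[-1] + w[-grid_n]) / 2 * diff(xs)))
    cdf <- cdf / cdf[grid_n]
    u <- stats::runif(n)
    stats::approx(cdf, xs, xout = u, ties = "ordered")$y
  } else {
    ng <- min(grid_n, 512L)
    xs <- seq(lower[1], upper[1], length.out = ng + 1)
    ys <- seq(lower[2], upper[2], length.out = ng + 1)
    xc <- (xs[-1] + xs[-(ng + 1)]) / 2
    yc <- (ys[-1] + ys[-(ng + 1)]) / 2
    E <- outer(seq_len(ng), seq_len(ng),
               Vectorize(function(i, j) etot(c(xc[i], yc[j]))))
    w <- exp(-beta * (E - min(E)))
    cell <- sample.int(ng * ng, n, replace = TRUE, prob = as.vector(w))
    i <- (cell - 1L) %% ng + 1L
    j <- (cell - 1L) %/% ng + 1L
    dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
    cbind(xc[i] + stats::runif(n, -dx / 2, dx / 2),
          yc[j] + stats::runif(n, -dy / 2, dy / 2))
  }
}
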