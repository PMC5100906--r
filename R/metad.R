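#' Square-well wall bias specification
#'
#' Restrains an auxiliary CV to `[lower, upper]` (the protocol walls the
#' alpha-helix RMSD CV of helix 12 to [5, 10]): inside the well the energy
#' is zero; outside, `E = k ((x - a + o)/s)^e` against the violated bound
#' `a`, with `k = 300` kJ/(mol nm^2), rescale `s = 1`, exponent `e = 2`
#' and offset `o = 0` by default.
#'
#' @param lower,upper well bounds (CV units), `lower < upper`.
#' @param k force constant.
#' @param s rescaling factor.
#' @param e exponent.
#' @param o offset.
#' @return object of class `wall_spec`.
#' @export
wall_spec <- function(lower = 5, upper = 10, k = 300, s = 1, e = 2, o = 0) {
  stopifnot(lower < upper, k > 0, s > 0)
  structure(list(lower = lower, upper = upper, k = k, s = s, e = e, o = o),
            class = "wall_spec")
}

#' Wall bias energy and derivative
#'
#' @param spec a [wall_spec()].
#' @param x CV value(s).
#' @return list with `energy` (kJ/mol) and `deriv`, vectorised over `x`.
#' @export
wall_energy <- function(spec, x) {
  lo <- x < spec$lower
  hi <- x > spec$upper
  a <- ifelse(lo, spec$lower, ifelse(hi, spec$upper, NA_real_))
  u <- (x - a + spec$o) / spec$s
  e <- ifelse(lo | hi, spec$k * u^spec$e, 0)
  d <- ifelse(lo | hi, spec$k * spec$e * u^(spec$e - 1) / spec$s, 0)
  list(energy = e, deriv = d)
}

#' Wall bias as a potential
#'
#' @param spec a [wall_spec()].
#' @return a [potential_model()] (1-D) for use with [langevin_run()].
#' @export
wall_potential <- function(spec) {
  potential_model(
    energy = function(x) wall_energy(spec, x[1])$energy,
    gradient = function(x) c(wall_energy(spec, x[1])$deriv),
    dimension = 1L
  )
}

#' Well-tempered metadynamics state
#'
#' The accumulating record of deposited Gaussian hills plus the
#' well-tempered parameters: base hill height `w0` (protocol 0.2 kJ/mol),
#' per-CV Gaussian widths (protocol 1.0 in contact-number units), bias
#' factor `gamma` (protocol 10) and temperature (300 K). The decay
#' temperature is `dT = (gamma - 1) T`, so each new hill carries height
#' `w0 exp(-V(s,t)/(kB dT))`.
#'
#' @param widths Gaussian width per CV dimension.
#' @param w0 base hill height (kJ/mol).
#' @param bias_factor `gamma` > 1.
#' @param temperature K.
#' @param walls optional list of [wall_spec()]s (applied to auxiliary CVs
#'   by the run driver; recorded here for provenance).
#' @return object of class `metad_state`.
#' @export
metad_state <- function(widths = 1.0, w0 = 0.2, bias_factor = 10,
                        temperature = 300, walls = list()) {
  stopifnot(all(widths > 0), w0 > 0, bias_factor > 1, temperature > 0)
  d <- length(widths)
  structure(list(centers = matrix(numeric(0), 0, d), heights = numeric(0),
                 times = numeric(0), widths = as.numeric(widths), w0 = w0,
                 bias_factor = bias_factor, temperature = temperature,
                 walls = walls),
            class = "metad_state")
}

#' @export
print.metad_state <- function(x, ...) {
  cat("metad_state:", length(x$heights), "hills,",
      ncol(x$centers), "CV dimension(s), gamma =", x$bias_factor,
      ", w0 =", x$w0, "kJ/mol\n")
  invisible(x)
}

# bias energies at a matrix of points (rows), using hills up to t_max
.metad_bias_at <- function(state, points, t_max = Inf) {
  points <- if (is.matrix(points)) points else matrix(points, ncol = ncol(state$centers))
  keep <- state$times <= t_max
  if (!any(keep)) return(numeric(nrow(points)))
  C <- state$centers[keep, , drop = FALSE]
  h <- state$heights[keep]
  V <- numeric(nrow(points))
  for (d in seq_len(ncol(points))) {
    dd <- outer(points[, d], C[, d], `-`)^2 / (2 * state$widths[d]^2)
    if (d == 1) ex <- dd else ex <- ex + dd
  }
  as.vector(exp(-ex) %*% h)
}

#' Metadynamics bias energy and gradient at a CV point
#'
#' Sum over deposited hills of
#' `h_i exp(-sum_d (s_d - c_id)^2 / (2 sigma_d^2))`, with analytic
#' gradient.
#'
#' @param state a [metad_state()].
#' @param s CV point (numeric vector).
#' @return list with `energy` (kJ/mol) and `gradient`.
#' @export
metad_bias_energy <- function(state, s) {
  d <- ncol(state$centers)
  stopifnot(length(s) == d)
  n <- length(state$heights)
  if (n == 0) return(list(energy = 0, gradient = rep(0, d)))
  diffs <- sweep(state$centers, 2, s, `-`)        # c_i - s
  ex <- exp(-rowSums(sweep(diffs^2, 2, 2 * state$widths^2, `/`)))
  e <- sum(state$heights * ex)
  g <- vapply(seq_len(d), function(k)
    sum(state$heights * ex * diffs[, k]) / state$widths[k]^2, numeric(1))
  list(energy = e, gradient = g)
}

#' Deposit a well-tempered hill
#'
#' Appends a Gaussian centred at `s` whose height is tempered by the bias
#' already present there: `w = w0 exp(-V(s)/(kB (gamma-1) T))`. The first
#' hill at any point therefore has height exactly `w0`, and heights at a
#' revisited point decay monotonically; as `gamma` grows the scheme
#' approaches standard (untempered) metadynamics.
#'
#' @param state a [metad_state()].
#' @param s CV point.
#' @param time deposit time (ps).
#' @return the updated `metad_state`.
#' @export
metad_deposit <- function(state, s, time) {
  dT <- (state$bias_factor - 1) * state$temperature
  V <- .metad_bias_at(state, matrix(s, 1), t_max = Inf)
  w <- state$w0 * exp(-V / (kB * dT))
  state$centers <- rbind(state$centers, s)
  state$heights <- c(state$heights, w)
  state$times <- c(state$times, time)
  state
}

#' Run well-tempered metadynamics with the Langevin engine
#'
#' Overdamped Langevin dynamics on `potential` plus the history-dependent
#' hill bias (and any static biases such as walls), depositing one tempered
#' hill every `deposit_stride` integrator steps. The hill bookkeeping uses
#' preallocated vectors so runs with thousands of hills stay cheap.
#'
#' @param potential a [potential_model()] whose dimension matches
#'   `length(state$widths)`.
#' @param state a fresh [metad_state()].
#' @param spec a [langevin_spec()].
#' @param deposit_stride steps between hill deposits (default 100).
#' @param biases list of static `potential_model` bias terms.
#' @param x0 start point.
#' @param domain optional `c(lo, hi)` bounds of the sampled 1-D CV range.
#'   When given, the accumulated hill bias is tabulated on a dense grid
#'   (spacing `grid_dx`) and interpolated linearly during integration,
#'   making the cost linear in the number of steps instead of
#'   steps x hills; the recorded hills themselves stay exact.
#' @param grid_dx grid spacing for the tabulated bias (CV units).
#' @return list with `track` (a `sample_track`) and `state` (the filled
#'   `metad_state`).
#' @export
metad_run <- function(potential, state, spec = langevin_spec(),
                      deposit_stride = 100L, biases = list(), x0 = NULL,
                      domain = NULL, grid_dx = 0.01) {
  if (!is.null(domain) && potential$dimension == 1L)
    return(.metad_run_grid1d(potential, state, spec, deposit_stride, biases,
                             x0, domain, grid_dx))
  d <- potential$dimension
  stopifnot(length(state$widths) == d, length(state$heights) == 0)
  if (is.null(x0))
    x0 <- if (!is.null(potential$minima)) potential$minima[1, ] else rep(0, d)
  set.seed(spec$seed)
  dT <- (state$bias_factor - 1) * state$temperature
  max_hills <- spec$n_steps %/% deposit_stride
  Hc <- matrix(NA_real_, max_hills, d)
  Hh <- numeric(max_hills)
  Ht <- numeric(max_hills)
  nh <- 0L
  inv2s2 <- 1 / (2 * state$widths^2)
  inv_s2 <- 1 / state$widths^2
  n_out <- spec$n_steps %/% spec$stride
  pos <- matrix(NA_real_, n_out, d)
  be <- numeric(n_out)
  pref <- spec$dt / spec$friction
  noise_sd <- sqrt(2 * kB * spec$temperature * spec$dt / spec$friction)
  noise <- matrix(stats::rnorm(spec$n_steps * d, sd = noise_sd), spec$n_steps, d)
  x <- as.numeric(x0)
  k_out <- 0L

  hill_terms <- function(x) {
    # exp factors for current hills at x; NULL when no hills yet
    if (nh == 0L) return(NULL)
    dx <- sweep(Hc[seq_len(nh), , drop = FALSE], 2, x, `-`)  # c - x
    list(dx = dx, ex = exp(-as.vector(dx^2 %*% inv2s2)))
  }

  for (step in seq_len(spec$n_steps)) {
    g <- potential$gradient(x)
    for (b in biases) g <- g + b$gradient(x)
    ht <- hill_terms(x)
    if (!is.null(ht)) {
      h_ex <- Hh[seq_len(nh)] * ht$ex
      # dV/dx_k = sum_i h_i ex_i (c_ik - x_k) / sigma_k^2
      g <- g + as.vector(crossprod(ht$dx, h_ex)) * inv_s2
    }
    if (any(!is.finite(g)))
      stop("non-finite force at step ", step)
    x <- x - pref * g + noise[step, ]
    if (step %% deposit_stride == 0L) {
      ht <- hill_terms(x)
      V <- if (is.null(ht)) 0 else sum(Hh[seq_len(nh)] * ht$ex)
      nh <- nh + 1L
      Hc[nh, ] <- x
      Hh[nh] <- state$w0 * exp(-V / (kB * dT))
      Ht[nh] <- step * spec$dt
    }
    if (step %% spec$stride == 0L) {
      k_out <- k_out + 1L
      pos[k_out, ] <- x
      ht <- hill_terms(x)
      be[k_out] <- if (is.null(ht)) 0 else sum(Hh[seq_len(nh)] * ht$ex)
    }
  }
  state$centers <- Hc[seq_len(nh), , drop = FALSE]
  state$heights <- Hh[seq_len(nh)]
  state$times <- Ht[seq_len(nh)]
  track <- structure(list(times = seq_len(n_out) * spec$stride * spec$dt,
                          positions = pos, bias_energy = be, spec = spec),
                     class = "sample_track")
  list(track = track, state = state)
}

# 1-D fast path: hill bias and its derivative tabulated on a dense grid,
# updated at each deposit, linearly interpolated during integration
.metad_run_grid1d <- function(potential, state, spec, deposit_stride, biases,
                              x0, domain, grid_dx) {
  stopifnot(length(domain) == 2, domain[2] > domain[1])
  if (is.null(x0))
    x0 <- if (!is.null(potential$minima)) potential$minima[1, 1] else mean(domain)
  set.seed(spec$seed)
  dT <- (state$bias_factor - 1) * state$temperature
  sigma <- state$widths[1]
  grid <- seq(domain[1], domain[2], by = grid_dx)
  ng <- length(grid)
  Vg <- numeric(ng)   # hill bias on grid
  Gg <- numeric(ng)   # its derivative
  max_hills <- spec$n_steps %/% deposit_stride
  Hc <- numeric(max_hills); Hh <- numeric(max_hills); Ht <- numeric(max_hills)
  nh <- 0L
  n_out <- spec$n_steps %/% spec$stride
  pos <- numeric(n_out); be <- numeric(n_out)
  pref <- spec$dt / spec$friction
  noise <- stats::rnorm(spec$n_steps, sd = sqrt(2 * kB * spec$temperature *
                                                  spec$dt / spec$friction))
  interp <- function(vals, x) {
    # clamped linear interpolation on the bias grid
    u <- (x - domain[1]) / grid_dx
    j <- max(0L, min(ng - 2L, as.integer(u)))
    w <- u - j
    if (w < 0) w <- 0 else if (w > 1) w <- 1
    vals[j + 1L] * (1 - w) + vals[j + 2L] * w
  }
  x <- as.numeric(x0)
  k_out <- 0L
  for (step in seq_len(spec$n_steps)) {
    g <- potential$gradient(x)[1]
    for (b in biases) g <- g + b$gradient(x)[1]
    g <- g + interp(Gg, x)
    if (!is.finite(g)) stop("non-finite force at step ", step)
    x <- x - pref * g + noise[step]
    if (step %% deposit_stride == 0L) {
      V <- interp(Vg, x)
      w <- state$w0 * exp(-V / (kB * dT))
      nh <- nh + 1L
      Hc[nh] <- x; Hh[nh] <- w; Ht[nh] <- step * spec$dt
      dg <- grid - x
      ex <- w * exp(-dg^2 / (2 * sigma^2))
      Vg <- Vg + ex
      Gg <- Gg - ex * dg / sigma^2
    }
    if (step %% spec$stride == 0L) {
      k_out <- k_out + 1L
      pos[k_out] <- x
      be[k_out] <- interp(Vg, x)
    }
  }
  state$centers <- matrix(Hc[seq_len(nh)], ncol = 1)
  state$heights <- Hh[seq_len(nh)]
  state$times <- Ht[seq_len(nh)]
  track <- structure(list(times = seq_len(n_out) * spec$stride * spec$dt,
                          positions = matrix(pos, ncol = 1), bias_energy = be,
                          spec = spec),
                     class = "sample_track")
  list(track = track, state = state)
}

#' Reconstruct the free-energy surface from deposited hills
#'
#' Well-tempered estimator `F(s) = -((T + dT)/dT) V_bias(s)
#' = -(gamma/(gamma-1)) V_bias(s)`, evaluated on a grid from the hill sum
#' and shifted so the minimum is zero.
#'
#' @param state a [metad_state()] holding deposited hills.
#' @param grid numeric vector of CV values (1-D) or list of two vectors
#'   (2-D grid axes).
#' @param t_max only hills deposited at `time <= t_max` contribute.
#' @return a [fes_profile()].
#' @export
reconstruct_fes <- function(state, grid, t_max = Inf) {
  gamma <- state$bias_factor
  fac <- gamma / (gamma - 1)
  if (is.list(grid)) {
    pts <- as.matrix(expand.grid(grid[[1]], grid[[2]]))
    V <- .metad_bias_at(state, pts, t_max)
    F <- matrix(-fac * V, length(grid[[1]]), length(grid[[2]]))
    fes_profile(grid, F, temperature = state$temperature)
  } else {
    V <- .metad_bias_at(state, matrix(grid, ncol = 1), t_max)
    fes_profile(grid, -fac * V, temperature = state$temperature)
  }
}

#' Convergence series of the basin free-energy difference
#'
#' At each checkpoint time the FES is rebuilt from the hills deposited so
#' far and the basin free-energy difference
#' `dF = -kBT ln(sum_A exp(-F/kBT) / sum_B exp(-F/kBT))` is evaluated.
#' A converged run shows `dF` drifting within ~1 kJ/mol over its final
#' stretch.
#'
#' @param state a [metad_state()].
#' @param grid 1-D CV grid.
#' @param time_checkpoints times (ps) at which to evaluate.
#' @param basinA,basinB length-2 CV ranges.
#' @param temperature K.
#' @return data.frame with columns `time` and `delta_f` (kJ/mol).
#' @export
delta_fes_series <- function(state, grid, time_checkpoints, basinA, basinB,
                             temperature = state$temperature) {
  df <- vapply(time_checkpoints, function(tc) {
    fes <- reconstruct_fes(state, grid, t_max = tc)
    fes_basin_delta(fes, basinA, basinB, temperature)
  }, numeric(1))
  data.frame(time = time_checkpoints, delta_f = df)
}

#' Write / read a plain-text hills log
#'
#' One hill per line: time (ps), centre per CV, width per CV, deposited
#' (already-tempered) height (kJ/mol), with a header recording the
#' well-tempered parameters.
#'
#' @param state a [metad_state()].
#' @param path file path.
#' @return `write_hills` returns `path` invisibly; `read_hills` a
#'   `metad_state`.
#' @export
write_hills <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metawham_hills dim=%d w0=%.10g bias_factor=%.10g temperature=%.10g widths=%s",
                     ncol(state$centers), state$w0, state$bias_factor,
                     state$temperature,
                     paste(format(state$widths, digits = 12), collapse = ",")), con)
  writeLines("# time center... width... height", con)
  for (i in seq_along(state$heights))
    writeLines(paste(format(c(state$times[i], state$centers[i, ],
                              state$widths, state$heights[i]), digits = 12),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!grepl("^# metawham_hills", hdr)) stop("not a metawham hills file: ", path)
  get <- function(key) sub(paste0(".*", key, "="), "", hdr)
  d <- as.integer(strsplit(get("dim"), " ")[[1]][1])
  w0 <- as.numeric(strsplit(get("w0"), " ")[[1]][1])
  gamma <- as.numeric(strsplit(get("bias_factor"), " ")[[1]][1])
  temp <- as.numeric(strsplit(get("temperature"), " ")[[1]][1])
  widths <- as.numeric(strsplit(strsplit(get("widths"), " ")[[1]][1], ",")[[1]])
  body <- lines[!grepl("^#", lines)]
  st <- metad_state(widths = widths, w0 = w0, bias_factor = gamma,
                    temperature = temp)
  if (length(body)) {
    vals <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
    st$times <- vals[, 1]
    st$centers <- vals[, 2:(1 + d), drop = FALSE]
    st$heights <- vals[, ncol(vals)]
  }
  st
}
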