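#' Umbrella window
#'
#' One window of an umbrella-sampling run: a harmonic restraint centre, the
#' force constant of the bias `E = k (x - C)^2` (note: no 1/2 factor;
#' protocol default `k = 10` kJ/(mol nm^2)), and the CV samples collected
#' under that bias.
#'
#' @param center restraint centre `C` (CV units).
#' @param k force constant (kJ/mol per CV unit squared), > 0.
#' @param samples numeric vector of CV values sampled under the bias.
#' @return object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k = 10, samples = numeric(0)) {
  stopifnot(k >= 0, all(is.finite(samples)))  # k = 0: unbiased window
  structure(list(center = center, k = k, samples = as.numeric(samples)),
            class = "umbrella_window")
}

#' Umbrella bias energy and derivative
#'
#' @param cv_value CV value(s) `x`.
#' @param window an [umbrella_window()].
#' @return list with `energy` `= k (x - C)^2` (kJ/mol) and `deriv`
#'   `= 2 k (x - C)`.
#' @export
umbrella_bias <- function(cv_value, window) {
  d <- cv_value - window$center
  list(energy = window$k * d^2, deriv = 2 * window$k * d)
}

#' Sample a ladder of umbrella windows on a toy potential
#'
#' Convenience driver reproducing the umbrella protocol on an analytic
#' potential: windows at `centers` with force constant `k`, sampled either
#' exactly (grid Boltzmann inversion of `V + bias`) or by overdamped
#' Langevin dynamics started at each centre.
#'
#' @param potential a [potential_model()] (1-D).
#' @param centers window centres (the protocol uses 30 windows spaced
#'   0.1 apart along the difference-RMSD coordinate).
#' @param k force constant, default 10.
#' @param temperature K.
#' @param n_samples samples kept per window.
#' @param seed integer; window `i` uses `seed + i`.
#' @param sampler `"exact"` or `"langevin"`.
#' @param lower,upper sampling domain for the exact sampler (defaults to
#'   the span of the centres widened by 5 thermal widths).
#' @param spec `langevin_spec` template for the Langevin sampler.
#' @return list of [umbrella_window()]s.
#' @export
run_umbrella_windows <- function(potential, centers, k = 10, temperature = 300,
                                 n_samples = 2000L, seed = 1L,
                                 sampler = c("exact", "langevin"),
                                 lower = NULL, upper = NULL, spec = NULL) {
  sampler <- match.arg(sampler)
  stopifnot(potential$dimension == 1L)
  sigma <- sqrt(kB * temperature / (2 * k))
  if (is.null(lower)) lower <- min(centers) - 5 * sigma
  if (is.null(upper)) upper <- max(centers) + 5 * sigma
  out <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    bias <- umbrella_potential(centers[i], k)
    s <- if (sampler == "exact") {
      boltzmann_sampler(potential, bias, temperature, n = n_samples,
                        seed = seed + i, lower = lower, upper = upper)
    } else {
      sp <- if (is.null(spec)) langevin_spec(temperature = temperature) else spec
      sp$seed <- as.integer(seed + i)
      sp$temperature <- temperature
      tr <- langevin_run(potential, list(bias), sp, x0 = centers[i])
      as.numeric(utils::tail(tr$positions[, 1], n_samples))
    }
    out[[i]] <- umbrella_window(centers[i], k, s)
  }
  out
}

#' Weighted histogram analysis (WHAM) of umbrella windows
#'
#' Standard self-consistent WHAM: iterates the unbiased bin probabilities
#' `P_b = sum_w H_wb / sum_w N_w exp(beta f_w - beta B_wb)` and window free
#' energies `f_w = -kBT ln sum_b P_b exp(-beta B_wb)` until the largest
#' change in any `f_w` falls below `tol`. Per-bin standard errors come from
#' bootstrap resampling of each window's samples. With a single unbiased
#' window the method reduces exactly to the histogram PMF.
#'
#' @param windows list of [umbrella_window()]s with overlapping histograms.
#' @param temperature K.
#' @param bin_edges strictly increasing bin edges; defaults to bins of
#'   width (window spacing)/5 spanning all samples.
#' @param tol convergence tolerance on window free-energy shifts (kJ/mol).
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param n_bootstrap bootstrap resamples for per-bin errors (0 disables).
#' @param seed seed for the bootstrap.
#' @return a [fes_profile()] with per-bin errors; attribute `f` holds the
#'   converged window free energies.
#' @export
wham <- function(windows, temperature = 300, bin_edges = NULL,
                 tol = 1e-8, max_iter = 1e5, n_bootstrap = 50L, seed = 1L) {
  stopifnot(length(windows) >= 1)
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  if (!length(all_s)) stop("windows contain no samples")
  if (is.null(bin_edges)) {
    centers <- sort(vapply(windows, `[[`, numeric(1), "center"))
    spacing <- if (length(centers) > 1) min(diff(centers)) else stats::sd(all_s)
    bw <- spacing / 5
    bin_edges <- seq(min(all_s) - bw, max(all_s) + bw, by = bw)
  }
  stopifnot(length(bin_edges) >= 3, !is.unsorted(bin_edges, strictly = TRUE))
  nb <- length(bin_edges) - 1
  centers_b <- (bin_edges[-1] + bin_edges[-(nb + 1)]) / 2
  beta <- 1 / (kB * temperature)
  W <- length(windows)
  # bias matrix B[w, b] at bin centres
  B <- t(vapply(windows, function(w) w$k * (centers_b - w$center)^2, numeric(nb)))

  hist_w <- function(ws) {
    t(vapply(ws, function(w) {
      ix <- findInterval(w$samples, bin_edges, rightmost.closed = TRUE)
      tabulate(ix[ix >= 1 & ix <= nb], nbins = nb)
    }, numeric(nb)))
  }

  solve_wham <- function(H, f_init = rep(0, W)) {
    N <- rowSums(H)
    h <- colSums(H)
    f <- f_init
    expB <- exp(-beta * B)
    for (it in seq_len(max_iter)) {
      denom <- colSums(N * exp(beta * f) * expB)
      P <- ifelse(h > 0, h / denom, 0)
      f_new <- -log(as.vector(expB %*% P)) / beta
      f_new <- f_new - f_new[1]
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol) {
        P <- P / sum(P)
        return(list(P = P, f = f, iter = it))
      }
    }
    stop("WHAM did not converge in ", max_iter,
         " iterations (residual ", signif(delta, 3), " kJ/mol)")
  }

  H <- hist_w(windows)
  # overlap check between adjacent windows (by centre order)
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  disconnected <- integer(0)
  for (i in seq_len(W - 1)) {
    a <- H[ord[i], ] > 0; b <- H[ord[i + 1], ] > 0
    if (!any(a & b)) disconnected <- c(disconnected, i)
  }
  if (length(disconnected))
    warning("non-overlapping adjacent windows (by centre order) at position(s) ",
            paste(disconnected, collapse = ", "),
            "; the profile is disconnected there")

  sol <- solve_wham(H)
  Fm <- -log(sol$P) / beta
  mask <- sol$P == 0

  err <- NULL
  if (n_bootstrap > 0) {
    set.seed(seed)
    boot <- matrix(NA_real_, n_bootstrap, nb)
    for (b in seq_len(n_bootstrap)) {
      ws <- lapply(windows, function(w) {
        w$samples <- sample(w$samples, length(w$samples), replace = TRUE)
        w
      })
      sb <- solve_wham(hist_w(ws), f_init = sol$f)
      Fb <- -log(sb$P) / beta
      Fb[!is.finite(Fb)] <- NA_real_   # bin empty in this resample
      boot[b, ] <- Fb - min(Fb, na.rm = TRUE)
    }
    err <- apply(boot, 2, stats::sd, na.rm = TRUE)
  }
  out <- fes_profile(centers_b, Fm, error = err, mask = mask,
                     temperature = temperature)
  attr(out, "f") <- sol$f
  attr(out, "disconnected") <- disconnected
  out
}
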