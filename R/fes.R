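#' Free-energy profile container
#'
#' Binned free energies in kJ/mol on a 1-D axis or a 2-D grid, with the
#' minimum over unmasked bins shifted to zero, optional per-bin errors and
#' a mask flagging bins that received no samples (masked bins are excluded
#' from minima, barriers and basin integrals rather than being set to an
#' arbitrary large value).
#'
#' @param centers bin centres: numeric vector (1-D) or list of two vectors
#'   (2-D).
#' @param F free energies: vector or matrix matching `centers`.
#' @param error per-bin standard errors (same shape) or NULL.
#' @param mask logical, TRUE where the bin is empty/undefined.
#' @param temperature temperature (K) the profile refers to.
#' @return object of class `fes_profile`.
#' @export
fes_profile <- function(centers, F, error = NULL, mask = NULL,
                        temperature = 300) {
  two_d <- is.list(centers)
  if (is.null(mask)) mask <- if (two_d) array(FALSE, dim(F)) else rep(FALSE, length(F))
  mask <- mask | !is.finite(F)
  if (all(mask)) stop("free-energy profile has no populated bins")
  F[!mask] <- F[!mask] - min(F[!mask])
  F[mask] <- NA_real_
  if (!is.null(error) && any(error[!mask] < 0, na.rm = TRUE))
    stop("negative per-bin errors")
  structure(list(centers = centers, F = F, error = error, mask = mask,
                 temperature = temperature, two_d = two_d),
            class = "fes_profile")
}

#' @export
print.fes_profile <- function(x, ...) {
  if (x$two_d) {
    cat("fes_profile (2-D):", length(x$centers[[1]]), "x",
        length(x$centers[[2]]), "bins,")
  } else {
    cat("fes_profile (1-D):", length(x$centers), "bins,")
  }
  cat(" range 0 to", signif(max(x$F, na.rm = TRUE), 4), "kJ/mol,",
      sum(x$mask), "masked bin(s)\n")
  invisible(x)
}

#' @export
plot.fes_profile <- function(x, ...) {
  if (x$two_d) {
    graphics::image(x$centers[[1]], x$centers[[2]], x$F,
                    xlab = "CV1", ylab = "CV2", ...)
    graphics::contour(x$centers[[1]], x$centers[[2]], x$F, add = TRUE,
                      levels = seq(0, max(x$F, na.rm = TRUE), by = 10))
  } else {
    graphics::plot(x$centers, x$F, type = "l", xlab = "CV",
                   ylab = "free energy (kJ/mol)", ...)
    if (!is.null(x$error))
      graphics::arrows(x$centers, x$F - x$error, x$centers, x$F + x$error,
                       angle = 90, code = 3, length = 0.02)
  }
  invisible(x)
}

#' Histogram potential of mean force
#'
#' `PMF_i = -kB T ln(P_i / P_max)` from the binned probability of unbiased
#' samples: the modal bin sits at zero by construction and empty bins are
#' masked.
#'
#' @param samples numeric vector (1-D) or two-column matrix (2-D) of CV
#'   values.
#' @param breaks bin edges: numeric vector, or list of two vectors in 2-D.
#'   Edges must be strictly increasing with at least 2 bins.
#' @param temperature K, default 300.
#' @return a [fes_profile()].
#' @export
pmf_from_samples <- function(samples, breaks, temperature = 300) {
  if (is.list(breaks)) {
    stopifnot(is.matrix(samples), ncol(samples) == 2,
              all(vapply(breaks, function(b) length(b) >= 3 && !is.unsorted(b, strictly = TRUE), logical(1))))
    ix <- findInterval(samples[, 1], breaks[[1]], rightmost.closed = TRUE)
    iy <- findInterval(samples[, 2], breaks[[2]], rightmost.closed = TRUE)
    nx <- length(breaks[[1]]) - 1; ny <- length(breaks[[2]]) - 1
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    counts <- matrix(0, nx, ny)
    tab <- table(factor(ix[ok], levels = 1:nx), factor(iy[ok], levels = 1:ny))
    counts[] <- as.numeric(tab)
    centers <- list((breaks[[1]][-1] + breaks[[1]][-(nx + 1)]) / 2,
                    (breaks[[2]][-1] + breaks[[2]][-(ny + 1)]) / 2)
  } else {
    stopifnot(length(breaks) >= 3, !is.unsorted(breaks, strictly = TRUE))
    ix <- findInterval(samples, breaks, rightmost.closed = TRUE)
    nx <- length(breaks) - 1
    counts <- tabulate(ix[ix >= 1 & ix <= nx], nbins = nx)
    centers <- (breaks[-1] + breaks[-(nx + 1)]) / 2
  }
  if (sum(counts) == 0) stop("no samples fall inside the bin range")
  P <- counts / sum(counts)
  F <- -kB * temperature * log(P / max(P))
  fes_profile(centers, F, mask = counts == 0, temperature = temperature)
}

#' Barrier between two basins of a 1-D profile
#'
#' Locates the minimum inside each basin range and returns the highest
#' free energy on the path between the two minima, relative to the lower
#' minimum.
#'
#' @param fes a 1-D [fes_profile()].
#' @param basinA,basinB length-2 CV ranges `c(lo, hi)` bracketing the two
#'   basins.
#' @return list with `barrier` (kJ/mol), `minA`, `minB`, `xA`, `xB`,
#'   `x_saddle`.
#' @export
fes_barrier <- function(fes, basinA, basinB) {
  stopifnot(!fes$two_d)
  x <- fes$centers; F <- fes$F
  inA <- which(x >= basinA[1] & x <= basinA[2] & !fes$mask)
  inB <- which(x >= basinB[1] & x <= basinB[2] & !fes$mask)
  if (!length(inA) || !length(inB)) stop("empty basin range")
  iA <- inA[which.min(F[inA])]; iB <- inB[which.min(F[inB])]
  lo <- min(iA, iB); hi <- max(iA, iB)
  mid <- lo:hi
  mid <- mid[!fes$mask[mid]]
  iS <- mid[which.max(F[mid])]
  list(barrier = F[iS] - min(F[iA], F[iB]),
       minA = F[iA], minB = F[iB], xA = x[iA], xB = x[iB], x_saddle = x[iS])
}

#' Free-energy difference between two basins
#'
#' `dF = -kB T ln( sum_A exp(-F/kBT) / sum_B exp(-F/kBT) )` over the
#' unmasked bins of each basin.
#'
#' @inheritParams fes_barrier
#' @param temperature K; defaults to the profile's temperature.
#' @return kJ/mol (negative when basin A is more populated).
#' @export
fes_basin_delta <- function(fes, basinA, basinB, temperature = fes$temperature) {
  stopifnot(!fes$two_d)
  beta <- 1 / (kB * temperature)
  x <- fes$centers; F <- fes$F
  inA <- x >= basinA[1] & x <= basinA[2] & !fes$mask
  inB <- x >= basinB[1] & x <= basinB[2] & !fes$mask
  if (!any(inA) || !any(inB)) stop("empty basin range")
  -log(sum(exp(-beta * F[inA])) / sum(exp(-beta * F[inB]))) / beta
}
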