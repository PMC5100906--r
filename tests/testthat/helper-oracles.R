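# Independent brute-force oracles, deliberately implemented on different
# algorithms than the package internals.

# Horn's quaternion method for optimal superposition RMSD
oracle_quaternion_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  Sxx <- sum(A[, 1] * B[, 1]); Sxy <- sum(A[, 1] * B[, 2]); Sxz <- sum(A[, 1] * B[, 3])
  Syx <- sum(A[, 2] * B[, 1]); Syy <- sum(A[, 2] * B[, 2]); Syz <- sum(A[, 2] * B[, 3])
  Szx <- sum(A[, 3] * B[, 1]); Szy <- sum(A[, 3] * B[, 2]); Szz <- sum(A[, 3] * B[, 3])
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# fit-then-evaluate RMSD through bio3d's fitting machinery
oracle_rmsd_after_fit <- function(frame, reference, fit_sel, calc_sel) {
  i_fit <- select_atoms(frame, fit_sel)
  i_calc <- select_atoms(frame, calc_sel)
  mob <- as.vector(t(structure_xyz(frame)))
  fix <- as.vector(t(structure_xyz(reference)))
  inds3 <- function(i) as.vector(rbind(3 * i - 2, 3 * i - 1, 3 * i))
  moved <- bio3d::fit.xyz(fixed = fix, mobile = matrix(mob, nrow = 1),
                          fixed.inds = inds3(i_fit), mobile.inds = inds3(i_fit))
  m <- matrix(moved[1, ], ncol = 3, byrow = TRUE)
  r <- matrix(fix, ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums((m[i_calc, , drop = FALSE] - r[i_calc, , drop = FALSE])^2)))
}

oracle_delta_rmsd <- function(frame, spec) {
  oracle_rmsd_after_fit(frame, spec$ref_agonistic, spec$fit_sel, spec$calc_sel) -
    oracle_rmsd_after_fit(frame, spec$ref_antagonistic, spec$fit_sel, spec$calc_sel)
}

# literal re-statement of the GROMOS neighbour-count algorithm over a
# precomputed distance matrix
oracle_gromos <- function(D, cutoff) {
  nf <- nrow(D)
  left <- rep(TRUE, nf)
  clusters <- list()
  while (any(left)) {
    idx <- which(left)
    best <- idx[1]; best_n <- -1L
    for (i in idx) {
      ni <- sum(D[i, idx] <= cutoff) - 1L
      if (ni > best_n) { best <- i; best_n <- ni }
    }
    members <- idx[D[best, idx] <= cutoff]
    clusters[[length(clusters) + 1]] <- members
    left[members] <- FALSE
  }
  clusters
}

# pairwise fitted C-alpha RMSD matrix via the quaternion oracle
oracle_rmsd_matrix <- function(traj, sel = sel_calpha()) {
  idx <- select_atoms(md_structure(traj$atoms), sel)
  nf <- n_frames(traj)
  cs <- lapply(seq_len(nf), function(f) frame_xyz(traj, f)[idx, , drop = FALSE])
  D <- matrix(0, nf, nf)
  if (nf > 1)
    for (i in 1:(nf - 1)) for (j in (i + 1):nf)
      D[i, j] <- D[j, i] <- oracle_quaternion_rmsd(cs[[j]], cs[[i]])
  D
}

# finite-difference gradient check for potential_model-like objects
fd_gradient <- function(energy, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    d <- numeric(length(x)); d[k] <- h
    (energy(x + d) - energy(x - d)) / (2 * h)
  }, numeric(1))
}

fixture_pdb <- function() {
  system.file("extdata", "synthetic_helix_dimer.pdb", package = "metawham")
}
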