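#' Per-frame RMSD series
#'
#' [rmsd_after_fit()] applied to every frame of a trajectory: fit on
#' `fit_sel`, evaluate on `calc_sel`.
#'
#' @param traj an `md_traj`.
#' @param reference an `md_structure` sharing the topology.
#' @param fit_sel,calc_sel `atom_selection`s.
#' @return numeric vector of RMSDs (nm), one per frame.
#' @export
rmsd_series <- function(traj, reference, fit_sel, calc_sel = fit_sel) {
  topo <- md_structure(traj$atoms)
  i_fit <- select_atoms(topo, fit_sel)
  i_calc <- select_atoms(topo, calc_sel)
  ref_fit <- select_coords(reference, fit_sel)
  ref_calc <- select_coords(reference, calc_sel)
  vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_xyz(traj, f)
    fit <- kabsch_superpose(xyz[i_fit, , drop = FALSE], ref_fit)
    moved <- apply_superpose(xyz[i_calc, , drop = FALSE], fit)
    sqrt(mean(rowSums((moved - ref_calc)^2)))
  }, numeric(1))
}

# fit every frame of the selected coordinates to their mean structure
# (two-pass: align to first frame, average, re-align to the average)
.fitted_sel_coords <- function(traj, sel) {
  topo <- md_structure(traj$atoms)
  idx <- select_atoms(topo, sel)
  nf <- n_frames(traj)
  arr <- array(NA_real_, c(nf, length(idx), 3))
  ref <- frame_xyz(traj, 1)[idx, , drop = FALSE]
  for (pass in 1:2) {
    for (f in seq_len(nf)) {
      xyz <- frame_xyz(traj, f)[idx, , drop = FALSE]
      fit <- kabsch_superpose(xyz, ref)
      arr[f, , ] <- apply_superpose(xyz, fit)
    }
    ref <- apply(arr, c(2, 3), mean)
  }
  list(coords = arr, mean = ref, idx = idx)
}

#' Per-atom root-mean-square fluctuation
#'
#' Each frame is superposed onto the mean structure over the selection;
#' the RMSF of atom `i` is `sqrt(mean |r_i(t) - <r_i>|^2)`. With a C-alpha
#' selection this is the per-residue RMSF.
#'
#' @param traj an `md_traj`.
#' @param fit_sel `atom_selection` (default: all C-alpha atoms).
#' @return named numeric vector (nm), names `chain:resno:name`.
#' @export
rmsf <- function(traj, fit_sel = sel_calpha()) {
  ft <- .fitted_sel_coords(traj, fit_sel)
  dev2 <- sweep(ft$coords, c(2, 3), ft$mean)^2
  out <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames and axes, times 3 axes
  a <- traj$atoms[ft$idx, ]
  names(out) <- paste(a$chain, a$resno, a$name, sep = ":")
  out
}

#' Block-averaged dynamic cross-correlation matrix
#'
#' Pearson correlation of C-alpha displacement vectors,
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)`, computed per
#' contiguous block about the block mean after rigid fitting, averaged
#' over blocks and then over repeat trajectories. Defaults mirror the
#' analysis protocol (last 40% of each trajectory, 4 blocks — the 10-ns
#' blocks of a 100-ns run) expressed as fractions so short toy
#' trajectories scale.
#'
#' @param trajs an `md_traj` or list of them (repeat runs over one
#'   topology).
#' @param sel `atom_selection`, default all C-alpha atoms.
#' @param window_fraction final fraction of each trajectory analysed.
#' @param n_blocks contiguous blocks per trajectory window.
#' @param fit superpose each frame onto the window mean first (default
#'   TRUE).
#' @return object of class `ccc_matrix`: `resno`, symmetric `C` with unit
#'   diagonal, `n_blocks`, `n_trajs`.
#' @export
cross_correlation <- function(trajs, sel = sel_calpha(), window_fraction = 0.4,
                              n_blocks = 4L, fit = TRUE) {
  if (inherits(trajs, "md_traj")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1, window_fraction > 0, window_fraction <= 1,
            n_blocks >= 1)
  acc <- NULL
  n_used <- 0L
  for (traj in trajs) {
    nf <- n_frames(traj)
    first <- nf - floor(nf * window_fraction) + 1L
    win <- md_traj(traj$atoms, traj$xyz[first:nf, , drop = FALSE],
                   traj$times[first:nf])
    nwin <- n_frames(win)
    if (nwin < 2L * n_blocks) stop("analysis window too short for ", n_blocks, " blocks")
    bounds <- floor(seq(0, nwin, length.out = n_blocks + 1))
    for (b in seq_len(n_blocks)) {
      rows <- (bounds[b] + 1):bounds[b + 1]
      blk <- md_traj(win$atoms, win$xyz[rows, , drop = FALSE], win$times[rows])
      if (fit) {
        ft <- .fitted_sel_coords(blk, sel)
        arr <- ft$coords; idx <- ft$idx
      } else {
        topo <- md_structure(blk$atoms)
        idx <- select_atoms(topo, sel)
        arr <- array(NA_real_, c(n_frames(blk), length(idx), 3))
        for (f in seq_len(n_frames(blk))) arr[f, , ] <- frame_xyz(blk, f)[idx, , drop = FALSE]
      }
      dev <- sweep(arr, c(2, 3), apply(arr, c(2, 3), mean))
      M <- (t(dev[, , 1]) %*% dev[, , 1] + t(dev[, , 2]) %*% dev[, , 2] +
              t(dev[, , 3]) %*% dev[, , 3]) / dim(dev)[1]
      C <- M / sqrt(outer(diag(M), diag(M)))
      acc <- if (is.null(acc)) C else acc + C
      n_used <- n_used + 1L
    }
  }
  C <- acc / n_used
  C <- (C + t(C)) / 2
  diag(C) <- 1
  a <- trajs[[1]]$atoms[select_atoms(md_structure(trajs[[1]]$atoms), sel), ]
  structure(list(resno = a$resno, C = C, n_blocks = n_used,
                 n_trajs = length(trajs)),
            class = "ccc_matrix")
}

#' @export
print.ccc_matrix <- function(x, ...) {
  cat("ccc_matrix:", nrow(x$C), "residues, averaged over", x$n_blocks,
      "block(s) from", x$n_trajs, "trajectory(ies)\n")
  invisible(x)
}

#' Correlation network edges from a cross-correlation matrix
#'
#' Residue pairs with `|i - j| > 10` (sequence neighbours are excluded as
#' trivially correlated) are classified by coefficient:
#' anti-correlated `-0.4 <= ccc < -0.2`, weak `0.2 <= ccc < 0.4`,
#' moderate `0.4 <= ccc < 0.6`, strong `ccc >= 0.6`. Values outside all
#' bins yield no edge.
#'
#' @param mat a `ccc_matrix`.
#' @param seq_exclusion pairs with `|i - j| <=` this are dropped
#'   (default 10).
#' @param bins named list of class bins `c(lo, hi)` (hi exclusive,
#'   `Inf` allowed).
#' @return data.frame with columns `resno_i`, `resno_j`, `ccc`, `class`.
#' @export
correlation_network <- function(mat, seq_exclusion = 10,
                                bins = list(
                                  anti = c(-0.4, -0.2),
                                  weak = c(0.2, 0.4),
                                  moderate = c(0.4, 0.6),
                                  strong = c(0.6, Inf))) {
  resno <- mat$resno
  n <- length(resno)
  ii <- which(upper.tri(mat$C), arr.ind = TRUE)
  keep <- abs(resno[ii[, 1]] - resno[ii[, 2]]) > seq_exclusion
  ii <- ii[keep, , drop = FALSE]
  ccc <- mat$C[ii]
  cls <- rep(NA_character_, length(ccc))
  for (nm in names(bins))
    cls[ccc >= bins[[nm]][1] & ccc < bins[[nm]][2]] <- nm
  sel <- !is.na(cls)
  data.frame(resno_i = resno[ii[sel, 1]], resno_j = resno[ii[sel, 2]],
             ccc = ccc[sel], class = cls[sel], stringsAsFactors = FALSE)
}

#' GROMOS conformational clustering
#'
#' Iterative neighbour-count clustering on the pairwise fitted C-alpha
#' RMSD matrix with a 0.2 nm cutoff: the frame with the most neighbours
#' within the cutoff seeds a cluster containing itself and its neighbours,
#' these frames are removed, and the procedure repeats. Ties on the
#' neighbour count break to the lowest frame index. Each cluster's
#' representative is the member whose summed RMSD to its co-members is
#' minimal.
#'
#' @param traj an `md_traj`.
#' @param sel `atom_selection`, default all C-alpha atoms.
#' @param cutoff RMSD cutoff (nm), default 0.2.
#' @return object of class `cluster_set`: `clusters` (list of frame-index
#'   vectors, decreasing size order of discovery), `representatives`,
#'   `cutoff`.
#' @export
gromos_cluster <- function(traj, sel = sel_calpha(), cutoff = 0.2) {
  nf <- n_frames(traj)
  stopifnot(nf >= 1)
  topo <- md_structure(traj$atoms)
  idx <- select_atoms(topo, sel)
  coords <- lapply(seq_len(nf), function(f) frame_xyz(traj, f)[idx, , drop = FALSE])
  D <- matrix(0, nf, nf)
  if (nf > 1) {
    for (i in 1:(nf - 1)) for (j in (i + 1):nf) {
      D[i, j] <- D[j, i] <- kabsch_superpose(coords[[j]], coords[[i]])$rmsd
    }
  }
  remaining <- seq_len(nf)
  clusters <- list()
  reps <- integer(0)
  while (length(remaining) > 0) {
    counts <- vapply(remaining, function(i)
      sum(D[i, remaining] <= cutoff) - 1L, integer(1))
    center <- remaining[which.max(counts)]   # which.max = lowest index on ties
    members <- remaining[D[center, remaining] <= cutoff]
    sumd <- vapply(members, function(i) sum(D[i, members]), numeric(1))
    reps <- c(reps, members[which.min(sumd)])
    clusters[[length(clusters) + 1]] <- members
    remaining <- setdiff(remaining, members)
  }
  structure(list(clusters = clusters, representatives = reps, cutoff = cutoff,
                 n_frames = nf),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "cluster(s) over", x$n_frames,
      "frames (cutoff", x$cutoff, "nm); sizes:",
      paste(utils::head(lengths(x$clusters), 10), collapse = " "), "\n")
  invisible(x)
}

# phi/psi dihedrals across all frames, vectorised per dihedral
.dihedral_frames <- function(traj, i1, i2, i3, i4) {
  P <- function(i) traj$xyz[, (3 * (i - 1) + 1):(3 * i), drop = FALSE]
  b1 <- P(i2) - P(i1); b2 <- P(i3) - P(i2); b3 <- P(i4) - P(i3)
  crossr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- crossr(b1, b2); n2 <- crossr(b2, b3)
  m1 <- crossr(n1, b2) / sqrt(rowSums(b2^2))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
}

#' Dihedral principal component analysis
#'
#' Backbone phi/psi dihedrals of the chosen residues are mapped to
#' `(cos, sin)` pairs (removing the angular periodicity), the covariance
#' of that representation is diagonalised, and frames are projected onto
#' the principal components; a 2-D histogram PMF over (PC1, PC2)
#' summarises the sampled basins. Residues at chain termini, which lack
#' one of the two dihedrals, are skipped.
#'
#' @param traj an `md_traj` with backbone atoms.
#' @param residue_range author residue numbers to include.
#' @param chain optional chain filter.
#' @param temperature K (for the PMF).
#' @param n_bins bins per PC axis for the PMF.
#' @return object of class `dpca`: `projections` (frames x components),
#'   `var_explained`, `sdev`, `pmf` (a 2-D [fes_profile()]), `angles`
#'   (frames x dihedrals, degrees).
#' @export
dpca <- function(traj, residue_range, chain = NULL, temperature = 300,
                 n_bins = 32L) {
  a <- traj$atoms
  rows <- if (is.null(chain)) rep(TRUE, nrow(a)) else a$chain %in% chain
  atom_row <- function(resno, name) {
    w <- which(rows & a$resno == resno & a$name == name)
    if (length(w) != 1) NA_integer_ else w
  }
  angles <- list()
  labels <- character(0)
  for (r in sort(intersect(residue_range, unique(a$resno[rows])))) {
    iN <- atom_row(r, "N"); iCA <- atom_row(r, "CA"); iC <- atom_row(r, "C")
    iCprev <- atom_row(r - 1, "C"); iNnext <- atom_row(r + 1, "N")
    if (!any(is.na(c(iCprev, iN, iCA, iC)))) {
      angles[[length(angles) + 1]] <- .dihedral_frames(traj, iCprev, iN, iCA, iC)
      labels <- c(labels, paste0("phi_", r))
    }
    if (!any(is.na(c(iN, iCA, iC, iNnext)))) {
      angles[[length(angles) + 1]] <- .dihedral_frames(traj, iN, iCA, iC, iNnext)
      labels <- c(labels, paste0("psi_", r))
    }
  }
  if (!length(angles)) stop("no complete phi/psi dihedrals in residue_range")
  A <- do.call(cbind, angles)
  colnames(A) <- labels
  rad <- A * pi / 180
  X <- cbind(cos(rad), sin(rad))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  proj <- pc$x
  pmf <- NULL
  if (nrow(proj) >= 4 && ncol(proj) >= 2 && pc$sdev[2] > 1e-12) {
    br <- function(v) seq(min(v) - 1e-9, max(v) + 1e-9, length.out = n_bins + 1)
    pmf <- pmf_from_samples(proj[, 1:2], list(br(proj[, 1]), br(proj[, 2])),
                            temperature = temperature)
  }
  structure(list(projections = proj, var_explained = ve, sdev = pc$sdev,
                 pmf = pmf, angles = A),
            class = "dpca")
}

#' @export
print.dpca <- function(x, ...) {
  cat("dpca:", nrow(x$projections), "frames,", ncol(x$angles), "dihedrals;",
      "PC1/PC2 variance:", paste(signif(100 * x$var_explained[1:2], 3),
                                 collapse = "% / "), "%\n")
  invisible(x)
}
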