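# internal-coordinate atom placement (NeRF): position d given atoms a-b-c,
# the bond length c-d, the angle b-c-d and the torsion a-b-c-d
.place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180; ph <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  c + bond * (-cos(th) * bc + sin(th) * cos(ph) * m - sin(th) * sin(ph) * n)
}

#' Build an ideal alpha-helix backbone
#'
#' A poly-alanine backbone (N, CA, C, O per residue) generated from ideal
#' internal coordinates with phi = -57 and psi = -47 degrees (trans
#' peptide), i.e. ~3.6 residues per turn with a ~0.15 nm rise and ~0.38 nm
#' consecutive C-alpha spacing. Deterministic (seed-free). This is also
#' the template behind the alpha-helix RMSD CV.
#'
#' @param n_residues chain length, >= 2.
#' @param chain chain identifier.
#' @param resno_start first author residue number.
#' @return an `md_structure`.
#' @export
build_ideal_helix <- function(n_residues, chain = "A", resno_start = 1L) {
  stopifnot(n_residues >= 2)
  phi <- -57; psi <- -47; omega <- 180
  b_NCA <- 0.1458; b_CAC <- 0.1525; b_CN <- 0.1329; b_CO <- 0.1231
  ang_NCAC <- 111.2; ang_CACN <- 116.2; ang_CNCA <- 121.7; ang_CACO <- 120.8

  n_at <- 4 * n_residues
  xyz <- matrix(NA_real_, n_at, 3)
  row_of <- function(i, k) 4 * (i - 1) + k  # k: 1=N 2=CA 3=C 4=O
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(b_NCA, 0, 0)
  t <- ang_NCAC * pi / 180
  xyz[3, ] <- xyz[2, ] + b_CAC * c(-cos(t), sin(t), 0)
  for (i in 2:n_residues) {
    iN <- row_of(i, 1); iCA <- row_of(i, 2); iC <- row_of(i, 3)
    pN <- row_of(i - 1, 1); pCA <- row_of(i - 1, 2); pC <- row_of(i - 1, 3)
    xyz[iN, ] <- .place_atom(xyz[pN, ], xyz[pCA, ], xyz[pC, ], b_CN, ang_CACN, psi)
    xyz[iCA, ] <- .place_atom(xyz[pCA, ], xyz[pC, ], xyz[iN, ], b_NCA, ang_CNCA, omega)
    xyz[iC, ] <- .place_atom(xyz[pC, ], xyz[iN, ], xyz[iCA, ], b_CAC, ang_NCAC, phi)
  }
  for (i in 1:n_residues) {
    iN <- row_of(i, 1); iCA <- row_of(i, 2); iC <- row_of(i, 3)
    xyz[row_of(i, 4), ] <- .place_atom(xyz[iN, ], xyz[iCA, ], xyz[iC, ],
                                       b_CO, ang_CACO, psi + 180)
  }
  resno <- rep(resno_start:(resno_start + n_residues - 1), each = 4)
  name <- rep(c("N", "CA", "C", "O"), n_residues)
  md_structure(data.frame(
    serial = seq_len(n_at), name = name, resname = "ALA", chain = chain,
    resno = resno, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = rep(c("N", "C", "C", "O"), n_residues),
    stringsAsFactors = FALSE))
}

#' Build a two-state helix-loop-helix conformer pair
#'
#' A rigid "core" helix shared by both states with a mobile C-terminal
#' "tail" displaced between them by a hinge rotation — the desk-scale
#' analogue of an agonistic-like and an antagonistic-like end state
#' (stable core 683-902 vs mobile segment 903-932). The hinge angle is
#' solved so the inter-state tail C-alpha RMSD meets `target_rmsd`; a
#' small Gaussian jitter decorates both states.
#'
#' The default tail displacement of 1.45 nm puts the difference-RMSD
#' endpoints at -1.45 and +1.45 nm, so a 30-conformation interpolated path
#' reproduces the umbrella protocol's 0.1 nm window spacing.
#'
#' @param chain_length residues, default 60.
#' @param core_fraction fraction of residues forming the rigid core.
#' @param target_rmsd desired inter-state C-alpha RMSD over the tail (nm).
#' @param jitter per-coordinate Gaussian noise sd (nm).
#' @param seed integer seed (jitter only; geometry is deterministic).
#' @return list with `state_a` (tail in the helical position), `state_b`
#'   (tail swung out), `core_resno`, `tail_resno`, `realized_rmsd`.
#' @export
build_two_state_pair <- function(chain_length = 60L, core_fraction = 2 / 3,
                                 target_rmsd = 1.45, jitter = 0.01, seed = 1L) {
  helix <- build_ideal_helix(chain_length)
  n_core <- max(2L, round(core_fraction * chain_length))
  stopifnot(n_core < chain_length)
  core_resno <- 1:n_core
  tail_resno <- (n_core + 1):chain_length

  ca <- select_coords(helix, sel_calpha())
  # helix axis: principal direction of the C-alpha cloud
  sv <- svd(sweep(ca, 2, colMeans(ca)))
  u <- sv$v[, 1]
  # rotation axis perpendicular to the helix axis
  v <- c(-u[2], u[1], 0)
  if (sqrt(sum(v^2)) < 1e-8) v <- c(1, 0, 0)
  v <- v / sqrt(sum(v^2))
  hinge <- ca[n_core, ]

  xyz <- structure_xyz(helix)
  tail_rows <- which(helix$atoms$resno %in% tail_resno)
  ca_tail_rows <- which(helix$atoms$resno %in% tail_resno & helix$atoms$name == "CA")

  rot_mat <- function(theta) {
    ct <- cos(theta); st <- sin(theta); vt <- 1 - ct
    matrix(c(ct + v[1]^2 * vt, v[1] * v[2] * vt - v[3] * st, v[1] * v[3] * vt + v[2] * st,
             v[1] * v[2] * vt + v[3] * st, ct + v[2]^2 * vt, v[2] * v[3] * vt - v[1] * st,
             v[1] * v[3] * vt - v[2] * st, v[2] * v[3] * vt + v[1] * st, ct + v[3]^2 * vt),
           3, 3, byrow = TRUE)
  }
  tail_rmsd <- function(theta) {
    R <- rot_mat(theta)
    moved <- sweep(sweep(xyz[ca_tail_rows, , drop = FALSE], 2, hinge) %*% t(R), 2, hinge, `+`)
    sqrt(mean(rowSums((moved - xyz[ca_tail_rows, , drop = FALSE])^2)))
  }
  if (tail_rmsd(pi) < target_rmsd)
    stop("target_rmsd unreachable: tail too short (max ",
         signif(tail_rmsd(pi), 3), " nm)")
  theta <- stats::uniroot(function(t) tail_rmsd(t) - target_rmsd,
                          c(0, pi), tol = 1e-10)$root
  R <- rot_mat(theta)
  xyz_b <- xyz
  xyz_b[tail_rows, ] <- sweep(sweep(xyz[tail_rows, , drop = FALSE], 2, hinge) %*% t(R),
                              2, hinge, `+`)
  set.seed(seed)
  xyz_a <- xyz + matrix(stats::rnorm(length(xyz), sd = jitter), nrow(xyz), 3)
  xyz_b <- xyz_b + matrix(stats::rnorm(length(xyz), sd = jitter), nrow(xyz), 3)
  state_a <- set_structure_xyz(helix, xyz_a)
  state_b <- set_structure_xyz(helix, xyz_b)
  realized <- sqrt(mean(rowSums((xyz_a[ca_tail_rows, ] - xyz_b[ca_tail_rows, ])^2)))
  list(state_a = state_a, state_b = state_b, core_resno = core_resno,
       tail_resno = tail_resno, realized_rmsd = realized)
}

#' Trajectory with prescribed residue-residue covariance
#'
#' Frames are the reference structure plus zero-mean Gaussian C-alpha
#' displacements whose covariance across residues equals `covariance` on
#' each Cartesian axis independently, so the dynamic cross-correlation of
#' the trajectory converges to `cov2cor(covariance)`. The truth source for
#' correlation-network recovery.
#'
#' @param covariance symmetric positive-semidefinite residue covariance
#'   (nm^2).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param reference optional `md_structure` whose C-alpha count matches
#'   `nrow(covariance)`; defaults to a C-alpha-only ideal helix.
#' @return an `md_traj`.
#' @export
correlated_gaussian_trajectory <- function(covariance, n_frames, seed = 1L,
                                           reference = NULL) {
  covariance <- as.matrix(covariance)
  n <- nrow(covariance)
  stopifnot(n == ncol(covariance), isSymmetric(covariance, tol = 1e-8))
  if (is.null(reference)) {
    hel <- build_ideal_helix(n)
    a <- hel$atoms[hel$atoms$name == "CA", ]
    a$serial <- seq_len(n)
    reference <- md_structure(a)
  }
  ref_xyz <- structure_xyz(reference)
  stopifnot(nrow(ref_xyz) == n)
  ev <- eigen(covariance, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(ev$values))
    stop("covariance is not positive semi-definite")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n)
  set.seed(seed)
  xyz <- matrix(NA_real_, n_frames, 3 * n)
  for (f in seq_len(n_frames)) {
    disp <- L %*% matrix(stats::rnorm(3 * n), n, 3)
    xyz[f, ] <- as.vector(t(ref_xyz + disp))
  }
  md_traj(reference$atoms, xyz)
}

#' Trajectory of i.i.d. isotropic Gaussian jitter
#'
#' Each frame displaces every atom of the reference independently by
#' N(0, sigma) per coordinate, so the per-atom RMSF converges to
#' `sqrt(3) * sigma`. Fixture for RMSF and clustering checks.
#'
#' @param reference an `md_structure`.
#' @param sigma per-coordinate displacement sd (nm).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return an `md_traj`.
#' @export
jittered_trajectory <- function(reference, sigma, n_frames, seed = 1L) {
  ref <- as.vector(t(structure_xyz(reference)))
  set.seed(seed)
  xyz <- matrix(ref, n_frames, length(ref), byrow = TRUE)
  if (sigma > 0)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = sigma), nrow(xyz))
  md_traj(reference$atoms, xyz)
}

#' Interpolated conformational path between two end states
#'
#' Linear Cartesian interpolation between the two structures after rigid
#' superposition of the second onto the first (on `fit_sel`, or all atoms
#' shared). With `n` points the endpoints equal the references and the
#' difference-RMSD progresses monotonically — ordered, roughly evenly
#' spaced seeds for umbrella windows. A morphing stand-in, not a physical
#' transition pathway.
#'
#' @param refA,refB `md_structure`s over an identical topology.
#' @param n number of conformations, >= 2 (the umbrella protocol uses 30).
#' @param fit_sel optional `atom_selection` to superpose on.
#' @return list of `n` `md_structure`s from `refA` to `refB`.
#' @export
interpolate_path <- function(refA, refB, n, fit_sel = NULL) {
  stopifnot(n >= 2)
  if (!identical(refA$atoms[c("name", "chain", "resno")],
                 refB$atoms[c("name", "chain", "resno")]))
    stop("end states must share an identical topology")
  xyzA <- structure_xyz(refA)
  xyzB <- structure_xyz(refB)
  if (!is.null(fit_sel)) {
    fit <- kabsch_superpose(select_coords(refB, fit_sel),
                            select_coords(refA, fit_sel))
    xyzB <- apply_superpose(xyzB, fit)
  }
  lapply(seq(0, 1, length.out = n), function(t)
    set_structure_xyz(refA, (1 - t) * xyzA + t * xyzB))
}
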