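#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid superposition of `mobile` onto `reference` via SVD of
#' the covariance of the centred coordinate sets, with the determinant
#' correction that guarantees a proper rotation.
#'
#' @param mobile,reference numeric matrices, `n` x 3 with `n >= 3`,
#'   matched rows.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3;
#'   `fitted = mobile %*% t(rotation)` then `+ translation` rowwise) and
#'   `rmsd` (nm).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("mobile and reference must be matched n x 3 matrices")
  if (nrow(mobile) < 3) stop("need at least 3 points for superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- t(A) %*% B
  s <- svd(H)
  if (s$d[2] < 1e-12 * max(s$d[1], 1e-300))
    stop("degenerate (collinear) configuration: superposition not unique")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)          # fitted_i = R %*% mobile_i
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)), rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#'
#' @param xyz numeric matrix `n` x 3.
#' @param fit result of [kabsch_superpose()].
#' @return transformed coordinates.
#' @export
apply_superpose <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' RMSD on one selection after fitting on another
#'
#' The frame is rigidly superposed onto the reference using the fit
#' selection only (e.g. the stable core, backbone 683-902); the RMSD is
#' then evaluated on the calculation selection only (e.g. C-alpha 903-932,
#' the mobile helix-loop-helix segment). Separating the two maximises the
#' discriminating power of the resulting coordinate.
#'
#' @param frame,reference `md_structure` objects.
#' @param fit_sel,calc_sel `atom_selection`s resolvable on both structures.
#' @return RMSD in nm.
#' @export
rmsd_after_fit <- function(frame, reference, fit_sel, calc_sel) {
  fit <- kabsch_superpose(select_coords(frame, fit_sel),
                          select_coords(reference, fit_sel))
  moved <- apply_superpose(select_coords(frame, calc_sel), fit)
  ref <- select_coords(reference, calc_sel)
  sqrt(mean(rowSums((moved - ref)^2)))
}

#' Specification of the difference-RMSD progress coordinate
#'
#' Holds the two reference end states and the fit/calculation selections of
#' the delta-RMSD coordinate. Defaults follow the umbrella-sampling
#' protocol for the receptor: fit on backbone 683-902, evaluate on C-alpha
#' 903-932.
#'
#' @param ref_agonistic,ref_antagonistic reference `md_structure`s.
#' @param fit_sel,calc_sel `atom_selection`s; defaults as above.
#' @return object of class `delta_rmsd_spec`.
#' @export
delta_rmsd_spec <- function(ref_agonistic, ref_antagonistic,
                            fit_sel = sel_backbone(683:902),
                            calc_sel = sel_calpha(903:932)) {
  # resolvable on both references, up front
  for (s in list(fit_sel, calc_sel)) {
    select_atoms(ref_agonistic, s)
    select_atoms(ref_antagonistic, s)
  }
  structure(list(ref_agonistic = ref_agonistic,
                 ref_antagonistic = ref_antagonistic,
                 fit_sel = fit_sel, calc_sel = calc_sel),
            class = "delta_rmsd_spec")
}

#' Difference RMSD to two reference conformations
#'
#' `delta_rmsd = RMSD(frame, agonistic ref) - RMSD(frame, antagonistic
#' ref)`, each RMSD computed on the calculation selection after fitting on
#' the fit selection. More negative values mean closer to the agonistic
#' end state; the coordinate is antisymmetric under swapping the two
#' references.
#'
#' @param frame an `md_structure`.
#' @param spec a [delta_rmsd_spec()].
#' @return signed length (nm).
#' @export
delta_rmsd <- function(frame, spec) {
  rmsd_after_fit(frame, spec$ref_agonistic, spec$fit_sel, spec$calc_sel) -
    rmsd_after_fit(frame, spec$ref_antagonistic, spec$fit_sel, spec$calc_sel)
}

#' Helix axis from terminal residue groups
#'
#' The axis vector points from the centre of mass of the C-alpha atoms of
#' the N-terminal residue group to that of the C-terminal group. For the
#' receptor, helix 11 uses residues 883-886 (tail) to 894-897 (head), and
#' helix 3 uses 712-715 to 730-733.
#'
#' @param start_resno residue numbers whose C-alpha COM is the vector tail.
#' @param end_resno residue numbers whose C-alpha COM is the vector head.
#' @param chain optional chain filter.
#' @return object of class `helix_axis_spec`.
#' @export
helix_axis_spec <- function(start_resno, end_resno, chain = NULL) {
  if (length(intersect(start_resno, end_resno)) > 0)
    stop("start and end residue ranges must not overlap")
  structure(list(start_resno = start_resno, end_resno = end_resno,
                 chain = chain), class = "helix_axis_spec")
}

.helix_axis_vector <- function(frame, axis) {
  head_xyz <- select_coords(frame, sel_calpha(axis$end_resno, axis$chain))
  tail_xyz <- select_coords(frame, sel_calpha(axis$start_resno, axis$chain))
  colMeans(head_xyz) - colMeans(tail_xyz)
}

#' Crossing angle between two helices
#'
#' Angle between the two directed COM-to-COM axis vectors, reported over
#' the full [0, 180] degree range (the direction of each helix matters; the
#' angle is deliberately not folded to [0, 90]).
#'
#' @param frame an `md_structure`.
#' @param axisA,axisB [helix_axis_spec()] objects.
#' @return angle in degrees.
#' @export
helix_cross_angle <- function(frame, axisA, axisB) {
  va <- .helix_axis_vector(frame, axisA)
  vb <- .helix_axis_vector(frame, axisB)
  cosang <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Smooth contact number between two atom groups
#'
#' `NC = sum_ij f(r_ij)` with the rational switching function
#' `f(r) = (1-(r/r0)^n)/(1-(r/r0)^m)`, `r0 = 0.85` nm, `n = 8`, `m = 12`
#' by default — the differentiable contact-counting CV used for biasing
#' (NC1: helix 12 vs helix 3; NC2: helix 12 vs helix 11).
#'
#' @param coordsA,coordsB numeric matrices (`n` x 3, nm), e.g. C-alpha
#'   coordinates of the two helices.
#' @param r0 switching radius (nm).
#' @param n,m switching exponents.
#' @return dimensionless contact number in (0, `nrow(coordsA) * nrow(coordsB)`].
#' @export
contact_number <- function(coordsA, coordsB, r0 = 0.85, n = 8L, m = 12L) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (nrow(coordsA) == 0 || nrow(coordsB) == 0) stop("empty coordinate set")
  d2 <- outer(rowSums(coordsA^2), rowSums(coordsB^2), `+`) -
    2 * coordsA %*% t(coordsB)
  r <- sqrt(pmax(d2, 0))
  sum(switching_fn(r, r0 = r0, n = n, m = m))
}

#' Alpha-helix RMSD collective variable
#'
#' A smooth count of how many contiguous 6-residue windows of a segment are
#' alpha-helical: for each window the backbone (N, CA, C, O) RMSD `r_i` to
#' an ideal 6-residue alpha-helix template (phi = -57, psi = -47 degrees)
#' is computed after optimal superposition and passed through the switching
#' function with `r0 = 0.08` nm; the CV is the sum over windows, bounded by
#' `length(residue_range) - 5`.
#'
#' @param frame an `md_structure` with backbone atoms present.
#' @param residue_range integer vector of consecutive author residue
#'   numbers, length >= 6.
#' @param r0 switching radius (nm), default 0.08.
#' @param n,m switching exponents.
#' @param chain optional chain filter.
#' @return dimensionless value in (0, `length(residue_range) - 5`].
#' @export
alpha_helix_rmsd_cv <- function(frame, residue_range, r0 = 0.08,
                                n = 8L, m = 12L, chain = NULL) {
  residue_range <- sort(as.integer(residue_range))
  if (length(residue_range) < 6) stop("residue_range must span at least 6 residues")
  template <- select_coords(build_ideal_helix(6), sel_backbone(1:6))
  total <- 0
  for (i in seq_len(length(residue_range) - 5)) {
    win <- residue_range[i:(i + 5)]
    coords <- select_coords(frame, sel_backbone(win, chain))
    r <- kabsch_superpose(coords, template)$rmsd
    total <- total + switching_fn(r, r0 = r0, n = n, m = m)
  }
  total
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}
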