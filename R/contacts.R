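#' Side-chain function-group atom table
#'
#' Maps residue types to the side-chain atoms whose centroid defines the
#' residue's interacting "function group" (e.g. the three guanidinium
#' nitrogens of Arg, the two carboxylate oxygens of Glu/Asp, the aromatic
#' ring atoms of Phe/Tyr/Trp/His). Used by [sidechain_group_distance()] and
#' the contact criteria.
#'
#' @return named list: residue 3-letter code to character vector of atom
#'   names.
#' @export
function_group_table <- function() {
  list(
    ARG = c("NE", "NH1", "NH2"),
    LYS = "NZ",
    GLU = c("OE1", "OE2"),
    ASP = c("OD1", "OD2"),
    ASN = c("OD1", "ND2"),
    GLN = c("OE1", "NE2"),
    SER = "OG",
    THR = "OG1",
    HIS = c("ND1", "NE2"),
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  )
}

.group_coords <- function(frame, resno, chain = NULL, table = function_group_table()) {
  a <- frame$atoms
  rows <- a$resno == resno & (if (is.null(chain)) TRUE else a$chain == chain)
  if (!any(rows)) stop("residue ", resno, " not found")
  resname <- a$resname[rows][1]
  grp <- table[[resname]]
  if (is.null(grp)) stop("no function-group entry for residue type ", resname)
  select_coords(frame, atom_selection(resno = resno, names = grp, chain = chain))
}

#' Distance between side-chain function-group centroids
#'
#' Euclidean distance between the centroids of the two residues' function
#' groups (e.g. for an Arg-Glu pair, between the centre of the three
#' side-chain nitrogens and the centre of the two carboxylate oxygens).
#'
#' @param frame an `md_structure`.
#' @param resA,resB author residue numbers.
#' @param chain optional chain filter.
#' @param table function-group table, see [function_group_table()].
#' @return distance in nm.
#' @export
sidechain_group_distance <- function(frame, resA, resB, chain = NULL,
                                     table = function_group_table()) {
  cA <- colMeans(.group_coords(frame, resA, chain, table))
  cB <- colMeans(.group_coords(frame, resB, chain, table))
  sqrt(sum((cA - cB)^2))
}

#' Close-contact criterion
#'
#' Two residues are in close contact when their side-chain function-group
#' distance is below 5 Angstrom (0.5 nm).
#'
#' @param distance distance(s) in nm.
#' @param cutoff cutoff in nm, default 0.5.
#' @return logical.
#' @export
is_close_contact <- function(distance, cutoff = 0.5) {
  distance < cutoff
}

#' Pi-cation interaction criterion
#'
#' TRUE when (i) the distance between the aromatic ring centroid and the
#' cationic-group centre is below 6 Angstrom (0.6 nm) and (ii) the angle
#' between the centroid-to-cation vector and the ring-plane normal lies in
#' [60, 120] degrees. Note the printed angular window places the cation
#' near the ring plane rather than stacked above it; the criterion is
#' applied exactly as stated.
#'
#' @param frame an `md_structure`.
#' @param aromatic_res residue number of the aromatic residue (Phe/Tyr/Trp).
#' @param cationic_res residue number of the cationic residue (Arg/Lys).
#' @param chain optional chain filter.
#' @param table function-group table.
#' @param d_cut distance cutoff (nm), default 0.6.
#' @param angle_range allowed angle window in degrees, default `c(60, 120)`.
#' @return logical scalar.
#' @export
is_pi_cation <- function(frame, aromatic_res, cationic_res, chain = NULL,
                         table = function_group_table(),
                         d_cut = 0.6, angle_range = c(60, 120)) {
  ring <- .group_coords(frame, aromatic_res, chain, table)
  if (nrow(ring) < 3) stop("aromatic residue must expose a ring of >= 3 atoms")
  cation <- colMeans(.group_coords(frame, cationic_res, chain, table))
  centroid <- colMeans(ring)
  v <- cation - centroid
  d <- sqrt(sum(v^2))
  if (d >= d_cut) return(FALSE)
  # ring-plane normal: least singular vector of the centred ring atoms
  sv <- svd(sweep(ring, 2, centroid))
  normal <- sv$v[, 3]
  cosang <- sum(v * normal) / d
  ang <- acos(min(1, max(-1, cosang))) * 180 / pi
  ang >= angle_range[1] && ang <= angle_range[2]
}
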