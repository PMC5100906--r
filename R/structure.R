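#' Construct a structure object from an atom table
#'
#' The central container for a protein conformation: an ordered atom table
#' with author residue numbering and coordinates in nm. Most users obtain
#' one from [read_pdb()] or from the synthetic builders
#' ([build_ideal_helix()], [build_two_state_pair()]).
#'
#' @param atoms data.frame with columns `serial` (integer), `name` (atom
#'   name), `resname` (3-letter residue code), `chain` (single character),
#'   `resno` (author residue number, integer), `x`, `y`, `z` (nm) and
#'   `element`.
#' @return an object of class `md_structure`.
#' @export
md_structure <- function(atoms) {
  req <- c("serial", "name", "resname", "chain", "resno", "x", "y", "z", "element")
  if (!all(req %in% names(atoms)))
    stop("atom table must have columns: ", paste(req, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) > 0) {
    if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
      stop("non-finite coordinates in atom table")
    if (any(!nzchar(atoms$name)))
      stop("empty atom names in atom table")
    key <- paste(atoms$chain, atoms$resno, atoms$name)
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      stop("duplicate (chain, resno, name) keys: ",
           paste(utils::head(dup, 5), collapse = "; "))
    }
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  a <- x$atoms
  cat("md_structure:", nrow(a), "atoms")
  if (nrow(a) > 0) {
    cat(",", length(unique(paste(a$chain, a$resno))), "residues,",
        "chains:", paste(unique(a$chain), collapse = " "),
        sprintf(", resno %d..%d", min(a$resno), max(a$resno)))
  }
  cat("\n")
  invisible(x)
}

#' Coordinate matrix of a structure
#'
#' @param structure an `md_structure`.
#' @return numeric matrix, one row per atom, columns x/y/z in nm.
#' @export
structure_xyz <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#'
#' @param structure an `md_structure`.
#' @param xyz numeric matrix, `n_atoms` x 3, nm.
#' @return a new `md_structure` with the same topology.
#' @export
set_structure_xyz <- function(structure, xyz) {
  stopifnot(is.matrix(xyz), nrow(xyz) == nrow(structure$atoms), ncol(xyz) == 3)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

.guess_element <- function(name) {
  # strip digits/primes, first remaining letter
  stripped <- gsub("[0-9']", "", name)
  toupper(substr(stripped, 1, 1))
}

#' Read a protein structure from a PDB file or text
#'
#' Parses ATOM/HETATM records (via bio3d), converting coordinates from
#' Angstrom to nm. When alternate-location indicators are present only the
#' first-listed conformer is kept, with a warning. Records carrying
#' insertion codes are rejected: every geometric CV in this package
#' addresses residues by plain author numbering, and silently dropping or
#' merging inserted residues would corrupt contact-number values.
#'
#' @param source path to a PDB file, or a character vector of PDB-format
#'   lines.
#' @return an `md_structure`.
#' @export
read_pdb <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  is_rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_rec)) stop("no ATOM/HETATM records found in PDB input")
  recs <- lines[is_rec]
  recno <- which(is_rec)

  bad <- nchar(recs) < 54
  if (!any(bad)) {
    for (fld in list(c(31, 38), c(39, 46), c(47, 54), c(7, 11), c(23, 26))) {
      v <- suppressWarnings(as.numeric(substr(recs, fld[1], fld[2])))
      bad <- bad | is.na(v)
    }
  }
  if (any(bad))
    stop("malformed ATOM/HETATM record at line ",
         recno[which(bad)[1]], ": ", recs[which(bad)[1]])

  ins <- substr(recs, 27, 27)
  if (any(ins != " "))
    stop("insertion codes are not supported (first at line ",
         recno[which(ins != " ")[1]], "); renumber the structure first")

  alt <- substr(recs, 17, 17)
  if (any(alt != " ")) {
    # keep blank altloc plus the first-listed alternate identifier
    first_alt <- alt[alt != " "][1]
    keep <- alt == " " | alt == first_alt
    warning("alternate locations present; keeping first-listed conformer '",
            first_alt, "'")
    recs <- recs[keep]
  }

  atoms <- data.frame(
    serial  = as.integer(substr(recs, 7, 11)),
    name    = trimws(substr(recs, 13, 16)),
    resname = trimws(substr(recs, 18, 20)),
    chain   = substr(recs, 22, 22),
    resno   = as.integer(substr(recs, 23, 26)),
    x       = as.numeric(substr(recs, 31, 38)) / 10,
    y       = as.numeric(substr(recs, 39, 46)) / 10,
    z       = as.numeric(substr(recs, 47, 54)) / 10,
    element = trimws(substr(recs, 77, 78)),
    stringsAsFactors = FALSE
  )
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <- .guess_element(atoms$name[blank])
  md_structure(atoms)
}

#' Write a structure to a PDB file
#'
#' Coordinates are converted nm to Angstrom; serials are renumbered 1..N in
#' storage order. An empty structure produces a file holding only END.
#'
#' @param structure an `md_structure`.
#' @param destination output path.
#' @return invisibly, `destination`.
#' @export
write_pdb <- function(structure, destination) {
  a <- structure$atoms
  if (nrow(a) == 0) {
    writeLines("END", destination)
    return(invisible(destination))
  }
  xyz_ang <- as.vector(t(structure_xyz(structure) * 10))
  if (any(abs(xyz_ang) >= 10000))
    stop("coordinates overflow fixed-width PDB columns (|x| >= 10000 Angstrom)")
  bio3d::write.pdb(
    pdb = NULL, file = destination, xyz = xyz_ang,
    resno = a$resno, resid = a$resname, eleno = seq_len(nrow(a)),
    elety = a$name, chain = a$chain, elesy = a$element,
    o = rep(1, nrow(a)), b = rep(0, nrow(a)), end = TRUE
  )
  invisible(destination)
}

#' Define an atom selection
#'
#' A declarative filter over chains, author residue numbers and atom names
#' that resolves to a deterministic, ordered atom list on any structure
#' containing the selected atoms. Selections fail loudly when a requested
#' atom is absent (e.g. a missing loop residue) rather than silently
#' skipping it.
#'
#' @param resno integer vector of author residue numbers, or NULL for all.
#' @param names character vector of atom names (e.g. `"CA"`, or
#'   `c("N","CA","C","O")`), or NULL for all atoms of the residues.
#' @param chain chain identifier(s), or NULL for all chains.
#' @return an object of class `atom_selection`.
#' @export
atom_selection <- function(resno = NULL, names = NULL, chain = NULL) {
  structure(list(resno = if (is.null(resno)) NULL else as.integer(resno),
                 names = names, chain = chain),
            class = "atom_selection")
}

#' Convenience selections: C-alpha and backbone atoms
#'
#' @inheritParams atom_selection
#' @rdname atom_selection
#' @export
sel_calpha <- function(resno = NULL, chain = NULL)
  atom_selection(resno = resno, names = "CA", chain = chain)

#' @rdname atom_selection
#' @export
sel_backbone <- function(resno = NULL, chain = NULL)
  atom_selection(resno = resno, names = c("N", "CA", "C", "O"), chain = chain)

.canonical_name_rank <- function(name) {
  bb <- match(name, c("N", "CA", "C", "O"))
  ifelse(is.na(bb), 4L + rank(name, ties.method = "first"), bb)
}

#' Resolve an atom selection to row indices
#'
#' @param structure an `md_structure`.
#' @param selection an `atom_selection`.
#' @return integer vector of row indices into the atom table, ordered by
#'   (chain, residue number, canonical atom order: N, CA, C, O, then
#'   alphabetical).
#' @export
select_atoms <- function(structure, selection) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(selection$chain)) keep <- keep & a$chain %in% selection$chain
  if (!is.null(selection$resno)) keep <- keep & a$resno %in% selection$resno
  if (!is.null(selection$names)) keep <- keep & a$name %in% selection$names
  idx <- which(keep)
  if (length(idx) == 0)
    stop("selection resolves to no atoms")

  chains <- if (!is.null(selection$chain)) selection$chain else
    unique(a$chain[if (!is.null(selection$resno)) a$resno %in% selection$resno else TRUE])
  if (!is.null(selection$resno)) {
    want <- expand.grid(chain = chains, resno = selection$resno,
                        stringsAsFactors = FALSE)
    if (!is.null(selection$names)) {
      want <- merge(want, data.frame(name = selection$names), by = NULL)
      have <- paste(a$chain[idx], a$resno[idx], a$name[idx])
      miss <- !(paste(want$chain, want$resno, want$name) %in% have)
    } else {
      have <- unique(paste(a$chain[idx], a$resno[idx]))
      miss <- !(paste(want$chain, want$resno) %in% have)
    }
    if (any(miss)) {
      w <- want[miss, , drop = FALSE]
      lab <- if (!is.null(selection$names))
        paste0(w$chain, ":", w$resno, ":", w$name) else paste0(w$chain, ":", w$resno)
      stop("selection atoms missing from structure: ",
           paste(utils::head(unique(lab), 8), collapse = ", "),
           if (length(unique(lab)) > 8) ", ..." else "")
    }
  }
  sub <- a[idx, ]
  ord <- order(sub$chain, sub$resno, .canonical_name_rank(sub$name))
  idx[ord]
}

#' Coordinates of a selection
#'
#' @inheritParams select_atoms
#' @return numeric matrix (`n_selected` x 3, nm) with rows ordered by
#'   (chain, residue number, canonical atom order); row names are
#'   `chain:resno:name`.
#' @export
select_coords <- function(structure, selection) {
  idx <- select_atoms(structure, selection)
  a <- structure$atoms[idx, ]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- paste(a$chain, a$resno, a$name, sep = ":")
  m
}
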