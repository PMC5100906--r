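#' Construct a trajectory over a fixed topology
#'
#' A time-ordered sequence of conformations sharing one atom table. Frames
#' are stored as a numeric matrix with one row per frame and atom-major
#' x/y/z triples in the columns, in nm.
#'
#' @param atoms atom table as in [md_structure()] (the shared topology), or
#'   an `md_structure`.
#' @param xyz numeric matrix, `n_frames` x `3 * n_atoms`.
#' @param times optional numeric vector of frame times (ps); defaults to
#'   `0:(n_frames-1)`.
#' @return an object of class `md_traj`.
#' @export
md_traj <- function(atoms, xyz, times = NULL) {
  if (inherits(atoms, "md_structure")) atoms <- atoms$atoms
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * nrow(atoms))
    stop("xyz has ", ncol(xyz), " columns; topology implies ", 3 * nrow(atoms))
  if (is.null(times)) times <- seq_len(nrow(xyz)) - 1
  if (length(times) != nrow(xyz)) stop("times length != number of frames")
  if (is.unsorted(times, strictly = TRUE)) stop("frame times must be strictly increasing")
  structure(list(atoms = as.data.frame(atoms), xyz = xyz, times = as.numeric(times)),
            class = "md_traj")
}

#' @export
print.md_traj <- function(x, ...) {
  cat("md_traj:", nrow(x$xyz), "frames x", nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_traj`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame as a structure
#'
#' @param traj an `md_traj`.
#' @param i frame index (1-based).
#' @return an `md_structure`.
#' @export
traj_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= nrow(traj$xyz))
  m <- matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
  set_structure_xyz(md_structure(traj$atoms), m)
}

#' Coordinates of one frame
#'
#' @inheritParams traj_frame
#' @return numeric matrix `n_atoms` x 3 (nm).
#' @export
frame_xyz <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Build a trajectory from a list of structures
#'
#' @param structures list of `md_structure` objects sharing one topology.
#' @param times optional frame times (ps).
#' @return an `md_traj`.
#' @export
traj_from_structures <- function(structures, times = NULL) {
  stopifnot(length(structures) >= 1)
  xyz <- t(vapply(structures, function(s) as.vector(t(structure_xyz(s))),
                  numeric(3 * nrow(structures[[1]]$atoms))))
  md_traj(structures[[1]]$atoms, xyz, times)
}

#' Write / read the plain-text trajectory container
#'
#' A portable, engine-independent text format: a header line with a format
#' tag, the atom table, then one whitespace-separated line of `3 * n_atoms`
#' coordinates (nm) per frame, preceded by its time (ps).
#'
#' @param traj an `md_traj`.
#' @param path file path.
#' @return `write_traj` returns `path` invisibly; `read_traj` returns an
#'   `md_traj`.
#' @export
write_traj <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("metawham_traj 1 %d %d", nrow(traj$atoms), nrow(traj$xyz)), con)
  utils::write.table(traj$atoms, con, row.names = FALSE, quote = TRUE)
  for (i in seq_len(nrow(traj$xyz)))
    writeLines(paste(c(format(traj$times[i], digits = 12),
                       format(traj$xyz[i, ], digits = 12)), collapse = " "), con)
  invisible(path)
}

#' @rdname write_traj
#' @export
read_traj <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  if (hdr[1] != "metawham_traj") stop("not a metawham trajectory file: ", path)
  n_at <- as.integer(hdr[3]); n_fr <- as.integer(hdr[4])
  atoms <- utils::read.table(text = lines[2:(2 + n_at)], header = TRUE,
                             stringsAsFactors = FALSE, colClasses = NA)
  atoms$chain <- as.character(atoms$chain)
  body <- lines[(3 + n_at):(2 + n_at + n_fr)]
  vals <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  times <- vapply(vals, `[`, numeric(1), 1)
  xyz <- do.call(rbind, lapply(vals, `[`, -1))
  md_traj(atoms, xyz, times)
}
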