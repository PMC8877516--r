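#' Trajectory ensemble container
#'
#' Frames x atoms x 3 coordinate array (Angstrom) plus the atom table of
#' the underlying structure, so atoms can be addressed by
#' (chain, residue, atom name).
#'
#' @param coordinates numeric array `c(n_frames, n_atoms, 3)`.
#' @param atom_table data.frame with elety/resid/chain/resno (one row per
#'   atom, same order as the coordinate slabs).
#' @export
trajectory_ensemble <- function(coordinates, atom_table) {
  stopifnot(is.array(coordinates), length(dim(coordinates)) == 3,
            dim(coordinates)[3] == 3,
            dim(coordinates)[2] == nrow(atom_table),
            dim(coordinates)[1] >= 1,
            all(is.finite(coordinates)))
  out <- list(coordinates = coordinates,
              atom_table = as.data.frame(atom_table),
              frame_count = dim(coordinates)[1])
  class(out) <- "trajectory_ensemble"
  out
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory_ensemble: %d frames x %d atoms\n",
              x$frame_count, dim(x$coordinates)[2]))
  invisible(x)
}

#' Extract one atom's per-frame positions as a point cloud
#'
#' @param traj a [trajectory_ensemble()].
#' @param chain,residue_index,atom_name address of the tracked atom
#'   (e.g. the terminal C-alpha of a disordered tail).
#' @return n_frames x 3 matrix, frame order preserved.
#' @export
track_atom <- function(traj, chain, residue_index, atom_name = "CA") {
  at <- traj$atom_table
  i <- which(at$chain == chain & at$resno == residue_index &
             at$elety == atom_name)
  if (length(i) != 1)
    stop(sprintf("atom (%s, %d, %s): %s", chain, residue_index, atom_name,
                 if (length(i)) "ambiguous" else "not found"))
  pts <- traj$coordinates[, i, , drop = FALSE]
  matrix(pts, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, standard fixed-width ATOM records.
#'
#' @param traj a [trajectory_ensemble()].
#' @param path output path.
#' @export
write_trajectory_pdb <- function(traj, path) {
  at <- traj$atom_table
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(traj$frame_count)) {
    writeLines(sprintf("MODEL %8d", f), con)
    xyz <- traj$coordinates[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, 1, 3)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(at)), substr(at$elety, 1, 4), substr(at$resid, 1, 3),
      substr(at$chain, 1, 1), at$resno, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB as a trajectory
#' @param path file path.
#' @return a [trajectory_ensemble()].
#' @export
read_trajectory_pdb <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
  at <- pdb$atom
  xyz <- pdb$xyz                       # n_frames x (3 * n_atoms)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  coord <- array(NA_real_, c(nf, na, 3))
  for (k in 1:3) coord[, , k] <- xyz[, seq(k, by = 3, length.out = na),
                                     drop = FALSE]
  atoms <- data.frame(elety = at$elety, resid = at$resid,
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = at$resno, stringsAsFactors = FALSE)
  trajectory_ensemble(coord, atoms)
}

#' Write/read a trajectory as plain XYZ frames
#'
#' Standard XYZ stanzas: atom count line, comment line, then
#' `name x y z` rows; one stanza per frame. Atom names encode
#' chain:resno:elety so the atom table survives the round trip.
#'
#' @param traj a [trajectory_ensemble()].
#' @param path file path.
#' @rdname trajectory_xyz
#' @export
write_trajectory_xyz <- function(traj, path) {
  at <- traj$atom_table
  con <- file(path, "w")
  on.exit(close(con))
  lab <- sprintf("%s:%d:%s", at$chain, at$resno, at$elety)
  for (f in seq_len(traj$frame_count)) {
    writeLines(c(as.character(nrow(at)), sprintf("frame %d", f)), con)
    xyz <- traj$coordinates[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, 1, 3)
    writeLines(sprintf("%-12s %12.6f %12.6f %12.6f",
                       lab, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' @rdname trajectory_xyz
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1; frames <- list(); lab <- NULL
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    block <- lines[(i + 2):(i + 1 + n)]
    tok <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(tok[, 2:4]), ncol = 3)
    if (is.null(lab)) lab <- tok[, 1]
    i <- i + 2 + n
  }
  nf <- length(frames); na <- length(lab)
  coord <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) coord[f, , ] <- frames[[f]]
  parts <- strsplit(lab, ":")
  atoms <- data.frame(
    elety = vapply(parts, function(p) if (length(p) >= 3) p[3] else "CA", ""),
    resid = "UNK",
    chain = vapply(parts, `[`, "", 1),
    resno = as.integer(vapply(parts, function(p)
      if (length(p) >= 2) p[2] else "1", "")),
    stringsAsFactors = FALSE)
  trajectory_ensemble(coord, atoms)
}
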