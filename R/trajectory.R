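#' Construct an MD trajectory object
#'
#' A lightweight frames-by-atoms container: one constant atom roster
#' (chain, residue number/name, atom name, element) plus Cartesian
#' coordinates in Angstrom for every frame, stored as a frames x 3N
#' matrix (x1, y1, z1, x2, ...).
#'
#' @param atoms data frame with columns `elety` (atom name), `resid`
#'   (residue name), `chain`, `resno`, `elesy` (element symbol).
#' @param xyz numeric matrix, one row per frame, `3 * nrow(atoms)`
#'   columns.
#' @return an object of class `"md_trajectory"`.
#' @export
md_trajectory <- function(atoms, xyz) {
  need <- c("elety", "resid", "chain", "resno", "elesy")
  if (!all(need %in% names(atoms)))
    stop("md_trajectory: atoms needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(atoms))
    stop("md_trajectory: xyz must have 3 * n_atoms columns",
         call. = FALSE)
  if (nrow(xyz) < 1) stop("md_trajectory: >= 1 frame required",
                          call. = FALSE)
  if (!all(is.finite(xyz)))
    stop("md_trajectory: coordinates must be finite", call. = FALSE)
  structure(list(atoms = atoms, xyz = xyz), class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("MD trajectory: %d frames, %d atoms, chains %s\n",
              nrow(x$xyz), nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `"md_trajectory"`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

# n_atoms x 3 coordinate matrix of one frame
.frame_coords <- function(traj, frame) {
  matrix(traj$xyz[frame, ], ncol = 3, byrow = TRUE)
}

#' Read a multi-model PDB trajectory
#'
#' Parses MODEL/ENDMDL-delimited frames via [bio3d::read.pdb()].
#' Element symbols missing from the file are inferred from the first
#' letter of the atom name. Insertion codes are not supported.
#'
#' @param file path to a PDB file.
#' @return an `"md_trajectory"`.
#' @export
read_trajectory <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("read_trajectory: insertion codes are unsupported",
         call. = FALSE)
  ele <- at$elesy
  blank <- is.na(ele) | !nzchar(trimws(ele))
  ele[blank] <- substr(gsub("[^A-Za-z].*", "", at$elety[blank]), 1, 1)
  atoms <- data.frame(elety = at$elety, resid = at$resid,
                      chain = at$chain, resno = at$resno,
                      elesy = toupper(trimws(ele)))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  md_trajectory(atoms, unclass(xyz))
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj an `"md_trajectory"`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_trajectory_pdb <- function(traj, file) {
  con <- file(file, "w")
  on.exit(close(con))
  a <- traj$atoms
  for (f in seq_len(n_frames(traj))) {
    xyz <- .frame_coords(traj, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)),
      ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
      a$resid, a$chain, a$resno, xyz[, 1], xyz[, 2], xyz[, 3], a$elesy)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Superposition RMSD along a trajectory
#'
#' Root-mean-square deviation of a selection against a reference frame
#' after optimal least-squares superposition (rotation + translation).
#' Frames are superposed with [bio3d::fit.xyz()]; the deviation is then
#' computed at full precision from the fitted coordinates.
#'
#' @param traj an `"md_trajectory"`.
#' @param reference_frame 1-based frame index used as reference.
#' @param selection `NULL` for all atoms; a character vector of atom
#'   names (e.g. `"CA"`); a logical or integer atom index vector.
#' @return numeric vector of per-frame RMSD values (Angstrom).
#' @export
trajectory_rmsd <- function(traj, reference_frame = 1,
                            selection = NULL) {
  idx <- if (is.null(selection)) seq_len(nrow(traj$atoms))
  else if (is.character(selection))
    which(trimws(traj$atoms$elety) %in% selection)
  else if (is.logical(selection)) which(selection)
  else as.integer(selection)
  if (length(idx) == 0)
    stop("trajectory_rmsd: empty atom selection", call. = FALSE)
  inds3 <- bio3d::atom2xyz(idx)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(traj$xyz[reference_frame, ], traj$xyz,
                   fixed.inds = inds3, mobile.inds = inds3))
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1)
  ref <- traj$xyz[reference_frame, inds3]
  vapply(seq_len(nrow(fitted)), function(f) {
    d <- fitted[f, inds3] - ref
    sqrt(sum(d^2) / length(idx))
  }, numeric(1))
}
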