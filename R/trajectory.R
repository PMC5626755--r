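## Trajectory container and coordinate I/O (DCD, multi-model PDB).
##
## Frames are stored as an n_frames x 3n matrix in (x1,y1,z1,x2,...) order,
## the same layout bio3d uses, so whole-trajectory operations vectorise.

#' Construct a Trajectory
#'
#' @param topology `Structure` the frames refer to.
#' @param xyz numeric matrix, n_frames x (3 * n_atoms), coordinates in
#'   Angstrom ordered x1,y1,z1,x2,...
#' @param timestep time between stored frames, ps.
#' @return Object of class `"Trajectory"`.
#' @export
new_trajectory <- function(topology, xyz, timestep = 2) {
  if (!inherits(topology, "Structure")) stop("topology must be a Structure")
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop(sprintf("frame width %d does not match topology (%d atoms -> %d)",
                 ncol(xyz), n_atoms(topology), 3L * n_atoms(topology)))
  if (nrow(xyz) < 1L) stop("a trajectory needs at least one frame")
  if (!isTRUE(timestep > 0)) stop("timestep must be > 0")
  structure(list(topology = topology, xyz = xyz, timestep = timestep),
            class = "Trajectory")
}

#' Number of frames
#' @param traj Trajectory.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame as an n x 3 coordinate matrix
#' @param traj Trajectory.
#' @param i frame index (1-based).
#' @return n_atoms x 3 matrix.
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

## n x 3 frame -> flat xyz vector
flatten_frame <- function(m) as.vector(t(m))

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, %.3g ps/frame\n",
              n_frames(x), n_atoms(x$topology), x$timestep))
  invisible(x)
}

is_dcd_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", n = 8L)
  if (length(hdr) < 8L) return(FALSE)
  magic <- rawToChar(hdr[5:8])
  identical(magic, "CORD")
}

#' Read a coordinate trajectory
#'
#' Reads a CHARMM/NAMD-flavour DCD file (via bio3d) or a multi-MODEL PDB as
#' a fallback, and checks the atom count against the supplied topology.
#'
#' @param path DCD or multi-model PDB file.
#' @param topology `Structure` with the matching atom count.
#' @param timestep time between stored frames, ps (DCD headers do not carry
#'   reliable units, so this is an explicit override; default 2 ps).
#' @return A `Trajectory`.
#' @export
read_trajectory <- function(path, topology, timestep = 2) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is_dcd_file(path)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    nat <- ncol(xyz) %/% 3L
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    nat <- ncol(xyz) %/% 3L
  }
  if (nat != n_atoms(topology))
    stop(sprintf("atom count mismatch: trajectory has %d atoms, topology %d",
                 nat, n_atoms(topology)))
  new_trajectory(topology, xyz, timestep = timestep)
}

#' Write a trajectory as a CHARMM-flavour DCD file
#'
#' Minimal single-precision DCD writer (no unit cell, no fixed atoms),
#' readable by standard MD tools.  Note DCD stores float32, so coordinates
#' round-trip to about 1e-3 Angstrom relative precision.
#'
#' @param traj Trajectory.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  nf <- n_frames(traj); nat <- n_atoms(traj$topology)
  con <- file(path, "wb"); on.exit(close(con))
  icntrl <- integer(20)
  icntrl[1] <- nf          # NSET
  icntrl[2] <- 1L          # ISTART
  icntrl[3] <- 1L          # NSAVC
  icntrl[20] <- 24L        # CHARMM version stamp
  writeBin(84L, con, size = 4)
  writeBin(charToRaw("CORD"), con)
  writeBin(icntrl, con, size = 4)
  writeBin(84L, con, size = 4)
  title <- sprintf("%-80s", "written by stardynet")
  writeBin(4L + 80L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeBin(charToRaw(title), con)
  writeBin(4L + 80L, con, size = 4)
  writeBin(4L, con, size = 4)
  writeBin(nat, con, size = 4)
  writeBin(4L, con, size = 4)
  nb <- 4L * nat
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    for (ax in 1:3) {
      writeBin(nb, con, size = 4)
      writeBin(as.numeric(fr[, ax]), con, size = 4)
      writeBin(nb, con, size = 4)
    }
  }
  invisible(path)
}

#' Write a trajectory as a multi-MODEL PDB
#'
#' Text fallback for tools without DCD support.
#'
#' @param traj Trajectory.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$topology$atoms
  con <- file(path, "wt"); on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    nm <- ifelse(nchar(a$atom_name) < 4,
                 sprintf(" %-3s", a$atom_name), a$atom_name)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$atom_id + 1L, nm, a$residue_name, a$chain_id, a$residue_seq,
      fr[, 1], fr[, 2], fr[, 3], a$occupancy, a$bfactor, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
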