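## Essential dynamics: dynamic cross-correlation maps (DCCM) and principal
## component analysis of C-alpha (or node-anchor) fluctuations.

## Node labels for a set of atom rows: one-letter residue code + author
## number for protein C-alpha nodes ("R130"); "<res><seq>:base"/":sp" for
## nucleotide anchors; fall back to chain:resseq:atomname when ambiguous.
node_labels <- function(atoms) {
  lab <- character(nrow(atoms))
  for (k in seq_len(nrow(atoms))) {
    a <- atoms[k, ]
    if (a$atom_name == "CA") {
      code <- AA3TO1[a$residue_name]
      if (is.na(code)) code <- substr(a$residue_name, 1, 1)
      lab[k] <- paste0(code, a$residue_seq)
    } else if (a$atom_name == "P") {
      lab[k] <- paste0(a$residue_name, a$residue_seq, ":sp")
    } else if (a$atom_name %in% c("N1", "N9")) {
      lab[k] <- paste0(a$residue_name, a$residue_seq, ":base")
    } else {
      lab[k] <- paste(a$chain_id, a$residue_seq, a$atom_name, sep = ":")
    }
  }
  if (anyDuplicated(lab))
    lab <- paste(atoms$chain_id, lab, sep = ":")
  lab
}

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

## Pool frames from one Trajectory or a list of Trajectories over the
## column subset for the selected atoms.
pool_frames <- function(trajs, cols) {
  if (inherits(trajs, "Trajectory")) trajs <- list(trajs)
  do.call(rbind, lapply(trajs, function(tr) tr$xyz[, cols, drop = FALSE]))
}

#' Dynamic cross-correlation matrix
#'
#' Normalised cross-correlations of 3D node displacements,
#' C_ij = <dr_i . dr_j> / (<dr_i^2>^1/2 <dr_j^2>^1/2), with dr the
#' deviation from the mean position after an optional rigid-body fit of
#' every frame to the (iterated) average structure.  Full 3D dot products
#' are used, not per-axis correlations.  Values of |C_ij| >= 0.25 are
#' conventionally read as correlated/anti-correlated, the band in between
#' as weak.
#'
#' @param traj a `Trajectory` or list of Trajectories (frames pooled).
#' @param selection node atoms (e.g. C-alpha + nucleotide anchors);
#'   `NULL` = all atoms.
#' @param fit rigid-body fit frames to the average structure first
#'   (default TRUE; use FALSE when frames are already aligned).
#' @return Object of class `"CorrelationMatrix"`: the n x n matrix with
#'   node labels as dimnames.  Zero-variance nodes get diagonal 1,
#'   off-diagonals 0, with a warning.
#' @export
dccm <- function(traj, selection = NULL, fit = TRUE) {
  top <- if (inherits(traj, "Trajectory")) traj$topology
         else traj[[1]]$topology
  idx <- sel_index(selection, top)
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  X <- pool_frames(traj, cols)
  if (nrow(X) < 2L) stop("DCCM needs at least 2 frames")
  if (fit) X <- iterated_fit(X, seq_along(idx))$xyz
  Xc <- sweep(X, 2, colMeans(X))
  M <- crossprod(Xc) / nrow(Xc)
  m <- length(idx)
  xs <- seq(1L, 3L * m, by = 3L)
  D <- M[xs, xs] + M[xs + 1L, xs + 1L] + M[xs + 2L, xs + 2L]
  v <- diag(D)
  zero <- v <= .Machine$double.eps * max(v, 1)
  if (any(zero)) {
    warning(sprintf("%d zero-variance node(s); correlations set to 0", sum(zero)))
    v[zero] <- 1
  }
  C <- D / sqrt(outer(v, v))
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  labs <- node_labels(top$atoms[idx, , drop = FALSE])
  dimnames(C) <- list(labs, labs)
  class(C) <- c("CorrelationMatrix", class(C))
  C
}

#' Classify DCCM values into correlated / weak / anti-correlated bands
#'
#' @param C `CorrelationMatrix`.
#' @param band half-width of the weak band (default 0.25).
#' @return Character matrix: "positive", "weak" or "negative".
#' @export
dccm_classes <- function(C, band = 0.25) {
  cls <- matrix("weak", nrow(C), ncol(C), dimnames = dimnames(C))
  cls[unclass(C) >= band] <- "positive"
  cls[unclass(C) <= -band] <- "negative"
  cls
}

#' Principal component analysis of coordinate fluctuations
#'
#' Eigendecomposition of the 3n x 3n covariance of (optionally fitted)
#' selected coordinates, pooled over one or several trajectories.
#' Eigenvector signs are fixed by making each vector's largest-magnitude
#' component positive, so results are deterministic.
#'
#' @param traj `Trajectory` or list of Trajectories.
#' @param selection node atoms; `NULL` = all.
#' @param n_components number of components to report (default all).
#' @param fit rigid-body fit to the average first (default TRUE).
#' @return Object of class `"PcaResult"`: `eigenvalues` (Angstrom^2,
#'   descending, full spectrum), `eigenvectors` (3n x n_components,
#'   orthonormal), `mean` (n x 3), `projections` (frames x n_components,
#'   Angstrom), `trace` (total variance).
#' @export
pca_traj <- function(traj, selection = NULL, n_components = NULL,
                     fit = TRUE) {
  top <- if (inherits(traj, "Trajectory")) traj$topology
         else traj[[1]]$topology
  idx <- sel_index(selection, top)
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  X <- pool_frames(traj, cols)
  m3 <- 3L * length(idx)
  if (is.null(n_components)) n_components <- m3
  if (n_components > m3) stop("n_components exceeds 3 x n_atoms")
  if (nrow(X) <= 3L * length(idx))
    warning(sprintf("only %d frames for %d coordinates; covariance is rank-deficient",
                    nrow(X), m3))
  if (fit) X <- iterated_fit(X, seq_along(idx))$xyz
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / (nrow(Xc) - 1L)
  ev <- eigen(S, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  vecs <- ev$vectors[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(ncol(vecs))) {
    imax <- which.max(abs(vecs[, k]))
    if (vecs[imax, k] < 0) vecs[, k] <- -vecs[, k]
  }
  proj <- Xc %*% vecs
  structure(list(eigenvalues = vals,
                 eigenvectors = vecs,
                 mean = matrix(mu, ncol = 3, byrow = TRUE),
                 projections = proj,
                 trace = sum(diag(S)),
                 atom_ids = top$atoms$atom_id[idx]),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  k <- min(3L, length(x$eigenvalues))
  cat(sprintf("PcaResult: trace %.3f A^2; first %d modes explain %.1f%%\n",
              x$trace, k, 100 * sum(x$eigenvalues[seq_len(k)]) / tot))
  invisible(x)
}

#' Export a PCA mode as a multi-model PDB (mean +/- scaled displacement)
#'
#' Writes frames interpolating mean - scale*mode ... mean + scale*mode so
#' external viewers can animate the mode.
#'
#' @param pca `PcaResult`.
#' @param topology `Structure` the atom ids refer to.
#' @param mode mode index.
#' @param path output PDB path.
#' @param scale displacement amplitude, Angstrom.
#' @param n_steps frames in the sweep.
#' @return Invisibly, `path`.
#' @export
write_mode_pdb <- function(pca, topology, mode, path, scale = 3,
                           n_steps = 7L) {
  idx <- match(pca$atom_ids, topology$atoms$atom_id)
  sub <- topology$atoms[idx, , drop = FALSE]
  substr_struct <- new_structure(sub[, c("atom_name", "residue_seq",
                                         "residue_name", "chain_id",
                                         "element", "bfactor",
                                         "occupancy", "mass")],
                                 pca$mean)
  v <- pca$eigenvectors[, mode]
  amps <- seq(-scale, scale, length.out = n_steps)
  xyz <- t(vapply(amps, function(a) as.vector(t(pca$mean)) + a * v,
                  numeric(length(v))))
  write_trajectory_pdb(new_trajectory(substr_struct, xyz, timestep = 1), path)
}
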