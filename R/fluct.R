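## Superposition and deviation/fluctuation statistics:
## Kabsch rigid-body fit, RMSD time series, per-atom RMSF, the Debye-Waller
## B-factor <-> RMSF conversion, and running-average convergence (RAC).

## Optimal proper rotation R and translation mapping mobile onto reference
## (both m x 3, same atom order): aligned = mobile %*% t(R) + t.
kabsch <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cr - as.vector(R %*% cm)
  aligned <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' selected atoms of a mobile and a reference frame.  Reflections are never
#' returned: a mirror-image cannot be superposed to zero RMSD.
#'
#' @param mobile,reference n x 3 coordinate matrices (or `Structure`s).
#' @param selection optional `AtomSelection` (or 0-based ids) naming the
#'   atoms the fit is computed on; default all atoms.
#' @return List of class `"SuperposeResult"`: `rotation` (3 x 3,
#'   det = +1), `translation` (length 3), `rmsd` (Angstrom), and the fully
#'   transformed `coords` of the mobile input.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mxyz <- if (inherits(mobile, "Structure")) mobile$xyz else as.matrix(mobile)
  rxyz <- if (inherits(reference, "Structure")) reference$xyz else as.matrix(reference)
  if (!all(dim(mxyz) == dim(rxyz)))
    stop("mobile and reference must have the same dimensions")
  idx <- if (is.null(selection)) seq_len(nrow(mxyz))
         else {
           ids <- if (inherits(selection, "AtomSelection")) selection$ids
                  else as.integer(selection)
           ids + 1L
         }
  sm <- mxyz[idx, , drop = FALSE]; sr <- rxyz[idx, , drop = FALSE]
  if (nrow(sm) < 3L) stop("superposition needs at least 3 atoms")
  if (qr(sweep(sm, 2, colMeans(sm)))$rank < 2L)
    stop("selected atoms are collinear; rotation is not determined")
  k <- kabsch(sm, sr)
  coords <- sweep(mxyz %*% t(k$rotation), 2, k$translation, `+`)
  structure(list(rotation = k$rotation, translation = k$translation,
                 rmsd = k$rmsd, coords = coords),
            class = "SuperposeResult")
}

#' @export
print.SuperposeResult <- function(x, ...) {
  cat(sprintf("SuperposeResult: rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

## RMSD between two frames over given 1-based row indices, no fitting.
raw_rmsd <- function(a, b, idx) {
  sqrt(mean(rowSums((a[idx, , drop = FALSE] - b[idx, , drop = FALSE])^2)))
}

## Fit every frame of an F x 3n coordinate matrix onto ref (n x 3) using
## fit_idx (1-based atom rows); returns the fitted F x 3n matrix.
fit_frame_matrix <- function(xyz, ref, fit_idx) {
  out <- xyz
  refsel <- ref[fit_idx, , drop = FALSE]
  for (f in seq_len(nrow(xyz))) {
    fr <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    k <- kabsch(fr[fit_idx, , drop = FALSE], refsel)
    out[f, ] <- as.vector(t(sweep(fr %*% t(k$rotation), 2,
                                  k$translation, `+`)))
  }
  out
}

## Iterated fit -> average -> refit (n_pass passes); returns list with the
## fitted frame matrix and the final average frame (n x 3).
iterated_fit <- function(xyz, fit_idx, n_pass = 2L) {
  ref <- matrix(xyz[1L, ], ncol = 3, byrow = TRUE)
  fitted <- xyz
  for (p in seq_len(n_pass)) {
    fitted <- fit_frame_matrix(xyz, ref, fit_idx)
    ref <- matrix(colMeans(fitted), ncol = 3, byrow = TRUE)
  }
  list(xyz = fitted, mean = ref)
}

#' Per-frame RMSD time series
#'
#' Each frame is rigid-body fitted to the reference on `fit_sel`, then the
#' RMSD is evaluated on `calc_sel` (so e.g. a domain RMSD after a whole-
#' molecule fit is a matter of choosing `calc_sel`).
#'
#' @param traj Trajectory.
#' @param reference n x 3 matrix or `Structure` (e.g. the crystal).
#' @param fit_sel,calc_sel `AtomSelection`s; `calc_sel` defaults to
#'   `fit_sel`; `NULL` means all atoms.
#' @return data.frame with `frame`, `time_ps`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference, fit_sel = NULL, calc_sel = fit_sel) {
  rxyz <- if (inherits(reference, "Structure")) reference$xyz
          else as.matrix(reference)
  fit_idx <- sel_index(fit_sel, traj$topology)
  calc_idx <- sel_index(calc_sel, traj$topology)
  nf <- n_frames(traj)
  out <- numeric(nf)
  refsel <- rxyz[fit_idx, , drop = FALSE]
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    k <- kabsch(fr[fit_idx, , drop = FALSE], refsel)
    al <- sweep(fr %*% t(k$rotation), 2, k$translation, `+`)
    out[f] <- raw_rmsd(al, rxyz, calc_idx)
  }
  data.frame(frame = seq_len(nf),
             time_ps = (seq_len(nf) - 1L) * traj$timestep,
             rmsd = out)
}

#' Per-atom RMSF profile
#'
#' Frames are fitted to the trajectory-average structure with a two-pass
#' iterated fit (fit to a provisional reference, re-average, refit), then
#' RMSF_i = sqrt(<|r_i - <r_i>|^2>).  Optionally fit to an external
#' reference (e.g. the crystal structure) instead.
#'
#' @param traj Trajectory.
#' @param fit_sel,calc_sel selections for the fit and for the reported
#'   atoms (`calc_sel` defaults to `fit_sel`; `NULL` = all).
#' @param reference optional n x 3 matrix / `Structure`; if given, frames
#'   are fitted to it instead of the iterated average.
#' @return data.frame with `atom_id`, `atom_name`, `residue_seq`,
#'   `chain_id`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(traj, fit_sel = NULL, calc_sel = fit_sel,
                         reference = NULL) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  fit_idx <- sel_index(fit_sel, traj$topology)
  calc_idx <- sel_index(calc_sel, traj$topology)
  if (is.null(reference)) {
    fitted <- iterated_fit(traj$xyz, fit_idx)$xyz
  } else {
    rxyz <- if (inherits(reference, "Structure")) reference$xyz
            else as.matrix(reference)
    fitted <- fit_frame_matrix(traj$xyz, rxyz, fit_idx)
  }
  mu <- colMeans(fitted)
  dev2 <- sweep(fitted, 2, mu)^2
  percoord <- colMeans(dev2)                       # length 3n
  peratom <- percoord[c(TRUE, FALSE, FALSE)] +
             percoord[c(FALSE, TRUE, FALSE)] +
             percoord[c(FALSE, FALSE, TRUE)]
  a <- traj$topology$atoms[calc_idx, , drop = FALSE]
  data.frame(atom_id = a$atom_id, atom_name = a$atom_name,
             residue_seq = a$residue_seq, chain_id = a$chain_id,
             rmsf = sqrt(peratom[calc_idx]))
}

#' Debye-Waller conversion between B-factor and RMSF
#'
#' RMSF = sqrt(3 B / (8 pi^2)); the inverse is B = 8 pi^2 RMSF^2 / 3.
#'
#' @param b B-factor(s), Angstrom^2 (non-negative).
#' @return RMSF in Angstrom.
#' @export
bfactor_to_rmsf <- function(b) {
  if (any(b < 0)) stop("B-factors must be non-negative")
  sqrt(3 * b / (8 * pi^2))
}

#' @rdname bfactor_to_rmsf
#' @param rmsf fluctuation amplitude(s), Angstrom (non-negative).
#' @export
rmsf_to_bfactor <- function(rmsf) {
  if (any(rmsf < 0)) stop("RMSF must be non-negative")
  8 * pi^2 * rmsf^2 / 3
}

#' Running-average convergence curve (RAC)
#'
#' For each window length w, running-average structures are computed over
#' all contiguous windows of w frames (frames first fitted to the global
#' average), each running average is RMS-fitted to the global average
#' structure, and RAC(w) is the mean of those RMSDs.  RAC at the full
#' trajectory length is exactly zero; on a stationary ensemble the curve
#' decays towards zero (slope -> 0 signals convergence).
#'
#' @param traj Trajectory.
#' @param selection atoms the averages and fits use (`NULL` = all).
#' @param window_lengths integer vector of window sizes, frames.
#' @param stride offset step between successive windows (1 = dense).
#' @return data.frame of class `"RacCurve"` with `window_frames`,
#'   `window_ps`, `rac` (Angstrom).
#' @export
rac_curve <- function(traj, selection = NULL, window_lengths,
                      stride = 1L) {
  idx <- sel_index(selection, traj$topology)
  nf <- n_frames(traj)
  window_lengths <- as.integer(window_lengths)
  if (any(window_lengths < 1L)) stop("window lengths must be >= 1 frame")
  if (any(window_lengths > nf)) stop("window length exceeds trajectory")
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  sub <- traj$xyz[, cols, drop = FALSE]
  fitres <- iterated_fit(sub, seq_along(idx))
  X <- fitres$xyz
  gmean <- fitres$mean
  cs <- apply(X, 2, cumsum)
  cs <- rbind(0, cs)
  m <- length(idx)
  rac <- vapply(window_lengths, function(w) {
    starts <- seq(1L, nf - w + 1L, by = stride)
    vals <- vapply(starts, function(s) {
      avg <- (cs[s + w, ] - cs[s, ]) / w
      kabsch(matrix(avg, ncol = 3, byrow = TRUE), gmean)$rmsd
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  out <- data.frame(window_frames = window_lengths,
                    window_ps = window_lengths * traj$timestep,
                    rac = rac)
  class(out) <- c("RacCurve", class(out))
  out
}
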