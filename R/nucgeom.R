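## RNA backbone geometry: torsion angles, sugar pseudorotation
## (phase/amplitude + conformer class) and eta/theta pseudo-torsions.

#' Signed dihedral angle of four points
#'
#' Standard atan2 construction with the IUPAC right-handed sign
#' convention; result in (-180, 180] degrees.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors, Angstrom.
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-10 || sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16)
    stop("dihedral undefined: collinear or coincident points")
  m1 <- cross(n1, b2 / nb2)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

PUCKER_CLASSES <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo",
                    "C2'-endo", "C3'-exo", "C4'-endo", "O4'-exo",
                    "C1'-endo", "C2'-exo")

#' Pseudorotation phase/amplitude from five ring torsions
#'
#' Inverts nu_j = tau_m cos(P + 144 (j - 2)) (the nu2-based
#' Altona-Sundaralingam convention) by exact least-squares projection,
#' which is numerically stable for all phases (including P near 90
#' degrees, where the textbook tau_m = nu2 / cos P form is singular).
#' The conformer class is the 36-degree pseudorotation-wheel sector of P
#' (C3'-endo = \[0, 36), O4'-endo = \[72, 108), C2'-endo = \[144, 180),
#' ...).  Amplitudes below 1e-3 degrees leave the class undefined.
#'
#' @param nu numeric vector of the five endocyclic torsions nu0..nu4,
#'   degrees.
#' @return Object of class `"PuckerRecord"`: list with `phase_P`
#'   (degrees, \[0, 360)), `amplitude_tau_m` (degrees), `pucker_class`
#'   (NA when undefined).
#' @export
pucker_from_torsions <- function(nu) {
  if (length(nu) != 5L || any(!is.finite(nu)))
    stop("need five finite torsions nu0..nu4")
  th <- (144 * ((0:4) - 2)) * pi / 180
  A <- (2 / 5) * sum(nu * cos(th))   # tau_m cos P
  B <- -(2 / 5) * sum(nu * sin(th))  # tau_m sin P
  tau <- sqrt(A^2 + B^2)
  P <- atan2(B, A) * 180 / pi
  if (P < 0) P <- P + 360
  cls <- if (tau < 1e-3) NA_character_
         else PUCKER_CLASSES[floor(P / 36) %% 10 + 1L]
  structure(list(phase_P = P, amplitude_tau_m = tau, pucker_class = cls),
            class = "PuckerRecord")
}

#' @export
print.PuckerRecord <- function(x, ...) {
  cat(sprintf("Pucker: P = %.2f deg, tau_m = %.2f deg, %s\n",
              x$phase_P, x$amplitude_tau_m,
              ifelse(is.na(x$pucker_class), "class undefined",
                     x$pucker_class)))
  invisible(x)
}

RING_ATOMS <- c("O4'", "C1'", "C2'", "C3'", "C4'")

## the five endocyclic torsions measured around the furanose ring
ring_torsions <- function(xyz_by_name) {
  g <- function(n) xyz_by_name[[n]]
  c(nu0 = dihedral(g("C4'"), g("O4'"), g("C1'"), g("C2'")),
    nu1 = dihedral(g("O4'"), g("C1'"), g("C2'"), g("C3'")),
    nu2 = dihedral(g("C1'"), g("C2'"), g("C3'"), g("C4'")),
    nu3 = dihedral(g("C2'"), g("C3'"), g("C4'"), g("O4'")),
    nu4 = dihedral(g("C3'"), g("C4'"), g("O4'"), g("C1'")))
}

#' Sugar pucker for every nucleotide of a chain
#'
#' Measures nu0..nu4 over the O4'-C1'-C2'-C3'-C4' ring and classifies via
#' [pucker_from_torsions()].  Residues missing a ring atom are skipped
#' with a warning naming the residue.
#'
#' @param structure `Structure`.
#' @param chain chain id holding the nucleotides.
#' @param coords optional n x 3 matrix overriding the structure
#'   coordinates (e.g. one trajectory frame).
#' @return data.frame: `residue_seq`, `residue_name`, `phase_P`,
#'   `amplitude_tau_m`, `pucker_class`.
#' @export
pucker_from_structure <- function(structure, chain, coords = NULL) {
  a <- structure$atoms
  X <- if (is.null(coords)) structure$xyz else as.matrix(coords)
  rows <- which(a$chain_id == chain)
  if (!length(rows)) stop("no atoms on chain ", chain)
  out <- NULL
  for (rs in unique(a$residue_seq[rows])) {
    rr <- rows[a$residue_seq[rows] == rs]
    nm <- a$atom_name[rr]
    if (!all(RING_ATOMS %in% nm)) {
      warning(sprintf("residue %s %d: missing ring atom(s) %s; skipped",
                      a$residue_name[rr[1]], rs,
                      paste(setdiff(RING_ATOMS, nm), collapse = ",")))
      next
    }
    xyzs <- lapply(RING_ATOMS, function(n) X[rr[nm == n][1], ])
    names(xyzs) <- RING_ATOMS
    pk <- pucker_from_torsions(ring_torsions(xyzs))
    out <- rbind(out, data.frame(residue_seq = rs,
                                 residue_name = a$residue_name[rr[1]],
                                 phase_P = pk$phase_P,
                                 amplitude_tau_m = pk$amplitude_tau_m,
                                 pucker_class = pk$pucker_class,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Eta/theta pseudo-torsions of a nucleic chain
#'
#' Coarse-grained backbone torsions over the P/C4' virtual bonds:
#' eta(i) = C4'(i-1)-P(i)-C4'(i)-P(i+1) and
#' theta(i) = P(i)-C4'(i)-P(i+1)-C4'(i+1).  Chain termini lacking the
#' flanking atoms are reported with NA (flagged, never zero-filled).
#'
#' @param structure `Structure`.
#' @param chain chain id.
#' @param coords optional n x 3 coordinate override (one frame).
#' @return data.frame: `residue_seq`, `residue_name`, `eta`, `theta`
#'   (degrees in (-180, 180\]).
#' @export
pseudo_torsions <- function(structure, chain, coords = NULL) {
  a <- structure$atoms
  X <- if (is.null(coords)) structure$xyz else as.matrix(coords)
  rows <- which(a$chain_id == chain)
  resseq <- sort(unique(a$residue_seq[rows]))
  if (length(resseq) < 3L)
    stop("eta/theta need a chain of at least 3 nucleotides")
  getxyz <- function(rs, name) {
    rr <- rows[a$residue_seq[rows] == rs & a$atom_name[rows] == name]
    if (!length(rr)) NULL else X[rr[1], ]
  }
  n <- length(resseq)
  out <- data.frame(residue_seq = resseq,
                    residue_name = vapply(resseq, function(rs)
                      a$residue_name[rows[a$residue_seq[rows] == rs][1]],
                      character(1)),
                    eta = NA_real_, theta = NA_real_)
  for (i in seq_len(n)) {
    rs <- resseq[i]
    P0 <- getxyz(rs, "P"); C0 <- getxyz(rs, "C4'")
    if (i > 1L && i < n) {
      Cm <- getxyz(resseq[i - 1L], "C4'")
      P1 <- getxyz(resseq[i + 1L], "P")
      if (!is.null(Cm) && !is.null(P0) && !is.null(C0) && !is.null(P1))
        out$eta[i] <- dihedral(Cm, P0, C0, P1)
    }
    if (i < n) {
      P1 <- getxyz(resseq[i + 1L], "P")
      C1 <- getxyz(resseq[i + 1L], "C4'")
      if (!is.null(P0) && !is.null(C0) && !is.null(P1) && !is.null(C1))
        out$theta[i] <- dihedral(P0, C0, P1, C1)
    }
  }
  out
}

#' Pseudo-torsion time series over a trajectory
#'
#' Applies [pseudo_torsions()] frame by frame, producing dial-plot-ready
#' per-residue time series.
#'
#' @param traj Trajectory.
#' @param chain chain id.
#' @return data.frame: `frame`, `residue_seq`, `eta`, `theta`.
#' @export
pseudo_torsion_series <- function(traj, chain) {
  out <- NULL
  for (f in seq_len(n_frames(traj))) {
    pt <- pseudo_torsions(traj$topology, chain,
                          coords = frame_coords(traj, f))
    out <- rbind(out, cbind(frame = f, pt[, c("residue_seq", "eta",
                                              "theta")]))
  }
  out
}
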