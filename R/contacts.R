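## Contact analysis: native-contact sets and Q/Qs metrics, raw contact
## counts, protein-RNA interface occupancy, and Shrake-Rupley SASA.
##
## All distance criteria are closed intervals (<= cutoff).

#' Native-contact set from a reference structure
#'
#' A native contact is an atom pair of the selection (typically C-alpha
#' atoms) whose residues are separated by more than `exclusion` positions
#' in sequence and whose reference distance is within `cutoff` (default
#' 8 Angstrom, excluding the two adjacent neighbours on either side).
#' Pairs on different chains are never sequence-excluded.
#'
#' @param reference `Structure` (e.g. the crystal structure).
#' @param selection `AtomSelection` or 0-based ids (`NULL` = all atoms).
#' @param cutoff contact distance, Angstrom (> 0); closed (<=).
#' @param exclusion minimum residue separation (pairs with
#'   |i - j| <= exclusion are skipped).
#' @return Object of class `"NativeContactSet"`: data.frame `pairs`
#'   (`i`, `j` 0-based atom ids, `native_distance`, `sep`) plus `cutoff`
#'   and `exclusion`.
#' @export
native_contacts <- function(reference, selection = NULL, cutoff = 8,
                            exclusion = 2L) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  idx <- sel_index(selection, reference)
  a <- reference$atoms[idx, , drop = FALSE]
  X <- reference$xyz[idx, , drop = FALSE]
  m <- length(idx)
  if (m < 2L) stop("selection must contain at least 2 atoms")
  D <- as.matrix(stats::dist(X))
  sep <- abs(outer(a$residue_seq, a$residue_seq, `-`))
  diffchain <- outer(a$chain_id, a$chain_id, `!=`)
  sep[diffchain] <- .Machine$integer.max
  keep <- upper.tri(D) & D <= cutoff + 1e-12 & sep > exclusion
  ij <- which(keep, arr.ind = TRUE)
  pairs <- data.frame(i = a$atom_id[ij[, 1]], j = a$atom_id[ij[, 2]],
                      native_distance = D[keep],
                      sep = ifelse(diffchain[keep], NA_integer_, sep[keep]))
  structure(list(pairs = pairs, cutoff = cutoff, exclusion = exclusion),
            class = "NativeContactSet")
}

#' @export
print.NativeContactSet <- function(x, ...) {
  cat(sprintf("NativeContactSet: %d pairs, cutoff %.2f A, exclusion %d\n",
              nrow(x$pairs), x$cutoff, x$exclusion))
  invisible(x)
}

## F x P matrix of distances for atom-id pairs (ai, aj) over all frames
pair_dist_matrix <- function(traj, ai, aj) {
  ci <- 3L * (ai + 1L); cj <- 3L * (aj + 1L)
  dx <- traj$xyz[, ci - 2L, drop = FALSE] - traj$xyz[, cj - 2L, drop = FALSE]
  dy <- traj$xyz[, ci - 1L, drop = FALSE] - traj$xyz[, cj - 1L, drop = FALSE]
  dz <- traj$xyz[, ci, drop = FALSE] - traj$xyz[, cj, drop = FALSE]
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Per-frame native-contact fraction Q and similarity Qs
#'
#' Q is the fraction of native pairs within the native cutoff in a frame.
#' Qs replaces the sharp count by a Gaussian penalty on the deviation from
#' the native distance: Qs = mean over pairs of
#' exp(-(r - r0)^2 / (2 sigma^2)), with a residue-separation-dependent
#' width sigma_ij = (1 + |i - j|)^0.15 Angstrom by default (cross-chain
#' pairs use the largest separation present).
#'
#' @param traj Trajectory.
#' @param native `NativeContactSet` from [native_contacts()].
#' @param sigma_fn width model: function of the residue separation,
#'   returning Angstrom.
#' @return data.frame: `frame`, `time_ps`, `q`, `qs` (both in \[0, 1\]).
#' @export
q_series <- function(traj, native, sigma_fn = function(sep) (1 + sep)^0.15) {
  p <- native$pairs
  if (!nrow(p)) stop("native contact set is empty")
  sep <- p$sep
  if (anyNA(sep)) sep[is.na(sep)] <- max(c(sep[!is.na(sep)], 1L))
  sig <- sigma_fn(sep)
  D <- pair_dist_matrix(traj, p$i, p$j)
  q <- rowMeans(D <= native$cutoff + 1e-12)
  dev <- sweep(D, 2, p$native_distance)
  qs <- rowMeans(exp(-sweep(dev^2, 2, 2 * sig^2, `/`)))
  data.frame(frame = seq_len(n_frames(traj)),
             time_ps = (seq_len(n_frames(traj)) - 1L) * traj$timestep,
             q = q, qs = qs)
}

#' Per-frame contact counts between two selections
#'
#' Counts atom pairs (one from each selection; each unordered pair once
#' when the selections overlap) within `cutoff` in each frame, skipping
#' pairs within `exclusion` residues on the same chain.  With both
#' selections equal this gives intra-domain counts; with disjoint domain
#' selections, inter-domain counts.
#'
#' @param traj Trajectory.
#' @param selection_a,selection_b `AtomSelection`s or 0-based ids.
#' @param cutoff Angstrom, closed.
#' @param exclusion minimum residue separation on the same chain.
#' @return data.frame: `frame`, `time_ps`, `count`.
#' @export
contact_count_series <- function(traj, selection_a, selection_b,
                                 cutoff = 6, exclusion = 2L) {
  top <- traj$topology
  ia <- sel_index(selection_a, top); ib <- sel_index(selection_b, top)
  if (!length(ia) || !length(ib)) stop("selections must be non-empty")
  g <- expand.grid(a = ia, b = ib)
  g <- g[g$a != g$b, , drop = FALSE]
  overlap <- length(intersect(ia, ib)) > 0
  if (overlap) {
    key <- paste(pmin(g$a, g$b), pmax(g$a, g$b))
    g <- g[!duplicated(key), , drop = FALSE]
  }
  at <- top$atoms
  same <- at$chain_id[g$a] == at$chain_id[g$b]
  sep <- abs(at$residue_seq[g$a] - at$residue_seq[g$b])
  g <- g[!(same & sep <= exclusion), , drop = FALSE]
  if (!nrow(g)) {
    return(data.frame(frame = seq_len(n_frames(traj)),
                      time_ps = (seq_len(n_frames(traj)) - 1L) * traj$timestep,
                      count = 0L))
  }
  D <- pair_dist_matrix(traj, at$atom_id[g$a], at$atom_id[g$b])
  data.frame(frame = seq_len(n_frames(traj)),
             time_ps = (seq_len(n_frames(traj)) - 1L) * traj$timestep,
             count = as.integer(rowSums(D <= cutoff + 1e-12)))
}

#' Interface-contact occupancy over a trajectory
#'
#' A labelled pair of atom groups is "present" in a frame if any
#' cross-group atom distance is within `cutoff`; its occupancy is the
#' fraction of frames present, flagged when it reaches `threshold`
#' (default 75%, the criterion used for dynamical-network edges).
#'
#' @param traj Trajectory.
#' @param pairs named list; each element a list with 0-based id vectors
#'   `a` and `b` (or `AtomSelection`s).  Names are the pair labels
#'   (e.g. `"U6-Q193"`).
#' @param cutoff Angstrom, closed.
#' @param threshold flagging occupancy (closed, >=).
#' @return Object of class `"OccupancyTable"`: data.frame with `label`,
#'   `occupancy`, `flagged`; the per-frame presence matrix is attached as
#'   attribute `"presence"` (frames x pairs).
#' @export
interface_occupancy <- function(traj, pairs, cutoff = 4.5,
                                threshold = 0.75) {
  top <- traj$topology
  labs <- names(pairs)
  if (is.null(labs) || any(!nzchar(labs))) stop("pairs must be named")
  nf <- n_frames(traj)
  pres <- matrix(FALSE, nf, length(pairs),
                 dimnames = list(NULL, labs))
  for (k in seq_along(pairs)) {
    ia <- sel_index(pairs[[k]]$a, top); ib <- sel_index(pairs[[k]]$b, top)
    if (!length(ia) || !length(ib))
      stop(sprintf("pair '%s' resolves to an empty group", labs[k]))
    g <- expand.grid(a = ia, b = ib)
    D <- pair_dist_matrix(traj, top$atoms$atom_id[g$a],
                          top$atoms$atom_id[g$b])
    pres[, k] <- apply(D <= cutoff + 1e-12, 1, any)
  }
  occ <- colMeans(pres)
  out <- data.frame(label = labs, occupancy = occ,
                    flagged = occ >= threshold, row.names = NULL)
  attr(out, "presence") <- pres
  class(out) <- c("OccupancyTable", class(out))
  out
}

## Default van der Waals radii by element, Angstrom.
DEFAULT_VDW <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, H = 1.20)

## Deterministic, nearly uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA: each atom is covered with `n_points` test points
#' at radius r_atom + probe; points buried inside any neighbour's expanded
#' sphere are discarded; the accessible fraction scales the expanded-sphere
#' area.  Per-residue SASA is the sum over the residue's atoms.
#'
#' @param structure `Structure`.
#' @param probe_radius solvent probe radius, Angstrom (water: 1.4).
#' @param n_points test points per atom (>= 100; 960 gives ~1% accuracy).
#' @param radii named vector of per-element radii, Angstrom.
#' @return List with `atom` (data.frame: atom_id, sasa) and `residue`
#'   (data.frame: chain_id, residue_seq, residue_name, sasa), Angstrom^2.
#' @export
sasa <- function(structure, probe_radius = 1.4, n_points = 960L,
                 radii = DEFAULT_VDW) {
  if (n_points < 100L) stop("n_points must be >= 100")
  a <- structure$atoms
  r <- radii[a$element]
  if (anyNA(r))
    stop("no radius configured for element of atom id ",
         a$atom_id[which(is.na(r))[1]])
  r <- unname(r) + probe_radius
  X <- structure$xyz
  n <- nrow(X)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  D <- as.matrix(stats::dist(X))
  for (i in seq_len(n)) {
    nb <- setdiff(which(D[i, ] <= r[i] + r), i)
    p <- sweep(pts * r[i], 2, X[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- (p[, 1] - X[j, 1])^2 + (p[, 2] - X[j, 2])^2 +
            (p[, 3] - X[j, 3])^2
      acc <- acc & d2 > r[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  atom <- data.frame(atom_id = a$atom_id, sasa = area)
  key <- paste(a$chain_id, a$residue_seq)
  resi <- !duplicated(key)
  residue <- data.frame(chain_id = a$chain_id[resi],
                        residue_seq = a$residue_seq[resi],
                        residue_name = a$residue_name[resi],
                        sasa = as.numeric(tapply(area, factor(key, levels = key[resi]), sum)))
  list(atom = atom, residue = residue)
}
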