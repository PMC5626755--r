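## Shared fixtures and independent oracles for the test suite.

## Bare C-alpha chain structure at given coordinates.
ca_structure <- function(xyz, residue_seq = seq_len(nrow(xyz)),
                         chain_id = "A", resname = "GLY") {
  new_structure(data.frame(atom_name = "CA", residue_seq = residue_seq,
                           residue_name = resname, chain_id = chain_id,
                           stringsAsFactors = FALSE),
                xyz)
}

## Trajectory from a list of n x 3 frames.
traj_from_frames <- function(topology, frames, timestep = 2) {
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  new_trajectory(topology, xyz, timestep = timestep)
}

## Independent dihedral oracle: projection construction with acos
## magnitude and triple-product sign (different algebra from the
## package's atan2 form).
oracle_dihedral <- function(p1, p2, p3, p4) {
  u <- p1 - p2; v <- p3 - p2; w <- p4 - p3
  nv <- v / sqrt(sum(v^2))
  a <- u - sum(u * nv) * nv
  b <- w - sum(w * nv) * nv
  cosang <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  cosang <- min(1, max(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  triple <- sum(nv * c(a[2] * b[3] - a[3] * b[2],
                       a[3] * b[1] - a[1] * b[3],
                       a[1] * b[2] - a[2] * b[1]))
  if (triple < 0) ang else -ang
}

## Random proper rotation matrix.
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

## Rand index between two partitions.
rand_index <- function(a, b) {
  n <- length(a); agree <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / choose(n, 2)
}

## Minimal DynamicalNetwork straight from an edge table (for graph-
## algorithm tests that need no trajectory).
graph_network <- function(n, edges) {
  nodes <- data.frame(node = seq_len(n) - 1L,
                      label = sprintf("N%02d", seq_len(n)),
                      kind = "residue", anchor_id = seq_len(n) - 1L,
                      chain_id = "A", residue_seq = seq_len(n) * 10L,
                      stringsAsFactors = FALSE)
  nodes$atom_ids <- as.list(seq_len(n) - 1L)
  edges$occupancy <- edges$occupancy %||% 1
  edges$correlation <- edges$correlation %||% exp(-edges$weight)
  structure(list(nodes = nodes, edges = edges, occupancy_cutoff = 0.75,
                 distance_cutoff = 4.5, weight_scheme = "minus_log"),
            class = "DynamicalNetwork")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Planted two-block random graph as a DynamicalNetwork (unit weights).
block_network <- function(seed, n_per_block = 10L, p_in = 0.9,
                          p_out = 0.05) {
  set.seed(seed)
  n <- 2L * n_per_block
  block <- rep(0:1, each = n_per_block)
  e <- NULL
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    p <- if (block[i] == block[j]) p_in else p_out
    if (runif(1) < p)
      e <- rbind(e, data.frame(i = i - 1L, j = j - 1L, weight = 1))
  }
  list(net = graph_network(n, e), truth = block)
}

## Pentagon ring with out-of-plane displacements giving a prescribed
## measured pseudorotation phase (synthetic ribose-ring stand-in; the
## construction phase maps to the measured phase with a +90 degree
## offset, verified by the round-trip tests themselves).
synthetic_ribose_ring <- function(target_P, q = 0.4, r = 1.2) {
  m <- 0:4
  ang <- 2 * pi * m / 5
  z <- sqrt(2 / 5) * q * cos((target_P - 90) * pi / 180 + 4 * pi * m / 5)
  xyz <- cbind(r * cos(ang), r * sin(ang), z)
  rownames(xyz) <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  xyz
}

## Structure holding one synthetic ribose ring (plus optional extra
## atoms) for pucker_from_structure.
ribose_structure <- function(target_P, chain = "R", resseq = 1L,
                             drop_atom = NULL) {
  ring <- synthetic_ribose_ring(target_P)
  nm <- rownames(ring)
  if (!is.null(drop_atom)) {
    keep <- nm != drop_atom
    ring <- ring[keep, , drop = FALSE]; nm <- nm[keep]
  }
  new_structure(data.frame(atom_name = nm, residue_seq = resseq,
                           residue_name = "U", chain_id = chain,
                           stringsAsFactors = FALSE),
                ring)
}

## Place a fourth point at given bond length, angle (deg) and dihedral
## (deg) from three predecessors (natural extension reference frame).
place_atom <- function(a, b, c, length, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-length * cos(ang),
         length * sin(ang) * cos(dih),
         -length * sin(ang) * sin(dih))
  c + d[1] * bc + d[2] * m + d[3] * n
}
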