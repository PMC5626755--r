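## Correlation-weighted dynamical network analysis.
##
## Nodes: one per protein residue (C-alpha anchor) and two per nucleotide
## (base anchored at N1/N9, sugar-phosphate anchored at P).  An edge joins
## two non-neighbouring nodes whose heavy-atom groups are within the
## distance cutoff for at least the occupancy threshold of frames; its
## length is w = -log |C_ij| so that strong correlation = short distance.

BASE_ATOMS <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9",
                "O2", "O4", "O6", "N2", "N4", "N6", "C5M")
SUGAR_PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "O1P", "O2P", "O5'", "C5'",
                           "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'")
PURINES <- c("A", "G", "ADE", "GUA", "DA", "DG", "RA", "RG", "I")

#' Define network nodes for a protein-nucleic topology
#'
#' Protein residues (those with a C-alpha atom and a non-nucleic residue
#' name) contribute one node each; nucleotides contribute a base node
#' (anchor N1 for pyrimidines, N9 for purines) and a sugar-phosphate node
#' (anchor P).  Each node owns the heavy atoms of its component, used for
#' the contact criterion; the anchor defines its position/correlation row.
#'
#' @param topology `Structure`.
#' @return data.frame: `node` (0-based), `label`, `kind`
#'   (residue/base/sugar_phosphate), `anchor_id` (0-based atom id),
#'   `chain_id`, `residue_seq`, plus list-column `atom_ids`.
#' @export
define_network_nodes <- function(topology) {
  a <- topology$atoms
  is_nuc <- a$residue_name %in% NUCLEIC_RESNAMES
  key <- paste(a$chain_id, a$residue_seq)
  nodes <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    ra <- a[rows, , drop = FALSE]
    if (!is_nuc[rows[1]]) {
      ca <- rows[ra$atom_name == "CA"]
      if (!length(ca))
        stop(sprintf("residue %s %d (chain %s) has no C-alpha anchor",
                     ra$residue_name[1], ra$residue_seq[1], ra$chain_id[1]))
      nodes[[length(nodes) + 1L]] <- list(
        kind = "residue", anchor_id = a$atom_id[ca[1]],
        chain_id = ra$chain_id[1], residue_seq = ra$residue_seq[1],
        resname = ra$residue_name[1],
        atom_ids = a$atom_id[rows][ra$element != "H"])
    } else {
      anchor_name <- if (ra$residue_name[1] %in% PURINES) "N9" else "N1"
      brows <- rows[ra$atom_name %in% BASE_ATOMS]
      srows <- rows[ra$atom_name %in% SUGAR_PHOSPHATE_ATOMS]
      banchor <- rows[ra$atom_name == anchor_name]
      sanchor <- rows[ra$atom_name == "P"]
      if (!length(banchor))
        stop(sprintf("nucleotide %s %d has no %s anchor",
                     ra$residue_name[1], ra$residue_seq[1], anchor_name))
      if (!length(sanchor))
        stop(sprintf("nucleotide %s %d has no P anchor",
                     ra$residue_name[1], ra$residue_seq[1]))
      nodes[[length(nodes) + 1L]] <- list(
        kind = "base", anchor_id = a$atom_id[banchor[1]],
        chain_id = ra$chain_id[1], residue_seq = ra$residue_seq[1],
        resname = ra$residue_name[1],
        atom_ids = a$atom_id[brows])
      nodes[[length(nodes) + 1L]] <- list(
        kind = "sugar_phosphate", anchor_id = a$atom_id[sanchor[1]],
        chain_id = ra$chain_id[1], residue_seq = ra$residue_seq[1],
        resname = ra$residue_name[1],
        atom_ids = a$atom_id[srows])
    }
  }
  lab <- vapply(nodes, function(n) {
    if (n$kind == "residue") {
      code <- AA3TO1[n$resname]
      if (is.na(code)) code <- substr(n$resname, 1, 1)
      paste0(code, n$residue_seq)
    } else paste0(n$resname, n$residue_seq, ":",
                  if (n$kind == "base") "base" else "sp")
  }, character(1))
  out <- data.frame(node = seq_along(nodes) - 1L, label = lab,
                    kind = vapply(nodes, `[[`, character(1), "kind"),
                    anchor_id = vapply(nodes, `[[`, integer(1), "anchor_id"),
                    chain_id = vapply(nodes, `[[`, character(1), "chain_id"),
                    residue_seq = vapply(nodes, `[[`, integer(1), "residue_seq"),
                    stringsAsFactors = FALSE)
  out$atom_ids <- lapply(nodes, `[[`, "atom_ids")
  out
}

#' Build the correlation-weighted dynamical network
#'
#' Two nodes are connected when any heavy-atom pair between their
#' components is within `distance_cutoff` in at least
#' `occupancy_cutoff` of frames, excluding neighbouring nodes (same
#' residue -- the glycosidic base/sugar pair -- or sequence-adjacent
#' residues on the same chain).  Retained edges are weighted
#' w_ij = -log(|C_ij|) with the correlation of the two anchor atoms
#' (|C| floored at 1e-6).
#'
#' @param traj Trajectory.
#' @param topology `Structure` (defaults to the trajectory topology).
#' @param correlation `CorrelationMatrix` over the node anchors in node
#'   order, or `NULL` to compute it from the trajectory (rigid-body
#'   fitted anchor displacements).
#' @param occupancy_cutoff minimum contact occupancy (default 0.75, >=).
#' @param distance_cutoff heavy-atom contact distance (default 4.5 A, <=).
#' @param weight_scheme `"minus_log"` (w = -log|C|) or
#'   `"one_minus"` (w = 1 - |C|).
#' @return Object of class `"DynamicalNetwork"`: `nodes` (from
#'   [define_network_nodes()]) and `edges` (data.frame `i`, `j` 0-based
#'   node ids, `occupancy`, `correlation`, `weight`).
#' @export
build_network <- function(traj, topology = traj$topology,
                          correlation = NULL,
                          occupancy_cutoff = 0.75, distance_cutoff = 4.5,
                          weight_scheme = c("minus_log", "one_minus")) {
  weight_scheme <- match.arg(weight_scheme)
  nodes <- define_network_nodes(topology)
  nn <- nrow(nodes)
  if (is.null(correlation))
    correlation <- dccm(traj, selection = nodes$anchor_id, fit = TRUE)
  if (!all(dim(correlation) == nn))
    stop("correlation matrix does not match the node count")

  ## candidate pairs: everything except neighbours
  cand <- which(upper.tri(matrix(0, nn, nn)), arr.ind = TRUE)
  same_chain <- nodes$chain_id[cand[, 1]] == nodes$chain_id[cand[, 2]]
  dsep <- abs(nodes$residue_seq[cand[, 1]] - nodes$residue_seq[cand[, 2]])
  neighbour <- same_chain & dsep <= 1L
  cand <- cand[!neighbour, , drop = FALSE]

  nf <- n_frames(traj)
  occ <- numeric(nrow(cand))
  ## per-frame any-pair-within-cutoff, evaluated via squared distances on
  ## each pair's atom groups
  for (p in seq_len(nrow(cand))) {
    ai <- nodes$atom_ids[[cand[p, 1]]]; aj <- nodes$atom_ids[[cand[p, 2]]]
    g <- expand.grid(a = ai, b = aj)
    D <- pair_dist_matrix(traj, g$a, g$b)
    mind <- if (ncol(D) == 1L) D[, 1] else do.call(pmin, asplit(D, 2))
    occ[p] <- mean(mind <= distance_cutoff + 1e-12)
  }
  keep <- occ >= occupancy_cutoff
  ii <- cand[keep, 1]; jj <- cand[keep, 2]
  cvals <- unclass(correlation)[cbind(ii, jj)]
  absc <- pmax(abs(cvals), 1e-6)
  w <- switch(weight_scheme,
              minus_log = -log(absc),
              one_minus = 1 - absc)
  edges <- data.frame(i = nodes$node[ii], j = nodes$node[jj],
                      occupancy = occ[keep], correlation = cvals,
                      weight = w)
  structure(list(nodes = nodes, edges = edges,
                 occupancy_cutoff = occupancy_cutoff,
                 distance_cutoff = distance_cutoff,
                 weight_scheme = weight_scheme),
            class = "DynamicalNetwork")
}

#' @export
print.DynamicalNetwork <- function(x, ...) {
  cat(sprintf("DynamicalNetwork: %d nodes, %d edges (>= %.0f%% occupancy, <= %.2f A)\n",
              nrow(x$nodes), nrow(x$edges), 100 * x$occupancy_cutoff,
              x$distance_cutoff))
  invisible(x)
}

## Symmetric weight matrix (Inf where no edge) from an edge table.
edge_weight_matrix <- function(n, edges) {
  W <- matrix(Inf, n, n)
  diag(W) <- 0
  if (nrow(edges)) {
    idx <- cbind(edges$i + 1L, edges$j + 1L)
    W[idx] <- edges$weight
    W[idx[, 2:1, drop = FALSE]] <- edges$weight
  }
  W
}

#' All-pairs shortest paths by Floyd-Warshall
#'
#' Dense dynamic-programming solve over the edge-weight matrix
#' (non-negative weights).  The characteristic path length (CPL) is the
#' mean shortest-path distance over all unordered connected node pairs;
#' unreachable pairs are excluded and counted.
#'
#' @param net `DynamicalNetwork`, or a symmetric weight matrix with Inf
#'   for missing edges and 0 on the diagonal.
#' @return List: `distances` (n x n), `cpl`, `n_unreachable_pairs`.
#' @export
shortest_paths_fw <- function(net) {
  W <- if (inherits(net, "DynamicalNetwork"))
         edge_weight_matrix(nrow(net$nodes), net$edges)
       else as.matrix(net)
  if (any(W < 0)) stop("Floyd-Warshall here requires non-negative weights")
  n <- nrow(W)
  D <- W
  for (k in seq_len(n)) {
    through <- outer(D[, k], D[k, ], `+`)
    D <- pmin(D, through)
  }
  ut <- upper.tri(D)
  finite <- is.finite(D[ut])
  list(distances = D,
       cpl = if (any(finite)) mean(D[ut][finite]) else NA_real_,
       n_unreachable_pairs = sum(!finite))
}

## igraph view of a DynamicalNetwork (weights carried as both 'weight'
## and 'w' attributes).
as_igraph_network <- function(net) {
  if (!nrow(net$edges)) {
    g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = net$nodes$label)
    return(g)
  }
  df <- data.frame(from = net$nodes$label[net$edges$i + 1L],
                   to = net$nodes$label[net$edges$j + 1L],
                   weight = net$edges$weight)
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = net$nodes$label))
}

#' Girvan-Newman community detection
#'
#' Divisive clustering by iterative removal of the maximum-betweenness
#' edge (weighted betweenness over the network's distance weights; ties
#' broken by lexicographic edge label for determinism), evaluating the
#' connected-component partition after every removal and returning the one
#' of maximum modularity (computed on the unweighted contact graph, since
#' the distance-like weights would invert modularity's meaning).
#'
#' @param net `DynamicalNetwork`.
#' @return Object of class `"CommunityPartition"`: `assignment`
#'   (data.frame `node`, `label`, `community` with ids dense from 0),
#'   `n_communities`, `modularity`, `n_removed` (edges removed to reach
#'   the returned partition).
#' @export
communities_gn <- function(net) {
  if (!nrow(net$edges)) stop("network has no edges")
  g0 <- as_igraph_network(net)
  ## zero-length edges break weighted betweenness; floor at a tiny value
  wfix <- function(g) pmax(igraph::E(g)$weight, 1e-12)
  score <- function(membership)
    igraph::modularity(g0, membership, weights = NULL)
  g <- g0
  best <- NULL
  memb <- igraph::components(g)$membership
  best <- list(memb = memb, mod = score(memb), removed = 0L)
  removed <- 0L
  while (igraph::ecount(g) > 0) {
    bt <- igraph::edge_betweenness(g, weights = wfix(g), directed = FALSE)
    mx <- which(bt >= max(bt) - 1e-9)
    if (length(mx) > 1L) {
      ends <- igraph::ends(g, igraph::E(g)[mx])
      lab <- apply(ends, 1, function(e) paste(sort(e), collapse = "|"))
      mx <- mx[order(lab)][1L]
    }
    g <- igraph::delete_edges(g, igraph::E(g)[mx])
    removed <- removed + 1L
    memb <- igraph::components(g)$membership
    m <- score(memb)
    if (m > best$mod + 1e-12)
      best <- list(memb = memb, mod = m, removed = removed)
  }
  comm <- as.integer(factor(best$memb, levels = unique(best$memb))) - 1L
  assignment <- data.frame(node = net$nodes$node, label = net$nodes$label,
                           community = comm[match(net$nodes$label,
                                                  names(best$memb))])
  ## isolated nodes absent from g0 keep their own communities
  if (anyNA(assignment$community)) {
    extra <- which(is.na(assignment$community))
    assignment$community[extra] <- max(comm, -1L) + seq_along(extra)
  }
  structure(list(assignment = assignment,
                 n_communities = length(unique(assignment$community)),
                 modularity = best$mod,
                 n_removed = best$removed),
            class = "CommunityPartition")
}

#' @export
print.CommunityPartition <- function(x, ...) {
  cat(sprintf("CommunityPartition: %d communities, modularity %.3f\n",
              x$n_communities, x$modularity))
  invisible(x)
}

#' Characteristic-path-length perturbation scan
#'
#' For every node v the network is perturbed -- `"edge_removal"` deletes
#' all edges incident to v (v stays, isolated); `"node_removal"` deletes v
#' itself -- and delta-CPL = CPL(perturbed) - CPL(baseline) is computed
#' over the node pairs that remain connected in both graphs (so the
#' comparison is like-for-like); pairs disconnected by the perturbation
#' are counted per node.
#'
#' @param net `DynamicalNetwork`.
#' @param mode `"edge_removal"` or `"node_removal"`.
#' @return Object of class `"CplReport"`: `baseline_cpl` and `scan`
#'   (data.frame `node`, `label`, `delta_cpl`, `n_disconnected_pairs`),
#'   ordered by residue number.
#' @export
delta_cpl_scan <- function(net, mode = c("edge_removal", "node_removal")) {
  mode <- match.arg(mode)
  n <- nrow(net$nodes)
  base <- shortest_paths_fw(net)
  D0 <- base$distances
  ut <- upper.tri(D0)
  out <- data.frame(node = net$nodes$node, label = net$nodes$label,
                    delta_cpl = NA_real_, n_disconnected_pairs = 0L)
  for (v in seq_len(n)) {
    e <- net$edges
    e2 <- e[e$i != (v - 1L) & e$j != (v - 1L), , drop = FALSE]
    Dp <- shortest_paths_fw(edge_weight_matrix(n, e2))$distances
    mask <- ut & is.finite(D0) & is.finite(Dp)
    if (mode == "node_removal") {
      mask[v, ] <- FALSE; mask[, v] <- FALSE
    }
    lost <- ut & is.finite(D0) & !is.finite(Dp)
    lost[v, ] <- FALSE; lost[, v] <- FALSE   # count collateral losses only
    out$delta_cpl[v] <- if (any(mask)) mean(Dp[mask]) - mean(D0[mask])
                        else NA_real_
    out$n_disconnected_pairs[v] <- sum(lost)
  }
  ord <- order(net$nodes$chain_id, net$nodes$residue_seq, net$nodes$kind)
  structure(list(baseline_cpl = base$cpl, mode = mode, scan = out[ord, ]),
            class = "CplReport")
}

#' @export
print.CplReport <- function(x, ...) {
  cat(sprintf("CplReport (%s): baseline CPL %.4f, %d nodes scanned\n",
              x$mode, x$baseline_cpl, nrow(x$scan)))
  invisible(x)
}

#' Export a network as an edge-list TSV
#'
#' Columns: node labels, occupancy, correlation and weight per edge.
#'
#' @param net `DynamicalNetwork`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_network_tsv <- function(net, path) {
  e <- net$edges
  df <- data.frame(from = net$nodes$label[e$i + 1L],
                   to = net$nodes$label[e$j + 1L],
                   occupancy = sprintf("%.4f", e$occupancy),
                   correlation = sprintf("%.6f", e$correlation),
                   weight = sprintf("%.6f", e$weight))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
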