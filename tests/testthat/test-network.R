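test_that("network edges require occupancy and carry -log|C| weights", {
  ## two residues far apart in sequence, always in contact; third far away
  st <- ca_structure(rbind(c(0, 0, 0), c(4, 0, 0), c(40, 0, 0)),
                     residue_seq = c(1L, 10L, 20L))
  frames <- rep(list(unname(st$xyz)), 8)
  tr <- traj_from_frames(st, frames)
  C <- matrix(1, 3, 3)
  net <- build_network(tr, st, correlation = C)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 0)          # -log(1)
  expect_equal(net$edges$occupancy, 1)

  ## 74% occupancy: below the closed >= 75% threshold -> no edge
  near <- unname(st$xyz)
  far <- near; far[2, 1] <- 30
  tr2 <- traj_from_frames(st, c(rep(list(near), 74), rep(list(far), 26)))
  net74 <- build_network(tr2, st, correlation = C)
  expect_equal(nrow(net74$edges), 0L)
  tr3 <- traj_from_frames(st, c(rep(list(near), 75), rep(list(far), 25)))
  expect_equal(nrow(build_network(tr3, st, correlation = C)$edges), 1L)
})

test_that("edge sets match a brute-force recomputation on the toy complex", {
  toy <- build_toy_complex(1)
  tr <- sample_harmonic_ensemble(toy, variances = 0.1, n_frames = 40,
                                 seed = 7)
  C <- dccm(tr, selection = define_network_nodes(toy)$anchor_id, fit = TRUE)
  net <- build_network(tr, toy, correlation = C)
  nodes <- net$nodes
  nn <- nrow(nodes)
  ## brute force: per-frame min cross-group distance, occupancy rule
  got <- sprintf("%d-%d", net$edges$i, net$edges$j)
  expected <- character()
  for (i in seq_len(nn - 1)) for (j in seq(i + 1, nn)) {
    if (nodes$chain_id[i] == nodes$chain_id[j] &&
        abs(nodes$residue_seq[i] - nodes$residue_seq[j]) <= 1) next
    ai <- nodes$atom_ids[[i]] + 1L; aj <- nodes$atom_ids[[j]] + 1L
    pres <- vapply(seq_len(40), function(f) {
      fc <- frame_coords(tr, f)
      min(as.matrix(stats::dist(rbind(fc[ai, , drop = FALSE],
                                      fc[aj, , drop = FALSE])))[
        seq_along(ai), length(ai) + seq_along(aj)]) <= 4.5
    }, logical(1))
    if (mean(pres) >= 0.75)
      expected <- c(expected, sprintf("%d-%d", nodes$node[i], nodes$node[j]))
  }
  expect_setequal(got, expected)
})

test_that("raising the occupancy threshold never adds edges", {
  toy <- build_toy_complex(2)
  tr <- sample_harmonic_ensemble(toy, variances = 0.15, n_frames = 30,
                                 seed = 8)
  C <- dccm(tr, selection = define_network_nodes(toy)$anchor_id, fit = TRUE)
  e50 <- build_network(tr, toy, correlation = C, occupancy_cutoff = 0.5)$edges
  e90 <- build_network(tr, toy, correlation = C, occupancy_cutoff = 0.9)$edges
  key <- function(e) sprintf("%d-%d", e$i, e$j)
  expect_true(all(key(e90) %in% key(e50)))
})

test_that("shortest paths take detours when direct edges are long", {
  net <- graph_network(3, data.frame(i = c(0L, 1L, 0L), j = c(1L, 2L, 2L),
                                     weight = c(1, 1, 3)))
  sp <- shortest_paths_fw(net)
  expect_equal(sp$distances[1, 3], 2)
  expect_equal(diag(sp$distances), rep(0, 3))
})

test_that("CPL of the 3-node unit path is 4/3", {
  net <- graph_network(3, data.frame(i = c(0L, 1L), j = c(1L, 2L),
                                     weight = c(1, 1)))
  sp <- shortest_paths_fw(net)
  expect_equal(sp$cpl, 4 / 3)
  expect_equal(sp$n_unreachable_pairs, 0L)
})

test_that("Floyd-Warshall equals per-source Dijkstra on random graphs", {
  set.seed(21)
  for (r in 1:50) {
    n <- sample(4:12, 1)
    W <- matrix(Inf, n, n); diag(W) <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) if (runif(1) < 0.45) {
      w <- runif(1, 0.1, 3); W[i, j] <- w; W[j, i] <- w
    }
    D <- shortest_paths_fw(W)$distances
    adj <- ifelse(is.finite(W) & W > 0, W, 0)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE)
    D2 <- igraph::distances(g, algorithm = "dijkstra")
    expect_equal(is.finite(D), is.finite(D2), ignore_attr = TRUE)
    both <- is.finite(D)
    expect_equal(D[both], D2[both], tolerance = 1e-12, ignore_attr = TRUE)
    ## triangle inequality on finite distances
    for (k in seq_len(n))
      expect_true(all(D[both] <= (outer(D[, k], D[k, ], `+`) + 1e-9)[both]))
  }
})

test_that("Girvan-Newman cuts the bridge between two triangles", {
  ## two triangles 0-1-2 and 3-4-5 joined by bridge 2-3
  e <- data.frame(i = c(0L, 0L, 1L, 3L, 3L, 4L, 2L),
                  j = c(1L, 2L, 2L, 4L, 5L, 5L, 3L),
                  weight = 1)
  net <- graph_network(6, e)
  ## exhaustive betweenness check: the bridge lies on all 9 cross pairs
  cm <- communities_gn(net)
  expect_equal(cm$n_communities, 2L)
  a <- cm$assignment$community
  expect_equal(a[1], a[2]); expect_equal(a[2], a[3])
  expect_equal(a[4], a[5]); expect_equal(a[5], a[6])
  expect_false(a[1] == a[4])
})

test_that("single triangles and disconnected components are respected", {
  tri <- graph_network(3, data.frame(i = c(0L, 0L, 1L), j = c(1L, 2L, 2L),
                                     weight = 1))
  expect_equal(communities_gn(tri)$n_communities, 1L)
  two <- graph_network(4, data.frame(i = c(0L, 2L), j = c(1L, 3L),
                                     weight = 1))
  cm <- communities_gn(two)
  a <- cm$assignment$community
  expect_equal(a[1], a[2]); expect_equal(a[3], a[4])
  expect_false(a[1] == a[3])
})

test_that("planted two-block graphs are recovered with high Rand index", {
  ris <- vapply(1:8, function(s) {
    b <- block_network(s)
    cm <- communities_gn(b$net)
    rand_index(cm$assignment$community, b$truth)
  }, numeric(1))
  expect_gte(mean(ris), 0.95)
  expect_gte(min(ris), 0.9)
})

test_that("delta-CPL scans match from-scratch recomputation", {
  set.seed(31)
  e <- data.frame(i = c(0L, 0L, 1L, 2L, 3L, 1L),
                  j = c(1L, 2L, 2L, 3L, 4L, 4L),
                  weight = round(runif(6, 0.5, 2), 3))
  net <- graph_network(5, e)
  for (mode in c("edge_removal", "node_removal")) {
    rep <- delta_cpl_scan(net, mode)
    D0 <- shortest_paths_fw(net)$distances
    for (v in 1:5) {
      keep <- e[e$i != (v - 1L) & e$j != (v - 1L), ]
      W <- matrix(Inf, 5, 5); diag(W) <- 0
      if (nrow(keep)) {
        W[cbind(keep$i + 1, keep$j + 1)] <- keep$weight
        W[cbind(keep$j + 1, keep$i + 1)] <- keep$weight
      }
      Dp <- shortest_paths_fw(W)$distances
      mask <- upper.tri(D0) & is.finite(D0) & is.finite(Dp)
      if (mode == "node_removal") { mask[v, ] <- FALSE; mask[, v] <- FALSE }
      want <- mean(Dp[mask]) - mean(D0[mask])
      got <- rep$scan$delta_cpl[rep$scan$node == v - 1L]
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("isolated nodes leave the CPL unchanged", {
  e <- data.frame(i = 0L, j = 1L, weight = 1)
  net <- graph_network(3, e)      # node 2 isolated
  rep <- delta_cpl_scan(net, "edge_removal")
  expect_equal(rep$scan$delta_cpl[rep$scan$node == 2L], 0)
})

test_that("removing a barbell bridge node flags disconnections", {
  e <- data.frame(i = c(0L, 0L, 1L, 2L, 3L, 3L, 4L),
                  j = c(1L, 2L, 2L, 6L, 4L, 5L, 5L),
                  weight = 1)
  ## 0-1-2 triangle - bridge node 6 - triangle 3-4-5
  e <- rbind(e, data.frame(i = 6L, j = 3L, weight = 1))
  net <- graph_network(7, e)
  rep <- delta_cpl_scan(net, "node_removal")
  row <- rep$scan[rep$scan$node == 6L, ]
  expect_gt(row$n_disconnected_pairs, 0L)
})
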