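test_that("native contacts respect exclusion, cutoff and closed boundary", {
  ## 3 collinear CA at 0/5/10 A, exclusion 2: all pairs excluded
  st <- ca_structure(cbind(c(0, 5, 10), 0, 0))
  nc <- native_contacts(st, NULL, cutoff = 8, exclusion = 2)
  expect_equal(nrow(nc$pairs), 0L)
  ## 4-residue chain where only pair (1,4) is far enough in sequence
  st2 <- ca_structure(rbind(c(0, 0, 0), c(3, 3, 0), c(6, 1, 0), c(6, 0, 0)))
  nc2 <- native_contacts(st2, NULL, cutoff = 8, exclusion = 2)
  expect_equal(nrow(nc2$pairs), 1L)
  expect_equal(nc2$pairs$i, 0L); expect_equal(nc2$pairs$j, 3L)
  expect_equal(nc2$pairs$native_distance, 6)
  ## boundary: exactly 8.0 A is included
  st3 <- ca_structure(cbind(c(0, 3, 5, 8), 0, 0))
  nc3 <- native_contacts(st3, NULL, cutoff = 8, exclusion = 2)
  expect_true(any(nc3$pairs$native_distance == 8))
  expect_error(native_contacts(st3, NULL, cutoff = 0), "> 0")
})

test_that("Q and Qs are exact at the reference and in the stretched limit", {
  set.seed(9)
  n <- 12
  xyz <- cbind(seq_len(n) * 2.5, rnorm(n), rnorm(n))
  st <- ca_structure(xyz)
  nc <- native_contacts(st, NULL, cutoff = 8, exclusion = 2)
  expect_gt(nrow(nc$pairs), 0)
  tr <- traj_from_frames(st, list(xyz, xyz * 3))
  qs <- q_series(tr, nc)
  expect_equal(qs$q[1], 1); expect_equal(qs$qs[1], 1)
  expect_equal(qs$q[2], 0)
  expect_lt(qs$qs[2], 0.01)
  expect_true(all(qs$q >= 0 & qs$q <= 1 & qs$qs >= 0 & qs$qs <= 1))
})

test_that("a single pair displaced by exactly sigma gives Qs = exp(-1/2)", {
  st <- ca_structure(rbind(c(0, 0, 0), c(6, 0, 0)), residue_seq = c(1L, 7L))
  nc <- native_contacts(st, NULL, cutoff = 8, exclusion = 2)
  expect_equal(nrow(nc$pairs), 1L)
  sig <- (1 + 6)^0.15
  tr <- traj_from_frames(st, list(rbind(c(0, 0, 0), c(6 + sig, 0, 0))))
  expect_equal(q_series(tr, nc)$qs, exp(-0.5), tolerance = 1e-9)
})

test_that("contact counts match hand geometry and the brute-force oracle", {
  stp <- ca_structure(rbind(c(0, 0, 0), c(5, 0, 0)), residue_seq = c(1L, 9L))
  tr <- traj_from_frames(stp, list(unname(stp$xyz)))
  expect_equal(contact_count_series(tr, NULL, NULL, cutoff = 6)$count, 1L)
  stp2 <- ca_structure(rbind(c(0, 0, 0), c(6.5, 0, 0)),
                       residue_seq = c(1L, 9L))
  tr2 <- traj_from_frames(stp2, list(unname(stp2$xyz)))
  expect_equal(contact_count_series(tr2, NULL, NULL, cutoff = 6)$count, 0L)

  set.seed(11)
  n <- 15
  st <- ca_structure(matrix(runif(3 * n, 0, 12), ncol = 3))
  tr3 <- sample_harmonic_ensemble(st, variances = 0.4, n_frames = 10,
                                  seed = 12)
  got <- contact_count_series(tr3, NULL, NULL, cutoff = 6, exclusion = 2)
  for (f in seq_len(10)) {
    fc <- frame_coords(tr3, f)
    cnt <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (abs(i - j) > 2 && sqrt(sum((fc[i, ] - fc[j, ])^2)) <= 6)
        cnt <- cnt + 1L
    expect_equal(got$count[f], cnt)
  }
})

test_that("contact counts are symmetric and monotone in the cutoff", {
  toy <- build_toy_complex(2)
  tr <- sample_harmonic_ensemble(toy, variances = 0.1, n_frames = 8,
                                 seed = 13)
  ca <- select_atoms(toy, "name CA")
  rna <- select_atoms(toy, "chain B")
  ab <- contact_count_series(tr, ca, rna, cutoff = 6)
  ba <- contact_count_series(tr, rna, ca, cutoff = 6)
  expect_equal(ab$count, ba$count)
  wide <- contact_count_series(tr, ca, rna, cutoff = 12)
  expect_true(all(wide$count >= ab$count))
})

test_that("interface occupancy flags the closed 75% boundary", {
  st <- ca_structure(rbind(c(0, 0, 0), c(20, 0, 0)),
                     residue_seq = c(1L, 9L))
  near <- rbind(c(0, 0, 0), c(4, 0, 0))
  far <- rbind(c(0, 0, 0), c(20, 0, 0))
  tr <- traj_from_frames(st, c(rep(list(near), 6), rep(list(far), 2)))
  occ <- interface_occupancy(tr, list(AB = list(a = 0L, b = 1L)),
                             cutoff = 4.5, threshold = 0.75)
  expect_equal(occ$occupancy, 0.75)
  expect_true(occ$flagged)
  occ2 <- interface_occupancy(tr, list(AB = list(a = 0L, b = 1L)),
                              cutoff = 25)
  expect_equal(occ2$occupancy, 1)
})

test_that("occupancies equal the brute-force per-frame recomputation", {
  toy <- build_toy_complex(1)
  tr <- sample_harmonic_ensemble(toy, variances = 0.12, n_frames = 12,
                                 seed = 14)
  ca_ids <- toy$atoms$atom_id[toy$atoms$atom_name == "CA"]
  base_ids <- toy$atoms$atom_id[toy$atoms$atom_name %in% c("N1", "N9")]
  pairs <- list(p1 = list(a = base_ids[2], b = ca_ids),
                p2 = list(a = base_ids[5], b = ca_ids))
  occ <- interface_occupancy(tr, pairs, cutoff = 4.5)
  for (k in 1:2) {
    b <- pairs[[k]]$a
    pres <- vapply(seq_len(12), function(f) {
      fc <- frame_coords(tr, f)
      any(sqrt(colSums((t(fc[ca_ids + 1L, , drop = FALSE]) -
                          fc[b + 1L, ])^2)) <= 4.5)
    }, logical(1))
    expect_equal(occ$occupancy[k], mean(pres))
  }
})

test_that("SASA of an isolated atom matches the analytic sphere", {
  st <- ca_structure(matrix(c(0, 0, 0), 1))
  s <- sasa(st, probe_radius = 1.4, n_points = 960)
  expect_lt(abs(s$atom$sasa - 4 * pi * (1.7 + 1.4)^2) /
              (4 * pi * (1.7 + 1.4)^2), 0.01)
})

test_that("coincident atoms occlude to a single sphere's area", {
  st <- ca_structure(rbind(c(0, 0, 0), c(0, 0, 0) + 1e-9),
                     residue_seq = c(1L, 5L))
  s <- sasa(st, n_points = 960)
  one <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(sum(s$atom$sasa) - one) / one, 0.02)
})

test_that("two touching atoms match a dense-grid oracle and shrink on approach", {
  mk <- function(d) ca_structure(rbind(c(0, 0, 0), c(d, 0, 0)),
                                 residue_seq = c(1L, 5L))
  d0 <- 2 * 1.7 + 2 * 1.4            # contact distance of expanded spheres
  fine <- sum(sasa(mk(3.4), n_points = 20000)$atom$sasa)
  got <- sum(sasa(mk(3.4), n_points = 960)$atom$sasa)
  expect_lt(abs(got - fine) / fine, 0.02)
  areas <- vapply(c(d0 + 1, d0, 5, 3.4, 2), function(d)
    sum(sasa(mk(d), n_points = 960)$atom$sasa), numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
  expect_error(sasa(mk(3), n_points = 50), ">= 100")
})

test_that("unknown elements without radii are rejected by name", {
  st <- new_structure(data.frame(atom_name = "FE", residue_seq = 1L,
                                 residue_name = "HEM", chain_id = "A",
                                 element = "FE"),
                      matrix(c(0, 0, 0), 1))
  expect_error(sasa(st), "atom id 0")
})
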