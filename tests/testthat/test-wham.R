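kB <- 0.0019872041

test_that("reaction coordinate is the mass-weighted COM distance", {
  ## two single atoms 5 A apart
  st <- ca_structure(rbind(c(0, 0, 0), c(5, 0, 0)), residue_seq = c(1L, 9L))
  tr <- traj_from_frames(st, list(unname(st$xyz)))
  expect_equal(reaction_coordinate(tr, 0L, 1L)$rc, 5)

  ## equal masses at x = 0 and 2 vs atom at 5: |1 - 5| = 4
  st2 <- ca_structure(rbind(c(0, 0, 0), c(2, 0, 0), c(5, 0, 0)))
  tr2 <- traj_from_frames(st2, list(unname(st2$xyz)))
  expect_equal(reaction_coordinate(tr2, c(0L, 1L), 2L)$rc, 4)

  ## unequal masses: 12 amu at 0, 1 amu at 2 -> COM 2/13
  at <- data.frame(atom_name = c("C1", "H1", "C2"),
                   residue_seq = c(1L, 1L, 9L),
                   residue_name = "LIG", chain_id = "A",
                   element = c("C", "H", "C"),
                   mass = c(12, 1, 12))
  st3 <- new_structure(at, rbind(c(0, 0, 0), c(2, 0, 0), c(5, 0, 0)))
  tr3 <- traj_from_frames(st3, list(unname(st3$xyz)))
  expect_equal(reaction_coordinate(tr3, c(0L, 1L), 2L)$rc, 5 - 2 / 13,
               tolerance = 1e-4)
  expect_error(reaction_coordinate(tr3, integer(0), 2L), "non-empty")
})

test_that("a single unbiased window degenerates to histogramming", {
  set.seed(1)
  x <- rnorm(20000, 14, 0.5)
  ud <- structure(list(windows = list(list(center = 14, force_constant = 0,
                                           x = x, y = NULL)),
                       temperature = 300), class = "UmbrellaDataset")
  pmf <- wham_1d(ud, n_bins = 60, tolerance = 1e-4)
  h <- hist(x, breaks = pmf$edges, plot = FALSE)$counts
  ref <- -kB * 300 * log(h / sum(h))
  ref <- ref - min(ref[h > 0])
  ok <- h > 0
  expect_equal(pmf$profile$free_energy[ok], ref[ok], tolerance = 1e-9)
  expect_equal(min(pmf$profile$free_energy, na.rm = TRUE), 0)
})

test_that("a flat potential reconstructs to a flat PMF", {
  lay <- umbrella_window_layout(n_samples = 4000L, burn_in = 400L, seed = 3L)
  ud <- sample_umbrella_windows(potential_flat(), lay)
  pmf <- wham_1d(ud, n_bins = 400, tolerance = 1e-4)
  pr <- pmf$profile
  ok <- !is.na(pr$free_energy) & pr$bin_center >= 10.5 & pr$bin_center <= 20
  dev <- pr$free_energy[ok] - mean(pr$free_energy[ok])
  expect_lt(sqrt(mean(dev^2)), 0.15)
})

test_that("a harmonic test potential is recovered up to a constant", {
  lay <- umbrella_window_layout(n_samples = 5000L, burn_in = 500L, seed = 5L)
  ud <- sample_umbrella_windows(potential_harmonic(2, 14), lay)
  pmf <- wham_1d(ud, n_bins = 500, tolerance = 1e-4)
  pr <- pmf$profile
  ok <- !is.na(pr$free_energy) & pr$bin_center >= 10.5 & pr$bin_center <= 20
  resid <- pr$free_energy[ok] - 0.5 * 2 * (pr$bin_center[ok] - 14)^2
  resid <- resid - mean(resid)
  expect_lt(sqrt(mean(resid^2)), 0.2)
})

test_that("WHAM is invariant to window order and consistent center shifts", {
  lay <- umbrella_window_layout(n_samples = 2000L, burn_in = 200L, seed = 7L)
  ud <- sample_umbrella_windows(potential_harmonic(2, 14), lay)
  pmf <- wham_1d(ud, n_bins = 200, tolerance = 1e-5)
  perm <- rev(seq_along(ud$windows))
  ud2 <- ud; ud2$windows <- ud$windows[perm]
  pmf2 <- wham_1d(ud2, n_bins = 200, tolerance = 1e-5)
  expect_equal(pmf$profile$free_energy, pmf2$profile$free_energy,
               tolerance = 1e-6)
  ## uniform shift of centers and samples translates the profile
  ud3 <- ud
  for (k in seq_along(ud3$windows)) {
    ud3$windows[[k]]$center <- ud3$windows[[k]]$center + 2
    ud3$windows[[k]]$x <- ud3$windows[[k]]$x + 2
  }
  pmf3 <- wham_1d(ud3, n_bins = 200, tolerance = 1e-5)
  expect_equal(pmf3$profile$free_energy, pmf$profile$free_energy,
               tolerance = 1e-6)
  expect_equal(pmf3$profile$bin_center, pmf$profile$bin_center + 2)
})

test_that("non-overlapping windows warn and non-convergence errors", {
  lay <- data.frame(center = c(10, 20), force_constant = 1e3,
                    n_samples = 500L, burn_in = 50L, seed = c(1L, 2L))
  ud <- sample_umbrella_windows(potential_flat(), lay)
  expect_warning(wham_1d(ud, n_bins = 100, tolerance = 1e-3),
                 "overlap")
  lay2 <- umbrella_window_layout(n_samples = 500L, burn_in = 50L, seed = 9L)
  ud2 <- sample_umbrella_windows(potential_harmonic(2, 14), lay2)
  expect_error(wham_1d(ud2, n_bins = 100, tolerance = 1e-10, max_iter = 2L),
               "converge")
})

test_that("2D surfaces are separable for an independent Gaussian auxiliary", {
  m0 <- 2; s0 <- 0.4
  lay <- umbrella_window_layout(n_samples = 4000L, burn_in = 400L, seed = 11L)
  ud <- sample_umbrella_windows(potential_harmonic(2, 14), lay,
                                aux = list(mean_fn = function(x) rep(m0, length(x)),
                                           sd = s0))
  surf <- wham_2d(ud, n_bins_x = 120, n_bins_y = 40, tolerance = 1e-4)
  F <- surf$free_energy
  kT <- kB * 300
  ## on well-sampled cells, F(x,y) - F(x,y_mode) ~ (y - m0)^2 kT / (2 s0^2)
  ok_x <- which(rowSums(surf$n_samples) > 800)
  expect_gt(length(ok_x), 5)
  for (bx in ok_x[c(1, length(ok_x) %/% 2, length(ok_x))]) {
    cells <- which(surf$n_samples[bx, ] > 60)
    expect_gte(length(cells), 3)
    yv <- surf$y_centers[cells]
    pred <- kT * (yv - m0)^2 / (2 * s0^2)
    resid <- F[bx, cells] - pred
    resid <- resid - mean(resid)
    expect_lt(sqrt(mean(resid^2)), 0.2)
  }
})

test_that("a deterministic auxiliary confines mass to the diagonal", {
  lay <- umbrella_window_layout(n_samples = 1000L, burn_in = 100L, seed = 13L)
  ud <- sample_umbrella_windows(potential_flat(), lay)
  for (k in seq_along(ud$windows)) ud$windows[[k]]$y <- ud$windows[[k]]$x
  surf <- wham_2d(ud, n_bins_x = 30, n_bins_y = 30, tolerance = 1e-3)
  off <- abs(outer(seq_len(30), seq_len(30), `-`)) > 2
  expect_true(all(is.na(surf$free_energy[off])))
})

test_that("marginalising the 2D PMF reproduces the 1D PMF", {
  lay <- umbrella_window_layout(n_samples = 3000L, burn_in = 300L, seed = 15L)
  ud <- sample_umbrella_windows(potential_harmonic(2, 14), lay,
                                aux = list(mean_fn = function(x) 1 + x / 4,
                                           sd = 0.3))
  pmf <- wham_1d(ud, n_bins = 200, tolerance = 1e-4)
  surf <- wham_2d(ud, n_bins_x = 200, n_bins_y = 60, tolerance = 1e-4)
  marg <- marginalize_pmf(surf)
  ok <- !is.na(marg$free_energy) & !is.na(pmf$profile$free_energy)
  expect_lt(max(abs(marg$free_energy[ok] - pmf$profile$free_energy[ok])),
            0.1)
  noy <- ud
  for (k in seq_along(noy$windows)) noy$windows[[k]]$y <- NULL
  expect_error(wham_2d(noy), "auxiliary")
})

test_that("bootstrap errors behave like a bootstrap", {
  lay <- umbrella_window_layout(n_samples = 600L, burn_in = 60L, seed = 17L)
  ud <- sample_umbrella_windows(potential_harmonic(2, 14), lay)
  ## full-length blocks make every replicate the original series
  be0 <- bootstrap_errors(ud, n_bins = 100, n_replicates = 20,
                          block_length = 600L, seed = 1)
  expect_true(all(be0$profile$error[!is.na(be0$profile$error)] == 0))
  be1 <- bootstrap_errors(ud, n_bins = 100, n_replicates = 20,
                          block_length = 10L, seed = 2)
  be1b <- bootstrap_errors(ud, n_bins = 100, n_replicates = 20,
                           block_length = 10L, seed = 2)
  expect_identical(be1$profile$error, be1b$profile$error)
  ## errors shrink roughly like 1/sqrt(n) with x4 samples
  lay4 <- umbrella_window_layout(n_samples = 2400L, burn_in = 60L, seed = 17L)
  ud4 <- sample_umbrella_windows(potential_harmonic(2, 14), lay4)
  be4 <- bootstrap_errors(ud4, n_bins = 100, n_replicates = 20,
                          block_length = 10L, seed = 2)
  r <- median(be1$profile$error, na.rm = TRUE) /
       median(be4$profile$error, na.rm = TRUE)
  expect_gt(r, 1.3); expect_lt(r, 3.2)
  expect_error(bootstrap_errors(ud, n_replicates = 5), "at least 20")
})
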