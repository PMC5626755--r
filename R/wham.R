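## Weighted histogram analysis method (WHAM) for umbrella-sampling data:
## reaction-coordinate extraction, 1D and 2D PMF reconstruction, and
## Monte-Carlo (block) bootstrap errors.
##
## Bias convention: U_bias = 0.5 * k * (x - x0)^2 with k the "elastic
## constant" as given (no hidden factor of two); set `half_spring = TRUE`
## where a dataset follows the U = k (x - x0)^2 convention instead.

#' Center-of-mass reaction coordinate
#'
#' Per-frame distance between the mass-weighted centers of two atom
#' groups -- e.g. the P/O5' backbone atoms of the central nucleotides
#' versus the C-alpha atoms within 5 Angstrom of the RNA in the crystal.
#'
#' @param traj Trajectory.
#' @param group_a,group_b `AtomSelection`s or 0-based ids.
#' @return data.frame: `frame`, `time_ps`, `rc` (Angstrom).
#' @export
reaction_coordinate <- function(traj, group_a, group_b) {
  top <- traj$topology
  ia <- sel_index(group_a, top); ib <- sel_index(group_b, top)
  if (!length(ia) || !length(ib)) stop("COM groups must be non-empty")
  com_series <- function(idx) {
    m <- top$atoms$mass[idx]
    wsum <- sum(m)
    cols <- function(off) traj$xyz[, 3L * idx - off, drop = FALSE]
    cbind(cols(2L) %*% m, cols(1L) %*% m, cols(0L) %*% m) / wsum
  }
  ca <- com_series(ia); cb <- com_series(ib)
  data.frame(frame = seq_len(n_frames(traj)),
             time_ps = (seq_len(n_frames(traj)) - 1L) * traj$timestep,
             rc = sqrt(rowSums((ca - cb)^2)))
}

## Bin samples on a fixed grid; returns integer counts per bin.
bin_counts <- function(x, edges) {
  b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(b, nbins = length(edges) - 1L)
}

## Core self-consistent solve for window free-energy offsets f_k.
## C:   K x M matrix of Boltzmann bias factors exp(-beta U_k(x_b))
## h:   length-M total histogram counts, N: length-K window sample counts
wham_solve <- function(C, h, N, beta, tolerance, max_iter) {
  K <- nrow(C)
  f <- numeric(K)
  for (it in seq_len(max_iter)) {
    g <- exp(beta * f)
    denom <- as.vector(crossprod(C, N * g))    # length M
    p <- ifelse(denom > 0, h / denom, 0)
    fnew <- -log(as.vector(C %*% p)) / beta
    fnew <- fnew - fnew[1L]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tolerance)
      return(list(f = f, p = p, iterations = it))
  }
  stop(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
               max_iter, delta))
}

check_window_overlap <- function(data) {
  rng <- t(vapply(data$windows, function(w) range(w$x), numeric(2)))
  ord <- order(vapply(data$windows, `[[`, numeric(1), "center"))
  for (k in seq_len(length(ord) - 1L)) {
    a <- rng[ord[k], ]; b <- rng[ord[k + 1L], ]
    if (a[2] < b[1] || b[2] < a[1])
      warning(sprintf("no histogram overlap between windows centred %.2f and %.2f A",
                      data$windows[[ord[k]]]$center,
                      data$windows[[ord[k + 1L]]]$center))
  }
}

#' 1D WHAM potential of mean force
#'
#' Standard self-consistent WHAM: iterate the window free-energy offsets
#' f_k to convergence (max |delta f_k| < `tolerance`), then
#' PMF = -kT ln p(x), anchored so the minimum over defined bins is 0.
#' Bins with no samples are reported as NA, never interpolated.
#'
#' @param data `UmbrellaDataset`.
#' @param n_bins histogram bins along the reaction coordinate
#'   (default 1000).
#' @param tolerance convergence threshold on the offsets, kcal/mol
#'   (default 1e-4).
#' @param max_iter iteration cap.
#' @param range optional c(min, max) for the binning grid (defaults to
#'   the pooled sample range).
#' @param half_spring if TRUE the window biases are k (x - x0)^2 instead
#'   of k/2 (x - x0)^2.
#' @return Object of class `"PmfProfile"`: `profile` (data.frame
#'   `bin_center`, `free_energy` kcal/mol, `n_samples`), `offsets` (f_k),
#'   `iterations`, `temperature`, `edges`.
#' @export
wham_1d <- function(data, n_bins = 1000L, tolerance = 1e-4,
                    max_iter = 100000L, range = NULL, half_spring = FALSE) {
  stopifnot(inherits(data, "UmbrellaDataset"))
  if (any(vapply(data$windows, function(w) length(w$x) == 0L, logical(1))))
    stop("empty umbrella window")
  check_window_overlap(data)
  beta <- 1 / (.kB * data$temperature)
  allx <- unlist(lapply(data$windows, `[[`, "x"))
  if (is.null(range)) range <- base::range(allx)
  edges <- seq(range[1] - 1e-9, range[2] + 1e-9, length.out = n_bins + 1L)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  K <- length(data$windows)
  spring <- if (half_spring) 1 else 0.5
  C <- t(vapply(data$windows, function(w)
    exp(-beta * spring * w$force_constant * (centers - w$center)^2),
    numeric(n_bins)))
  counts <- t(vapply(data$windows, function(w) bin_counts(w$x, edges),
                     integer(n_bins)))
  h <- colSums(counts)
  N <- vapply(data$windows, function(w) length(w$x), numeric(1))
  sol <- wham_solve(C, h, N, beta, tolerance, max_iter)
  Fx <- ifelse(sol$p > 0, -log(sol$p) / beta, NA_real_)
  Fx <- Fx - min(Fx, na.rm = TRUE)
  structure(list(profile = data.frame(bin_center = centers,
                                      free_energy = Fx,
                                      n_samples = h),
                 offsets = sol$f, iterations = sol$iterations,
                 temperature = data$temperature, edges = edges,
                 beta = beta),
            class = "PmfProfile")
}

#' @export
print.PmfProfile <- function(x, ...) {
  pr <- x$profile
  ok <- !is.na(pr$free_energy)
  cat(sprintf("PmfProfile: %d/%d defined bins, range %.2f kcal/mol, %d WHAM iterations\n",
              sum(ok), nrow(pr), max(pr$free_energy[ok]), x$iterations))
  invisible(x)
}

#' 2D WHAM free-energy surface (biased x, unbiased y)
#'
#' The auxiliary coordinate carries no bias ("added with zero force
#' constant"), so the unbiased 2D density is assembled from the converged
#' 1D window offsets: the denominator depends only on x.  The surface is
#' anchored to min = 0; empty cells are NA.
#'
#' @param data `UmbrellaDataset` whose windows all carry `y` samples.
#' @param n_bins_x bins along the biased coordinate (default 500).
#' @param n_bins_y bins along the auxiliary coordinate (default 100).
#' @param tolerance,max_iter,range_x,range_y,half_spring as in
#'   [wham_1d()].
#' @return Object of class `"PmfSurface"`: `x_centers`, `y_centers`,
#'   `free_energy` (matrix x by y, kcal/mol), `n_samples`, `offsets`.
#' @export
wham_2d <- function(data, n_bins_x = 500L, n_bins_y = 100L,
                    tolerance = 1e-4, max_iter = 100000L,
                    range_x = NULL, range_y = NULL, half_spring = FALSE) {
  stopifnot(inherits(data, "UmbrellaDataset"))
  if (any(vapply(data$windows, function(w) is.null(w$y), logical(1))))
    stop("2D WHAM requires an auxiliary sample series in every window")
  beta <- 1 / (.kB * data$temperature)
  allx <- unlist(lapply(data$windows, `[[`, "x"))
  ally <- unlist(lapply(data$windows, `[[`, "y"))
  if (is.null(range_x)) range_x <- range(allx)
  if (is.null(range_y)) range_y <- range(ally)
  xedges <- seq(range_x[1] - 1e-9, range_x[2] + 1e-9,
                length.out = n_bins_x + 1L)
  yedges <- seq(range_y[1] - 1e-9, range_y[2] + 1e-9,
                length.out = n_bins_y + 1L)
  xcenters <- (xedges[-1L] + xedges[-length(xedges)]) / 2
  ycenters <- (yedges[-1L] + yedges[-length(yedges)]) / 2
  spring <- if (half_spring) 1 else 0.5
  C <- t(vapply(data$windows, function(w)
    exp(-beta * spring * w$force_constant * (xcenters - w$center)^2),
    numeric(n_bins_x)))
  countsx <- t(vapply(data$windows, function(w) bin_counts(w$x, xedges),
                      integer(n_bins_x)))
  hx <- colSums(countsx)
  N <- vapply(data$windows, function(w) length(w$x), numeric(1))
  sol <- wham_solve(C, hx, N, beta, tolerance, max_iter)
  denom <- as.vector(crossprod(C, N * exp(beta * sol$f)))  # per x-bin
  H <- matrix(0L, n_bins_x, n_bins_y)
  for (w in data$windows) {
    bx <- findInterval(w$x, xedges, rightmost.closed = TRUE, all.inside = TRUE)
    by <- findInterval(w$y, yedges, rightmost.closed = TRUE, all.inside = TRUE)
    H <- H + matrix(tabulate((by - 1L) * n_bins_x + bx,
                             nbins = n_bins_x * n_bins_y),
                    n_bins_x, n_bins_y)
  }
  P <- H / denom    # recycles denom down the x axis
  Fxy <- ifelse(P > 0, -log(P) / beta, NA_real_)
  Fxy <- Fxy - min(Fxy, na.rm = TRUE)
  structure(list(x_centers = xcenters, y_centers = ycenters,
                 free_energy = Fxy, n_samples = H,
                 offsets = sol$f, iterations = sol$iterations,
                 temperature = data$temperature, beta = beta),
            class = "PmfSurface")
}

#' Marginalise a 2D PMF over the auxiliary coordinate
#'
#' F(x) = -kT ln sum_y exp(-F(x, y)/kT), re-anchored to min 0; x-bins with
#' no defined cells stay NA.
#'
#' @param surface `PmfSurface`.
#' @return data.frame: `bin_center`, `free_energy`.
#' @export
marginalize_pmf <- function(surface) {
  beta <- surface$beta
  w <- exp(-beta * surface$free_energy)
  s <- rowSums(w, na.rm = TRUE)
  s[apply(is.na(surface$free_energy), 1, all)] <- NA
  Fx <- -log(s) / beta
  Fx <- Fx - min(Fx, na.rm = TRUE)
  data.frame(bin_center = surface$x_centers, free_energy = Fx)
}

#' Monte-Carlo bootstrap errors for a 1D PMF
#'
#' Within each window the sample series is resampled with replacement in
#' blocks (block length > 1 respects autocorrelation), WHAM is re-run per
#' replicate on the same binning grid, each replicate is re-anchored at
#' its minimum, and the per-bin error is the standard deviation across
#' replicates.
#'
#' @param data `UmbrellaDataset`.
#' @param n_bins,tolerance,max_iter as in [wham_1d()].
#' @param n_replicates bootstrap replicates (>= 20).
#' @param block_length resampling block length, samples.
#' @param seed RNG seed.
#' @return The [wham_1d()] profile of the original data with an added
#'   `error` column (kcal/mol).
#' @export
bootstrap_errors <- function(data, n_bins = 1000L, tolerance = 1e-4,
                             max_iter = 100000L, n_replicates = 20L,
                             block_length = 1L, seed = 1L) {
  if (n_replicates < 20L) stop("use at least 20 bootstrap replicates")
  base <- wham_1d(data, n_bins = n_bins, tolerance = tolerance,
                  max_iter = max_iter)
  rng <- range(base$edges)
  set.seed(seed)
  reps <- matrix(NA_real_, n_replicates, n_bins)
  for (r in seq_len(n_replicates)) {
    boot <- data
    for (k in seq_along(boot$windows)) {
      x <- boot$windows[[k]]$x
      n <- length(x)
      bl <- min(block_length, n)
      nblocks <- ceiling(n / bl)
      starts <- sample.int(n - bl + 1L, nblocks, replace = TRUE)
      idx <- as.vector(outer(0:(bl - 1L), starts, `+`))[seq_len(n)]
      boot$windows[[k]]$x <- x[idx]
    }
    prof <- suppressWarnings(
      wham_1d(boot, n_bins = n_bins, tolerance = tolerance,
              max_iter = max_iter, range = rng))
    reps[r, ] <- prof$profile$free_energy
  }
  err <- apply(reps, 2, stats::sd, na.rm = TRUE)
  err[colSums(!is.na(reps)) < 2L] <- NA_real_
  base$profile$error <- err
  base$n_replicates <- n_replicates
  base$block_length <- block_length
  base
}
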