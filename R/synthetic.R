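## Synthetic-data generators: everything an MD engine would normally supply.
##
## * harmonic (multivariate-normal) ensembles around a mean structure with a
##   planted covariance -- stand-in for equilibrated NPT ensembles;
## * Metropolis-sampled umbrella windows from analytic 1D potentials, with
##   an optional conditionally-Gaussian auxiliary coordinate for 2D WHAM;
## * furanose ring torsions at prescribed pseudorotation phase/amplitude;
## * a deterministic toy two-domain protein + single-stranded RNA complex.

#' Sample a harmonic (Gaussian) ensemble around a mean structure
#'
#' Frames are mean + multivariate-normal displacements with a planted
#' covariance, either a full 3n x 3n matrix (Angstrom^2) or per-atom
#' isotropic variances.  Deterministic given `seed`.
#'
#' @param mean_structure `Structure` supplying the mean coordinates.
#' @param covariance full 3n x 3n symmetric PSD matrix (Angstrom^2), or
#'   `NULL` to use `variances`.
#' @param variances per-atom isotropic variance(s), Angstrom^2 per
#'   coordinate; recycled over atoms.  Ignored when `covariance` is given.
#' @param n_frames number of frames (>= 2).
#' @param seed integer RNG seed.
#' @param timestep ps between frames (metadata only).
#' @return A `Trajectory`.
#' @export
sample_harmonic_ensemble <- function(mean_structure, covariance = NULL,
                                     variances = NULL, n_frames,
                                     seed = 1L, timestep = 2) {
  stopifnot(inherits(mean_structure, "Structure"))
  n <- n_atoms(mean_structure)
  if (n_frames < 2L) stop("n_frames must be >= 2")
  set.seed(seed)
  mu <- as.vector(t(mean_structure$xyz))
  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    if (!all(dim(covariance) == 3L * n))
      stop("covariance must be 3n x 3n")
    if (max(abs(covariance - t(covariance))) > 1e-8)
      stop("covariance must be symmetric")
    ev <- eigen(covariance, symmetric = TRUE)
    lam <- ev$values
    if (min(lam) < -1e-8 * max(abs(lam)))
      stop(sprintf("covariance is not positive semi-definite (smallest eigenvalue %.3g)",
                   min(lam)))
    lam <- pmax(lam, 0)
    L <- ev$vectors %*% diag(sqrt(lam), length(lam))
    Z <- matrix(stats::rnorm(n_frames * 3L * n), nrow = n_frames)
    disp <- Z %*% t(L)
  } else {
    v <- rep_len(if (is.null(variances)) 0 else variances, n)
    if (any(v < 0)) stop("variances must be non-negative")
    sd3 <- rep(sqrt(v), each = 3L)
    disp <- matrix(stats::rnorm(n_frames * 3L * n), nrow = n_frames)
    disp <- sweep(disp, 2, sd3, `*`)
  }
  xyz <- sweep(disp, 2, mu, `+`)
  new_trajectory(mean_structure, xyz, timestep = timestep)
}

#' Analytic 1D potentials for umbrella-sampling tests
#'
#' Constructors return a `PotentialSpec`: a list with a `form` tag and an
#' energy function `u(x)` in kcal/mol (x in Angstrom).
#'
#' @param k harmonic force constant, kcal/mol/A^2.
#' @param x0 minimum position, Angstrom.
#' @return A `PotentialSpec`.
#' @export
potential_harmonic <- function(k, x0) {
  structure(list(form = "harmonic", k = k, x0 = x0,
                 u = function(x) 0.5 * k * (x - x0)^2),
            class = "PotentialSpec")
}

#' @rdname potential_harmonic
#' @export
potential_flat <- function() {
  structure(list(form = "flat", u = function(x) rep(0, length(x))),
            class = "PotentialSpec")
}

#' @rdname potential_harmonic
#' @param barrier barrier height of the double well, kcal/mol.
#' @param half_sep half-distance between the two minima, Angstrom.
#' @param center midpoint between the wells, Angstrom.
#' @export
potential_double_well <- function(barrier, half_sep, center = 0) {
  structure(list(form = "double_well", barrier = barrier,
                 half_sep = half_sep, center = center,
                 u = function(x) {
                   s <- ((x - center)^2 - half_sep^2) / half_sep^2
                   barrier * s^2
                 }),
            class = "PotentialSpec")
}

#' @rdname potential_harmonic
#' @param x,u tabulated abscissae (Angstrom) and energies (kcal/mol);
#'   interpolated with a natural spline, extrapolated linearly.
#' @export
potential_tabulated <- function(x, u) {
  fn <- stats::splinefun(x, u, method = "natural")
  structure(list(form = "tabulated", x = x, utab = u, u = fn),
            class = "PotentialSpec")
}

#' The umbrella window layout used throughout
#'
#' Fifteen window centres: 10.5 to 15 Angstrom in 0.5 A steps, then 16 to
#' 20 in 1 A steps, all with the same elastic constant (default
#' 5 kcal/mol/A^2).
#'
#' @param force_constant bias spring constant, kcal/mol/A^2.
#' @param n_samples retained samples per window.
#' @param burn_in discarded equilibration samples per window.
#' @param seed base RNG seed; window i uses seed + i.
#' @return data.frame with one row per window: `center`,
#'   `force_constant`, `n_samples`, `burn_in`, `seed`.
#' @export
umbrella_window_layout <- function(force_constant = 5, n_samples = 5000L,
                                   burn_in = 500L, seed = 1L) {
  centers <- c(seq(10.5, 15, by = 0.5), seq(16, 20, by = 1))
  data.frame(center = centers, force_constant = force_constant,
             n_samples = n_samples, burn_in = burn_in,
             seed = seed + seq_along(centers))
}

## Single-particle Metropolis with uniform proposals; the proposal width is
## auto-tuned towards 30-50% acceptance during burn-in only, so the
## post-burn-in chain satisfies detailed balance for the target
## exp(-beta * [U(x) + 0.5 k (x - c)^2]).
metropolis_window <- function(ufun, center, kspring, n_keep, burn_in,
                              beta, seed) {
  set.seed(seed)
  e <- function(x) ufun(x) + 0.5 * kspring * (x - center)^2
  x <- center
  ex <- e(x)
  width <- if (kspring > 0) 2 / sqrt(beta * kspring) else 1
  n_tot <- burn_in + n_keep
  keep <- numeric(n_keep)
  acc_win <- 0L; n_win <- 0L; n_acc_total <- 0L
  for (i in seq_len(n_tot)) {
    prop <- x + stats::runif(1, -width, width)
    ep <- e(prop)
    if (stats::runif(1) < exp(-beta * (ep - ex))) {
      x <- prop; ex <- ep
      acc_win <- acc_win + 1L
      if (i > burn_in) n_acc_total <- n_acc_total + 1L
    }
    n_win <- n_win + 1L
    if (i <= burn_in && n_win == 50L) {
      rate <- acc_win / n_win
      if (rate > 0.5) width <- width * 1.25
      else if (rate < 0.3) width <- width / 1.25
      acc_win <- 0L; n_win <- 0L
    }
    if (i > burn_in) keep[i - burn_in] <- x
  }
  list(x = keep, acceptance = n_acc_total / max(1L, n_keep))
}

#' Sample umbrella-sampling windows from an analytic potential
#'
#' Each window holds Metropolis samples from
#' exp(-beta * \[U(x) + k/2 (x - x0)^2\]) after discarding `burn_in` steps.
#' Optionally an auxiliary coordinate y is emitted from the conditional law
#' y | x ~ Normal(m(x), s^2) -- the stand-in for an unbiased second
#' coordinate (e.g. an RMSD) in 2D WHAM tests.
#'
#' @param potential a `PotentialSpec`.
#' @param windows data.frame as from [umbrella_window_layout()].
#' @param temperature Kelvin.
#' @param aux optional list `list(mean_fn = function(x) ..., sd = s)`
#'   defining the auxiliary coordinate law.
#' @param timestep ps between retained samples (metadata for output files).
#' @return An `UmbrellaDataset`: list with `windows` (each holding
#'   `center`, `force_constant`, `x`, optionally `y`, `acceptance`) and
#'   `temperature`.
#' @export
sample_umbrella_windows <- function(potential, windows, temperature = 300,
                                    aux = NULL, timestep = 2) {
  stopifnot(inherits(potential, "PotentialSpec"))
  beta <- 1 / (.kB * temperature)
  wl <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    if (w$n_samples < 1L) stop(sprintf("window %d is empty", i))
    if (w$force_constant < 0) stop("force constants must be >= 0")
    mw <- metropolis_window(potential$u, w$center, w$force_constant,
                            w$n_samples, w$burn_in, beta, w$seed)
    if (mw$acceptance < 0.05 || mw$acceptance > 0.95)
      warning(sprintf("window %d (center %.2f A): acceptance rate %.2f outside [0.05, 0.95]",
                      i, w$center, mw$acceptance))
    y <- NULL
    if (!is.null(aux)) {
      set.seed(w$seed + 1000003L)
      y <- stats::rnorm(length(mw$x), mean = aux$mean_fn(mw$x), sd = aux$sd)
    }
    wl[[i]] <- list(center = w$center, force_constant = w$force_constant,
                    x = mw$x, y = y, acceptance = mw$acceptance,
                    timestep = timestep)
  }
  structure(list(windows = wl, temperature = temperature),
            class = "UmbrellaDataset")
}

#' @export
print.UmbrellaDataset <- function(x, ...) {
  cat(sprintf("UmbrellaDataset: %d windows, T = %g K, %s auxiliary coordinate\n",
              length(x$windows), x$temperature,
              if (is.null(x$windows[[1]]$y)) "no" else "with"))
  invisible(x)
}

#' Write / read an umbrella dataset as plain-text window files
#'
#' Each window becomes a whitespace-separated file `window_<i>.dat` with
#' columns `time_ps x [y]`, plus a manifest `windows.tsv` (comment header
#' carries the temperature) listing file, center and force constant.
#'
#' @param data `UmbrellaDataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_umbrella_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(data$windows))
  for (i in seq_along(data$windows)) {
    w <- data$windows[[i]]
    files[i] <- sprintf("window_%02d.dat", i)
    t_ps <- (seq_along(w$x) - 1L) * w$timestep
    m <- if (is.null(w$y)) cbind(t_ps, w$x) else cbind(t_ps, w$x, w$y)
    utils::write.table(format(m, digits = 10, trim = TRUE, scientific = FALSE),
                       file.path(dir, files[i]),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  manifest <- file.path(dir, "windows.tsv")
  con <- file(manifest, "wt")
  writeLines(sprintf("# temperature_K\t%g", data$temperature), con)
  writeLines("file\tcenter\tforce_constant", con)
  for (i in seq_along(data$windows)) {
    w <- data$windows[[i]]
    writeLines(sprintf("%s\t%g\t%g", files[i], w$center, w$force_constant), con)
  }
  close(con)
  invisible(manifest)
}

#' @rdname write_umbrella_dataset
#' @param manifest path to a `windows.tsv` manifest.
#' @export
read_umbrella_dataset <- function(manifest) {
  lines <- readLines(manifest)
  hdr <- grep("^#", lines, value = TRUE)
  temperature <- 300
  th <- grep("temperature_K", hdr, value = TRUE)
  if (length(th)) temperature <- as.numeric(strsplit(th[1], "\t")[[1]][2])
  tab <- utils::read.delim(manifest, comment.char = "#",
                           stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  wl <- lapply(seq_len(nrow(tab)), function(i) {
    m <- as.matrix(utils::read.table(file.path(dir, tab$file[i])))
    list(center = tab$center[i], force_constant = tab$force_constant[i],
         x = m[, 2],
         y = if (ncol(m) >= 3) m[, 3] else NULL,
         acceptance = NA_real_,
         timestep = if (nrow(m) > 1) m[2, 1] - m[1, 1] else 1)
  })
  structure(list(windows = wl, temperature = temperature),
            class = "UmbrellaDataset")
}

#' Endocyclic ring torsions at a prescribed sugar pucker
#'
#' Inverts the pseudorotation analysis: nu_j = tau_m * cos(P + 144 (j - 2))
#' degrees for j = 0..4, so nu2 = tau_m cos(P) (the nu2-based
#' Altona-Sundaralingam convention; see [pucker_from_torsions()]).
#'
#' @param phase_P pseudorotation phase, degrees.
#' @param amplitude_tau_m pucker amplitude, degrees (>= 0).
#' @return Named numeric vector nu0..nu4, degrees.
#' @export
make_pucker_torsions <- function(phase_P, amplitude_tau_m) {
  if (amplitude_tau_m < 0) stop("amplitude must be >= 0")
  j <- 0:4
  nu <- amplitude_tau_m * cos((phase_P + 144 * (j - 2)) * pi / 180)
  names(nu) <- paste0("nu", j)
  nu
}

## --- toy protein-RNA complex -------------------------------------------

helix_ca <- function(n, radius = 2.3, rise = 1.5, turn = 100) {
  t <- (seq_len(n) - 1L)
  cbind(radius * cos(t * turn * pi / 180),
        radius * sin(t * turn * pi / 180),
        t * rise)
}

#' Build a deterministic toy protein-RNA complex
#'
#' A ~30-residue two-segment C-alpha-resolution "protein" (two helical
#' segments joined by a linker, echoing a two-domain fold) plus a
#' 7-nucleotide single-stranded RNA carrying P, O5', C4' and N1/N9
#' pseudo-atoms, laid into the inter-helix cleft so that at least three
#' protein C-alpha atoms sit within 4.5 Angstrom of RNA atoms.  Coordinates
#' are deterministic given `seed` (a small seeded jitter breaks exact
#' symmetries).
#'
#' @param seed integer seed for the jitter.
#' @return A `Structure` with protein chain "A" (residues 101-130) and RNA
#'   chain "B" (nucleotides 1-7, sequence ACUAACA).
#' @export
build_toy_complex <- function(seed = 1L) {
  set.seed(seed)
  n1 <- 13L; nl <- 4L; n2 <- 13L
  h1 <- helix_ca(n1)
  ## linker arcs away, second helix runs back antiparallel, offset in x
  lk <- cbind(seq(2.8, 6.5, length.out = nl),
              seq(0.5, 1.5, length.out = nl),
              max(h1[, 3]) + seq(1.2, 3.2, length.out = nl))
  h2 <- helix_ca(n2)
  h2 <- cbind(8.4 - h2[, 1], h2[, 2] + 1.0, max(lk[, 3]) - h2[, 3] * 1.0)
  prot <- rbind(h1, lk, h2)
  nres <- nrow(prot)
  aa <- rep(c("ALA", "GLY", "SER", "VAL", "LEU"), length.out = nres)
  prot_atoms <- data.frame(
    atom_name = "CA", residue_seq = 100L + seq_len(nres),
    residue_name = aa, chain_id = "A", element = "C",
    stringsAsFactors = FALSE)

  ## RNA threaded through the cleft between the two helices (x ~ 4.2),
  ## bases pointing at the protein surface
  seqrna <- c("A", "C", "U", "A", "A", "C", "A")
  nnt <- length(seqrna)
  rna_atoms <- NULL; rna_xyz <- NULL
  for (i in seq_len(nnt)) {
    z <- 1.0 + (i - 1) * 2.6
    px <- 5.6; py <- -2.6
    p <- c(px, py, z)
    o5 <- c(px - 0.6, py + 1.1, z + 0.4)
    c4 <- c(px - 1.2, py + 2.0, z + 0.9)
    base <- c(px - 2.4, py + 3.2, z + 1.2)   # toward the helices
    anchor <- if (seqrna[i] %in% c("A", "G")) "N9" else "N1"
    rna_atoms <- rbind(rna_atoms, data.frame(
      atom_name = c("P", "O5'", "C4'", anchor),
      residue_seq = i, residue_name = seqrna[i], chain_id = "B",
      element = c("P", "O", "C", "N"), stringsAsFactors = FALSE))
    rna_xyz <- rbind(rna_xyz, p, o5, c4, base)
  }
  xyz <- rbind(prot, rna_xyz)
  xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = 0.05), ncol = 3)
  atoms <- rbind(prot_atoms, rna_atoms)
  new_structure(atoms, xyz)
}
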