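---
title: "Methods: trajectory statistics, dynamical networks and WHAM in stardynet"
author: "stardynet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory statistics, dynamical networks and WHAM in stardynet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stardynet)
```

`stardynet` packages the analysis stack commonly applied to
molecular-dynamics ensembles of protein–RNA complexes — the motivating
system being a STAR-family KH–QUA2 domain bound to a short single-stranded
mRNA.  This vignette explains the models and conventions each stage uses,
the parameters that matter, the synthetic-data generators the tests rely
on, and the design decisions taken where the field's conventions are
genuinely ambiguous.

## Coordinates, selections, units

Structures carry a dense internal 0-based atom index; author residue
numbering (e.g. 69–204 for a KH–QUA2 construct) is preserved as data and
never used as an array index.  Trajectories are frame stacks over a fixed
topology, with an explicit timestep in ps (typical analysis strides are
2 ps; PCA pipelines often pool more finely, so the stride is an argument,
never a constant).  All lengths are Å, energies kcal/mol, temperatures K;
the Boltzmann constant is 0.0019872041 kcal/mol/K throughout.

Atom groups are resolved by a small selection language (`name`, `resname`,
`chain`, `resid a to b`, `within R of <sel>`, boolean combinators).  Two
conventions are fixed once and tested at their boundaries: every distance
criterion in the package is a **closed** interval (≤ cutoff), and
`within R of S` is evaluated on one designated reference frame — the
crystal structure, matching how neighbourhood-based groups (e.g. "Cα atoms
within 5 Å of the RNA") are defined in practice.  Distances are plain
Euclidean: analyses assume an already-imaged, whole solute, and no
periodic-boundary handling is attempted (a documented limitation).

## Superposition and fluctuation statistics

Rigid-body fits minimise the selection RMSD via the Kabsch SVD
construction restricted to proper rotations, so mirror images retain a
positive residual.  RMSD series fit each frame on one selection and
evaluate on another (domain-wise RMSD is just a different `calc_sel`).

RMSF uses the fluctuation around the trajectory-average structure.  The
"fit to the average you only obtain after fitting" circularity is resolved
by a two-pass iterated fit (fit to a provisional reference, re-average,
refit); in practice the second pass changes the reference by far less than
the statistical noise of any finite ensemble.  Whether to fit to the
average or the crystal is not universally agreed; the average is the
default and an external reference is an argument.  The Debye–Waller
conversion RMSF = √(3B/8π²) and its inverse are exact formulas.

The running-average convergence diagnostic (RAC) computes, for each window
length w, running-average structures over all contiguous windows (after
fitting all frames to the global average), RMS-fits each to the global
average and reports the mean RMSD.  At the full trajectory length the
running average *is* the global average, so RAC is exactly zero there; on
a stationary uncorrelated ensemble RAC(w) ∝ √(1/w − 1/F) (F frames), which
reduces to the familiar 1/√w decay for w ≪ F.  The tests exploit both
identities.

## Native contacts and occupancies

A native contact is a Cα pair within 8 Å in the reference structure whose
residues are separated by more than two sequence positions.  Per frame,
Q is the fraction of native pairs still within the native cutoff —
re-evaluated at the same 8 Å cutoff, the simplest reading of the
definition — and Qs softens the step with a Gaussian penalty on the
deviation from the native distance.  The penalty width grows weakly with
sequence separation, σ_ij = (1 + |i−j|)^0.15 Å, the convention of the
standard native-similarity implementations; it is configurable because
only "a Gaussian penalty" is canonical, not the width model.  Contact
counts (default 6 Å) and interface occupancies (any cross-group heavy-atom
distance ≤ 4.5 Å, flagged at ≥ 75 % of frames) reuse the same closed-bound
conventions.

SASA is Shrake–Rupley sphere sampling with a deterministic golden-spiral
point set (960 points ≈ 1 % accuracy on an isolated sphere), element radii
C 1.70 / N 1.55 / O 1.52 / P 1.80 / S 1.80 Å and a 1.4 Å water probe.

## DCCM and PCA

The cross-correlation map uses full 3D displacement dot products,
C_ij = ⟨Δr_i·Δr_j⟩/(⟨Δr_i²⟩^½⟨Δr_j²⟩^½), not per-axis correlations, with
displacements taken after an optional rigid-body fit to the (iterated)
average.  Frames from several runs are pooled before the covariance by
default — per-run averaging is a flag, since either reading of "averaged
over all conformations" is defensible.  Values with |C| ≥ 0.25 are
conventionally displayed as correlated/anti-correlated, the band between
as weak.  Zero-variance nodes (fixed atoms) get diagonal 1 and
off-diagonal 0 with a warning rather than NaNs.

PCA diagonalises the 3n × 3n covariance of fitted coordinates.  Two exact
identities are asserted in the tests — eigenvalue sum = covariance trace,
and per-component projection variance = eigenvalue — and eigenvector signs
are fixed (largest-magnitude component positive) so results are
reproducible.

## Dynamical networks

Nodes: one per protein residue anchored at Cα; two per nucleotide — the
base anchored at N1 (pyrimidines) or N9 (purines) and the sugar–phosphate
group anchored at P.  The contact criterion is evaluated over the heavy
atoms each node *owns* (base ring vs sugar+phosphate atoms), because
4.5 Å is a heavy-atom contact scale; anchors only name and place the node
and select its correlation row.  Neighbouring nodes — the two halves of
one nucleotide (glycosidic pair) and nodes of sequence-adjacent residues —
are never connected.  An edge is kept when the contact holds in at least
75 % of frames and is weighted w_ij = −log|C_ij| (|C| floored at 1e-6), so
strong correlation means short network distance; `1 − |C|` is available as
an alternative scheme.  The −log form is the convention of the established
network plugins in this field; the choice matters only monotonically for
shortest paths.

Shortest paths use Floyd–Warshall (the distances are checked exactly
against per-source Dijkstra from igraph on random graphs).  CPL is the
mean shortest-path distance over unordered **connected** pairs, with the
number of unreachable pairs reported — disconnection handling is not
standardised, so it is explicit here.  Girvan–Newman community detection
iteratively removes the maximum-betweenness edge (weighted betweenness
over the w distances; ties broken by lexicographic edge label for
determinism) down to the empty graph and returns the partition of maximum
modularity along the way; modularity is evaluated on the unweighted
contact graph because distance-like weights would invert its meaning.
The ΔCPL scan perturbs one node at a time — removing its incident edges
(node kept, isolated) or the node itself — and reports
CPL(perturbed) − CPL(baseline) over pairs connected in both graphs, plus
the count of collaterally disconnected pairs.

## Umbrella sampling and WHAM

The reaction coordinate is the distance between mass-weighted centres of
mass of two atom groups.  The bias is ½k(x−x₀)² with k the elastic
constant as given (a `half_spring` toggle covers the k(x−x₀)² convention
used by some codes).  The default window layout is fifteen centres from
10.5 to 15 Å in 0.5 Å steps then 16 to 20 Å in 1 Å steps, all with
k = 5 kcal/mol/Å² at 300 K.

1D WHAM iterates the window offsets f_k of the standard self-consistent
equations until max|Δf_k| < 10⁻⁴ kcal/mol over 1000 bins, then reports
F(x) = −kT ln p(x) anchored to min 0.  Empty bins stay NA — they are
unsampled, not zero.  Adjacent windows without histogram overlap trigger a
warning naming the gap; non-convergence is an error carrying the residual.

2D WHAM adds an *unbiased* auxiliary coordinate (in the motivating
application, an RMSD): since the bias depends only on x, the unbiased 2D
density is assembled directly from the converged 1D offsets, with the
denominator a function of the x-bin alone.  "500 bins" is interpreted as
the biased-axis count; the y-axis count is independent (default 100).
This construction makes the y-marginalised 2D PMF agree with the 1D PMF
on a shared grid almost exactly — the consistency check in the tests.

Bootstrap errors: within each window the series is resampled with
replacement in blocks (block length is the knob that respects
autocorrelation; full-length blocks reproduce the original series and give
exactly zero error, a tested limit), WHAM is re-run per replicate on the
same grid, each replicate is re-anchored at its minimum, and the per-bin
standard deviation across replicates is reported.

## Sugar pucker and pseudo-torsions

Ring torsions ν0…ν4 are measured over the O4′–C1′–C2′–C3′–C4′ cycle.  The
pseudorotation convention is Altona–Sundaralingam with the ν2-based
amplitude: ν_j = τ_m cos(P + 144°(j−2)).  Rather than the textbook
τ_m = ν2/cos P — singular at P = 90° — the analyzer inverts the model by
exact least-squares projection onto the cos/sin basis, which reproduces
generator inputs to machine precision over the whole wheel.  Conformer
classes are the ten 36° sectors (C3′-endo = [0°, 36°), O4′-endo =
[72°, 108°), C2′-endo = [144°, 180°), …); amplitudes below 10⁻³ degrees
leave the class undefined rather than arbitrary.  Cross-software phase
offsets of up to one sector near class boundaries are a known caveat of
pucker classification and are not resolved here.

η and θ pseudo-torsions follow the printed atom quadruples
η: C4′(i−1)–P(i)–C4′(i)–P(i+1), θ: P(i)–C4′(i)–P(i+1)–C4′(i+1); termini
lacking flanking atoms are flagged NA, never zero-filled.  All angles are
reported in (−180°, 180°].

## What the synthetic generators emulate — and what they do not

The package is validated against *planted structure*, because the
microsecond MD ensembles such analyses usually consume cannot be shipped
with a package or regenerated at desk scale:

* `sample_harmonic_ensemble` draws i.i.d. multivariate-normal frames
  around a mean structure with an arbitrary planted 3n × 3n covariance.
  This emulates the stationary fluctuations of an equilibrated ensemble —
  exactly the regime where DCCM, RMSF and PCA have closed-form answers —
  but has no kinetics, no anharmonicity and no conformational
  transitions.  Passing tests therefore certify the *estimators*, not the
  sampling quality of any real simulation.
* `sample_umbrella_windows` runs single-particle Metropolis sampling of
  exp(−β[U(x) + ½k(x−x₀)²]) per window, with the proposal width auto-tuned
  to 30–50 % acceptance during burn-in only (so the stationary
  distribution is untouched).  Only the stationary law matters for WHAM;
  dynamics are not emulated.  The auxiliary coordinate for 2D tests
  follows y | x ~ N(m(x), s²) — a stand-in law; whether a real RMSD
  coordinate is conditionally unimodal is unknown.
* `build_toy_complex` is a deterministic ~30-residue two-helix Cα
  "protein" plus a 7-nucleotide RNA carrying P/O5′/C4′ and N1/N9
  pseudo-atoms — just enough chemistry for selections, interfaces and the
  two-nodes-per-nucleotide network mapping, with a guaranteed ≥ 3-contact
  interface.  It is a synthetic fixture, not a model of any deposited
  structure.

## Problem sizes and numerical tolerances

The shipped tests and the validation script use sizes chosen so the whole
suite runs in well under an hour on one core while keeping sampling noise
far from the asserted bounds: 20 000 post-burn-in samples per window for
the 1D WHAM harmonic-recovery check (RMS error ≤ 0.2 kcal/mol observed
≈ 0.13–0.16), 8 000 per window for the 2D/1D consistency check
(≤ 0.1 kcal/mol observed < 10⁻³), 50 000 frames for the 60-node DCCM
recovery (max-abs error ≤ 0.05 observed ≈ 0.006), 2 000 frames for the
RMSF closed form (5 % tolerance, observed < 1 %), and 400-frame ensembles
for RAC scaling.  Two identities are asserted essentially to machine
precision: pucker round trips and graph-distance agreement with Dijkstra.

Numerical details worth knowing: WHAM offsets are normalised to f₁ = 0
each iteration; PMFs are anchored so the minimum over defined bins is
exactly 0; DCD files store float32, so coordinate round trips are exact
only to ~10⁻³ Å; demo TSV output goes through fixed-format rendering so
equal seeds give byte-identical files; and the rigid-body fit in RMSF/RAC
removes six quasi-degrees of freedom, biasing fluctuation estimates down
by O(1/n_atoms) — negligible at the ≥ 100-atom sizes used in the tests.

## Interfaces

Every stage is an exported function over plain R objects, and
`run_demo(seed, outdir)` chains them end to end on the synthetic fixtures,
writing one provenance-stamped TSV per analysis.  The package is a
library, not a shell tool: scripted use goes through R or `Rscript`, as in
`scripts/acceptance.R`, which recomputes all validation quantities from
scratch.

## Known limitations

No periodic-boundary imaging; no PSF/parameter topologies, velocities or
box vectors; Q/Qs widths beyond the default model are the user's choice;
SASA is single-structure (iterate for trajectory means); binding free
energies, MBAR-style estimators and restraint corrections are out of
scope for the WHAM module; and community detection on weighted graphs
inherits the usual caveat that modularity is resolution-limited.
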