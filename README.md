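# stardynet

Trajectory analysis, allosteric network analysis and umbrella-sampling free
energies for protein–RNA complexes, in R.

`stardynet` implements the complete analysis pipeline used to characterise
molecular-dynamics ensembles of RNA-binding proteins such as the STAR
(KH–QUA2) domain bound to a short single-stranded mRNA:

* **Deviation and fluctuation statistics** — Kabsch superposition, RMSD time
  series, per-residue RMSF, the Debye–Waller conversion
  RMSF = √(3B/8π²) between crystallographic B-factors and fluctuation
  amplitudes, and running-average convergence (RAC) curves.
* **Contact analysis** — native-contact sets (Cα pairs within 8 Å excluding
  two sequence neighbours), the fraction of native contacts
  Q = ⟨1[r_ij ≤ r_c]⟩ and its Gaussian-penalised relative
  Qs = ⟨exp(−(r_ij − r⁰_ij)²/2σ_ij²)⟩ with σ_ij = (1+|i−j|)^0.15 Å,
  per-frame contact counts (6 Å), protein–RNA interface occupancies
  (4.5 Å / 75 % criterion) and Shrake–Rupley solvent-accessible surface
  area.
* **Essential dynamics** — dynamic cross-correlation maps
  C_ij = ⟨Δr_i·Δr_j⟩ / (⟨Δr_i²⟩^½⟨Δr_j²⟩^½) on full 3D displacement dot
  products, and principal component analysis of the 3n × 3n Cα covariance.
* **Dynamical networks** — one node per protein residue (Cα anchor), two
  per nucleotide (base at N1/N9, sugar–phosphate at P); an edge joins
  non-neighbouring nodes in heavy-atom contact (≤ 4.5 Å) for ≥ 75 % of
  frames, weighted w_ij = −log|C_ij|.  All-pairs shortest paths by
  Floyd–Warshall, characteristic path length (CPL), Girvan–Newman
  community detection, and ΔCPL node/edge-removal perturbation scans.
* **WHAM free energies** — self-consistent 1D WHAM (1000 bins, 10⁻⁴
  tolerance, 300 K) and 2D WHAM along the biased reaction coordinate plus
  an unbiased auxiliary coordinate, with Monte-Carlo block-bootstrap error
  bars.  The reaction coordinate is the mass-weighted centre-of-mass
  distance between user-selected atom groups.
* **RNA backbone geometry** — signed dihedrals, sugar pseudorotation
  (phase P, amplitude τ_m, conformer classes C3'-endo … C2'-endo on the
  36° wheel) and η/θ pseudo-torsions over the C4'/P virtual backbone.
* **Synthetic data** — harmonic ensembles with planted covariance,
  Metropolis-sampled umbrella windows from analytic potentials, furanose
  torsions at prescribed pucker, and a deterministic toy protein–RNA
  complex, so that every analysis stage is testable against closed forms.

Structures are read from PDB files (alternate locations resolved by
occupancy), trajectories from CHARMM/NAMD DCD or multi-model PDB, and
atom groups are picked with a small selection language
(`"name CA and resid 69 to 204"`, `"within 5.0 of chain B"`).

## Worked example

```r
library(stardynet)

toy  <- build_toy_complex(seed = 1)                     # 30-res protein + 7-nt RNA
traj <- sample_harmonic_ensemble(toy, variances = 0.1,  # Gaussian ensemble
                                 n_frames = 200, seed = 2)
ca   <- select_atoms(toy, "name CA")

mean(rmsd_series(traj, toy, fit_sel = ca)$rmsd)
#> 0.530                                    # A, mean deviation from the mean structure

nc <- native_contacts(toy, ca, cutoff = 8, exclusion = 2)
qs <- q_series(traj, nc)
c(Q = mean(qs$q), Qs = mean(qs$qs))
#>     Q    Qs
#> 0.967 0.947                              # native contacts largely kept

net <- build_network(traj, toy)            # 44 nodes, 60 edges
shortest_paths_fw(net)$cpl
#> 11.853                                   # characteristic path length
communities_gn(net)
#> CommunityPartition: 14 communities, modularity 0.556

ud  <- sample_umbrella_windows(potential_harmonic(2, 14),
                               umbrella_window_layout(n_samples = 5000,
                                                      burn_in = 500, seed = 3))
pmf <- wham_1d(ud, n_bins = 1000, tolerance = 1e-4)
pmf$profile$bin_center[which.min(pmf$profile$free_energy)]
#> 14.08                                    # PMF minimum at the planted well (14 A)

pucker_from_torsions(make_pucker_torsions(162, 38.7))
#> Pucker: P = 162.00 deg, tau_m = 38.70 deg, C2'-endo
```

The numbers above mean: the harmonic ensemble fluctuates ~0.5 Å around its
mean; almost all crystal contacts persist (Q ≈ 0.97); the
correlation-weighted contact graph has a CPL of ≈ 11.9 in −log|C| units
and splits into communities along the two helical segments and the RNA;
WHAM recovers the minimum of the planted harmonic potential at the right
reaction-coordinate value; and the pseudorotation analysis inverts the
torsion generator exactly, classifying phase 162° as C2'-endo.

`run_demo(seed, outdir)` executes the whole pipeline end to end on the
synthetic fixtures and writes one TSV per analysis (deterministic and
byte-reproducible for a fixed seed).

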