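---
title: "Generating and benchmarking transition-state conformer ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and benchmarking transition-state conformer ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racerts)
```

## The problem

Activation energies computed from a single transition-state (TS) guess are
only as good as that guess: the TS of a flexible molecule is itself an
ensemble of conformers, and the lowest-energy member — not the first one a
chemist happens to optimise — determines the barrier. Ground-state conformer
generators cannot be applied directly because the reaction center is not a
molecule: it has partial bonds, unusual valences and a geometry that exists
only at the saddle point. `racerts` generates TS conformer ensembles by
treating the reaction center as a rigid body and sampling everything else.

The user supplies three things: a 3D TS guess (xyz, in Å), the total charge,
and the 1-based indices of the reaction-center atoms. Optionally a
reactant- or product-side SMILES can be given as a bonding template.

**All atom indices in files, CLI arguments and APIs are 1-based**, matching
xyz body line order. (An early design sketch used 0-based indices for
consistency with Python cheminformatics toolkits; in an R package that
convention would invite off-by-one errors in every user script, so the
package is uniformly 1-based and says so everywhere.)

## The procedure

1. **Topology.** A bond graph is perceived from geometry (bond iff distance
   ≤ 1.3 × the sum of Pyykkö covalent radii, with a 0.4 Å overlap floor).
   Bond orders and formal charges are assigned where a valence model exists;
   at reaction-center atoms *any* internally consistent assignment is
   accepted, because those atoms never display textbook valences and their
   geometry is constrained anyway. When no assignment exists — transition
   metals are the usual culprits — perception degrades to connectivity-only,
   never an error. A SMILES template, when given, is mapped onto the heavy
   atoms by a backtracking maximum-common-bond search (element labels must
   match; hydrogens follow their parent heavy atom; ties broken by
   depth-first order since a template has no coordinates to measure
   displacement against) and its bond orders and formal charges are copied
   over; forming/breaking bonds present only in 3D stay as
   connectivity-only bonds.

2. **Frozen atoms.** The reaction center plus the immediate bonded
   neighbours of every reaction-center atom. Nothing further: freezing
   second shells was considered and rejected as it removes exactly the
   flexibility the ensemble is supposed to explore.

3. **Constrained distance geometry.** Reaction-center positions and *all*
   pairwise distances within the frozen set are fixed (tolerance 0.01 Å, a
   near-exact bound standing in for exact fixing). The bounds matrix takes
   1-2 and 1-3 distances from the input geometry (bond lengths and angles
   are not the degrees of freedom of interest), leaves torsions free between
   a van-der-Waals floor and the bond-path length, and is triangle-smoothed.
   Random distance matrices are embedded by metric-matrix
   eigendecomposition, polished against the bounds by gradient descent,
   superposed onto the input frozen core, and accepted only if every fixed
   distance is within tolerance + 0.1 Å, every reaction-center atom lies
   within 0.2 Å of its fixed position, and the signed volume of the most
   non-planar frozen quadruple has the input's sign (distance geometry is
   chirality-blind; mirror images are rejected and re-sampled; planar cores
   skip the check). The number of initial conformers is
   `conf_factor × max(1, free rotatable bonds)` with `conf_factor = 30` by
   default — the knob scales with flexibility and never drops below
   `conf_factor` for rigid systems.

4. **Refinement.** Each conformer is minimised with the first engine in the
   chain that accepts all its atom types: an organic-elements force-field
   tier first, a universal tier (default parameters for anything in the
   radius table) as fallback, a topology-free mock pair potential last so
   the pipeline runs anywhere. Frozen atoms are simply not optimisation
   variables, so they are fixed *exactly* — zero drift, not small drift.
   L-BFGS-B, at most 2000 steps, projected-gradient tolerance 1e-4;
   non-converged members are kept but flagged, matching the permissive
   pruning philosophy. External engines (e.g. tight-binding binaries) plug
   in through the `energy_engine()` adapter contract; without one the
   pipeline runs exactly as the "no post-optimisation" variant.

5. **Pruning.** Single-point re-ranking (stable sort), then an energy window
   of 20 kcal/mol above the minimum — deliberately conservative because
   force-field energies are inaccurate; 6 kcal/mol is the window used after
   tight-binding post-optimisation and when building combined reference
   ensembles — then greedy duplicate removal: sweeping upward in energy, a
   conformer is dropped iff its heavy-atom RMSD to an already-retained
   member is < 0.125 Å. Keep-lowest-first resolves "RMSD to a lower-energy
   conformer" deterministically; energy ties break by input order. RMSD is
   Kabsch superposition with determinant correction (no reflections:
   enantiomeric conformers are distinct chemical objects) and no
   atom-permutation canonicalisation (heavy-only RMSD already removes the
   worst hydrogen ambiguity).

## The benchmark metrics

The metrics module reimplements the evaluation framework used to compare TS
conformer generators, operating on user-supplied ensembles:

* **comp_cost** — mean over reactions of the wall-time ratio to a reference
  method.
* **combine_ensembles** — concatenation of all methods' ensembles, pruned at
  6 kcal/mol and 0.125 Å: the best available approximation of the complete
  reference ensemble.
* **space exploration** — the combined ensemble is Butina-clustered
  (sphere exclusion, 1.0 Å heavy-atom RMSD radius; ties in neighbour count
  break to the lowest index, making the partition deterministic). A method
  conformer counts as present iff it is *identical* to a combined member
  (RMSD < 0.125 Å **and** |ΔE| < 0.05 kcal/mol — conformers pruned away in
  the combination step count as absent). Precision = matched fraction of the
  method's conformers, recall = fraction of clusters hit, F1 their harmonic
  mean (0 when both vanish).
* **space distribution** — Jensen–Shannon divergence between the RMSD-to-input
  distributions of the method and the combined ensemble, on shared
  fixed-width 0.25 Å bins spanning [0, max), base-2 logarithms so the value
  lies in [0, 1], `0·log 0 = 0`. Neither the binning nor the log base is
  canonical; both are package conventions and configurable.
* **success rate, top-N accuracy** — validity labels and rankings are
  inputs; rankings are the *generator's own* energy order, because that is
  what a high-throughput workflow would consume.
* **ΔE‡ statistics** — lowest-conformer error per method, and the
  Boltzmann-averaged error of representative-conformer subsets (selection of
  representatives is external; subsets are accepted as given, up to the
  conventional 10 per method). Boltzmann averaging shifts by the minimum for
  numerical safety and defaults to 298.15 K — no temperature is canonical
  for the benchmark, so room temperature is used.

## What the synthetic fixtures do and do not establish

`make_sn2_toy(tail_length)` builds a pentacoordinate SN2-like TS — axial
fluoride (1.80 Å) and chloride (2.10 Å) exactly collinear through the
central carbon, two equatorial hydrogens, and an equatorial n-alkyl tail
contributing `tail_length − 1` free rotors (standard 1.54/1.09 Å bonds,
tetrahedral angles). Its rotamer inventory is enumerable by an independent
rigid torsion scan (`torsion_scan_oracle()`), which is what the embedding
tests are checked against. `make_metal_toy()` is a square-planar Pd
surrogate that deterministically exercises the connectivity-only and
universal-force-field fallback paths. A pathological two-atom overlap
fixture exercises the geometry-error path.

These toys validate *contracts* — constraint satisfaction, chirality
preservation, determinism, pruning and metric algebra — not chemistry. A
green suite does not establish that the force field ranks real TS conformers
correctly (the functional form is generic: harmonic bonds at radius-sum
lengths, cosine-harmonic angles, threefold torsions, soft Lennard-Jones),
nor that the ensemble of a real reaction is exhaustive.

One acceptance check is deliberately red and worth understanding: on the
`tail_length = 3` toy, the number of Butina clusters (1.0 Å) found in the
final ensemble must reach the torsion-scan minima count (3). It never does —
not because sampling misses rotamers (the embedding visits all basins; the
pre-refinement torsion histogram shows it) but because the toy is small:
rotating the short tail moves one or two of six heavy atoms, so rotamer
states sit 0.6–1.0 Å apart in heavy-atom RMSD, inside the 1.0 Å
sphere-exclusion radius that is calibrated for full-sized transition states.
Sphere exclusion merges them into one cluster regardless of `conf_factor`.
The monotonicity half of the same criterion (more initial conformers never
discover fewer clusters) holds.

## Numerical choices and limitations

* Fixed-distance tolerance 0.01 Å; embedding acceptance slack
  tolerance + 0.1 Å; reaction-center placement 0.2 Å after superposition.
* Embedding retries up to 10 × the requested count; chirality rejection
  costs roughly every second attempt on chiral cores.
* The bounds matrix freezes input bond lengths and angles (±0.02/±0.06 Å);
  conformers therefore differ essentially by torsions, which refinement then
  relaxes. Ring conformational sampling is limited accordingly.
* No symmetry-aware RMSD: a methyl rotation by 120° is a distinct conformer
  until pruning merges it by geometry. Heavy-only RMSD hides pure-hydrogen
  rotamers from the duplicate filter by design.
* SMILES support covers the organic subset, brackets with charges and
  explicit H counts, rings (including `%nn`), branches and dots; stereo
  descriptors are ignored. The template mapper is exponential in the worst
  case and intended for template-sized molecules.
* Energies are kcal/mol and coordinates Å at every module boundary; any
  hartree-native backend converts inside its adapter.
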