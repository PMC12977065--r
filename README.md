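# racerts — transition-state conformer ensembles by constrained distance geometry

Computing an activation energy from a single transition-state (TS) guess is a
gamble: for flexible molecules the TS is an ensemble, and the barrier is set
by its lowest-energy conformer. Ground-state conformer generators cannot be
pointed at a TS — the reaction center has partial bonds and valences no
force field or perception toolkit understands. `racerts` is for
computational chemists running (high-throughput) barrier calculations: it
takes one TS guess and returns a TS conformer ensemble, cheaply enough to
sit in front of every TS optimisation.

## Method in brief

Given a TS guess with coordinates $X$, total charge, and reaction-center
atom indices $\mathcal{RC}$ (1-based):

1. **Frozen core.** $\mathcal{F} = \mathcal{RC} \cup N(\mathcal{RC})$ —
   the reaction center and its immediate bonded neighbours.
2. **Constrained distance geometry.** Positions $x_a$ for
   $a \in \mathcal{RC}$ and all pairwise distances $d_{ij}$,
   $i,j \in \mathcal{F}$, are fixed to their input values (±0.01 Å);
   torsional degrees of freedom are sampled by embedding random distance
   matrices drawn from a triangle-smoothed bounds matrix. Mirror images of
   the frozen core are rejected. $n_\text{conf} = \texttt{conf\_factor}
   \times \max(1, n_\text{rot})$ with `conf_factor = 30` by default.
3. **Refinement.** Each conformer is minimised with a classical force field
   under *exact* frozen-atom fixing (frozen coordinates are not optimisation
   variables); an organic parameter tier is tried first, a universal tier is
   the fallback for unrecognised atom types (metals, radical centers).
4. **Pruning.** Energy window $E - E_\min \le 20$ kcal/mol, then greedy
   deduplication: a conformer is removed iff its heavy-atom RMSD (Kabsch,
   proper rotations only) to a retained lower-energy conformer is
   < 0.125 Å.

The package also implements the standard benchmark metrics for comparing
conformer generators — normalised computational cost, combined reference
ensembles (6 kcal/mol / 0.125 Å), Butina clustering (1.0 Å), space
exploration $F_1 = 2\,\mathrm{PRE}\cdot\mathrm{REC}/(\mathrm{PRE}+
\mathrm{REC})$, Jensen–Shannon space distribution, success rate, top-1/top-5
accuracy, and $\Delta E^\ddagger$ statistics with Boltzmann averaging
(identity criterion: RMSD < 0.125 Å and $|\Delta E|$ < 0.05 kcal/mol) — plus
programmatic toy TS fixtures (a pentacoordinate SN2-like core and a
square-planar Pd surrogate) whose rotamer inventories are enumerable by a
brute-force torsion scan, so everything is testable offline.

## Worked example

```r
library(racerts)

toy <- make_sn2_toy(tail_length = 2)      # [F...CH(C2H5)...Cl]- toy TS
res <- generate_ts_conformers(toy$structure, toy$reaction_center,
                              conf_factor = 5, seed = 1)
res
#> <racerts_result> engine ff94: 5 embedded -> 5 in window -> 3 unique conformer(s)
#> <ts_ensemble> 3 conformer(s), energy-ranked
#>   relative energies (kcal/mol): 0.00, 0.59, 2.03

write_multi_xyz(res$ensemble, "ensemble.xyz")
```

Five embeddings of the one-rotor toy minimise into the three staggered
rotamer basins (the toy's brute-force rotamer count is
`toy$expected_rotamer_count == 3`); duplicates landing in the same basin are
pruned at 0.125 Å, leaving one conformer per basin. Relative force-field
energies (0, 0.59, 2.03 kcal/mol) separate the anti-like minimum from the
two gauche-like ones. Absolute energies are force-field numbers and only
their ordering and differences are meaningful.

## Command line

```sh
racerts run input.xyz --charge -1 --reaction-center 1,2,3 \
        [--smiles "CCCl.[F-]"] [--conf-factor 30] [--energy-window 20] \
        [--rmsd-threshold 0.125] [--seed 7] [--engine forcefield] -o out.xyz
racerts bench --manifest manifest.yaml --timings timings.csv -o report.json
racerts fixtures --system sn2 --tail 2 -o toy.xyz   # + toy.yaml sidecar
```

(`exec/racerts` after installation, or
`Rscript -e 'racerts::racerts_main(...)'`.) Atom indices are **1-based**.

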