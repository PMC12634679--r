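# resFEP

Setup and analysis toolkit for **hybrid-topology free energy perturbation
(FEP) of protein point mutations**, written in R.

## The problem and the method

Predicting how a point mutation shifts protein stability, ligand binding or
a protein–protein interaction amounts to computing a relative free energy

    ΔΔG = ΔG_A − ΔG_B   (kcal·mol⁻¹)

from a thermodynamic cycle whose two alchemical legs transform the wild-type
(wt) residue into the mutant (mut) in two environments — e.g. the folded
protein (a solvated sphere centered on the mutation site) and a capped
reference peptide standing in for the unfolded state.

The transformation uses a *hybrid topology*: the backbone is a single shared
set of atoms, while the wt and mut side chains coexist as separate,
mutually non-interacting atom sets. All wt × mut side-chain non-bonded pairs
are excluded, and the bonded terms that would couple the two Cβ atoms
through Cα (the Cβ_wt–Cα–Cβ_mut angle and every torsion through it) are
deactivated. The perturbation runs in two stages: (1) the wt side-chain
charges are scaled 1→0 while a soft-core potential is active on the
side-chain van der Waals terms, then (2) the mut charges are scaled 0→1
with the soft-core removed. To keep the two side chains geometrically
coupled without forcing unphysical overlap, analogous heavy atoms are
enumerated outward from Cα and pairwise distance restraints
(10.0 kcal·mol⁻¹·Å⁻²) are applied while consecutive pairs share an atom type
and sit within 0.5 Å — the first violation stops the restraint list. The
identical restraint scheme is applied to both legs of the cycle.

Per λ-window energy gaps are turned into free energies with either the
Zwanzig exponential formula

    ΔG_i = −β⁻¹ ln ⟨exp(−β(U_{i+1} − U_i))⟩_i

or the Bennett acceptance ratio (BAR), solved self-consistently per window;
legs are averaged over independent replicas with the SEM, and cycles are
solved by subtraction with errors propagated in quadrature.

The toolkit builds all of this — structures, templates, topologies,
restraints, λ schedules, job specifications, estimators, mutation scans and
benchmark statistics — and validates the estimators against systems with
closed-form answers (Crooks-consistent Gaussian work distributions and a
1-D harmonic λ-coupled model). It does **not** run protein MD.

## Worked example

```r
library(resFEP)

## a small structure (generated here; any PDB file works the same way)
s <- buildIdealPeptide("KYT", startResno = 24)

## Y25F: map analogous atoms, assign restraints, build the topology
wt  <- getResidue(s, "A", 25)
scn <- atoms(getTemplate("TYR"))
wtc <- wt[wt$elety %in% scn$name[scn$sidechain], c("elety","x","y","z")]
mutc <- placeMutantSideChain(s, "A", 25, "PHE")
m  <- mapAnalogousAtoms("TYR", "PHE", wtc, mutc)
rs <- assignRestraints(m)
rs
#> RestraintScheme: 6 pair(s), k = 10 kcal/mol/A^2, cutoff 0.50 A, stop: type-mismatch
buildHybridTopology("TYR", "PHE", m)
#> HybridTopology TYR -> PHE
#>   side-chain atoms: 15 (wt) x 14 (mut) -> 210 exclusions
#>   deactivated bonded terms: 1 angle(s), 6 torsion(s)
```

The six restrained pairs are Cβ, Cγ, Cδ1, Cδ2, Cε1, Cε2: the walk stops at
Cζ because the hydroxyl-substituted aromatic carbon of Tyr and the C–H
aromatic carbon of Phe have different atom types.

```r
## estimator validation on the 1-D harmonic toy (exact answer 0.4105)
model <- harmonicToyModel(1, 4)
analyticDG(model)
#> [1] 0.4104718
leg <- estimateLeg(harmonicToyReplicas(model, toyProtocol(), seed = 31))
leg
#> FepLegResult (bar): dG = 0.4113 +/- 0.0033 kcal/mol over 10 replica(s)

## benchmark statistics with bootstrap CIs (hydration dataset shipped)
fom <- figuresOfMerit(hydrationBenchmark())
round(unlist(fom[c("mae","r2","rho","tau")]), 2)
#>  mae   r2  rho  tau
#> 0.32 0.99 0.96 0.85

## protocol arithmetic
samplingBudget(buildProtocol("H"))
#> BudgetReport: 1,000,000 steps/replica/leg; 2 ns/replica/leg; 20 ns/leg; 40 ns/cycle

## domain-wide mutation scan of the 56-residue B1 domain
enumerateScan(gb1Sequence(), fluorescenceScanConfig())
#> MutationMatrix: 38 position(s), 456 entries
```

A command-line front end is installed at `inst/scripts/resfep`
(`setup`, `templates`, `protocol`, `budget`, `scan`, `analyze`, `stats`,
`toy`); see its header for usage.

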