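---
title: "Hybrid-topology residue FEP: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-topology residue FEP: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resFEP)
```

# Scope

resFEP builds and analyzes alchemical free energy perturbation (FEP)
calculations for amino-acid point mutations. It covers everything around the
molecular dynamics engine — topology and restraint construction, λ
protocols, spherical-system bookkeeping, free-energy estimation, mutation
scans and benchmark statistics — and validates the numerical core on toy
systems with closed-form answers. Running protein MD, force-field parameter
derivation, charge-changing mutations and proline are out of scope.

# The thermodynamic cycle

A mutation's effect on stability is the difference between two alchemical
legs, wt → mut performed in the folded protein and in a small capped peptide
representing the unfolded state:

$$\Delta\Delta G = \Delta G_{\mathrm{fold}} - \Delta G_{\mathrm{unfold}},
\qquad \mathrm{SEM} = \sqrt{\mathrm{SEM}_A^2 + \mathrm{SEM}_B^2}.$$

The same cycle structure serves ligand binding (holo/apo legs) and
protein–protein interactions (complex/monomer legs); `solveCycle()` treats
all three identically. Both legs must run under identical conditions — same
protocol, same restraint scheme — which `emitJobSpec()` enforces by
construction and by an explicit consistency check.

The unfolded-state reference defaults to the natural-sequence tripeptide
(scheme `ZXZ`), with `AXA`, `GXG` and single-residue `X` variants available;
all are capped with an acetyl group on the N-terminus and an N-methylamide
on the C-terminus. The central residue always keeps the crystal coordinates
of the protein site, so the transformation geometry is shared between the
legs. Published comparisons of flank choices find no statistically
significant effect of the reference model; we default to the natural flanks
because they require no side-chain rebuilding and keep the dynamic restraint
definition meaningful in both environments.

# Hybrid topology

The transformation shares the backbone between end states and keeps both
side chains as disjoint atom sets:

* **Exclusions.** Every non-bonded pair between a wt side-chain atom and a
  mut side-chain atom is excluded; hydrogens are carried with their heavy
  atoms, so the exclusion count is exactly |A|·|B| (169 for Leu → Ile).
* **Deactivated bonded terms.** The Cβ~wt~–Cα–Cβ~mut~ angle and every
  torsion x–Cβ~wt~–Cα–Cβ~mut~ and Cβ~wt~–Cα–Cβ~mut~–y are switched off, so
  the two side chains never "feel" each other through bonded terms. With
  glycine on either side there is no Cβ and the list is empty.
* **End states.** State 0 carries full wt charges/vdW and a discharged,
  dummy-vdW mut side chain; state 1 is the mirror image. Stage 1 scales the
  wt charges 1→0 with a soft-core potential active on both side chains'
  van der Waals terms; stage 2 scales the mut charges 0→1 and removes the
  soft-core. Atoms disappearing at an end state become dummies that interact
  only through bonded terms, so their cycle contributions cancel.

A mutation that changes the side-chain net charge breaks the cancellation
and is rejected (`buildHybridTopology()` errors); like-charge swaps such as
Asp → Glu pass.

## Analogous-atom mapping

Pairs of "equivalent" heavy atoms are enumerated level by level outward from
Cα (Cβ is level 1). At a branch point the candidate children of an
already-matched pair are matched greedily by, in order: atom-type agreement,
similarity of heavy-atom descendant counts, smallest initial distance, and
an alphabetical tie-break on the name pair. The name tie-break uses the
unordered pair, which makes the whole mapping symmetric:
`mapAnalogousAtoms(wt, mut)` reversed equals `mapAnalogousAtoms(mut, wt)`
pair for pair (property-tested over all supported residue pairs). Aromatic
CD1/CD2–CE1/CE2 assignments are additionally checked against the
name-swapped alternative and the smaller summed ring distance wins,
preventing crossed ring mappings. Hydrogens never participate in the
mapping. The literature fixes only the restraint criterion and leaves the
enumeration open; this tie-break hierarchy is the package's own
deterministic choice.

## Dynamic restraints

Mapped pairs are restrained (harmonic, k = 10.0 kcal·mol⁻¹·Å⁻²) while every
pair so far has identical atom types **and** an initial separation of at
most 0.5 Å; the first violation (type mismatch checked first) stops the
walk, so the restrained set is always a contiguous prefix of the mapping
order, and the stop reason (`type-mismatch`, `distance`, `exhausted`) is
recorded. We apply the rule uniformly from Cβ onward — a Cβ pair that fails
the test leaves the scheme empty — since a Cβ-only scheme is the minimal
non-empty case and nothing in the rule privileges Cβ. For Tyr → Phe this
yields restraints through Cε and stops at Cζ, where the hydroxyl-substituted
aromatic carbon's type differs.

# Protocols and budgets

λ schedules are linear ($\lambda_i = i/(n-1)$) or sigmoidal,
$\lambda_i = \tfrac12\!\left(1+\sin\pi(t_i-\tfrac12)\right)$: symmetric
about ½ with exact endpoints and tighter spacing near the end states, where
the integrand varies fastest during charging/decharging. The exact
end-dense map used by any particular MD engine is not contractual; only
monotonicity, symmetry and end density are, and a steepness parameter blends
the sine map with the linear ramp (steepness 0 recovers `linear`).

Preset **H** (the production default) is 2 stages × 50 sigmoidal windows ×
10,000 steps of 2 fs — 20 ps per window, 1 M steps and 2 ns per replica per
leg, hence 20 ns per leg and 40 ns per cycle with the default 10 replicas.
Preset **J** doubles the windows per stage. `samplingBudget()` does this
arithmetic exactly, including the legacy single-topology comparison
(6 subperturbations × 50 windows × 10,000 one-fs steps = 3 M steps for a
mid-size side chain). The equilibration stanza (10 ps optimization, heating
to 298 K over 150 ps, 350 ps restraint release, 0.5 ns free equilibration)
is emitted declaratively into job specifications and never executed here.

Job specifications are the package's own documented JSON dialect — one
self-contained document per leg with atoms, end-state charges, exclusions,
deactivated terms, restraints, window stanzas and the equilibration block —
not a bit-compatible rendering of any engine's native format.

# Spherical-system bookkeeping

The simulation system is a sphere (default diameter 50 Å) centered on the
mutable residue's Cβ — for glycine, the side-chain hydrogen, or an ideal Cβ
rebuilt from the N/Cα/C frame when hydrogens are absent. Atoms inside move
freely; protein atoms outside are restrained to their initial coordinates
(200 kcal·mol⁻¹·Å⁻²) and excluded from non-bonded interactions; waters and
heterogroups outside are dropped. Ionizable residues whose charged-group
reference atom (Arg Cζ, Lys Nζ, Asp Cγ, Glu Cδ, His Nε2) lies within 3 Å of
the sphere surface are listed for neutralization, since dielectric screening
is poor near the boundary. Which atom anchors the 3 Å test is not specified
in the literature; fixing it to the charged group's central atom is the
package's documented choice, as is measuring the shell from the atom rather
than from any atom of the residue.

# Residue templates and mutant construction

The shipped template library covers the 20 standard residues plus the ACE
and NME caps: atom names, type codes, partial charges, bonds, and internal
coordinates rooted in the N–Cα–C(–Cβ) frame, with rotatable χ torsions
marked. The charges are a minimal self-consistent set — every neutral
residue sums to exactly 0 e, ionizable side chains to their formal charge —
and the type codes distinguish chemically distinct positions (the
restraint rule needs exactly this and no more). They are not a reproduction
of any published force field, which is out of scope.

Mutant side chains are built deterministically from the template's internal
coordinates on the wild-type backbone frame, copying each shared χ~k~ from
the wild-type conformation when the wild type defines one and falling back
to template defaults otherwise. This replaces interactive rotamer-picking
tools: published comparisons of initial-conformation generators (rotamer
tools vs structure predictors) show no significant effect on the FEP
estimates, which licenses the simpler deterministic build. Chirality is
preserved by construction (the Cβ improper torsion is fixed at the
L-amino-acid value) and verified by a signed-volume test.

# Estimators

Both estimators work per window interface on the recorded energy gaps:

* **Zwanzig (exponential averaging)**, forward-only by default, computed
  with log-sum-exp so large gaps cannot overflow.
* **BAR**, solved per interface by bracketed root search on the implicit
  acceptance-ratio equation — the score function is strictly monotone in
  the constant C, so the bracket is expanded geometrically and `uniroot`
  polishes to the 10⁻⁷ kcal·mol⁻¹ tolerance (500-iteration cap; the
  degenerate zero-width case returns its fixed point directly). Unequal
  forward/reverse sample counts enter through the standard ln(n_F/n_R)
  offset. Interfaces with no overlap between the forward and negated
  reverse work distributions are flagged with a warning rather than
  silently returned.

Replica aggregation uses the arithmetic mean and the SEM with the n−1
sample standard deviation (the convention when none is stated). β = 1/(RT)
with R = 1.9872×10⁻³ kcal·mol⁻¹·K⁻¹ and T = 298 K by default. Affinity data
convert through ΔΔG = RT ln(K_i^mut / K_i^wt).

# What the toy generators emulate — and what they do not

`gaussianWorkSamples()` draws forward work from N(ΔG + βσ²/2, σ²) and
reverse from N(−ΔG + βσ²/2, σ²), the unique Gaussian pair satisfying the
Crooks relation with true change ΔG, giving an exact oracle for both
estimators. `harmonicToyFEP()` samples a 1-D coordinate under
$U_\lambda = (1-\lambda)U_A + \lambda U_B$ with Metropolis Monte Carlo —
ensemble correctness is all the estimators need, so no dynamics are
simulated. The proposal step is adapted toward 30–70 % acceptance during
equilibration only (100 steps per window by default) and frozen for
production, keeping the production chain a valid sampler. The default toy
protocol (50 sigmoidal windows × 200 samples) keeps one replica under a
second with negligible λ-discretization bias; the test suite verifies that
coarsening to 5 windows inflates the forward-estimator bias, as it must.

These fixtures share the estimators' input format with real simulations but
none of their pathologies: no autocorrelation beyond the short Metropolis
memory, no slow conformational degrees of freedom, no anharmonicity.
Passing tests therefore certify the estimator arithmetic and the cycle
bookkeeping, not the convergence of any protein simulation.

A note on coverage testing: with 10 replicas, a ±3·SEM interval is a
t-statistic with 9 degrees of freedom, whose expected coverage is ≈98.5 %,
not 99 %+. The calibration tests in the suite therefore assert a 95 % floor
over 200 seeded repetitions — tight enough to catch systematic estimator
bias, loose enough not to fail on the t-distribution's own tails.

# Mutation scans and benchmark statistics

`enumerateScan()` applies the standard exclusion rules of stability scans:
no mutations to Trp (fluorescence interference), Cys (disulfide
oligomerization) or Pro (unsupported topology), none to or from titratable
residues, and terminal positions skipped because they compare inconsistently
with a tripeptide reference. "Terminal" means exactly the first and last
sequence positions. `fluorescenceScanConfig()` additionally skips Trp
*positions* (the assay's reporter). On the 56-residue B1 domain these rules
yield 38 positions × 12 targets = 456 mutations. Histidine is deliberately
not treated as titratable here — the 12-target wheel requires it.

`figuresOfMerit()` reports MAE, R² (squared Pearson), Spearman ρ (average
ranks on ties), Kendall τ-b, sign accuracy, and the MCC of the
stabilizing/destabilizing confusion matrix; a single-class table leaves the
MCC undefined (NA). The accuracy default is pure sign agreement at
threshold 0, with the threshold configurable because per-dataset "% correct"
definitions vary. Confidence intervals are case-resampling percentile
bootstraps (default 10,000 resamples, seeded); undefined resamples are
redrawn up to a 10× cap. Point estimates and bootstrap means are both
reported — on the shipped hydration table the point MAE is 0.32 while
published tables print the bootstrap average 0.33; neither is silently
preferred. Qualitative records (no numeric experimental value) are kept for
classification but excluded from quantitative statistics.

# Numerical choices and degenerate inputs

* Altloc resolution prefers conformer 'A', then occupancy, then serial —
  deterministic and conventional. Only the first model of multi-model files
  is kept. Malformed fixed-column records fail with the line number.
* Sphere membership is boundary-inclusive (distance ≤ radius is free).
* The soft-core form is declarative: a shifted-distance
  r⁶ → r⁶ + α·σ⁶·(1−λ) marker with α = 0.5 default, configurable. The
  MD literature does not pin a single form; the toolkit only needs the
  specification plus a toy implementation.
* Stage-internal λ always runs 0→1 along transformation progress; the
  mapping to charge-scaling factors (wt 1→0 in stage 1, mut 0→1 in stage 2)
  is explicit in the stage markers.
* All randomness (toys, bootstraps) is seed-scoped and restores the global
  RNG state.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale, chosen so the
whole suite completes in about a minute: Gaussian oracles at 10⁵ samples,
harmonic toys at 50 windows × 200 samples × 10 replicas, bootstraps at
10,000 resamples, property tests over all 13 × 13 supported residue pairs.
Protein ΔΔG values from the literature require nanosecond MD and are not
reproduced here; the statistics modules reproduce the published
figures-of-merit arithmetic from printed tables instead.

# Known limitations

* Charge-changing and proline mutations are rejected, not approximated.
* Forward-only Zwanzig is the default; MBAR across all windows and
  autocorrelation-aware uncertainties are not implemented.
* The template geometry is idealized; side-chain builds copy χ angles but
  do not repack or resolve clashes (real setups rely on MD equilibration
  for that).
* mmCIF input, protonation-state prediction and hydrogen placement beyond
  the glycine fallback are not provided.
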