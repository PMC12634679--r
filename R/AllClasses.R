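#' @import methods
NULL

# ---------------------------------------------------------------------------
# Structure / sphere bookkeeping
# ---------------------------------------------------------------------------

#' PdbStructure: an atomic protein structure
#'
#' Holds the atom records of a (single-model, altloc-resolved) PDB structure.
#' Author residue numbering from the file is the only numbering exposed.
#'
#' @slot atoms data.frame with one row per atom: \code{eleno} (serial),
#'   \code{elety} (atom name), \code{resid} (residue name), \code{chain},
#'   \code{resno} (author numbering), \code{alt} (altloc code kept),
#'   \code{occ} (occupancy), \code{x}, \code{y}, \code{z} (Angstrom),
#'   \code{elesy} (element symbol), \code{rectype} ("ATOM" or "HETATM").
#' @export
setClass("PdbStructure", representation(atoms = "data.frame"))

setValidity("PdbStructure", function(object) {
  a <- object@atoms
  need <- c("eleno", "elety", "resid", "chain", "resno",
            "occ", "x", "y", "z", "rectype")
  if (!all(need %in% names(a)))
    return(paste("atoms must contain columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("structure contains no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  # within a residue, atom names must be unique after altloc resolution
  key <- paste(a$chain, a$resno, a$elety)
  if (anyDuplicated(key))
    return("duplicate atom name within a residue after altloc resolution")
  TRUE
})

#' SphereSelection: spherical simulation-system membership
#'
#' Partition of a structure's atoms induced by a solvent sphere centered on
#' the mutation site: atoms inside the sphere move freely; protein atoms
#' outside are harmonically restrained to their initial coordinates and
#' excluded from non-bonded interactions; non-protein atoms (waters,
#' heterogroups) outside the sphere are dropped.
#'
#' @slot center numeric 3-vector, sphere center (Angstrom).
#' @slot radius sphere radius in Angstrom (default 25, i.e. 50 A diameter).
#' @slot freeIdx integer row indices (into \code{atoms()}) of free atoms.
#' @slot restrainedIdx indices of restrained protein atoms outside the sphere.
#' @slot excludedIdx indices of dropped non-protein atoms outside the sphere.
#' @slot kOut positional restraint force constant, kcal mol^-1 A^-2.
#' @export
setClass("SphereSelection",
         representation(center = "numeric", radius = "numeric",
                        freeIdx = "integer", restrainedIdx = "integer",
                        excludedIdx = "integer", kOut = "numeric"))

setValidity("SphereSelection", function(object) {
  if (length(object@center) != 3L) return("center must be a 3-vector")
  if (object@radius <= 0) return("radius must be positive")
  idx <- c(object@freeIdx, object@restrainedIdx, object@excludedIdx)
  if (anyDuplicated(idx)) return("free/restrained/excluded sets overlap")
  TRUE
})

# ---------------------------------------------------------------------------
# Residue templates and peptide models
# ---------------------------------------------------------------------------

#' ResidueTemplate: amino-acid topology template
#'
#' @slot name 3-letter residue (or cap) code.
#' @slot atoms data.frame: \code{name}, \code{type} (atom-type code),
#'   \code{charge} (partial charge, e), \code{heavy} (logical),
#'   \code{sidechain} (logical; CB and beyond).
#' @slot bonds data.frame of bonded atom-name pairs (\code{a}, \code{b}).
#' @slot zmatrix data.frame of internal coordinates for side-chain atoms:
#'   \code{atom}, \code{ref1}, \code{ref2}, \code{ref3} (dihedral reference,
#'   angle vertex neighbour, bonded parent), \code{bond} (A),
#'   \code{angle} (deg), \code{torsion} (deg), \code{chi} (integer; k > 0
#'   marks the torsion as the chi_k rotatable dihedral, 0 = fixed).
#' @export
setClass("ResidueTemplate",
         representation(name = "character", atoms = "data.frame",
                        bonds = "data.frame", zmatrix = "data.frame"))

setValidity("ResidueTemplate", function(object) {
  a <- object@atoms
  if (!all(c("name", "type", "charge", "heavy", "sidechain") %in% names(a)))
    return("atoms must have name/type/charge/heavy/sidechain columns")
  if (anyDuplicated(a$name)) return("duplicate atom names")
  b <- object@bonds
  known <- c(a$name, "N", "CA", "C", "O", "H", "HA")
  if (nrow(b) && !all(c(b$a, b$b) %in% known))
    return("bond references unknown atom")
  TRUE
})

#' PeptideModel: capped reference peptide for the unfolded-state leg
#'
#' @slot atoms data.frame with \code{resno} (1-based position in the peptide,
#'   caps included), \code{resid}, \code{elety}, \code{x}, \code{y}, \code{z}.
#' @slot scheme one of "ZXZ", "AXA", "GXG", "X".
#' @slot centralResno position (resno) of the mutable residue.
#' @export
setClass("PeptideModel",
         representation(atoms = "data.frame", scheme = "character",
                        centralResno = "integer"))

setValidity("PeptideModel", function(object) {
  a <- object@atoms
  res <- unique(a[, c("resno", "resid")])
  res <- res[order(res$resno), ]
  if (res$resid[1L] != "ACE" || res$resid[nrow(res)] != "NME")
    return("peptide must be capped with ACE (N-terminus) and NME (C-terminus)")
  cen <- res$resid[res$resno == object@centralResno]
  if (length(cen) != 1L || cen %in% c("ACE", "NME"))
    return("central residue must be a non-cap position")
  TRUE
})

# ---------------------------------------------------------------------------
# Hybrid topology
# ---------------------------------------------------------------------------

#' AtomMapping: analogous heavy-atom pairing between two side chains
#'
#' @slot pairs data.frame ordered by increasing topological level from CA:
#'   \code{level}, \code{wt}, \code{mut} (atom names), \code{typeMatch}
#'   (logical), \code{distance} (initial inter-atom distance, A; NA when
#'   coordinates were not supplied).
#' @slot unmatchedWt,unmatchedMut heavy side-chain atoms left unpaired.
#' @slot wtName,mutName residue names.
#' @export
setClass("AtomMapping",
         representation(pairs = "data.frame",
                        unmatchedWt = "character", unmatchedMut = "character",
                        wtName = "character", mutName = "character"))

setValidity("AtomMapping", function(object) {
  p <- object@pairs
  if (nrow(p)) {
    if (is.unsorted(p$level)) return("pairs must be ordered by level")
    if (anyDuplicated(p$wt) || anyDuplicated(p$mut))
      return("an atom appears in more than one pair")
  }
  TRUE
})

#' RestraintScheme: pairwise distance restraints between analogous atoms
#'
#' A contiguous prefix of the atom mapping: walking outward from CA, a pair
#' is restrained only while every pair so far has identical atom types and
#' initial separation within the cutoff.
#'
#' @slot pairs data.frame (\code{level}, \code{wt}, \code{mut},
#'   \code{distance}) of restrained pairs.
#' @slot k force constant, kcal mol^-1 A^-2 (default 10.0).
#' @slot cutoff distance criterion in Angstrom (default 0.5).
#' @slot stopReason one of "type-mismatch", "distance", "exhausted".
#' @export
setClass("RestraintScheme",
         representation(pairs = "data.frame", k = "numeric",
                        cutoff = "numeric", stopReason = "character"))

#' SoftCoreSpec: declarative soft-core van der Waals specification
#'
#' @slot form identifier of the functional form; the default
#'   "shifted-r6" stands for r_sc^6 = r^6 + alpha * sigma^6 * (1 - lambda).
#' @slot alpha dimensionless softness parameter (> 0).
#' @export
setClass("SoftCoreSpec", representation(form = "character", alpha = "numeric"),
         prototype(form = "shifted-r6", alpha = 0.5))

setValidity("SoftCoreSpec", function(object) {
  if (object@alpha <= 0) return("alpha must be > 0")
  TRUE
})

#' HybridTopology: merged wild-type/mutant residue representation
#'
#' Shared backbone, separate side-chain atom sets A (wild type) and B
#' (mutant) that never interact with each other: all A x B non-bonded pairs
#' are excluded, and the bonded terms that would couple the two CB atoms
#' through CA are deactivated.
#'
#' @slot wtName,mutName residue names.
#' @slot backboneAtoms shared backbone atom names.
#' @slot wtAtoms,mutAtoms side-chain atom names (heavy plus hydrogens),
#'   mutant names suffixed to keep the merged atom namespace unique.
#' @slot exclusions data.frame (\code{a}, \code{b}) of all A x B pairs.
#' @slot deactivatedAngles,deactivatedTorsions data.frames of bonded terms
#'   switched off (the CBwt-CA-CBmut angle and every torsion through it).
#' @slot endStates data.frame per transforming atom: \code{atom}, \code{set}
#'   ("wt"/"mut"), \code{charge} (full), \code{q0}, \code{q1} (end-state
#'   charges), \code{vdw0}, \code{vdw1} ("full"/"dummy").
#' @slot stages list of two stage markers: stage 1 discharges the wild-type
#'   side chain with soft-core active on both sets; stage 2 charges the
#'   mutant side chain with soft-core removed.
#' @slot softcore a \linkS4class{SoftCoreSpec}.
#' @export
setClass("HybridTopology",
         representation(wtName = "character", mutName = "character",
                        backboneAtoms = "character",
                        wtAtoms = "character", mutAtoms = "character",
                        exclusions = "data.frame",
                        deactivatedAngles = "data.frame",
                        deactivatedTorsions = "data.frame",
                        endStates = "data.frame",
                        stages = "list", softcore = "SoftCoreSpec"))

setValidity("HybridTopology", function(object) {
  nex <- length(object@wtAtoms) * length(object@mutAtoms)
  if (nrow(object@exclusions) != nex)
    return("exclusion list must contain exactly |A| x |B| pairs")
  es <- object@endStates
  q0 <- sum(es$q0[es$set == "wt"])
  q1 <- sum(es$q1[es$set == "mut"])
  if (abs(q0 - q1) > 1e-6)
    return("active side-chain net charge differs between end states")
  TRUE
})

# ---------------------------------------------------------------------------
# Protocols
# ---------------------------------------------------------------------------

#' LambdaSchedule: ordered coupling-parameter values for one FEP stage
#'
#' @slot lambdas strictly increasing values in [0, 1] with exact endpoints.
#' @slot mode "linear" or "sigmoidal".
#' @export
setClass("LambdaSchedule",
         representation(lambdas = "numeric", mode = "character"))

setValidity("LambdaSchedule", function(object) {
  l <- object@lambdas
  if (length(l) < 2L) return("need at least 2 lambda values")
  if (l[1L] != 0 || l[length(l)] != 1) return("endpoints must be 0 and 1")
  if (any(diff(l) <= 0)) return("lambdas must be strictly increasing")
  TRUE
})

#' PerturbationStage: one of the two consecutive FEP subperturbations
#'
#' @slot id 1 (discharge wild type, soft-core on) or 2 (charge mutant,
#'   soft-core off).
#' @slot schedule a \linkS4class{LambdaSchedule}.
#' @slot stepsPerWindow MD steps sampled per lambda window.
#' @slot timestepFs integration timestep in femtoseconds.
#' @export
setClass("PerturbationStage",
         representation(id = "integer", schedule = "LambdaSchedule",
                        stepsPerWindow = "integer", timestepFs = "numeric"))

setValidity("PerturbationStage", function(object) {
  if (object@stepsPerWindow < 1L) return("stepsPerWindow must be >= 1")
  if (object@timestepFs <= 0) return("timestep must be positive")
  TRUE
})

#' FepProtocol: staged lambda schedules plus sampling parameters
#'
#' @slot stages ordered list of \linkS4class{PerturbationStage} (exactly two
#'   for the hybrid-topology scheme).
#' @slot replicas number of independent replica simulations (default 10).
#' @slot preset preset label ("H", "J", or "custom").
#' @slot equilibration declarative equilibration stanza (never executed by
#'   this toolkit): optimization, heating, restraint release, free phase.
#' @export
setClass("FepProtocol",
         representation(stages = "list", replicas = "integer",
                        preset = "character", equilibration = "list"))

setValidity("FepProtocol", function(object) {
  if (length(object@stages) != 2L)
    return("the two-stage perturbation scheme requires exactly 2 stages")
  if (!all(vapply(object@stages, is, logical(1L), "PerturbationStage")))
    return("stages must be PerturbationStage objects")
  if (object@replicas < 1L) return("replicas must be >= 1")
  TRUE
})

#' BudgetReport: sampling budget of a protocol
#'
#' @slot stepsPerReplicaPerLeg MD steps for one replica of one leg.
#' @slot nsPerReplicaPerLeg sampling time (ns) per replica per leg.
#' @slot nsPerLeg aggregate sampling (ns) per leg over all replicas.
#' @slot nsPerCycle aggregate for the full two-leg thermodynamic cycle.
#' @export
setClass("BudgetReport",
         representation(stepsPerReplicaPerLeg = "numeric",
                        nsPerReplicaPerLeg = "numeric",
                        nsPerLeg = "numeric", nsPerCycle = "numeric"))

setValidity("BudgetReport", function(object) {
  if (abs(object@nsPerCycle - 2 * object@nsPerLeg) > 1e-9)
    return("cycle aggregate must equal 2 x leg aggregate")
  TRUE
})

# ---------------------------------------------------------------------------
# Estimation
# ---------------------------------------------------------------------------

#' EstimatorConfig: thermodynamic and numerical settings for estimators
#'
#' @slot temperature simulation temperature in Kelvin (default 298).
#' @slot method "bar" or "zwanzig".
#' @slot tolerance convergence tolerance on the BAR constant, kcal mol^-1.
#' @slot maxIterations iteration cap for the BAR self-consistency search.
#' @export
setClass("EstimatorConfig",
         representation(temperature = "numeric", method = "character",
                        tolerance = "numeric", maxIterations = "integer"),
         prototype(temperature = 298, method = "bar",
                   tolerance = 1e-7, maxIterations = 500L))

setValidity("EstimatorConfig", function(object) {
  if (object@temperature <= 0) return("temperature must be positive")
  if (!object@method %in% c("bar", "zwanzig"))
    return("method must be 'bar' or 'zwanzig'")
  TRUE
})

#' EnergySamples: per-window potential-energy evaluations for one replica
#'
#' @slot samples data.frame with one row per recorded sample: \code{stage},
#'   \code{window} (1-based within stage), \code{lambda}, \code{u_self}
#'   (energy at the window's own lambda), \code{u_forward} (at the next
#'   lambda; NA in the last window), \code{u_reverse} (at the previous
#'   lambda; NA in the first window). Energies in kcal mol^-1.
#' @export
setClass("EnergySamples", representation(samples = "data.frame"))

setValidity("EnergySamples", function(object) {
  s <- object@samples
  need <- c("stage", "window", "lambda", "u_self", "u_forward", "u_reverse")
  if (!all(need %in% names(s)))
    return(paste("samples must have columns:", paste(need, collapse = ", ")))
  if (nrow(s) == 0L) return("no samples")
  for (st in unique(s$stage)) {
    ss <- s[s$stage == st, ]
    w <- sort(unique(ss$window))
    last <- max(w)
    bad_f <- ss$window < last & !is.finite(ss$u_forward)
    bad_r <- ss$window > 1L & !is.finite(ss$u_reverse)
    if (any(bad_f)) return("forward series missing before the last window")
    if (any(bad_r)) return("reverse series missing after the first window")
  }
  TRUE
})

#' FepLegResult: replica-averaged free energy of one FEP leg
#'
#' @slot perReplica total Delta G per replica, kcal mol^-1.
#' @slot mean arithmetic mean over replicas.
#' @slot sem standard error of the mean (n-1 sample SD / sqrt(n)).
#' @slot perWindow list (one per replica) of per-interface Delta G_i.
#' @slot barConstants list of converged BAR constants C_i (method "bar").
#' @slot method estimator label.
#' @slot structure integer vector c(stages, windows) used, for leg
#'   compatibility checks.
#' @export
setClass("FepLegResult",
         representation(perReplica = "numeric", mean = "numeric",
                        sem = "numeric", perWindow = "list",
                        barConstants = "list", method = "character",
                        structure = "integer"))

#' CycleResult: solved thermodynamic cycle
#'
#' @slot ddg Delta Delta G = Delta G(leg A) - Delta G(leg B), kcal mol^-1.
#' @slot sem propagated SEM, sqrt(semA^2 + semB^2).
#' @slot legA,legB the two \linkS4class{FepLegResult} legs (A: folded /
#'   holo / complex; B: unfolded / apo / free monomer).
#' @slot kind "stability", "ligand-binding" or "PPI".
#' @export
setClass("CycleResult",
         representation(ddg = "numeric", sem = "numeric",
                        legA = "FepLegResult", legB = "FepLegResult",
                        kind = "character"))

#' AffinityPair: wild-type/mutant inhibition constants
#'
#' @slot kiWt,kiMut inhibition constants in the same concentration units.
#' @slot temperature Kelvin.
#' @export
setClass("AffinityPair",
         representation(kiWt = "numeric", kiMut = "numeric",
                        temperature = "numeric"),
         prototype(temperature = 298))

setValidity("AffinityPair", function(object) {
  if (object@kiWt <= 0 || object@kiMut <= 0) return("Ki values must be > 0")
  TRUE
})

# ---------------------------------------------------------------------------
# Scanning and benchmarking
# ---------------------------------------------------------------------------

#' ScanConfig: exclusion rules for a systematic mutation scan
#'
#' Defaults implement the scan rules used for fluorescence-assayed stability
#' data: no mutations to Trp (fluorescence interference), Cys (disulfide
#' oligomerization) or Pro (not supported by the topology machinery), no
#' mutations to or from titratable residues, and terminal positions skipped
#' because they compare inconsistently with the tripeptide reference state.
#'
#' @slot excludedTargets residue types never used as mutation targets.
#' @slot excludedWtTypes wild-type residue types whose positions are skipped.
#' @slot excludeTerminal drop the first and last sequence positions.
#' @slot extraExcludedPositions additional 1-based positions to skip.
#' @slot allowSelf emit self-mutations (default FALSE).
#' @export
setClass("ScanConfig",
         representation(excludedTargets = "character",
                        excludedWtTypes = "character",
                        excludeTerminal = "logical",
                        extraExcludedPositions = "integer",
                        allowSelf = "logical"),
         prototype(excludedTargets = c("TRP", "CYS", "PRO",
                                       "ARG", "LYS", "ASP", "GLU"),
                   excludedWtTypes = c("PRO", "ARG", "LYS", "ASP", "GLU"),
                   excludeTerminal = TRUE,
                   extraExcludedPositions = integer(0),
                   allowSelf = FALSE))

#' MutationMatrix: enumerated mutation scan
#'
#' @slot positions data.frame (\code{position}, \code{wt}) of eligible sites.
#' @slot targets list of allowed target residues per position.
#' @slot entries flat data.frame (\code{position}, \code{wt}, \code{mut}).
#' @export
setClass("MutationMatrix",
         representation(positions = "data.frame", targets = "list",
                        entries = "data.frame"))

setValidity("MutationMatrix", function(object) {
  if (nrow(object@entries) != sum(lengths(object@targets)))
    return("entry count must equal the sum of per-position target counts")
  TRUE
})

#' BenchmarkTable: paired experimental/calculated mutation results
#'
#' @slot records data.frame: \code{id}, \code{ddg_exp} (kcal mol^-1, NA for
#'   qualitative records), \code{qualitative} (logical), \code{ddg_calc},
#'   \code{sem}.
#' @slot dataset free-text dataset label.
#' @export
setClass("BenchmarkTable",
         representation(records = "data.frame", dataset = "character"))

setValidity("BenchmarkTable", function(object) {
  r <- object@records
  need <- c("id", "ddg_exp", "qualitative", "ddg_calc", "sem")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(r$id)) return("duplicate mutation id")
  if (any(!r$qualitative & !is.finite(r$ddg_exp)))
    return("quantitative records must carry a numeric experimental value")
  TRUE
})

#' BootstrapSpec: case-resampling bootstrap settings
#'
#' @slot resamples number of bootstrap resamples (default 10000).
#' @slot seed RNG seed.
#' @slot confidence central interval mass (default 0.95, percentile method).
#' @export
setClass("BootstrapSpec",
         representation(resamples = "integer", seed = "integer",
                        confidence = "numeric"),
         prototype(resamples = 10000L, seed = 1L, confidence = 0.95))

setValidity("BootstrapSpec", function(object) {
  if (object@resamples < 1L) return("resamples must be >= 1")
  if (object@confidence <= 0 || object@confidence >= 1)
    return("confidence must be in (0, 1)")
  TRUE
})

# ---------------------------------------------------------------------------
# Toy systems
# ---------------------------------------------------------------------------

#' GaussianWorkSpec: Crooks-consistent Gaussian work fixture
#'
#' Forward work values are drawn from N(dg + beta sigma^2 / 2, sigma^2) and
#' reverse values from N(-dg + beta sigma^2 / 2, sigma^2), so the pair
#' satisfies the Crooks fluctuation relation with true free-energy change
#' \code{dg} exactly.
#'
#' @slot dg true free-energy change, kcal mol^-1.
#' @slot sigma work standard deviation, kcal mol^-1 (>= 0).
#' @slot n samples per direction.
#' @slot seed RNG seed.
#' @slot temperature Kelvin.
#' @export
setClass("GaussianWorkSpec",
         representation(dg = "numeric", sigma = "numeric", n = "integer",
                        seed = "integer", temperature = "numeric"),
         prototype(temperature = 298))

setValidity("GaussianWorkSpec", function(object) {
  if (object@sigma < 0) return("sigma must be >= 0")
  if (object@n < 1L) return("n must be >= 1")
  TRUE
})

#' HarmonicToyModel: 1-D harmonic lambda-coupled system
#'
#' End states U_A = k_A x^2 / 2 and U_B = k_B (x - d)^2 / 2. The exact
#' free-energy change is ln(k_B / k_A) / (2 beta), independent of the
#' displacement d.
#'
#' @slot kA,kB force constants, kcal mol^-1 A^-2 (> 0).
#' @slot d displacement of the B minimum, Angstrom.
#' @export
setClass("HarmonicToyModel",
         representation(kA = "numeric", kB = "numeric", d = "numeric"),
         prototype(d = 0))

setValidity("HarmonicToyModel", function(object) {
  if (object@kA <= 0 || object@kB <= 0) return("force constants must be > 0")
  TRUE
})

#' ToyCycleFixture: two-leg toy thermodynamic cycle with exact answer
#'
#' @slot legA,legB the two \linkS4class{HarmonicToyModel} legs.
#' @slot exactDdg closed-form Delta Delta G = dG(legA) - dG(legB).
#' @slot samplesA,samplesB lists of \linkS4class{EnergySamples}, one per
#'   replica, for each leg.
#' @export
setClass("ToyCycleFixture",
         representation(legA = "HarmonicToyModel", legB = "HarmonicToyModel",
                        exactDdg = "numeric",
                        samplesA = "list", samplesB = "list"))
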