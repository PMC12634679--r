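# Lambda schedules, the two-stage perturbation protocol and job emission.

#' Evenly spaced lambda schedule
#'
#' @param n number of windows (>= 2); lambda_i = i/(n-1).
#' @return a \linkS4class{LambdaSchedule}.
#' @export
linearLambdas <- function(n) {
  if (n < 2L) stop("a schedule needs at least 2 windows")
  new("LambdaSchedule", lambdas = seq(0, 1, length.out = n), mode = "linear")
}

#' Sigmoidal lambda schedule
#'
#' End-point-dense spacing: lambda_i = (1 + sin(pi * (i/(n-1) - 1/2))) / 2,
#' which is symmetric about 1/2 (lambda_i + lambda_(n-1-i) = 1), has exact
#' endpoints, and spaces windows more tightly near the end states than in
#' the middle. A steepness parameter generalizes the map by mixing with the
#' linear ramp; steepness 1 is the pure sine map and steepness 0 recovers
#' the linear schedule.
#'
#' @param n number of windows (>= 2).
#' @param steepness mixing weight in [0, 1] between the linear ramp and the
#'   sine map (default 1, the pure sigmoidal form).
#' @return a \linkS4class{LambdaSchedule}.
#' @export
sigmoidalLambdas <- function(n, steepness = 1) {
  if (n < 2L) stop("a schedule needs at least 2 windows")
  stopifnot(steepness >= 0, steepness <= 1)
  t <- seq(0, 1, length.out = n)
  lam <- (1 - steepness) * t + steepness * (1 + sin(pi * (t - 0.5))) / 2
  lam[1L] <- 0; lam[n] <- 1
  new("LambdaSchedule", lambdas = lam,
      mode = if (steepness > 0) "sigmoidal" else "linear")
}

.mkStage <- function(id, schedule, stepsPerWindow, timestepFs)
  new("PerturbationStage", id = as.integer(id), schedule = schedule,
      stepsPerWindow = as.integer(stepsPerWindow), timestepFs = timestepFs)

# declarative equilibration stanza (emitted into job specs, never executed)
.EQUILIBRATION <- list(
  optimization = list(duration_ps = 10, temperature_K = 0),
  heating = list(target_K = 298, duration_ps = 150),
  restraint_release = list(duration_ps = 350,
                           solute_k = 10.0,
                           bath_coupling_fs = c(0.2, 10)),
  free = list(duration_ps = 500, temperature_K = 298))

#' Build a two-stage FEP protocol
#'
#' Preset H is the production default: 2 stages x 50 sigmoidal lambda
#' windows x 10,000 steps of 2 fs (20 ps sampling per window), 10 replicas.
#' Preset J doubles the window count (100 per stage) to match the sampling
#' of a legacy single-topology annihilation. Custom protocols pass explicit
#' parameters.
#'
#' @param preset "H", "J" or "custom".
#' @param windows,stepsPerWindow,timestepFs,spacing,replicas explicit
#'   parameters used when \code{preset = "custom"} (spacing "sigmoidal" or
#'   "linear"); \code{replicas} also overrides the preset default.
#' @return a \linkS4class{FepProtocol}.
#' @examples
#' buildProtocol("H")
#' buildProtocol("custom", windows = 20, stepsPerWindow = 5000,
#'               timestepFs = 2, spacing = "linear")
#' @export
buildProtocol <- function(preset = c("H", "J", "custom"),
                          windows = NULL, stepsPerWindow = NULL,
                          timestepFs = NULL, spacing = "sigmoidal",
                          replicas = 10L) {
  preset <- match.arg(preset)
  if (preset == "H") {
    windows <- 50L; stepsPerWindow <- 10000L; timestepFs <- 2
    spacing <- "sigmoidal"
  } else if (preset == "J") {
    windows <- 100L; stepsPerWindow <- 10000L; timestepFs <- 2
    spacing <- "sigmoidal"
  } else {
    if (is.null(windows) || is.null(stepsPerWindow) || is.null(timestepFs))
      stop("custom protocol requires windows, stepsPerWindow and timestepFs")
  }
  sched <- switch(spacing,
                  sigmoidal = sigmoidalLambdas(windows),
                  linear = linearLambdas(windows),
                  stop("spacing must be 'sigmoidal' or 'linear'"))
  new("FepProtocol",
      stages = list(.mkStage(1L, sched, stepsPerWindow, timestepFs),
                    .mkStage(2L, sched, stepsPerWindow, timestepFs)),
      replicas = as.integer(replicas), preset = preset,
      equilibration = .EQUILIBRATION)
}

#' Sampling budget of a protocol
#'
#' Exact integer bookkeeping of the production sampling: steps per replica
#' per leg are stages x windows x steps-per-window (or, in legacy
#' single-topology mode, subperturbations x windows x steps-per-window);
#' times follow from the timestep and the replica count, and the full
#' thermodynamic cycle is twice one leg.
#'
#' @param protocol a \linkS4class{FepProtocol}.
#' @param legacy if TRUE, budget a legacy single-topology annihilation with
#'   \code{subperturbations} subperturbations instead of the protocol's two
#'   stages.
#' @param subperturbations subperturbation count for legacy mode.
#' @param timestepFs optional timestep override (legacy protocols used 1 fs).
#' @return a \linkS4class{BudgetReport}.
#' @examples
#' samplingBudget(buildProtocol("H"))             # 1e6 steps, 20 ns per leg
#' samplingBudget(buildProtocol("H"), legacy = TRUE,
#'                subperturbations = 6, timestepFs = 1)   # 3e6 steps
#' @export
samplingBudget <- function(protocol, legacy = FALSE, subperturbations = 0L,
                           timestepFs = NULL) {
  st <- protocol@stages[[1L]]
  nw <- length(st@schedule@lambdas)
  dt <- if (is.null(timestepFs)) st@timestepFs else timestepFs
  nblocks <- if (legacy) {
    if (subperturbations < 1L)
      stop("legacy mode requires a subperturbation count")
    as.numeric(subperturbations)
  } else length(protocol@stages)
  steps <- nblocks * nw * st@stepsPerWindow
  nsReplica <- steps * dt * 1e-6   # fs -> ns
  nsLeg <- nsReplica * protocol@replicas
  new("BudgetReport", stepsPerReplicaPerLeg = steps,
      nsPerReplicaPerLeg = nsReplica, nsPerLeg = nsLeg,
      nsPerCycle = 2 * nsLeg)
}

#' Emit self-contained job specifications for both legs of a cycle
#'
#' Serializes the hybrid topology, restraint scheme, lambda schedules,
#' sphere bookkeeping and equilibration stanza into one structured (JSON)
#' document per leg. The two legs of a cycle must run under identical
#' conditions, so both documents carry byte-identical restraint tables; a
#' peptide-leg restraint scheme differing from the protein-leg scheme is an
#' error.
#'
#' @param topology a \linkS4class{HybridTopology}.
#' @param protocol a \linkS4class{FepProtocol}.
#' @param restraints the \linkS4class{RestraintScheme} used in both legs.
#' @param selection the protein-leg \linkS4class{SphereSelection}.
#' @param peptide the reference-state \linkS4class{PeptideModel}.
#' @param peptideRestraints optional scheme for the peptide leg; must equal
#'   \code{restraints} (default).
#' @return named list of two single-string JSON documents,
#'   \code{protein} and \code{peptide}.
#' @export
emitJobSpec <- function(topology, protocol, restraints, selection, peptide,
                        peptideRestraints = restraints) {
  if (!identical(restraints@pairs, peptideRestraints@pairs) ||
      restraints@k != peptideRestraints@k)
    stop("protein and peptide legs must use identical restraint schemes")
  restraintTable <- list(
    k_kcal_mol_A2 = restraints@k, cutoff_A = restraints@cutoff,
    stop_reason = restraints@stopReason,
    pairs = restraints@pairs)
  topo <- list(
    wt = topology@wtName, mut = topology@mutName,
    backbone = topology@backboneAtoms,
    wt_side_chain = topology@wtAtoms, mut_side_chain = topology@mutAtoms,
    exclusions = topology@exclusions,
    deactivated_angles = topology@deactivatedAngles,
    deactivated_torsions = topology@deactivatedTorsions,
    end_states = topology@endStates,
    softcore = list(form = topology@softcore@form,
                    alpha = topology@softcore@alpha),
    stages = topology@stages)
  stageSpecs <- lapply(protocol@stages, function(s) list(
    id = s@id, spacing = s@schedule@mode,
    steps_per_window = s@stepsPerWindow, timestep_fs = s@timestepFs,
    windows = lapply(seq_along(s@schedule@lambdas), function(i)
      list(window = i, lambda = s@schedule@lambdas[i]))))
  mkLeg <- function(legName, environment) {
    doc <- list(
      leg = legName, environment = environment,
      protocol = list(preset = protocol@preset,
                      replicas = protocol@replicas,
                      equilibration = protocol@equilibration,
                      stages = stageSpecs),
      topology = topo,
      restraints = restraintTable)
    if (legName == "protein") {
      doc$sphere <- list(center = selection@center,
                         radius_A = selection@radius,
                         k_out_kcal_mol_A2 = selection@kOut,
                         n_free = length(selection@freeIdx),
                         n_restrained = length(selection@restrainedIdx),
                         n_dropped = length(selection@excludedIdx))
    } else {
      doc$peptide <- list(scheme = peptide@scheme,
                          central_resno = peptide@centralResno,
                          atoms = atoms(peptide))
    }
    jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     dataframe = "rows")
  }
  list(protein = as.character(mkLeg("protein", "folded protein sphere")),
       peptide = as.character(mkLeg("peptide", "capped reference peptide sphere")))
}
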