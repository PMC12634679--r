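# Generics, accessors and show methods.

#' Atom table of an object
#' @param x a \linkS4class{PdbStructure}, \linkS4class{ResidueTemplate} or
#'   \linkS4class{PeptideModel}.
#' @return data.frame of atom records.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "PdbStructure", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "ResidueTemplate", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "PeptideModel", function(x) x@atoms)

#' Number of atoms
#' @param x object with an atom table.
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "PdbStructure", function(x) nrow(x@atoms))

#' Lambda values of a schedule or stage
#' @param x a \linkS4class{LambdaSchedule} or \linkS4class{PerturbationStage}.
#' @return numeric vector of lambda values.
#' @export
setGeneric("lambdas", function(x) standardGeneric("lambdas"))

#' @rdname lambdas
#' @export
setMethod("lambdas", "LambdaSchedule", function(x) x@lambdas)

#' @rdname lambdas
#' @export
setMethod("lambdas", "PerturbationStage", function(x) x@schedule@lambdas)

#' Energy-sample table
#' @param x an \linkS4class{EnergySamples} object.
#' @return data.frame of per-sample energies.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname samples
#' @export
setMethod("samples", "EnergySamples", function(x) x@samples)

#' Free-energy value of a result
#' @param x a \linkS4class{FepLegResult} (replica-mean leg Delta G) or
#'   \linkS4class{CycleResult} (Delta Delta G).
#' @return free energy in kcal mol^-1.
#' @export
setGeneric("ddG", function(x) standardGeneric("ddG"))

#' @rdname ddG
#' @export
setMethod("ddG", "FepLegResult", function(x) x@mean)

#' @rdname ddG
#' @export
setMethod("ddG", "CycleResult", function(x) x@ddg)

#' Standard error of the mean of a result
#' @param x a \linkS4class{FepLegResult} or \linkS4class{CycleResult}.
#' @return SEM in kcal mol^-1.
#' @export
setGeneric("semOf", function(x) standardGeneric("semOf"))

#' @rdname semOf
#' @export
setMethod("semOf", "FepLegResult", function(x) x@sem)

#' @rdname semOf
#' @export
setMethod("semOf", "CycleResult", function(x) x@sem)

#' Benchmark records
#' @param x a \linkS4class{BenchmarkTable}.
#' @param quantitativeOnly drop qualitative (flagged) records.
#' @return data.frame of records.
#' @export
setGeneric("records", function(x, quantitativeOnly = FALSE)
  standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "BenchmarkTable", function(x, quantitativeOnly = FALSE) {
  r <- x@records
  if (quantitativeOnly) r <- r[!r$qualitative, , drop = FALSE]
  r
})

#' Flat entry list of a mutation matrix
#' @param x a \linkS4class{MutationMatrix}.
#' @return data.frame with columns position, wt, mut.
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))

#' @rdname entries
#' @export
setMethod("entries", "MutationMatrix", function(x) x@entries)

#' Mapping pairs
#' @param x an \linkS4class{AtomMapping} or \linkS4class{RestraintScheme}.
#' @return data.frame of atom pairs.
#' @export
setGeneric("mappedPairs", function(x) standardGeneric("mappedPairs"))

#' @rdname mappedPairs
#' @export
setMethod("mappedPairs", "AtomMapping", function(x) x@pairs)

#' @rdname mappedPairs
#' @export
setMethod("mappedPairs", "RestraintScheme", function(x) x@pairs)

# --- show methods ----------------------------------------------------------

setMethod("show", "PdbStructure", function(object) {
  a <- object@atoms
  nres <- nrow(unique(a[, c("chain", "resno")]))
  cat("PdbStructure:", nrow(a), "atoms,", nres, "residues,",
      length(unique(a$chain)), "chain(s)\n")
})

setMethod("show", "SphereSelection", function(object) {
  cat(sprintf(
    "SphereSelection: radius %.1f A, center (%.2f, %.2f, %.2f)\n",
    object@radius, object@center[1L], object@center[2L], object@center[3L]))
  cat(sprintf("  free: %d | restrained (k = %g kcal/mol/A^2): %d | dropped: %d\n",
              length(object@freeIdx), object@kOut,
              length(object@restrainedIdx), length(object@excludedIdx)))
})

setMethod("show", "ResidueTemplate", function(object) {
  a <- object@atoms
  cat(sprintf("ResidueTemplate %s: %d atoms (%d side-chain heavy), net charge %+.3f e\n",
              object@name, nrow(a), sum(a$heavy & a$sidechain),
              sum(a$charge)))
})

setMethod("show", "AtomMapping", function(object) {
  cat(sprintf("AtomMapping %s -> %s: %d pair(s), %d + %d unmatched\n",
              object@wtName, object@mutName, nrow(object@pairs),
              length(object@unmatchedWt), length(object@unmatchedMut)))
  if (nrow(object@pairs)) print(object@pairs, row.names = FALSE)
})

setMethod("show", "RestraintScheme", function(object) {
  cat(sprintf(
    "RestraintScheme: %d pair(s), k = %g kcal/mol/A^2, cutoff %.2f A, stop: %s\n",
    nrow(object@pairs), object@k, object@cutoff, object@stopReason))
})

setMethod("show", "HybridTopology", function(object) {
  cat(sprintf("HybridTopology %s -> %s\n", object@wtName, object@mutName))
  cat(sprintf("  side-chain atoms: %d (wt) x %d (mut) -> %d exclusions\n",
              length(object@wtAtoms), length(object@mutAtoms),
              nrow(object@exclusions)))
  cat(sprintf("  deactivated bonded terms: %d angle(s), %d torsion(s)\n",
              nrow(object@deactivatedAngles), nrow(object@deactivatedTorsions)))
})

setMethod("show", "FepProtocol", function(object) {
  w <- vapply(object@stages, function(s) length(s@schedule@lambdas), integer(1L))
  cat(sprintf("FepProtocol (preset %s): %d stages x %s windows, %d replicas\n",
              object@preset, length(object@stages),
              paste(w, collapse = "/"), object@replicas))
})

setMethod("show", "BudgetReport", function(object) {
  cat(sprintf("BudgetReport: %s steps/replica/leg; %.3g ns/replica/leg; %.3g ns/leg; %.3g ns/cycle\n",
              format(object@stepsPerReplicaPerLeg, big.mark = ","),
              object@nsPerReplicaPerLeg, object@nsPerLeg, object@nsPerCycle))
})

setMethod("show", "FepLegResult", function(object) {
  cat(sprintf("FepLegResult (%s): dG = %.4f +/- %.4f kcal/mol over %d replica(s)\n",
              object@method, object@mean, object@sem,
              length(object@perReplica)))
})

setMethod("show", "CycleResult", function(object) {
  cat(sprintf("CycleResult (%s): ddG = %.4f +/- %.4f kcal/mol\n",
              object@kind, object@ddg, object@sem))
})

setMethod("show", "MutationMatrix", function(object) {
  cat(sprintf("MutationMatrix: %d position(s), %d entries\n",
              nrow(object@positions), nrow(object@entries)))
})

setMethod("show", "BenchmarkTable", function(object) {
  r <- object@records
  cat(sprintf("BenchmarkTable '%s': %d record(s), %d quantitative\n",
              object@dataset, nrow(r), sum(!r$qualitative)))
})
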