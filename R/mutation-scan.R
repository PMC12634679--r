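# Systematic mutation-scan enumeration and benchmark-table assembly.

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
.AA3TO1 <- setNames(names(.AA1TO3), .AA1TO3)

#' Scan configuration
#'
#' See \linkS4class{ScanConfig} for the semantics of each rule. Defaults
#' exclude mutations to Trp/Cys/Pro and to or from titratable residues
#' (Arg, Lys, Asp, Glu), and skip terminal positions.
#'
#' @param excludedTargets,excludedWtTypes 3-letter residue codes.
#' @param excludeTerminal drop first and last positions.
#' @param extraExcludedPositions additional 1-based positions to skip.
#' @param allowSelf emit self-mutations.
#' @return a \linkS4class{ScanConfig}.
#' @export
scanConfig <- function(excludedTargets = c("TRP", "CYS", "PRO",
                                           "ARG", "LYS", "ASP", "GLU"),
                       excludedWtTypes = c("PRO", "ARG", "LYS",
                                           "ASP", "GLU"),
                       excludeTerminal = TRUE,
                       extraExcludedPositions = integer(0),
                       allowSelf = FALSE) {
  new("ScanConfig", excludedTargets = excludedTargets,
      excludedWtTypes = excludedWtTypes, excludeTerminal = excludeTerminal,
      extraExcludedPositions = as.integer(extraExcludedPositions),
      allowSelf = allowSelf)
}

#' Scan configuration for a Trp-fluorescence stability assay
#'
#' The default rules plus tryptophan positions excluded as wild types: a
#' fluorescence-based assay cannot report on mutations at its reporter Trp,
#' so Trp sites are skipped entirely.
#'
#' @return a \linkS4class{ScanConfig}.
#' @export
fluorescenceScanConfig <- function()
  scanConfig(excludedWtTypes = c("PRO", "ARG", "LYS", "ASP", "GLU", "TRP"))

#' Enumerate a systematic mutation scan
#'
#' Eligible positions are those that are not terminal (when excluded), whose
#' wild-type residue is not of an excluded type, and that are not explicitly
#' skipped. Targets at each position are the 20 standard residues minus the
#' excluded target types and (unless self-mutations are allowed) the
#' wild-type residue itself.
#'
#' @param sequence protein sequence as a 1-letter string.
#' @param config a \linkS4class{ScanConfig}.
#' @return a \linkS4class{MutationMatrix}.
#' @examples
#' m <- enumerateScan("AAPAA", scanConfig())
#' entries(m)   # positions 2 and 4, 12 targets each
#' @export
enumerateScan <- function(sequence, config = scanConfig()) {
  stopifnot(nchar(sequence) >= 1L)
  aa1 <- strsplit(toupper(sequence), "")[[1L]]
  bad <- !aa1 %in% names(.AA1TO3)
  if (any(bad))
    stop(sprintf("unknown residue letter '%s' at position %d",
                 aa1[which(bad)[1L]], which(bad)[1L]))
  aa3 <- .AA1TO3[aa1]
  n <- length(aa3)
  eligible <- rep(TRUE, n)
  if (config@excludeTerminal) eligible[c(1L, n)] <- FALSE
  eligible[aa3 %in% config@excludedWtTypes] <- FALSE
  eligible[config@extraExcludedPositions] <- FALSE
  pos <- which(eligible)
  positions <- data.frame(position = pos, wt = unname(aa3[pos]),
                          stringsAsFactors = FALSE)
  allTargets <- setdiff(unname(.AA1TO3), config@excludedTargets)
  targets <- lapply(pos, function(p) {
    t <- allTargets
    if (!config@allowSelf) t <- setdiff(t, aa3[p])
    sort(t)
  })
  entries <- do.call(rbind, lapply(seq_along(pos), function(i)
    if (length(targets[[i]]))
      data.frame(position = pos[i], wt = unname(aa3[pos[i]]),
                 mut = targets[[i]], stringsAsFactors = FALSE)))
  if (is.null(entries))
    entries <- data.frame(position = integer(0), wt = character(0),
                          mut = character(0))
  entries$id <- paste0(.AA3TO1[entries$wt], entries$position,
                       .AA3TO1[entries$mut])
  new("MutationMatrix", positions = positions, targets = targets,
      entries = entries)
}

#' Assemble a benchmark table from per-mutation records
#'
#' Merges experimental and calculated results into a
#' \linkS4class{BenchmarkTable}. Records without a numeric experimental
#' value are flagged qualitative: they are retained for sign/classification
#' analysis but excluded from quantitative statistics. Records lacking a
#' calculated value are rejected by id.
#'
#' @param records data.frame with columns \code{id}, \code{ddg_exp} (NA
#'   allowed), \code{ddg_calc}, and optionally \code{sem} and
#'   \code{qualitative} (derived from missing \code{ddg_exp} when absent).
#' @param dataset dataset label.
#' @return a \linkS4class{BenchmarkTable}.
#' @export
assembleBenchmark <- function(records, dataset = "benchmark") {
  need <- c("id", "ddg_exp", "ddg_calc")
  if (!all(need %in% names(records)))
    stop(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(records$id))
    stop(sprintf("duplicate mutation id: %s",
                 records$id[which(duplicated(records$id))[1L]]))
  if (!"sem" %in% names(records)) records$sem <- NA_real_
  if (!"qualitative" %in% names(records))
    records$qualitative <- !is.finite(records$ddg_exp)
  missCalc <- !is.finite(records$ddg_calc)
  if (any(missCalc))
    stop(sprintf("record '%s' has no calculated value",
                 records$id[which(missCalc)[1L]]))
  new("BenchmarkTable",
      records = records[, c("id", "ddg_exp", "qualitative",
                            "ddg_calc", "sem")],
      dataset = dataset)
}
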