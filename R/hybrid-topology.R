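# Hybrid (dual-like) topology construction for a wt -> mut transformation:
# analogous-atom enumeration, the dynamic pairwise restraint scheme,
# side-chain exclusion lists, deactivated cross bonded terms and the
# two-stage end-state bookkeeping.

.coordsList <- function(coords) {
  if (is.null(coords)) return(NULL)
  out <- lapply(seq_len(nrow(coords)), function(i)
    as.numeric(coords[i, c("x", "y", "z")]))
  names(out) <- coords$elety
  out
}

.pairDist <- function(cw, cm, a, b) {
  if (is.null(cw) || is.null(cm)) return(NA_real_)
  pa <- cw[[a]]; pb <- cm[[b]]
  if (is.null(pa) || is.null(pb)) return(NA_real_)
  .vnorm(pa - pb)
}

#' Enumerate analogous heavy atoms between two side chains
#'
#' Pairs the heavy side-chain atoms of two residues built on a common
#' backbone, walking outward from CA level by level. Within a branch point,
#' candidate children of an already-paired parent pair are matched to
#' maximize (in order) atom-type agreement, then similarity of heavy-atom
#' descendant counts, then smallest initial inter-atom distance, with a final
#' deterministic tie-break on atom names. Hydrogens never participate in the
#' mapping. Aromatic CD1/CD2 (and the dependent CE1/CE2) assignments are
#' checked against the name-swapped alternative and the one with the smaller
#' summed ring distance is kept, preventing crossed ring mappings.
#'
#' @param wtName,mutName 3-letter residue codes.
#' @param wtCoords,mutCoords optional data.frames (\code{elety}, \code{x},
#'   \code{y}, \code{z}) of side-chain coordinates on the shared backbone;
#'   when omitted, pair distances are NA and distance criteria are skipped.
#' @return an \linkS4class{AtomMapping}; a glycine on either side yields an
#'   empty mapping (no CB to pair).
#' @examples
#' m <- mapAnalogousAtoms("ALA", "SER")
#' mappedPairs(m)   # the single (CB, CB) pair; SER OG left unmatched
#' @export
mapAnalogousAtoms <- function(wtName, mutName,
                              wtCoords = NULL, mutCoords = NULL) {
  wt <- getTemplate(wtName)
  mut <- getTemplate(mutName)
  lvlW <- sideChainLevels(wt)
  lvlM <- sideChainLevels(mut)
  cw <- .coordsList(wtCoords)
  cm <- .coordsList(mutCoords)
  empty <- data.frame(level = integer(0), wt = character(0),
                      mut = character(0), typeMatch = logical(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (!length(lvlW) || !length(lvlM))
    return(new("AtomMapping", pairs = empty,
               unmatchedWt = names(lvlW), unmatchedMut = names(lvlM),
               wtName = wtName, mutName = mutName))

  typeOf <- function(tpl, at) tpl@atoms$type[match(at, tpl@atoms$name)]
  childrenOf <- function(tpl, lvl, at) {
    b <- tpl@bonds
    nb <- c(b$b[b$a == at], b$a[b$b == at])
    nb[nb %in% names(lvl) & lvl[nb] == lvl[at] + 1L]
  }
  descW <- .descendantCounts(wt)
  descM <- .descendantCounts(mut)

  pairs <- data.frame(level = 1L, wt = "CB", mut = "CB",
                      typeMatch = typeOf(wt, "CB") == typeOf(mut, "CB"),
                      distance = .pairDist(cw, cm, "CB", "CB"),
                      stringsAsFactors = FALSE)
  frontier <- list(c("CB", "CB"))
  level <- 1L
  while (length(frontier)) {
    nxt <- list()
    for (pp in frontier) {
      aw <- setdiff(childrenOf(wt, lvlW, pp[1L]), pairs$wt)
      am <- setdiff(childrenOf(mut, lvlM, pp[2L]), pairs$mut)
      while (length(aw) && length(am)) {
        grid <- expand.grid(a = aw, b = am, stringsAsFactors = FALSE)
        grid$tm <- typeOf(wt, grid$a) == typeOf(mut, grid$b)
        grid$dd <- abs(descW[grid$a] - descM[grid$b])
        grid$dist <- vapply(seq_len(nrow(grid)), function(i)
          .pairDist(cw, cm, grid$a[i], grid$b[i]), numeric(1L))
        dist4rank <- ifelse(is.na(grid$dist), 0, grid$dist)
        lo <- pmin(grid$a, grid$b)
        hi <- pmax(grid$a, grid$b)
        best <- order(-grid$tm, grid$dd, dist4rank, lo, hi)[1L]
        sel <- grid[best, ]
        pairs <- rbind(pairs, data.frame(
          level = level + 1L, wt = sel$a, mut = sel$b, typeMatch = sel$tm,
          distance = sel$dist, stringsAsFactors = FALSE))
        nxt[[length(nxt) + 1L]] <- c(sel$a, sel$b)
        aw <- setdiff(aw, sel$a)
        am <- setdiff(am, sel$b)
      }
    }
    frontier <- nxt
    level <- level + 1L
  }
  pairs <- .fixRingCrossing(pairs, cw, cm)
  pairs <- pairs[order(pairs$level, pairs$wt), , drop = FALSE]
  rownames(pairs) <- NULL
  new("AtomMapping", pairs = pairs,
      unmatchedWt = setdiff(names(lvlW), pairs$wt),
      unmatchedMut = setdiff(names(lvlM), pairs$mut),
      wtName = wtName, mutName = mutName)
}

# If both residues carry a symmetric aromatic ring (CD1/CD2 + CE1/CE2 all
# mapped within the ring-name set), compare the chosen assignment with the
# fully swapped one and keep the smaller total distance.
.fixRingCrossing <- function(pairs, cw, cm) {
  ring <- c("CD1", "CD2", "CE1", "CE2")
  idx <- which(pairs$wt %in% ring & pairs$mut %in% ring)
  if (length(idx) != 4L || is.null(cw) || is.null(cm)) return(pairs)
  if (any(is.na(pairs$distance[idx]))) return(pairs)
  swapName <- c(CD1 = "CD2", CD2 = "CD1", CE1 = "CE2", CE2 = "CE1")
  alt <- pairs
  alt$mut[idx] <- swapName[alt$mut[idx]]
  altDist <- vapply(idx, function(i)
    .pairDist(cw, cm, alt$wt[i], alt$mut[i]), numeric(1L))
  if (anyNA(altDist)) return(pairs)
  if (sum(altDist) < sum(pairs$distance[idx])) {
    pairs$mut[idx] <- alt$mut[idx]
    pairs$distance[idx] <- altDist
    pairs$typeMatch[idx] <- TRUE  # ring CH carbons share a type by symmetry
  }
  pairs
}

#' Assign the dynamic pairwise distance-restraint scheme
#'
#' Walks the mapped pairs outward from CA and restrains each pair only while
#' every pair so far has identical atom types and an initial separation
#' within the cutoff; at the first violation (type mismatch checked first)
#' no further restraints are applied, making the restrained set a contiguous
#' prefix of the mapping order.
#'
#' @param mapping an \linkS4class{AtomMapping} whose pairs carry distances.
#' @param cutoff distance criterion in Angstrom (default 0.5).
#' @param k restraint force constant, kcal mol^-1 A^-2 (default 10).
#' @return a \linkS4class{RestraintScheme}.
#' @export
assignRestraints <- function(mapping, cutoff = 0.5, k = 10.0) {
  p <- mappedPairs(mapping)
  keep <- integer(0)
  stop_reason <- "exhausted"
  for (i in seq_len(nrow(p))) {
    if (!isTRUE(p$typeMatch[i])) { stop_reason <- "type-mismatch"; break }
    if (is.na(p$distance[i]))
      stop("mapping pairs carry no initial distances; supply coordinates")
    if (p$distance[i] > cutoff) { stop_reason <- "distance"; break }
    keep <- c(keep, i)
  }
  new("RestraintScheme",
      pairs = p[keep, c("level", "wt", "mut", "distance"), drop = FALSE],
      k = k, cutoff = cutoff, stopReason = stop_reason)
}

.sideChainAtoms <- function(tpl) tpl@atoms$name[tpl@atoms$sidechain]

.bondedTo <- function(tpl, at) {
  b <- tpl@bonds
  unique(c(b$b[b$a == at], b$a[b$b == at]))
}

#' Build the hybrid topology for a wt -> mut transformation
#'
#' Emits the merged representation: a shared backbone, the two side-chain
#' atom sets A (wild type) and B (mutant) with every A x B non-bonded pair
#' excluded, the deactivated bonded terms that would otherwise couple the
#' two CB atoms through CA (the CBwt-CA-CBmut angle and all torsions through
#' it), per-atom end-state charges (state 0: B discharged; state 1: A
#' discharged) with dummy van der Waals markers, and the two stage markers of
#' the perturbation: stage 1 scales the A charges 1 -> 0 with the soft-core
#' potential active on the side-chain van der Waals terms, stage 2 scales
#' the B charges 0 -> 1 with the soft-core removed.
#'
#' @param wtName,mutName 3-letter residue codes (proline and mutations that
#'   change the side-chain net charge are rejected).
#' @param mapping optional \linkS4class{AtomMapping} carried along for
#'   reporting; computed topology does not depend on it.
#' @param softcore a \linkS4class{SoftCoreSpec}.
#' @return a \linkS4class{HybridTopology}.
#' @examples
#' ht <- buildHybridTopology("LEU", "ILE")
#' nrow(ht@exclusions)   # 13 x 13 = 169
#' @export
buildHybridTopology <- function(wtName, mutName, mapping = NULL,
                                softcore = new("SoftCoreSpec")) {
  wt <- getTemplate(wtName, role = "mutation")
  mut <- getTemplate(mutName, role = "mutation")
  A <- .sideChainAtoms(wt)
  B <- .sideChainAtoms(mut)
  qA <- wt@atoms$charge[match(A, wt@atoms$name)]
  qB <- mut@atoms$charge[match(B, mut@atoms$name)]
  if (abs(sum(qA) - sum(qB)) > 1e-6)
    stop(sprintf(
      "charge-changing mutation %s -> %s (side-chain charge %+.3f -> %+.3f) is unsupported by default",
      wtName, mutName, sum(qA), sum(qB)))

  exclusions <- if (length(A) && length(B))
    expand.grid(a = A, b = B, stringsAsFactors = FALSE)
  else data.frame(a = character(0), b = character(0))

  hasCB <- "CB" %in% A && "CB" %in% B
  if (hasCB) {
    angles <- data.frame(a = "CB", vertex = "CA", b = "CB",
                         setA = "wt", setB = "mut", stringsAsFactors = FALSE)
    xs <- setdiff(.bondedTo(wt, "CB"), "CA")
    ys <- setdiff(.bondedTo(mut, "CB"), "CA")
    torsions <- rbind(
      if (length(xs)) data.frame(a = xs, b = "CB", c = "CA", d = "CB",
                                 aSet = "wt", dSet = "mut",
                                 stringsAsFactors = FALSE),
      if (length(ys)) data.frame(a = "CB", b = "CA", c = "CB", d = ys,
                                 aSet = "wt", dSet = "mut",
                                 stringsAsFactors = FALSE))
  } else {
    angles <- data.frame(a = character(0), vertex = character(0),
                         b = character(0), setA = character(0),
                         setB = character(0))
    torsions <- data.frame(a = character(0), b = character(0),
                           c = character(0), d = character(0),
                           aSet = character(0), dSet = character(0))
  }

  endStates <- rbind(
    if (length(A)) data.frame(atom = A, set = "wt", charge = qA,
                              q0 = qA, q1 = 0,
                              vdw0 = "full", vdw1 = "dummy",
                              stringsAsFactors = FALSE),
    if (length(B)) data.frame(atom = B, set = "mut", charge = qB,
                              q0 = 0, q1 = qB,
                              vdw0 = "dummy", vdw1 = "full",
                              stringsAsFactors = FALSE))
  if (is.null(endStates))
    endStates <- data.frame(atom = character(0), set = character(0),
                            charge = numeric(0), q0 = numeric(0),
                            q1 = numeric(0), vdw0 = character(0),
                            vdw1 = character(0))

  stages <- list(
    list(id = 1L, charges = "wt:1->0", softcore = TRUE,
         description = "discharge wild-type side chain; soft-core active on wt+mut side-chain vdW"),
    list(id = 2L, charges = "mut:0->1", softcore = FALSE,
         description = "charge mutant side chain; soft-core removed"))

  bb <- wt@atoms$name[!wt@atoms$sidechain]
  new("HybridTopology", wtName = wtName, mutName = mutName,
      backboneAtoms = bb, wtAtoms = A, mutAtoms = B,
      exclusions = exclusions, deactivatedAngles = angles,
      deactivatedTorsions = torsions, endStates = endStates,
      stages = stages, softcore = softcore)
}
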