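# Template access, mutant side-chain construction and reference peptides.

#' Retrieve a residue template
#'
#' @param name 3-letter code of one of the 20 standard residues, or a cap
#'   ("ACE", "NME").
#' @param role "any" (default) or "mutation": proline is a valid template but
#'   an unsupported mutation endpoint (its backbone-bonded ring cannot be
#'   handled by the side-chain transformation machinery).
#' @return a \linkS4class{ResidueTemplate}.
#' @examples
#' tpl <- getTemplate("TYR")
#' sum(atoms(tpl)$charge)          # neutral residue: 0
#' sideChainLevels(tpl)            # CB=1 ... OH=6
#' @export
getTemplate <- function(name, role = c("any", "mutation")) {
  role <- match.arg(role)
  lib <- .templates()
  if (!name %in% names(lib))
    stop(sprintf("unknown residue template '%s'", name))
  if (role == "mutation" && name == "PRO")
    stop("proline is unsupported as a mutation endpoint")
  lib[[name]]
}

#' Topological levels of side-chain heavy atoms
#'
#' Graph distance from CA along the side-chain bond graph; CB is level 1.
#'
#' @param template a \linkS4class{ResidueTemplate}.
#' @return named integer vector (empty for glycine).
#' @export
sideChainLevels <- function(template) {
  a <- template@atoms
  sc <- a$name[a$sidechain & a$heavy]
  if (!length(sc)) return(setNames(integer(0), character(0)))
  nodes <- c("CA", sc)
  b <- template@bonds
  b <- b[b$a %in% nodes & b$b %in% nodes, , drop = FALSE]
  lvl <- setNames(rep(NA_integer_, length(nodes)), nodes)
  lvl["CA"] <- 0L
  frontier <- "CA"
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      nb <- c(b$b[b$a == v], b$a[b$b == v])
      new <- nb[is.na(lvl[nb])]
      lvl[new] <- lvl[v] + 1L
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  lvl[sc]
}

# number of heavy side-chain descendants strictly beyond each atom
# (graph nodes at greater level reachable without passing back through CA)
.descendantCounts <- function(template) {
  lvl <- sideChainLevels(template)
  if (!length(lvl)) return(lvl)
  vapply(names(lvl), function(at) sum(lvl > lvl[at] &
    .reachableFrom(template, at, names(lvl))), integer(1L))
}

.reachableFrom <- function(template, atom, heavy) {
  # heavy atoms whose bond path from CA passes through `atom`
  b <- template@bonds
  lvl <- sideChainLevels(template)
  inset <- logical(length(heavy))
  names(inset) <- heavy
  frontier <- atom
  seen <- atom
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      nb <- c(b$b[b$a == v], b$a[b$b == v])
      nb <- nb[nb %in% heavy & !nb %in% seen & lvl[nb] > lvl[v]]
      seen <- c(seen, nb)
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  inset[intersect(seen, heavy)] <- TRUE
  inset
}

# Evaluate the chi_k torsions of a residue from coordinates.
# coords: named list of 3-vectors. Returns named numeric (chi1, chi2, ...).
.measureChis <- function(template, coords) {
  zm <- template@zmatrix
  rows <- zm[zm$chi > 0L, , drop = FALSE]
  out <- numeric(0)
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    nm <- c(r$ref1, r$ref2, r$ref3, r$atom)
    if (all(nm %in% names(coords))) {
      out[paste0("chi", r$chi)] <-
        dihedralAngle(coords[[nm[1L]]], coords[[nm[2L]]],
                      coords[[nm[3L]]], coords[[nm[4L]]])
    }
  }
  out
}

# Build template side-chain coordinates on a backbone frame.
# frame: named list with at least N, CA, C. chiOverrides: named numeric
# ("chi1", ...) replacing the template defaults for rotatable torsions.
.buildSideChain <- function(template, frame, chiOverrides = numeric(0)) {
  zm <- template@zmatrix
  coords <- frame
  for (i in seq_len(nrow(zm))) {
    r <- zm[i, ]
    tor <- r$torsion
    if (r$chi > 0L) {
      key <- paste0("chi", r$chi)
      if (key %in% names(chiOverrides)) tor <- chiOverrides[[key]]
    }
    refs <- lapply(c(r$ref1, r$ref2, r$ref3), function(nm) {
      if (is.null(coords[[nm]]))
        stop(sprintf("reference atom %s missing while building %s",
                     nm, template@name))
      coords[[nm]]
    })
    coords[[r$atom]] <- placeInternal(refs[[1L]], refs[[2L]], refs[[3L]],
                                      r$bond, r$angle, tor)
  }
  built <- zm$atom
  do.call(rbind, lapply(built, function(nm)
    data.frame(elety = nm, x = coords[[nm]][1L], y = coords[[nm]][2L],
               z = coords[[nm]][3L], stringsAsFactors = FALSE)))
}

#' Build a mutant side chain on an existing backbone
#'
#' Constructs the mutant residue's side-chain atoms (heavy atoms and
#' hydrogens) from the template's internal coordinates, in the frame defined
#' by the wild-type residue's N/CA/C atoms. Rotatable chi torsions shared
#' between the two residues are copied from the wild-type conformation
#' (chi_k is copied whenever the wild-type structure contains the four atoms
#' defining its own chi_k); deeper torsions fall back to template defaults.
#' The construction is fully deterministic.
#'
#' @param x a \linkS4class{PdbStructure}.
#' @param chain chain identifier.
#' @param resnum author residue number of the site.
#' @param mutName 3-letter code of the mutant residue.
#' @return data.frame (\code{elety}, \code{x}, \code{y}, \code{z}) of the
#'   built mutant side-chain atoms (empty for glycine).
#' @export
placeMutantSideChain <- function(x, chain, resnum, mutName) {
  res <- getResidue(x, chain, resnum)
  wtName <- res$resid[1L]
  if (wtName == "PRO" || mutName == "PRO")
    stop("mutations to or from proline are unsupported")
  mut <- getTemplate(mutName, role = "mutation")
  frame <- list(N = .coordOf(res, "N"), CA = .coordOf(res, "CA"),
                C = .coordOf(res, "C"))
  if (any(vapply(frame, is.null, logical(1L))))
    stop(sprintf("residue %s/%s lacks backbone atoms N/CA/C", chain, resnum))
  chis <- numeric(0)
  if (wtName %in% names(.templates())) {
    wt <- getTemplate(wtName)
    wtCoords <- frame
    for (nm in wt@zmatrix$atom) {
      p <- .coordOf(res, nm)
      if (!is.null(p)) wtCoords[[nm]] <- p
    }
    chis <- .measureChis(wt, wtCoords)
  }
  sc <- .buildSideChain(mut, frame, chis)
  if (is.null(sc))
    sc <- data.frame(elety = character(0), x = numeric(0), y = numeric(0),
                     z = numeric(0), stringsAsFactors = FALSE)
  sc
}

#' Build an ideal residue from template geometry
#'
#' Constructs a full residue (backbone plus template side chain) with an
#' idealized backbone placed at the origin. Used for desk-scale fixtures and
#' as the geometric reference for template-built side chains.
#'
#' @param resname 3-letter residue code.
#' @param chis optional named numeric vector ("chi1", ...) of side-chain
#'   torsions overriding template defaults.
#' @return data.frame (\code{elety}, \code{x}, \code{y}, \code{z}).
#' @export
buildIdealResidue <- function(resname, chis = numeric(0)) {
  tpl <- getTemplate(resname)
  ca <- c(0, 0, 0)
  n <- c(-1.458, 0, 0)
  cc <- placeInternal(n + c(0, 1, 0), n, ca, 1.525, 111.0, 120.0)
  frame <- list(N = n, CA = ca, C = cc)
  o <- placeInternal(n, ca, cc, 1.23, 120.5, 180.0)
  bb <- data.frame(elety = c("N", "CA", "C", "O"),
                   x = c(n[1L], ca[1L], cc[1L], o[1L]),
                   y = c(n[2L], ca[2L], cc[2L], o[2L]),
                   z = c(n[3L], ca[3L], cc[3L], o[3L]),
                   stringsAsFactors = FALSE)
  sc <- .buildSideChain(tpl, frame, chis)
  if (is.null(sc)) return(bb)
  rbind(bb, sc)
}

#' Build an ideal polypeptide structure from templates
#'
#' Constructs a chain with idealized backbone geometry at fixed backbone
#' dihedrals and template side chains, returning a full
#' \linkS4class{PdbStructure}. Intended for desk-scale fixtures, examples
#' and geometry tests rather than production modeling.
#'
#' @param sequence character vector of 3-letter residue codes, or a 1-letter
#'   string.
#' @param phi,psi backbone dihedrals in degrees (default extended chain).
#' @param chain chain identifier.
#' @param startResno author number of the first residue.
#' @return a \linkS4class{PdbStructure}.
#' @examples
#' s <- buildIdealPeptide("KYT", startResno = 24)
#' mutationCenter(s, "A", 25)
#' @export
buildIdealPeptide <- function(sequence, phi = -120, psi = 130,
                              chain = "A", startResno = 1L) {
  if (length(sequence) == 1L && !sequence %in% names(.templates())) {
    aa1 <- strsplit(toupper(sequence), "")[[1L]]
    bad <- !aa1 %in% names(.AA1TO3)
    if (any(bad)) stop(sprintf("unknown residue letter '%s'", aa1[bad][1L]))
    sequence <- unname(.AA1TO3[aa1])
  }
  n <- c(0, 0, 0)
  ca <- c(1.458, 0, 0)
  cc <- placeInternal(c(0, 1, 0), n, ca, 1.525, 111.0, phi)
  rows <- list()
  for (i in seq_along(sequence)) {
    resname <- sequence[i]
    if (resname == "PRO") stop("ideal-chain builder does not place proline")
    o <- placeInternal(n, ca, cc, 1.23, 120.5, psi + 180)
    frame <- list(N = n, CA = ca, C = cc)
    tpl <- getTemplate(resname)
    h <- placeInternal(cc, ca, n, 1.01, 119.0, 180.0)
    bb <- data.frame(elety = c("N", "H", "CA", "C", "O"),
                     x = c(n[1L], h[1L], ca[1L], cc[1L], o[1L]),
                     y = c(n[2L], h[2L], ca[2L], cc[2L], o[2L]),
                     z = c(n[3L], h[3L], ca[3L], cc[3L], o[3L]),
                     stringsAsFactors = FALSE)
    if (resname == "GLY") bb <- bb[bb$elety != "H" | i > 0, , drop = FALSE]
    sc <- .buildSideChain(tpl, frame)
    res <- if (is.null(sc)) bb else rbind(bb, sc)
    rows[[i]] <- data.frame(resno = startResno + i - 1L, resid = resname,
                            res, stringsAsFactors = FALSE)
    # next backbone frame
    n2 <- placeInternal(n, ca, cc, 1.335, 116.6, psi)
    ca2 <- placeInternal(ca, cc, n2, 1.458, 121.7, 180.0)
    cc2 <- placeInternal(cc, n2, ca2, 1.525, 111.0, phi)
    n <- n2; ca <- ca2; cc <- cc2
  }
  body <- do.call(rbind, rows)
  new("PdbStructure", atoms = data.frame(
    eleno = seq_len(nrow(body)), elety = body$elety, resid = body$resid,
    chain = chain, resno = body$resno, alt = "", occ = 1,
    x = body$x, y = body$y, z = body$z,
    elesy = substr(body$elety, 1L, 1L), rectype = "ATOM",
    stringsAsFactors = FALSE))
}

# residues ordered as they appear in one chain
.chainResidues <- function(x, chain) {
  a <- atoms(x)
  a <- a[a$chain == chain, , drop = FALSE]
  unique(a[, c("resno", "resid")])
}

.capAce <- function(first) {
  # first: named list with N, CA, C of the first peptide residue
  cace <- placeInternal(first$C, first$CA, first$N, 1.335, 121.7, 180.0)
  oace <- placeInternal(first$CA, first$N, cace, 1.23, 123.0, 0.0)
  ch3 <- placeInternal(first$CA, first$N, cace, 1.52, 116.0, 180.0)
  h1 <- placeInternal(first$N, cace, ch3, 1.09, 109.5, 60)
  h2 <- placeInternal(first$N, cace, ch3, 1.09, 109.5, 180)
  h3 <- placeInternal(first$N, cace, ch3, 1.09, 109.5, -60)
  m <- rbind(ch3, h1, h2, h3, cace, oace)
  data.frame(elety = c("CH3", "HH31", "HH32", "HH33", "C", "O"),
             x = m[, 1L], y = m[, 2L], z = m[, 3L], stringsAsFactors = FALSE)
}

.capNme <- function(last) {
  # last: named list with CA, C, O of the last peptide residue
  nn <- placeInternal(last$O, last$CA, last$C, 1.335, 116.0, 180.0)
  h <- placeInternal(last$CA, last$C, nn, 1.01, 119.0, 0.0)
  ch3 <- placeInternal(last$CA, last$C, nn, 1.45, 121.0, 180.0)
  h1 <- placeInternal(last$C, nn, ch3, 1.09, 109.5, 60)
  h2 <- placeInternal(last$C, nn, ch3, 1.09, 109.5, 180)
  h3 <- placeInternal(last$C, nn, ch3, 1.09, 109.5, -60)
  m <- rbind(nn, h, ch3, h1, h2, h3)
  data.frame(elety = c("N", "H", "CH3", "HH31", "HH32", "HH33"),
             x = m[, 1L], y = m[, 2L], z = m[, 3L], stringsAsFactors = FALSE)
}

.peptideUnit <- function(res, resno, resid = res$resid[1L]) {
  data.frame(resno = resno, resid = resid, elety = res$elety,
             x = res$x, y = res$y, z = res$z, stringsAsFactors = FALSE)
}

#' Build the capped reference peptide for the unfolded-state leg
#'
#' The unfolded state of a stability cycle is modeled by a small capped
#' peptide carrying the mutable residue: the natural-sequence tripeptide
#' (scheme "ZXZ", the default), alanine or glycine flanks ("AXA", "GXG"), or
#' the single mutable residue ("X"). All schemes are capped with an acetyl
#' group on the N-terminus and an N-methylamide on the C-terminus. The
#' mutable residue keeps its crystal coordinates, so the peptide leg and the
#' protein leg of a cycle share identical side-chain geometry at the site.
#'
#' @param x a \linkS4class{PdbStructure}.
#' @param chain chain identifier.
#' @param resnum author residue number of the mutable residue.
#' @param scheme "ZXZ", "AXA", "GXG" or "X".
#' @return a \linkS4class{PeptideModel}.
#' @export
buildReferencePeptide <- function(x, chain, resnum,
                                  scheme = c("ZXZ", "AXA", "GXG", "X")) {
  scheme <- match.arg(scheme)
  resl <- .chainResidues(x, chain)
  pos <- which(resl$resno == resnum)
  if (length(pos) != 1L)
    stop(sprintf("residue %s/%s not found", chain, resnum))
  central <- getResidue(x, chain, resnum)
  units <- list()
  if (scheme == "X") {
    units[[1L]] <- .peptideUnit(central, 2L)
  } else {
    if (pos == 1L || pos == nrow(resl))
      stop("terminal residues cannot anchor a tripeptide reference scheme")
    prev <- getResidue(x, chain, resl$resno[pos - 1L])
    nxt <- getResidue(x, chain, resl$resno[pos + 1L])
    if (scheme == "ZXZ") {
      units[[1L]] <- .peptideUnit(prev, 2L)
      units[[2L]] <- .peptideUnit(central, 3L)
      units[[3L]] <- .peptideUnit(nxt, 4L)
    } else {
      flankName <- if (scheme == "AXA") "ALA" else "GLY"
      units[[1L]] <- .replaceFlank(prev, 2L, flankName)
      units[[2L]] <- .peptideUnit(central, 3L)
      units[[3L]] <- .replaceFlank(nxt, 4L, flankName)
    }
  }
  first <- units[[1L]]
  last <- units[[length(units)]]
  firstFrame <- list(N = .unitCoord(first, "N"), CA = .unitCoord(first, "CA"),
                     C = .unitCoord(first, "C"))
  lastFrame <- list(CA = .unitCoord(last, "CA"), C = .unitCoord(last, "C"),
                    O = .unitCoord(last, "O"))
  ace <- .capAce(firstFrame)
  nme <- .capNme(lastFrame)
  k <- length(units) + 2L
  body <- do.call(rbind, units)
  atoms <- rbind(
    data.frame(resno = 1L, resid = "ACE", ace, stringsAsFactors = FALSE),
    body,
    data.frame(resno = k, resid = "NME", nme, stringsAsFactors = FALSE))
  centralResno <- if (scheme == "X") 2L else 3L
  new("PeptideModel", atoms = atoms, scheme = scheme,
      centralResno = centralResno)
}

.unitCoord <- function(unit, name) {
  i <- match(name, unit$elety)
  if (is.na(i)) stop(sprintf("peptide unit lacks backbone atom %s", name))
  as.numeric(unit[i, c("x", "y", "z")])
}

# replace a flanking residue's side chain by an Ala/Gly template build,
# keeping its crystal backbone
.replaceFlank <- function(res, resno, flankName) {
  keep <- res[res$elety %in% c("N", "H", "CA", "C", "O"), , drop = FALSE]
  out <- data.frame(resno = resno, resid = flankName, elety = keep$elety,
                    x = keep$x, y = keep$y, z = keep$z,
                    stringsAsFactors = FALSE)
  if (flankName == "ALA") {
    frame <- list(N = .coordOf(res, "N"), CA = .coordOf(res, "CA"),
                  C = .coordOf(res, "C"))
    if (any(vapply(frame, is.null, logical(1L))))
      stop("flanking residue lacks backbone atoms N/CA/C")
    sc <- .buildSideChain(getTemplate("ALA"), frame)
    out <- rbind(out, data.frame(resno = resno, resid = flankName,
                                 elety = sc$elety, x = sc$x, y = sc$y,
                                 z = sc$z, stringsAsFactors = FALSE))
  }
  out
}
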