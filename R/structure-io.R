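# PDB reading/writing and spherical-system bookkeeping.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.WATER <- c("HOH", "WAT", "TIP", "TIP3", "SPC", "SOL")

.isProteinAtom <- function(atoms) atoms$resid %in% c(.AA3, "ACE", "NME")

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}) into a
#' \linkS4class{PdbStructure}. Author residue numbering is preserved
#' unchanged. Only the first model of a multi-model file is retained.
#' Alternate locations are resolved per (chain, residue, atom-name) group by
#' keeping altloc 'A' when present, otherwise the highest-occupancy
#' conformer, ties broken by atom serial.
#'
#' @param pdb path to a PDB file, or a character vector of PDB-format lines.
#' @return a \linkS4class{PdbStructure}.
#' @examples
#' lines <- c(paste0("ATOM      1  CA  ALA A   1      ",
#'                   "11.000  22.000  33.000  1.00  0.00           C"), "END")
#' s <- readStructure(lines)
#' nAtoms(s)
#' @export
readStructure <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE))
  }
  recs <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(recs)) stop("no ATOM/HETATM records: empty structure")
  # fixed-column validation with line numbers before handing off to bio3d
  for (i in which(recs)) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop(sprintf("malformed PDB record at line %d: too short", i))
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      stop(sprintf("malformed PDB record at line %d: non-numeric coordinates", i))
    if (is.na(suppressWarnings(as.integer(substr(ln, 23, 26)))))
      stop(sprintf("malformed PDB record at line %d: bad residue number", i))
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  p <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- p$atom
  atoms <- data.frame(
    eleno = a$eleno, elety = a$elety, resid = a$resid,
    chain = ifelse(is.na(a$chain), " ", a$chain), resno = a$resno,
    alt = ifelse(is.na(a$alt), "", a$alt),
    occ = ifelse(is.na(a$o), 1, a$o),
    x = a$x, y = a$y, z = a$z,
    elesy = ifelse(is.na(a$elesy), "", a$elesy),
    rectype = a$type, stringsAsFactors = FALSE)
  # altloc resolution: prefer 'A', then occupancy, then serial
  grp <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), grp), function(idx) {
    if (length(idx) == 1L) return(idx)
    sub <- atoms[idx, ]
    ia <- idx[sub$alt == "A"]
    if (length(ia)) return(ia[which.max(atoms$occ[ia])][1L])
    idx[order(-sub$occ, sub$eleno)][1L]
  }), use.names = FALSE)
  atoms <- atoms[sort(keep), , drop = FALSE]
  rownames(atoms) <- NULL
  new("PdbStructure", atoms = atoms)
}

#' Write a structure to PDB format
#'
#' @param x a \linkS4class{PdbStructure}.
#' @param file output path.
#' @return invisibly, the path written.
#' @export
writeStructure <- function(x, file) {
  a <- atoms(x)
  bio3d::write.pdb(file = file,
                   type = a$rectype, eleno = a$eleno, elety = a$elety,
                   resid = a$resid, chain = ifelse(a$chain == " ", "", a$chain),
                   resno = a$resno, o = a$occ, b = rep(0, nrow(a)),
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   elesy = a$elesy)
  invisible(file)
}

#' Atoms of one residue
#'
#' @param x a \linkS4class{PdbStructure}.
#' @param chain chain identifier.
#' @param resnum author residue number.
#' @return data.frame of the residue's atom records.
#' @export
getResidue <- function(x, chain, resnum) {
  a <- atoms(x)
  r <- a[a$chain == chain & a$resno == resnum, , drop = FALSE]
  if (nrow(r) == 0L)
    stop(sprintf("residue %s/%s not found", chain, resnum))
  r
}

.coordOf <- function(res, name) {
  i <- match(name, res$elety)
  if (is.na(i)) return(NULL)
  as.numeric(res[i, c("x", "y", "z")])
}

#' Simulation-sphere center for a mutation site
#'
#' The sphere is centered on the mutable residue's CB atom; for glycine the
#' side-chain hydrogen (HA2) is used, and when hydrogens are absent an ideal
#' CB position is reconstructed from the N/CA/C backbone frame.
#'
#' @param x a \linkS4class{PdbStructure}.
#' @param chain chain identifier.
#' @param resnum author residue number.
#' @return numeric 3-vector, center coordinates in Angstrom.
#' @export
mutationCenter <- function(x, chain, resnum) {
  res <- getResidue(x, chain, resnum)
  cb <- .coordOf(res, "CB")
  if (!is.null(cb)) return(cb)
  if (res$resid[1L] == "GLY") {
    for (nm in c("HA2", "2HA", "HA1", "1HA")) {
      h <- .coordOf(res, nm)
      if (!is.null(h)) return(h)
    }
  }
  n <- .coordOf(res, "N"); ca <- .coordOf(res, "CA"); cc <- .coordOf(res, "C")
  if (is.null(n) || is.null(ca) || is.null(cc))
    stop(sprintf("residue %s/%s has no CB, no side-chain hydrogen and an incomplete backbone",
                 chain, resnum))
  placeInternal(cc, n, ca, 1.53, 110.5, 120.0)
}

#' Select the spherical simulation system
#'
#' Atoms within the sphere move freely. Protein atoms outside the sphere are
#' harmonically restrained to their initial coordinates (default force
#' constant 200 kcal mol^-1 A^-2) and excluded from non-bonded interactions;
#' non-protein atoms (waters, heterogroups) outside the sphere are dropped.
#'
#' @param x a \linkS4class{PdbStructure}.
#' @param center numeric 3-vector, sphere center (Angstrom).
#' @param diameter sphere diameter in Angstrom (default 50).
#' @param kOut positional restraint force constant for outside protein atoms.
#' @return a \linkS4class{SphereSelection}.
#' @export
selectSphere <- function(x, center, diameter = 50, kOut = 200) {
  stopifnot(length(center) == 3L, diameter > 0)
  a <- atoms(x)
  radius <- diameter / 2
  d <- sqrt((a$x - center[1L])^2 + (a$y - center[2L])^2 + (a$z - center[3L])^2)
  inside <- d <= radius
  prot <- .isProteinAtom(a)
  new("SphereSelection", center = as.numeric(center), radius = radius,
      freeIdx = which(inside),
      restrainedIdx = which(!inside & prot),
      excludedIdx = which(!inside & !prot),
      kOut = kOut)
}

# reference atom carrying the (de)protonatable charged group
.IONIZABLE_REF <- c(ARG = "CZ", LYS = "NZ", ASP = "CG", GLU = "CD",
                    HIS = "NE2", HIP = "NE2", HSP = "NE2")

#' Ionizable residues in the sphere outer layer
#'
#' Lists the ionizable residues whose charged-group reference atom (CZ for
#' Arg, NZ for Lys, CG for Asp, CD for Glu, NE2 for charged His) lies inside
#' the sphere but within \code{shell} Angstrom of its surface. These are the
#' residues a spherical-boundary setup neutralizes to avoid artifacts from
#' insufficient dielectric screening near the boundary.
#'
#' @param x a \linkS4class{PdbStructure}.
#' @param selection a \linkS4class{SphereSelection} computed on \code{x}.
#' @param shell shell thickness in Angstrom (default 3).
#' @return data.frame with columns chain, resno, resid, distance.
#' @export
outerLayerIonizables <- function(x, selection, shell = 3) {
  a <- atoms(x)
  hit <- a$resid %in% names(.IONIZABLE_REF) &
    a$elety == .IONIZABLE_REF[a$resid]
  out <- a[which(hit), , drop = FALSE]
  if (nrow(out) == 0L)
    return(data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), distance = numeric(0)))
  ctr <- selection@center
  d <- sqrt((out$x - ctr[1L])^2 + (out$y - ctr[2L])^2 + (out$z - ctr[3L])^2)
  sel <- d <= selection@radius & d > selection@radius - shell
  res <- data.frame(chain = out$chain[sel], resno = out$resno[sel],
                    resid = out$resid[sel], distance = d[sel],
                    stringsAsFactors = FALSE)
  res[order(res$chain, res$resno), , drop = FALSE]
}
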