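# Shipped amino-acid template library.
#
# The atom-type codes and partial charges form a minimal self-consistent set
# chosen so that every neutral residue sums to exactly 0 e (ionizable side
# chains to their formal charge) and so that chemically distinct positions
# carry distinct type codes (e.g. an aromatic C-H carbon vs the
# hydroxyl-substituted aromatic carbon of tyrosine). They make no claim of
# fidelity to any published force field: force-field parameter reproduction
# is out of scope for this toolkit, which only needs types for the
# restraint-eligibility rule and charges for the end-state bookkeeping.
#
# Internal coordinates use the convention that the third reference atom is
# the bonded parent; torsions flagged chi = k are the rotatable chi_k
# dihedrals (replaced by the wild-type value when a mutant side chain is
# built on an existing backbone).

# side-chain zmatrix row
.sc <- function(name, type, charge, r1, r2, r3, bond, angle, torsion,
                chi = 0L, heavy = TRUE) {
  data.frame(name = name, type = type, charge = charge,
             ref1 = r1, ref2 = r2, ref3 = r3,
             bond = bond, angle = angle, torsion = torsion,
             chi = as.integer(chi), heavy = heavy,
             stringsAsFactors = FALSE)
}

# three methyl hydrogens staggered about the r3 parent bond
.methylH <- function(stem, charge, r1, r2, r3, bond = 1.09, angle = 109.5) {
  rbind(.sc(paste0(stem, "1"), "HC", charge, r1, r2, r3, bond, angle,  60, heavy = FALSE),
        .sc(paste0(stem, "2"), "HC", charge, r1, r2, r3, bond, angle, 180, heavy = FALSE),
        .sc(paste0(stem, "3"), "HC", charge, r1, r2, r3, bond, angle, -60, heavy = FALSE))
}

# the two methylene hydrogens flanking a placed chain substituent `anchor`
.ch2H <- function(n2, n3, anchor, b, c_, charge = 0.06) {
  rbind(.sc(n2, "HC", charge, anchor, b, c_, 1.09, 109.4,  121, heavy = FALSE),
        .sc(n3, "HC", charge, anchor, b, c_, 1.09, 109.4, -121, heavy = FALSE))
}

.CB <- function(type = "CT", charge, bond = 1.53)
  .sc("CB", type, charge, "C", "N", "CA", bond, 110.5, 120.0)

.backboneAtoms <- function(resname) {
  if (resname == "GLY") {
    data.frame(
      name = c("N", "H", "CA", "HA2", "HA3", "C", "O"),
      type = c("N", "HN", "CT", "HC", "HC", "C", "O"),
      charge = c(-0.40, 0.25, 0.05, 0.05, 0.05, 0.55, -0.55),
      heavy = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
      sidechain = FALSE, stringsAsFactors = FALSE)
  } else if (resname == "PRO") {
    data.frame(
      name = c("N", "CA", "HA", "C", "O"),
      type = c("NP", "CT", "HC", "C", "O"),
      charge = c(-0.15, 0.10, 0.05, 0.55, -0.55),
      heavy = c(TRUE, TRUE, FALSE, TRUE, TRUE),
      sidechain = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame(
      name = c("N", "H", "CA", "HA", "C", "O"),
      type = c("N", "HN", "CT", "HC", "C", "O"),
      charge = c(-0.40, 0.25, 0.10, 0.05, 0.55, -0.55),
      heavy = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
      sidechain = FALSE, stringsAsFactors = FALSE)
  }
}

.backboneBonds <- function(resname) {
  if (resname == "GLY")
    data.frame(a = c("N", "N", "CA", "CA", "CA", "C"),
               b = c("H", "CA", "HA2", "HA3", "C", "O"),
               stringsAsFactors = FALSE)
  else if (resname == "PRO")
    data.frame(a = c("N", "CA", "CA", "C"),
               b = c("CA", "HA", "C", "O"), stringsAsFactors = FALSE)
  else
    data.frame(a = c("N", "N", "CA", "CA", "C"),
               b = c("H", "CA", "HA", "C", "O"), stringsAsFactors = FALSE)
}

.mkTemplate <- function(name, sc = NULL, closures = NULL) {
  bb <- .backboneAtoms(name)
  bonds <- .backboneBonds(name)
  if (!is.null(sc) && nrow(sc)) {
    at <- data.frame(name = sc$name, type = sc$type, charge = sc$charge,
                     heavy = sc$heavy, sidechain = TRUE,
                     stringsAsFactors = FALSE)
    atoms <- rbind(bb, at)
    # every zmatrix row bonds to its third reference
    bonds <- rbind(bonds, data.frame(a = sc$ref3, b = sc$name,
                                     stringsAsFactors = FALSE))
    zm <- sc[, c("name", "ref1", "ref2", "ref3",
                 "bond", "angle", "torsion", "chi")]
    names(zm)[1L] <- "atom"
  } else {
    atoms <- bb
    zm <- data.frame(atom = character(0), ref1 = character(0),
                     ref2 = character(0), ref3 = character(0),
                     bond = numeric(0), angle = numeric(0),
                     torsion = numeric(0), chi = integer(0),
                     stringsAsFactors = FALSE)
  }
  if (!is.null(closures))
    bonds <- rbind(bonds, do.call(rbind, lapply(closures, function(p)
      data.frame(a = p[1L], b = p[2L], stringsAsFactors = FALSE))))
  new("ResidueTemplate", name = name, atoms = atoms, bonds = bonds,
      zmatrix = zm)
}

.buildTemplateLibrary <- function() {
  lib <- list()

  lib$GLY <- .mkTemplate("GLY")

  lib$ALA <- .mkTemplate("ALA", rbind(
    .CB("CT", -0.18),
    .methylH("HB", 0.06, "N", "CA", "CB")))

  lib$VAL <- .mkTemplate("VAL", rbind(
    .CB("CT", -0.06),
    .sc("CG1", "CT", -0.18, "N", "CA", "CB", 1.526, 110.7, -65, chi = 1L),
    .sc("CG2", "CT", -0.18, "CG1", "CA", "CB", 1.526, 110.7, 122.5),
    .sc("HB", "HC", 0.06, "CG1", "CA", "CB", 1.09, 108.0, -118, heavy = FALSE),
    .methylH("HG1", 0.06, "CA", "CB", "CG1"),
    .methylH("HG2", 0.06, "CA", "CB", "CG2")))

  lib$LEU <- .mkTemplate("LEU", rbind(
    .CB("CT", -0.12),
    .sc("CG", "CT", -0.06, "N", "CA", "CB", 1.526, 114.0, -65, chi = 1L),
    .ch2H("HB2", "HB3", "CG", "CA", "CB"),
    .sc("CD1", "CT", -0.18, "CA", "CB", "CG", 1.526, 110.7, 180, chi = 2L),
    .sc("CD2", "CT", -0.18, "CD1", "CB", "CG", 1.526, 110.7, 122.5),
    .sc("HG", "HC", 0.06, "CD1", "CB", "CG", 1.09, 108.0, -118, heavy = FALSE),
    .methylH("HD1", 0.06, "CB", "CG", "CD1"),
    .methylH("HD2", 0.06, "CB", "CG", "CD2")))

  lib$ILE <- .mkTemplate("ILE", rbind(
    .CB("CT", -0.06),
    .sc("CG1", "CT", -0.12, "N", "CA", "CB", 1.526, 110.7, -65, chi = 1L),
    .sc("CG2", "CT", -0.18, "CG1", "CA", "CB", 1.526, 110.7, -122.5),
    .sc("HB", "HC", 0.06, "CG1", "CA", "CB", 1.09, 108.0, 118, heavy = FALSE),
    .sc("CD1", "CT", -0.18, "CA", "CB", "CG1", 1.526, 110.7, 180, chi = 2L),
    .ch2H("HG12", "HG13", "CD1", "CB", "CG1"),
    .methylH("HG2", 0.06, "CA", "CB", "CG2"),
    .methylH("HD1", 0.06, "CB", "CG1", "CD1")))

  lib$SER <- .mkTemplate("SER", rbind(
    .CB("CT", 0.145),
    .sc("OG", "OH", -0.683, "N", "CA", "CB", 1.41, 110.8, -65, chi = 1L),
    .ch2H("HB2", "HB3", "OG", "CA", "CB"),
    .sc("HG", "HO", 0.418, "CA", "CB", "OG", 0.96, 109.0, 180, heavy = FALSE)))

  lib$THR <- .mkTemplate("THR", rbind(
    .CB("CT", 0.205),
    .sc("OG1", "OH", -0.683, "N", "CA", "CB", 1.41, 109.6, -65, chi = 1L),
    .sc("CG2", "CT", -0.18, "OG1", "CA", "CB", 1.526, 110.7, -122.5),
    .sc("HB", "HC", 0.06, "OG1", "CA", "CB", 1.09, 108.0, 118, heavy = FALSE),
    .sc("HG1", "HO", 0.418, "CA", "CB", "OG1", 0.96, 109.0, 180, heavy = FALSE),
    .methylH("HG2", 0.06, "CA", "CB", "CG2")))

  lib$CYS <- .mkTemplate("CYS", rbind(
    .CB("CT", 0.06),
    .sc("SG", "SH", -0.335, "N", "CA", "CB", 1.81, 108.6, -65, chi = 1L),
    .ch2H("HB2", "HB3", "SG", "CA", "CB"),
    .sc("HG", "HS", 0.155, "CA", "CB", "SG", 1.34, 96.0, 180, heavy = FALSE)))

  lib$MET <- .mkTemplate("MET", rbind(
    .CB("CT", -0.12),
    .sc("CG", "CT", 0.00, "N", "CA", "CB", 1.526, 114.0, -65, chi = 1L),
    .ch2H("HB2", "HB3", "CG", "CA", "CB"),
    .sc("SD", "S", -0.30, "CA", "CB", "CG", 1.81, 112.7, 180, chi = 2L),
    .ch2H("HG2", "HG3", "SD", "CB", "CG"),
    .sc("CE", "CT", 0.00, "CB", "CG", "SD", 1.79, 100.9, 180, chi = 3L),
    .methylH("HE", 0.06, "CG", "SD", "CE")))

  lib$ASN <- .mkTemplate("ASN", rbind(
    .CB("CT", -0.12),
    .sc("CG", "CAM", 0.50, "N", "CA", "CB", 1.52, 112.7, -65, chi = 1L),
    .ch2H("HB2", "HB3", "CG", "CA", "CB"),
    .sc("OD1", "OAM", -0.50, "CA", "CB", "CG", 1.23, 120.4, -65, chi = 2L),
    .sc("ND2", "NAM", -0.76, "OD1", "CB", "CG", 1.33, 116.7, 180),
    .sc("HD21", "HN", 0.38, "CB", "CG", "ND2", 1.01, 119.0, 180, heavy = FALSE),
    .sc("HD22", "HN", 0.38, "CB", "CG", "ND2", 1.01, 119.0, 0, heavy = FALSE)))

  lib$GLN <- .mkTemplate("GLN", rbind(
    .CB("CT", -0.12),
    .sc("CG", "CT", -0.12, "N", "CA", "CB", 1.526, 114.0, -65, chi = 1L),
    .ch2H("HB2", "HB3", "CG", "CA", "CB"),
    .sc("CD", "CAM", 0.50, "CA", "CB", "CG", 1.52, 112.7, 180, chi = 2L),
    .ch2H("HG2", "HG3", "CD", "CB", "CG"),
    .sc("OE1", "OAM", -0.50, "CB", "CG", "CD", 1.23, 120.4, -65, chi = 3L),
    .sc("NE2", "NAM", -0.76, "OE1", "CG", "CD", 1.33, 116.7, 180),
    .sc("HE21", "HN", 0.38, "CG", "CD", "NE2", 1.01, 119.0, 180, heavy = FALSE),
    .sc("HE22", "HN", 0.38, "CG", "CD", "NE2", 1.01, 119.0, 0, heavy = FALSE)))

  lib$PHE <- .mkTemplate("PHE", rbind(
    .CB("CT", -0.12),
    .sc("CG", "CAJ", 0.00, "N", "CA", "CB", 1.51, 114.0, -65, chi = 1L),
    .ch2H("HB2", "HB3", "CG", "CA", "CB"),
    .sc("CD1", "CA", -0.115, "CA", "CB", "CG", 1.39, 120.6, 90, chi = 2L),
    .sc("CD2", "CA", -0.115, "CD1", "CB", "CG", 1.39, 120.6, 180),
    .sc("CE1", "CA", -0.115, "CB", "CG", "CD1", 1.39, 120.3, 180),
    .sc("CE2", "CA", -0.115, "CB", "CG", "CD2", 1.39, 120.3, 180),
    .sc("CZ", "CA", -0.115, "CG", "CD1", "CE1", 1.39, 120.0, 0),
    .sc("HD1", "HAR", 0.115, "CB", "CG", "CD1", 1.08, 120.0, 0, heavy = FALSE),
    .sc("HD2", "HAR", 0.115, "CB", "CG", "CD2", 1.08, 120.0, 0, heavy = FALSE),
    .sc("HE1", "HAR", 0.115, "CG", "CD1", "CE1", 1.08, 120.0, 0, heavy = FALSE),
    .sc("HE2", "HAR", 0.115, "CG", "CD2", "CE2", 1.08, 120.0, 0, heavy = FALSE),
    .sc("HZ", "HAR", 0.115, "CD1", "CE1", "CZ", 1.08, 120.0, 180, heavy = FALSE)),
    closures = list(c("CZ", "CE2")))

  lib$TYR <- .mkTemplate("TYR", rbind(
    .CB("CT", -0.12),
    .sc("CG", "CAJ", 0.00, "N", "CA", "CB", 1.51, 114.0, -65, chi = 1L),
    .ch2H("HB2", "HB3", "CG", "CA", "CB"),
    .sc("CD1", "CA", -0.115, "CA", "CB", "CG", 1.39, 120.6, 90, chi = 2L),
    .sc("CD2", "CA", -0.115, "CD1", "CB", "CG", 1.39, 120.6, 180),
    .sc("CE1", "CA", -0.115, "CB", "CG", "CD1", 1.39, 120.3, 180),
    .sc("CE2", "CA", -0.115, "CB", "CG", "CD2", 1.39, 120.3, 180),
    .sc("CZ", "CAO", 0.15, "CG", "CD1", "CE1", 1.39, 120.0, 0),
    .sc("OH", "OH", -0.585, "CD1", "CE1", "CZ", 1.36, 120.0, 180),
    .sc("HD1", "HAR", 0.115, "CB", "CG", "CD1", 1.08, 120.0, 0, heavy = FALSE),
    .sc("HD2", "HAR", 0.115, "CB", "CG", "CD2", 1.08, 120.0, 0, heavy = FALSE),
    .sc("HE1", "HAR", 0.115, "CG", "CD1", "CE1", 1.08, 120.0, 0, heavy = FALSE),
    .sc("HE2", "HAR", 0.115, "CG", "CD2", "CE2", 1.08, 120.0, 0, heavy = FALSE),
    .sc("HH", "HO", 0.435, "CE1", "CZ", "OH", 0.96, 110.0, 0, heavy = FALSE)),
    closures = list(c("CZ", "CE2")))

  lib$TRP <- .mkTemplate("TRP", rbind(
    .CB("CT", -0.12),
    .sc("CG", "CST", -0.115, "N", "CA", "CB", 1.50, 114.0, -65, chi = 1L),
    .ch2H("HB2", "HB3", "CG", "CA", "CB"),
    .sc("CD1", "CW", 0.05, "CA", "CB", "CG", 1.37, 127.0, 90, chi = 2L),
    .sc("CD2", "CBT", -0.10, "CD1", "CB", "CG", 1.43, 126.6, 180),
    .sc("NE1", "NA", -0.50, "CB", "CG", "CD1", 1.37, 110.0, 180),
    .sc("CE2", "CN", 0.15, "CG", "CD1", "NE1", 1.37, 109.0, 0),
    .sc("CE3", "CA", -0.115, "CD1", "CG", "CD2", 1.40, 134.0, 180),
    .sc("CZ2", "CA", -0.115, "CG", "CD2", "CE2", 1.40, 122.0, 180),
    .sc("CZ3", "CA", -0.115, "CE2", "CD2", "CE3", 1.39, 118.0, 0),
    .sc("CH2", "CA", -0.115, "CD2", "CE3", "CZ3", 1.39, 121.0, 0),
    .sc("HD1", "HAR", 0.115, "CB", "CG", "CD1", 1.08, 126.0, 0, heavy = FALSE),
    .sc("HE1", "HN", 0.40, "CG", "CD1", "NE1", 1.01, 125.0, 180, heavy = FALSE),
    .sc("HE3", "HAR", 0.115, "CG", "CD2", "CE3", 1.08, 120.0, 0, heavy = FALSE),
    .sc("HZ2", "HAR", 0.115, "CD2", "CE2", "CZ2", 1.08, 119.0, 180, heavy = FALSE),
    .sc("HZ3", "HAR", 0.115, "CD2", "CE3", "CZ3", 1.08, 119.0, 180, heavy = FALSE),
    .sc("HH2", "HAR", 0.115, "CE3", "CZ3", "CH2", 1.08, 119.0, 180, heavy = FALSE)),
    closures = list(c("CD2", "CE2"), c("CZ2", "CH2")))

  lib$HIS <- .mkTemplate("HIS", rbind(
    .CB("CT", -0.12),
    .sc("CG", "CC", -0.09, "N", "CA", "CB", 1.50, 114.0, -65, chi = 1L),
    .ch2H("HB2", "HB3", "CG", "CA", "CB"),
    .sc("ND1", "NB", -0.56, "CA", "CB", "CG", 1.38, 122.0, -75, chi = 2L),
    .sc("CD2", "CV", 0.12, "ND1", "CB", "CG", 1.36, 131.0, 180),
    .sc("CE1", "CR", 0.39, "CB", "CG", "ND1", 1.32, 109.5, 180),
    .sc("NE2", "NA", -0.51, "CG", "ND1", "CE1", 1.34, 111.0, 0),
    .sc("HD2", "HAR", 0.10, "CB", "CG", "CD2", 1.08, 129.0, 0, heavy = FALSE),
    .sc("HE1", "HAR", 0.13, "CG", "ND1", "CE1", 1.08, 124.0, 180, heavy = FALSE),
    .sc("HE2", "HN", 0.42, "ND1", "CE1", "NE2", 1.01, 125.0, 180, heavy = FALSE)),
    closures = list(c("NE2", "CD2")))

  lib$ASP <- .mkTemplate("ASP", rbind(
    .CB("CT", -0.22),
    .sc("CG", "CO2", 0.70, "N", "CA", "CB", 1.52, 112.7, -65, chi = 1L),
    .ch2H("HB2", "HB3", "CG", "CA", "CB"),
    .sc("OD1", "O2", -0.80, "CA", "CB", "CG", 1.25, 117.0, 90, chi = 2L),
    .sc("OD2", "O2", -0.80, "OD1", "CB", "CG", 1.25, 117.0, 180)))

  lib$GLU <- .mkTemplate("GLU", rbind(
    .CB("CT", -0.12),
    .sc("CG", "CT", -0.22, "N", "CA", "CB", 1.526, 114.0, -65, chi = 1L),
    .ch2H("HB2", "HB3", "CG", "CA", "CB"),
    .sc("CD", "CO2", 0.70, "CA", "CB", "CG", 1.52, 112.7, 180, chi = 2L),
    .ch2H("HG2", "HG3", "CD", "CB", "CG"),
    .sc("OE1", "O2", -0.80, "CB", "CG", "CD", 1.25, 117.0, 90, chi = 3L),
    .sc("OE2", "O2", -0.80, "OE1", "CG", "CD", 1.25, 117.0, 180)))

  lib$LYS <- .mkTemplate("LYS", rbind(
    .CB("CT", -0.12),
    .sc("CG", "CT", -0.12, "N", "CA", "CB", 1.526, 114.0, -65, chi = 1L),
    .ch2H("HB2", "HB3", "CG", "CA", "CB"),
    .sc("CD", "CT", -0.12, "CA", "CB", "CG", 1.526, 110.7, 180, chi = 2L),
    .ch2H("HG2", "HG3", "CD", "CB", "CG"),
    .sc("CE", "CT", 0.19, "CB", "CG", "CD", 1.526, 110.7, 180, chi = 3L),
    .ch2H("HD2", "HD3", "CE", "CG", "CD"),
    .sc("NZ", "N3", -0.30, "CG", "CD", "CE", 1.47, 111.0, 180, chi = 4L),
    .ch2H("HE2", "HE3", "NZ", "CD", "CE"),
    .sc("HZ1", "HN3", 0.33, "CD", "CE", "NZ", 1.01, 109.5, 60, heavy = FALSE),
    .sc("HZ2", "HN3", 0.33, "CD", "CE", "NZ", 1.01, 109.5, 180, heavy = FALSE),
    .sc("HZ3", "HN3", 0.33, "CD", "CE", "NZ", 1.01, 109.5, -60, heavy = FALSE)))

  lib$ARG <- .mkTemplate("ARG", rbind(
    .CB("CT", -0.12),
    .sc("CG", "CT", -0.12, "N", "CA", "CB", 1.526, 114.0, -65, chi = 1L),
    .ch2H("HB2", "HB3", "CG", "CA", "CB"),
    .sc("CD", "CT", 0.19, "CA", "CB", "CG", 1.526, 110.7, 180, chi = 2L),
    .ch2H("HG2", "HG3", "CD", "CB", "CG"),
    .sc("NE", "N2", -0.70, "CB", "CG", "CD", 1.47, 111.0, 180, chi = 3L),
    .ch2H("HD2", "HD3", "NE", "CG", "CD"),
    .sc("CZ", "CGU", 0.71, "CG", "CD", "NE", 1.33, 124.0, 180, chi = 4L),
    .sc("NH1", "N2", -0.80, "CD", "NE", "CZ", 1.33, 120.0, 0),
    .sc("NH2", "N2", -0.80, "NH1", "NE", "CZ", 1.33, 120.0, 180),
    .sc("HE", "HN", 0.44, "NH1", "CZ", "NE", 1.01, 118.0, 180, heavy = FALSE),
    .sc("HH11", "HN", 0.46, "NE", "CZ", "NH1", 1.01, 120.0, 0, heavy = FALSE),
    .sc("HH12", "HN", 0.46, "NE", "CZ", "NH1", 1.01, 120.0, 180, heavy = FALSE),
    .sc("HH21", "HN", 0.46, "NE", "CZ", "NH2", 1.01, 120.0, 0, heavy = FALSE),
    .sc("HH22", "HN", 0.46, "NE", "CZ", "NH2", 1.01, 120.0, 180, heavy = FALSE)))

  lib$PRO <- .mkTemplate("PRO", rbind(
    .sc("CB", "CT", -0.12, "C", "N", "CA", 1.53, 103.0, 115.0),
    .sc("CG", "CT", -0.12, "N", "CA", "CB", 1.495, 104.0, 30, chi = 1L),
    .ch2H("HB2", "HB3", "CG", "CA", "CB"),
    .sc("CD", "CT", -0.12, "CA", "CB", "CG", 1.50, 105.0, -35, chi = 2L),
    .ch2H("HG2", "HG3", "CD", "CB", "CG"),
    .ch2H("HD2", "HD3", "N", "CG", "CD")),
    closures = list(c("CD", "N")))

  # Caps: acetyl (N-terminal) and N-methylamide (C-terminal). Their
  # coordinates are constructed by the peptide builder relative to the
  # adjacent residue, so they carry no zmatrix of their own.
  ace <- new("ResidueTemplate", name = "ACE",
             atoms = data.frame(
               name = c("CH3", "HH31", "HH32", "HH33", "C", "O"),
               type = c("CT", "HC", "HC", "HC", "C", "O"),
               charge = c(-0.18, 0.06, 0.06, 0.06, 0.50, -0.50),
               heavy = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
               sidechain = FALSE, stringsAsFactors = FALSE),
             bonds = data.frame(a = c("CH3", "CH3", "CH3", "CH3", "C"),
                                b = c("HH31", "HH32", "HH33", "C", "O"),
                                stringsAsFactors = FALSE),
             zmatrix = data.frame(atom = character(0), ref1 = character(0),
                                  ref2 = character(0), ref3 = character(0),
                                  bond = numeric(0), angle = numeric(0),
                                  torsion = numeric(0), chi = integer(0)))
  nme <- new("ResidueTemplate", name = "NME",
             atoms = data.frame(
               name = c("N", "H", "CH3", "HH31", "HH32", "HH33"),
               type = c("N", "HN", "CT", "HC", "HC", "HC"),
               charge = c(-0.46, 0.30, -0.02, 0.06, 0.06, 0.06),
               heavy = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
               sidechain = FALSE, stringsAsFactors = FALSE),
             bonds = data.frame(a = c("N", "N", "CH3", "CH3", "CH3"),
                                b = c("H", "CH3", "HH31", "HH32", "HH33"),
                                stringsAsFactors = FALSE),
             zmatrix = data.frame(atom = character(0), ref1 = character(0),
                                  ref2 = character(0), ref3 = character(0),
                                  bond = numeric(0), angle = numeric(0),
                                  torsion = numeric(0), chi = integer(0)))
  lib$ACE <- ace
  lib$NME <- nme
  lib
}

# Built once at load time; templates are immutable.
.templateEnv <- new.env(parent = emptyenv())

.templates <- function() {
  if (is.null(.templateEnv$lib)) .templateEnv$lib <- .buildTemplateLibrary()
  .templateEnv$lib
}
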