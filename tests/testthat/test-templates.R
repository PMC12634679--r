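test_that("templates carry the expected composition and charges", {
  ala <- getTemplate("ALA")
  expect_equal(sum(atoms(ala)$sidechain & atoms(ala)$heavy), 1L)
  lvl <- sideChainLevels(getTemplate("TYR"))
  expect_equal(lvl[c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH")],
               c(CB = 1L, CG = 2L, CD1 = 3L, CD2 = 3L, CE1 = 4L, CE2 = 4L,
                 CZ = 5L, OH = 6L))
  for (nm in c("ALA", "ASN", "GLN", "GLY", "HIS", "ILE", "LEU", "MET",
               "PHE", "SER", "THR", "TRP", "TYR", "VAL", "CYS", "PRO",
               "ACE", "NME")) {
    expect_equal(sum(atoms(getTemplate(nm))$charge), 0, tolerance = 1e-6,
                 label = paste("net charge of", nm))
  }
  expect_equal(sum(atoms(getTemplate("ASP"))$charge), -1, tolerance = 1e-6)
  expect_equal(sum(atoms(getTemplate("LYS"))$charge), 1, tolerance = 1e-6)
})

test_that("levels start at CB and increase along bonds away from CA", {
  for (nm in supportedResidues()) {
    lvl <- sideChainLevels(getTemplate(nm))
    if (!length(lvl)) next   # glycine
    expect_equal(unname(lvl["CB"]), 1L)
    tpl <- getTemplate(nm)
    b <- tpl@bonds
    heavy <- names(lvl)
    sc <- b[b$a %in% heavy & b$b %in% heavy, ]
    expect_true(all(abs(lvl[sc$a] - lvl[sc$b]) <= 1L),
                label = paste("level steps of", nm))
  }
})

test_that("unknown and proline-endpoint templates are rejected", {
  expect_error(getTemplate("XYZ"), "unknown")
  expect_error(getTemplate("PRO", role = "mutation"), "unsupported")
  expect_s4_class(getTemplate("PRO"), "ResidueTemplate")
})

test_that("self-mutation reproduces the wild-type side chain", {
  s <- buildIdealPeptide(c("GLY", "LEU", "GLY"))
  wt <- sideChainCoords(s, "A", 2L)
  built <- placeMutantSideChain(s, "A", 2L, "LEU")
  shared <- intersect(wt$elety, built$elety)
  dev <- vapply(shared, function(nm) {
    p1 <- as.numeric(wt[wt$elety == nm, c("x", "y", "z")])
    p2 <- as.numeric(built[built$elety == nm, c("x", "y", "z")])
    sqrt(sum((p1 - p2)^2))
  }, numeric(1L))
  expect_lt(max(dev), 0.1)
})

test_that("glycine to alanine adds one heavy atom at ideal CB geometry", {
  s <- buildIdealPeptide(c("ALA", "GLY", "ALA"))
  built <- placeMutantSideChain(s, "A", 2L, "ALA")
  expect_equal(sum(built$elety == "CB"), 1L)
  ca <- as.numeric(getResidue(s, "A", 2)[
    getResidue(s, "A", 2)$elety == "CA", c("x", "y", "z")])
  cb <- as.numeric(built[built$elety == "CB", c("x", "y", "z")])
  expect_equal(sqrt(sum((cb - ca)^2)), 1.53, tolerance = 0.01)
})

test_that("aromatic substitutions preserve the ring when chis are copied", {
  s <- buildIdealPeptide(c("GLY", "TYR", "GLY"))
  wt <- sideChainCoords(s, "A", 2L)
  phe <- placeMutantSideChain(s, "A", 2L, "PHE")
  for (nm in c("CB", "CG", "CD1", "CD2", "CE1", "CE2")) {
    p1 <- as.numeric(wt[wt$elety == nm, c("x", "y", "z")])
    p2 <- as.numeric(phe[phe$elety == nm, c("x", "y", "z")])
    expect_lt(sqrt(sum((p1 - p2)^2)), 0.5)
  }
})

test_that("placement is deterministic and preserves L chirality", {
  s <- buildIdealPeptide(c("GLY", "THR", "GLY"))
  b1 <- placeMutantSideChain(s, "A", 2L, "TRP")
  b2 <- placeMutantSideChain(s, "A", 2L, "TRP")
  expect_identical(b1, b2)
  res <- getResidue(s, "A", 2)
  g <- function(df, nm) as.numeric(df[df$elety == nm, c("x", "y", "z")])
  sv <- function(p0, p1, p2, p3) {
    v1 <- p1 - p0; v2 <- p2 - p0; v3 <- p3 - p0
    sum(c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1]) * v3)
  }
  svWt <- sv(g(res, "CA"), g(res, "N"), g(res, "C"), g(res, "CB"))
  svMut <- sv(g(res, "CA"), g(res, "N"), g(res, "C"), g(b1, "CB"))
  expect_gt(svWt * svMut, 0)
})

test_that("proline mutations and broken backbones are rejected", {
  s <- buildIdealPeptide(c("GLY", "LEU", "GLY"))
  expect_error(placeMutantSideChain(s, "A", 2L, "PRO"), "proline|unsupported")
  a <- atoms(s)
  a <- a[!(a$resno == 2L & a$elety == "CA"), ]
  a$eleno <- seq_len(nrow(a))
  expect_error(placeMutantSideChain(new("PdbStructure", atoms = a),
                                    "A", 2L, "ALA"), "backbone")
})

test_that("reference peptide schemes assemble the right units", {
  s <- buildIdealPeptide("KYT", startResno = 24)
  pz <- buildReferencePeptide(s, "A", 25, "ZXZ")
  resl <- unique(atoms(pz)[, c("resno", "resid")])
  expect_equal(resl$resid[order(resl$resno)],
               c("ACE", "LYS", "TYR", "THR", "NME"))
  pa <- buildReferencePeptide(s, "A", 25, "AXA")
  expect_equal(sort(unique(atoms(pa)$resid)),
               sort(c("ACE", "ALA", "TYR", "NME")))
  pg <- buildReferencePeptide(s, "A", 25, "GXG")
  expect_equal(sort(unique(atoms(pg)$resid)),
               sort(c("ACE", "GLY", "TYR", "NME")))
  px <- buildReferencePeptide(s, "A", 25, "X")
  resx <- unique(atoms(px)[, c("resno", "resid")])
  expect_equal(nrow(resx), 3L)   # cap - TYR - cap
  expect_equal(resx$resid[order(resx$resno)], c("ACE", "TYR", "NME"))
})

test_that("the peptide's mutable residue keeps the protein-site coordinates", {
  s <- buildIdealPeptide("KYT", startResno = 24)
  site <- getResidue(s, "A", 25)
  for (scheme in c("ZXZ", "AXA", "GXG", "X")) {
    p <- buildReferencePeptide(s, "A", 25, scheme)
    cen <- atoms(p)[atoms(p)$resno == p@centralResno, ]
    shared <- intersect(cen$elety, site$elety)
    expect_gt(length(shared), 3L)
    for (nm in shared) {
      expect_equal(
        as.numeric(cen[cen$elety == nm, c("x", "y", "z")]),
        as.numeric(site[site$elety == nm, c("x", "y", "z")]),
        label = paste(scheme, nm))
    }
  }
})

test_that("terminal residues cannot anchor tripeptide schemes", {
  s <- buildIdealPeptide("KYT", startResno = 24)
  expect_error(buildReferencePeptide(s, "A", 24, "ZXZ"), "terminal")
  expect_error(buildReferencePeptide(s, "A", 26, "AXA"), "terminal")
  expect_s4_class(buildReferencePeptide(s, "A", 24, "X"), "PeptideModel")
})
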