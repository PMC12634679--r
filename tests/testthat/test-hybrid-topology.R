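test_that("branched aliphatic mapping follows the stated tie-breaks", {
  m <- mappingWithCoords("LEU", "ILE")
  p <- mappedPairs(m)
  expect_equal(p$wt[p$level == 1L], "CB")
  expect_equal(p$mut[p$level == 1L], "CB")
  expect_equal(p$mut[p$wt == "CG"], "CG1")   # chain continuation by descendants
  expect_equal(p$mut[p$wt == "CD1"], "CD1")
  expect_true("CG2" %in% m@unmatchedMut)
})

test_that("aromatic mapping pairs the ring and leaves the hydroxyl unmatched", {
  m <- mappingWithCoords("TYR", "PHE")
  p <- mappedPairs(m)
  for (nm in c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
    expect_equal(p$mut[p$wt == nm], nm)
  expect_equal(m@unmatchedWt, "OH")
  expect_false(p$typeMatch[p$wt == "CZ"])   # hydroxyl- vs H-substituted carbon
})

test_that("minimal and empty mappings behave as specified", {
  m <- mappingWithCoords("ALA", "SER")
  p <- mappedPairs(m)
  expect_equal(nrow(p), 1L)
  expect_equal(p$wt, "CB")
  expect_equal(m@unmatchedMut, "OG")
  g <- mapAnalogousAtoms("GLY", "TRP")
  expect_equal(nrow(mappedPairs(g)), 0L)
  expect_equal(length(g@unmatchedWt), 0L)
  expect_gt(length(g@unmatchedMut), 0L)
})

test_that("mapping is symmetric across all supported residue pairs", {
  res <- supportedResidues()
  for (wt in res) for (mut in res) {
    m1 <- mappingWithCoords(wt, mut)
    # reversed mapping on the same geometry
    s <- buildIdealPeptide(c("GLY", wt, "GLY"))
    wtc <- sideChainCoords(s, "A", 2L)
    mutc <- placeMutantSideChain(s, "A", 2L, mut)
    m2 <- mapAnalogousAtoms(mut, wt, mutc, wtc)
    p1 <- mappedPairs(m1)
    p2 <- mappedPairs(m2)
    expect_setequal(paste(p1$wt, p1$mut), paste(p2$mut, p2$wt))
  }
})

test_that("restraints form a contiguous prefix for every supported pair", {
  res <- supportedResidues()
  for (wt in res) for (mut in res) {
    m <- mappingWithCoords(wt, mut)
    rs <- assignRestraints(m)
    p <- mappedPairs(m)
    k <- nrow(rs@pairs)
    expect_true(k <= nrow(p))
    if (k > 0L) {
      expect_identical(rs@pairs$wt, p$wt[seq_len(k)])
      expect_true(all(p$typeMatch[seq_len(k)]))
      expect_true(all(p$distance[seq_len(k)] <= 0.5))
    }
    if (nrow(p) == 0L) expect_equal(rs@stopReason, "exhausted")
    expect_true(rs@stopReason %in% c("type-mismatch", "distance", "exhausted"))
    expect_equal(rs@k, 10.0)
  }
})

test_that("restraint walk stops for the right reason", {
  m <- mappingWithCoords("TYR", "PHE")
  rs <- assignRestraints(m)
  expect_setequal(rs@pairs$wt, c("CB", "CG", "CD1", "CD2", "CE1", "CE2"))
  expect_equal(rs@stopReason, "type-mismatch")

  # a pair displaced beyond the cutoff stops the walk on distance
  p <- mappedPairs(m)
  p$distance[p$wt == "CG"] <- 0.6
  m2 <- new("AtomMapping", pairs = p, unmatchedWt = m@unmatchedWt,
            unmatchedMut = m@unmatchedMut, wtName = "TYR", mutName = "PHE")
  rs2 <- assignRestraints(m2)
  expect_equal(rs2@pairs$wt, "CB")
  expect_equal(rs2@stopReason, "distance")

  rs3 <- assignRestraints(mapAnalogousAtoms("GLY", "ALA"))
  expect_equal(nrow(rs3@pairs), 0L)
  expect_equal(rs3@stopReason, "exhausted")
})

test_that("exclusion lists cover all wt x mut side-chain pairs", {
  ht <- buildHybridTopology("LEU", "ILE")
  expect_equal(length(ht@wtAtoms), 13L)
  expect_equal(length(ht@mutAtoms), 13L)
  expect_equal(nrow(ht@exclusions), 169L)
  for (wt in c("ALA", "SER", "TYR")) for (mut in c("VAL", "HIS")) {
    h <- buildHybridTopology(wt, mut)
    expect_equal(nrow(h@exclusions),
                 length(h@wtAtoms) * length(h@mutAtoms))
  }
})

test_that("deactivated bonded terms are the CB-CA-CB angle and its torsions", {
  ht <- buildHybridTopology("LEU", "ILE")
  expect_equal(nrow(ht@deactivatedAngles), 1L)
  expect_equal(ht@deactivatedAngles$vertex, "CA")
  # every torsion runs through the deactivated angle
  t <- ht@deactivatedTorsions
  through <- (t$b == "CB" & t$c == "CA") | (t$b == "CA" & t$c == "CB")
  expect_true(all(through))
  # x atoms bonded to CBwt plus y atoms bonded to CBmut, CA excluded
  nx <- sum(t$aSet == "wt" & t$b == "CB")
  ny <- sum(t$dSet == "mut" & t$c == "CB")
  expect_equal(nx + ny, nrow(t))
  expect_gt(nx, 0L); expect_gt(ny, 0L)
  # glycine involvement leaves nothing to deactivate
  hg <- buildHybridTopology("GLY", "ALA")
  expect_equal(nrow(hg@deactivatedAngles), 0L)
  expect_equal(nrow(hg@deactivatedTorsions), 0L)
})

test_that("end states conserve the active net charge and stage markers", {
  ht <- buildHybridTopology("LEU", "ILE")
  es <- ht@endStates
  expect_equal(sum(es$q0[es$set == "wt"]), sum(es$q1[es$set == "mut"]),
               tolerance = 1e-9)
  expect_equal(sum(es$q0[es$set == "mut"]), 0)
  expect_equal(sum(es$q1[es$set == "wt"]), 0)
  expect_true(ht@stages[[1L]]$softcore)
  expect_false(ht@stages[[2L]]$softcore)
  expect_equal(ht@stages[[1L]]$charges, "wt:1->0")
  expect_equal(ht@stages[[2L]]$charges, "mut:0->1")
})

test_that("charge-changing and proline mutations are rejected", {
  expect_error(buildHybridTopology("LEU", "ASP"), "charge-changing")
  expect_error(buildHybridTopology("LYS", "ALA"), "charge-changing")
  expect_error(buildHybridTopology("ALA", "PRO"), "unsupported")
  # like-charged swaps conserve the net charge and are allowed
  expect_s4_class(buildHybridTopology("ASP", "GLU"), "HybridTopology")
})

test_that("soft-core specification validates alpha", {
  expect_error(new("SoftCoreSpec", form = "shifted-r6", alpha = -1),
               "alpha")
  sc <- new("SoftCoreSpec")
  expect_equal(sc@alpha, 0.5)
})

test_that("job specs carry identical restraint tables in both legs", {
  s <- buildIdealPeptide("KYT", startResno = 24)
  wtc <- sideChainCoords(s, "A", 25L)
  mutc <- placeMutantSideChain(s, "A", 25L, "PHE")
  m <- mapAnalogousAtoms("TYR", "PHE", wtc, mutc)
  rs <- assignRestraints(m)
  ht <- buildHybridTopology("TYR", "PHE", m)
  sel <- selectSphere(s, mutationCenter(s, "A", 25))
  pep <- buildReferencePeptide(s, "A", 25, "ZXZ")
  js <- emitJobSpec(ht, buildProtocol("H"), rs, sel, pep)
  extract <- function(doc) jsonlite::fromJSON(doc)$restraints
  expect_identical(extract(js$protein), extract(js$peptide))
  # re-emission is byte-identical
  expect_identical(js, emitJobSpec(ht, buildProtocol("H"), rs, sel, pep))
  # a differing peptide-leg scheme is an inconsistent cycle
  rs2 <- rs; rs2@pairs <- rs@pairs[1L, , drop = FALSE]
  expect_error(emitJobSpec(ht, buildProtocol("H"), rs, sel, pep,
                           peptideRestraints = rs2), "identical")
  # preset H emits 50 window stanzas per stage, 100 per leg
  doc <- jsonlite::fromJSON(js$protein, simplifyVector = FALSE)
  expect_equal(sum(vapply(doc$protocol$stages,
                          function(st) length(st$windows), integer(1L))),
               100L)
})
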