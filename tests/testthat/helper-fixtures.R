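# Shared fixture builders: all test structures are generated in code.

# wrap a (elety, x, y, z) table as a single-residue PdbStructure
structureFromAtoms <- function(df, resid, chain = "A", resno = 1L) {
  new("PdbStructure", atoms = data.frame(
    eleno = seq_len(nrow(df)), elety = df$elety, resid = resid,
    chain = chain, resno = as.integer(resno), alt = "", occ = 1,
    x = df$x, y = df$y, z = df$z,
    elesy = substr(df$elety, 1L, 1L), rectype = "ATOM",
    stringsAsFactors = FALSE))
}

# fixed-column ATOM record
pdbLine <- function(serial, name, resid, chain, resno, x, y, z,
                    occ = 1, alt = " ", rectype = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
          rectype, serial, paste0(" ", name), alt, resid, chain, resno,
          x, y, z, occ, 0, substr(name, 1L, 1L))
}

# side-chain coordinates of a residue in a structure
sideChainCoords <- function(s, chain, resno) {
  res <- getResidue(s, chain, resno)
  tpl <- getTemplate(res$resid[1L])
  sc <- atoms(tpl)$name[atoms(tpl)$sidechain]
  res[res$elety %in% sc, c("elety", "x", "y", "z")]
}

# residues supported as both scan targets and mutation endpoints
supportedResidues <- function()
  c("ALA", "ASN", "GLN", "GLY", "HIS", "ILE", "LEU",
    "MET", "PHE", "SER", "THR", "TYR", "VAL")

# map wt -> mut on an ideal wt structure, with built coordinates
mappingWithCoords <- function(wtName, mutName) {
  s <- buildIdealPeptide(c("GLY", wtName, "GLY"), startResno = 1L)
  wtCoords <- sideChainCoords(s, "A", 2L)
  mutCoords <- placeMutantSideChain(s, "A", 2L, mutName)
  mapAnalogousAtoms(wtName, mutName, wtCoords, mutCoords)
}

# synthetic energy samples with explicit forward/reverse work vectors
workSamples <- function(wF, wR) {
  new("EnergySamples", samples = rbind(
    data.frame(stage = 1L, window = 1L, lambda = 0, u_self = 0,
               u_forward = wF, u_reverse = NA_real_),
    data.frame(stage = 1L, window = 2L, lambda = 1, u_self = 0,
               u_forward = NA_real_, u_reverse = wR)))
}
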