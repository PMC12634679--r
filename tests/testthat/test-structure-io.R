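test_that("single ATOM record parses to a one-atom structure", {
  s <- readStructure(c(pdbLine(1, "CA", "ALA", "A", 1, 1, 2, 3), "END"))
  expect_equal(nAtoms(s), 1L)
  a <- atoms(s)
  expect_equal(a$resno, 1L)
  expect_equal(a$chain, "A")
  expect_equal(c(a$x, a$y, a$z), c(1, 2, 3))
})

test_that("atom and residue counts follow the records", {
  lines <- character(0)
  k <- 0L
  for (r in 1:3) for (at in c("N", "CA", "C", "O", "CB")) {
    k <- k + 1L
    lines <- c(lines, pdbLine(k, at, "ALA", "A", r, r + k / 10, 0, 0))
  }
  s <- readStructure(c(lines, "END"))
  expect_equal(nAtoms(s), 15L)
  expect_equal(nrow(unique(atoms(s)[, c("chain", "resno")])), 3L)
})

test_that("altloc resolution keeps the A conformer", {
  lines <- c(
    pdbLine(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdbLine(2, "CA", "ALA", "A", 1, 1.458, 0, 0, occ = 0.6, alt = "A"),
    pdbLine(3, "CA", "ALA", "A", 1, 1.5, 0.1, 0, occ = 0.4, alt = "B"),
    "END")
  s <- readStructure(lines)
  a <- atoms(s)
  expect_equal(sum(a$elety == "CA"), 1L)
  expect_equal(a$x[a$elety == "CA"], 1.458)
})

test_that("highest occupancy wins without an A conformer", {
  lines <- c(
    pdbLine(1, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.3, alt = "B"),
    pdbLine(2, "CA", "ALA", "A", 1, 2.0, 0, 0, occ = 0.7, alt = "C"),
    "END")
  s <- readStructure(lines)
  expect_equal(atoms(s)$x, 2.0)
})

test_that("malformed records and empty structures are rejected by line", {
  bad <- c(pdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0), "ATOM       2 CA", "END")
  expect_error(readStructure(bad), "line 2")
  badnum <- pdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0)
  substr(badnum, 31, 38) <- "   abc  "
  expect_error(readStructure(c(badnum, "END")), "line 1")
  expect_error(readStructure(c("HEADER", "END")), "empty")
})

test_that("PDB round trip preserves names, keys and coordinates", {
  s <- buildIdealPeptide("KYT", startResno = 24)
  f <- tempfile(fileext = ".pdb")
  writeStructure(s, f)
  s2 <- readStructure(f)
  a1 <- atoms(s); a2 <- atoms(s2)
  expect_equal(a2$elety, a1$elety)
  expect_equal(a2$resno, a1$resno)
  expect_equal(a2$resid, a1$resid)
  expect_equal(a2$x, a1$x, tolerance = 1e-3)
  expect_equal(a2$z, a1$z, tolerance = 1e-3)
})

test_that("mutation center is CB, or the glycine side-chain hydrogen", {
  leu <- data.frame(elety = c("N", "CA", "C", "CB"),
                    x = c(0, 1.458, 2, 1), y = c(0, 0, 1.4, 2),
                    z = c(0, 0, 0, 3))
  s <- structureFromAtoms(leu, "LEU")
  expect_equal(mutationCenter(s, "A", 1), c(1, 2, 3))
  gly <- data.frame(elety = c("N", "CA", "C", "HA2"),
                    x = c(0, 1.458, 2, 0), y = c(0, 0, 1.4, 1),
                    z = c(0, 0, 0, 0))
  sg <- structureFromAtoms(gly, "GLY")
  expect_equal(mutationCenter(sg, "A", 1), c(0, 1, 0))
})

test_that("glycine center without hydrogens reconstructs an ideal CB", {
  s <- buildIdealPeptide("GVG")
  a <- atoms(s)
  a <- a[!(a$resno == 1L & !a$elety %in% c("N", "CA", "C", "O")), ]
  a$eleno <- seq_len(nrow(a))
  sg <- new("PdbStructure", atoms = a)
  ctr <- mutationCenter(sg, "A", 1)
  ca <- as.numeric(getResidue(sg, "A", 1)[
    getResidue(sg, "A", 1)$elety == "CA", c("x", "y", "z")])
  expect_equal(sqrt(sum((ctr - ca)^2)), 1.53, tolerance = 1e-6)
  # missing backbone is an error
  a2 <- a[a$elety != "N" | a$resno != 1L, ]
  a2$eleno <- seq_len(nrow(a2))
  expect_error(mutationCenter(new("PdbStructure", atoms = a2), "A", 1),
               "backbone")
})

test_that("sphere membership is boundary-inclusive and matches brute force", {
  near <- structureFromAtoms(
    data.frame(elety = "CA", x = 24.9, y = 0, z = 0), "ALA")
  expect_equal(selectSphere(near, c(0, 0, 0))@freeIdx, 1L)
  far <- structureFromAtoms(
    data.frame(elety = "CA", x = 25.1, y = 0, z = 0), "ALA")
  selFar <- selectSphere(far, c(0, 0, 0))
  expect_equal(selFar@restrainedIdx, 1L)
  expect_equal(selFar@kOut, 200)

  grid <- expand.grid(x = seq(-30, 30, 5), y = seq(-30, 30, 5),
                      z = seq(-30, 30, 5))
  s <- new("PdbStructure", atoms = data.frame(
    eleno = seq_len(nrow(grid)), elety = "CA", resid = "ALA", chain = "A",
    resno = seq_len(nrow(grid)), alt = "", occ = 1,
    x = grid$x, y = grid$y, z = grid$z, elesy = "C", rectype = "ATOM"))
  sel <- selectSphere(s, c(0, 0, 0))
  brute <- sum(sqrt(grid$x^2 + grid$y^2 + grid$z^2) <= 25)
  expect_equal(length(sel@freeIdx), brute)
})

test_that("selection partitions atoms and is translation invariant", {
  set.seed(42)
  n <- 300L
  a <- data.frame(
    eleno = seq_len(n), elety = "CA",
    resid = sample(c("ALA", "HOH"), n, replace = TRUE),
    chain = "A", resno = seq_len(n), alt = "", occ = 1,
    x = runif(n, -40, 40), y = runif(n, -40, 40), z = runif(n, -40, 40),
    elesy = "C", rectype = "ATOM", stringsAsFactors = FALSE)
  s <- new("PdbStructure", atoms = a)
  for (ctr in list(c(0, 0, 0), c(10, -5, 3))) {
    sel <- selectSphere(s, ctr, diameter = 38)
    idx <- sort(c(sel@freeIdx, sel@restrainedIdx, sel@excludedIdx))
    expect_equal(idx, seq_len(n))
    nprot <- sum(a$resid == "ALA")
    expect_equal(sum(a$resid[sel@freeIdx] == "ALA") +
                   length(sel@restrainedIdx), nprot)
    shift <- c(7, -2, 11)
    a2 <- a; a2$x <- a$x + shift[1L]; a2$y <- a$y + shift[2L]
    a2$z <- a$z + shift[3L]
    sel2 <- selectSphere(new("PdbStructure", atoms = a2), ctr + shift,
                         diameter = 38)
    expect_identical(sel2@freeIdx, sel@freeIdx)
    expect_identical(sel2@restrainedIdx, sel@restrainedIdx)
  }
})

test_that("outer-layer ionizables follow the shell rule", {
  mkIon <- function(resid, refAt, resno, dist) {
    data.frame(eleno = resno, elety = refAt, resid = resid, chain = "A",
               resno = resno, alt = "", occ = 1,
               x = dist, y = 0, z = 0, elesy = substr(refAt, 1, 1),
               rectype = "ATOM", stringsAsFactors = FALSE)
  }
  a <- rbind(mkIon("LYS", "NZ", 1L, 24),     # radius - 1: listed
             mkIon("LYS", "NZ", 2L, 0),      # center: interior
             mkIon("GLU", "CD", 3L, 23.5),   # in shell: listed
             mkIon("ARG", "CZ", 4L, 26))     # outside sphere: not listed
  s <- new("PdbStructure", atoms = a)
  sel <- selectSphere(s, c(0, 0, 0))
  ion <- outerLayerIonizables(s, sel)
  expect_setequal(ion$resno, c(1L, 3L))
})

test_that("randomized ionizable placements match a brute-force shell test", {
  set.seed(7)
  kinds <- c(ARG = "CZ", LYS = "NZ", ASP = "CG", GLU = "CD", HIS = "NE2")
  n <- 20L
  resid <- sample(names(kinds), n, replace = TRUE)
  d <- runif(n, 0, 30)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  a <- data.frame(eleno = seq_len(n), elety = unname(kinds[resid]),
                  resid = resid, chain = "A", resno = seq_len(n), alt = "",
                  occ = 1, x = d * u[, 1], y = d * u[, 2], z = d * u[, 3],
                  elesy = "X", rectype = "ATOM", stringsAsFactors = FALSE)
  s <- new("PdbStructure", atoms = a)
  sel <- selectSphere(s, c(0, 0, 0))
  ion <- outerLayerIonizables(s, sel, shell = 3)
  brute <- which(d <= 25 & d > 22)
  expect_setequal(ion$resno, brute)
})
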