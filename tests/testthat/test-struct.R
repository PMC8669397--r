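test_that("minimal PDB and mmCIF fixtures load with exact coordinates", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(toy_pdb_text, pdb)
  m <- readStructure(pdb)
  at <- structureAtoms(m)
  expect_identical(nrow(at), 2L)
  expect_equal(at$x, c(0, 1.5))
  expect_identical(at$atom_name, c("N", "CA"))
  expect_identical(at$element, c("N", "C"))

  cif <- tempfile(fileext = ".cif")
  writeLines(toy_cif_text, cif)
  m2 <- readStructure(cif)
  at2 <- structureAtoms(m2)
  expect_identical(nrow(at2), 2L)
  key <- function(a) paste(a$atom_name, a$element, a$x, a$y, a$z)
  expect_setequal(key(at2), key(at))

  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(readStructure(empty), "empty model|parse")
})

test_that("the PDB writer round-trips generated scenes", {
  tr <- genHelixScene(45, 12)
  path <- tempfile(fileext = ".pdb")
  writeStructurePDB(tr$scene, path)
  back <- readStructure(path)
  a0 <- structureAtoms(tr$scene); a1 <- structureAtoms(back)
  expect_identical(nrow(a1), nrow(a0))
  expect_setequal(unique(a1$chain_id), c("A", "B", "C", "D"))
  expect_equal(sort(a1$x), sort(round(a0$x, 3)), tolerance = 1e-9)
})

test_that("altloc resolution keeps the highest-occupancy copy", {
  lines <- c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BGLY A   1       9.000   0.000   0.000  0.70  0.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  at <- structureAtoms(readStructure(f))
  expect_identical(nrow(at), 1L)
  expect_equal(at$x, 9.0)
})

test_that("duplex axis fitting is exact on ideal helices", {
  tr <- genHelixScene(0, 20) # two full turns: midpoints are symmetric
  a <- fitDuplexAxis(tr$scene, "A", "B")
  b <- fitDuplexAxis(tr$scene, "C", "D")
  expect_equal(abs(sum(axisDirection(a) * c(0, 0, 1))), 1, tolerance = 1e-4)
  expect_equal(crossingAngle(a, b), 0, tolerance = 0.5)
  expect_lt(a@rms_axial_deviation, 9.4) # midpoints hug the axis

  ninety <- genHelixScene(90, 20)
  expect_equal(crossingAngle(fitDuplexAxis(ninety$scene, "A", "B"),
                             fitDuplexAxis(ninety$scene, "C", "D")),
               90, tolerance = 0.5)
})

test_that("short duplexes and anchorless residues are rejected", {
  tr <- genHelixScene(30, 8)
  at <- structureAtoms(tr$scene)
  short <- StructureModel(at[at$residue_number <= 3, ])
  expect_error(fitDuplexAxis(short, "A", "B"), "at least 4")
  noanchor <- at
  noanchor$atom_name <- "C2"
  expect_error(fitDuplexAxis(StructureModel(noanchor), "A", "B"),
               "no C1' or P")
})

test_that("crossing angle recovery is within 1 degree across many scenes", {
  angles <- seq(2, 88, length.out = 50)
  err <- vapply(seq_along(angles), function(i) {
    tr <- genHelixScene(angles[i], 14, seed = i)
    got <- crossingAngle(fitDuplexAxis(tr$scene, "A", "B"),
                         fitDuplexAxis(tr$scene, "C", "D"))
    abs(got - angles[i])
  }, numeric(1))
  expect_lt(max(err), 1)
})

test_that("crossing angle is symmetric and flip invariant in acute mode", {
  tr <- genHelixScene(37, 14)
  a <- fitDuplexAxis(tr$scene, "A", "B")
  b <- fitDuplexAxis(tr$scene, "C", "D")
  expect_equal(crossingAngle(a, b), crossingAngle(b, a), tolerance = 1e-9)
  flipped <- a
  flipped@direction <- -a@direction
  expect_equal(crossingAngle(flipped, b), crossingAngle(a, b),
               tolerance = 1e-9)
})

test_that("measurements are invariant under rigid-body transforms", {
  set.seed(21)
  tr <- genHelixScene(60, 14)
  ang0 <- crossingAngle(fitDuplexAxis(tr$scene, "A", "B"),
                        fitDuplexAxis(tr$scene, "C", "D"))
  toy <- toy_protein_model()
  vdw0 <- as.numeric(minBackboneVdwDistance(toy, "A", "B"))
  for (i in 1:4) {
    R <- random_rotation(); t <- rnorm(3, 0, 50)
    sc <- transform_model(tr$scene, R, t)
    expect_equal(crossingAngle(fitDuplexAxis(sc, "A", "B"),
                               fitDuplexAxis(sc, "C", "D")),
                 ang0, tolerance = 1e-6)
    expect_equal(as.numeric(minBackboneVdwDistance(
      transform_model(toy, R, t), "A", "B")), vdw0, tolerance = 1e-6)
  }
})

test_that("minimum backbone VDW distance matches hand-computed tables", {
  # two carbons exactly at VDW contact
  at <- data.frame(chain_id = c("A", "B"), residue_number = 1L,
                   residue_name = "GLY", atom_name = "CA", element = "C",
                   x = c(0, 3.40), y = 0, z = 0, occupancy = 1)
  m <- StructureModel(at)
  expect_equal(as.numeric(minBackboneVdwDistance(m, "A", "B")), 0,
               tolerance = 1e-12)

  toy <- toy_protein_model()
  # hand table: B:CA at (0,4,0) vs A:{N,CA,C}; B:O at (10,0,0) vs same
  # closest cross pair is A:N (r 1.55) to B:CA (r 1.70): 4 - 3.25 = 0.75
  got <- minBackboneVdwDistance(toy, "A", "B")
  expect_equal(as.numeric(got), 0.75, tolerance = 1e-9)
  pair <- attr(got, "pair")
  expect_setequal(pair$atom_name, c("N", "CA"))
  expect_error(minBackboneVdwDistance(toy, "A", "C"), "no atoms|no backbone")
})

test_that("VDW minimum equals the all-pairs oracle on random selections", {
  set.seed(17)
  radii <- vdwRadii("bondi")
  for (i in 1:3) {
    n <- sample(50:120, 1)
    mk <- function(chain) data.frame(
      chain_id = chain, residue_number = seq_len(n), residue_name = "ALA",
      atom_name = sample(c("N", "CA", "C", "O"), n, replace = TRUE),
      element = NA_character_, x = rnorm(n, 0, 10), y = rnorm(n, 0, 10),
      z = rnorm(n, 0, 10), occupancy = 1)
    a <- mk("A"); b <- mk("B")
    a$element <- substr(a$atom_name, 1, 1)
    b$element <- substr(b$atom_name, 1, 1)
    m <- StructureModel(rbind(a, b))
    got <- as.numeric(minBackboneVdwDistance(m, "A", "B"))
    want <- oracle_min_vdw(as.matrix(a[, c("x", "y", "z")]),
                           unname(radii[a$element]),
                           as.matrix(b[, c("x", "y", "z")]),
                           unname(radii[b$element]))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("selection parsing restricts chains and residue ranges", {
  tr <- genHelixScene(10, 12)
  m <- tr$scene
  expect_length(selectAtoms(m, "A"), 12L)
  expect_length(selectAtoms(m, "A:3-6"), 4L)
  expect_length(selectAtoms(m, "A:1-2,B:1-2"), 4L)
  expect_error(selectAtoms(m, "A:xx"), "malformed")
})

test_that("unknown radii tables and elements are rejected", {
  expect_error(vdwRadii("martian"), "unknown radii table")
  at <- toy_protein_model()
  bad <- structureAtoms(at)
  bad$element[1] <- "ZZ"
  expect_error(minBackboneVdwDistance(StructureModel(bad), "A", "B"),
               "no VDW radius")
})
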