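test_that("multi-model PDB files load with one frame per MODEL", {
  path <- withr::local_tempfile(fileext = ".pdb")
  fix <- writePDBFixture(path, models = 3L, natoms = 14L)
  ens <- readMultimodelPDB(path)
  expect_s4_class(ens, "ConformerEnsemble")
  expect_equal(nFrames(ens), 3L)
  expect_equal(nAtoms(ens), 14L)
  expect_equal(atomNames(ens), fix$names)
  # PDB stores 3 decimals; frame 2 offset = base + 0.10
  expect_equal(frameCoords(ens, 2), fix$base + 0.10,
               tolerance = 1e-3, ignore_attr = TRUE)

  single <- withr::local_tempfile(fileext = ".pdb")
  writePDBFixture(single, models = 1L, natoms = 14L)
  expect_equal(nFrames(readMultimodelPDB(single)), 1L)
})

test_that("a model with a missing atom is rejected with a validation error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writePDBFixture(path, models = 3L, natoms = 14L, dropAtomInModel = 2L)
  expect_error(readMultimodelPDB(path), class = "vicinalJ_validation_error")
  expect_error(readMultimodelPDB(path), "model")
})

test_that("unparseable PDB input raises a format error naming the problem", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HELLO WORLD", "NOT A PDB"), path)
  err <- expect_error(readMultimodelPDB(path), class = "vicinalJ_format_error")
  expect_match(conditionMessage(err), "HELLO WORLD")
})

test_that("concatenated XYZ blocks load as frames with derived atom names", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeXYZFixture(path, frames = 2L)
  ens <- readXYZFrames(path)
  expect_equal(nFrames(ens), 2L)
  expect_equal(nAtoms(ens), 5L)
  expect_equal(atomNames(ens), c("C1", "C2", "O1", "H1", "H2"))
  expect_equal(ens@atoms$element, c("C", "C", "O", "H", "H"))
})

test_that("XYZ parsing rejects empty and truncated files", {
  empty <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(0), empty)
  expect_error(readXYZFrames(empty), class = "vicinalJ_format_error")

  trunc <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "comment", "C 0 0 0", "C 1 0 0"), trunc)
  expect_error(readXYZFrames(trunc), class = "vicinalJ_format_error")

  badcount <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("two", "comment", "C 0 0 0"), badcount)
  expect_error(readXYZFrames(badcount), class = "vicinalJ_format_error")
})

test_that("write-then-read roundtrips preserve frames, order and coordinates", {
  gen <- generateRotamerEnsemble(fragmentBlueprint("R"), nFrames = 20,
                                 seed = 301)
  xyzPath <- withr::local_tempfile(fileext = ".xyz")
  writeXYZFrames(gen$ensemble, xyzPath)
  back <- readXYZFrames(xyzPath)
  expect_equal(nFrames(back), 20L)
  expect_equal(atomNames(back), atomNames(gen$ensemble))
  expect_lt(max(abs(back@coords - gen$ensemble@coords)), 1e-3)

  pdbPath <- withr::local_tempfile(fileext = ".pdb")
  writeMultimodelPDB(gen$ensemble, pdbPath)
  back2 <- readMultimodelPDB(pdbPath)
  expect_equal(nFrames(back2), 20L)
  expect_equal(atomNames(back2), atomNames(gen$ensemble))
  expect_lt(max(abs(back2@coords - gen$ensemble@coords)), 1e-3)
})

test_that("the built-in delta-chi group table holds exactly the five groups", {
  tab <- deltaChiTable()
  expect_equal(tab$label, c("H", "CHMeOH", "CH2C(O)R", "CH2CH2R", "OH"))
  expect_equal(tab$deltaChi, c(0, 0.62, 0.72, 0.76, 1.33))
  expect_true(all(tab$deltaChi >= 0))
  expect_error(substituentGroup("NOPE"), class = "vicinalJ_validation_error")
  expect_equal(substituentGroup("OH")$deltaChi, 1.33)
})

test_that("coupling definitions enforce their structural invariants", {
  expect_error(couplingDefinition("bad", "H1", "C1", "C1", "H2"),
               "distinct")
  expect_error(
    couplingDefinition("bad", "H1", "C1", "C2", "H2",
                       data.frame(atom = "H1", side = "carbon_a",
                                  deltaChi = 0)),
    "distinct from path atoms")
  cd <- couplingDefinition("ok", "H1", "C1", "C2", "H2",
                           data.frame(atom = c("O1", "C3"),
                                      side = c("carbon_a", "carbon_b"),
                                      group = c("OH", "CH2CH2R"),
                                      deltaChi = c(NA, NA)))
  expect_equal(cd@substituents$deltaChi, c(1.33, 0.76))
})

test_that("topology validation passes plausible geometry and flags the rest", {
  fr <- buildConformer(fragmentBlueprint("R"), c(chi1 = 60, chi2 = 180))
  topo <- readTopologyConfig(exampleTopologyPath())
  for (cp in topo$couplings) expect_silent(validateTopology(fr, cp))

  ghost <- couplingDefinition("ghost", "H99", "C40", "C41", "H41")
  expect_error(validateTopology(fr, ghost),
               class = "vicinalJ_lookup_error")

  # stretch the C40-C41 bond to 3 A by translating C41's subtree atom C41
  co <- fr@coords
  i <- match("C41", atomNames(fr))
  co[i, 1, 1] <- co[i, 1, 1] + 1.6
  broken <- conformerEnsemble(fr@atoms, co)
  err <- expect_error(validateTopology(broken, topo$couplings[[1]]),
                      class = "vicinalJ_validation_error")
  expect_match(conditionMessage(err), "distance")
})

test_that("the example topology config parses measured values and groups", {
  topo <- readTopologyConfig(exampleTopologyPath())
  expect_length(topo$couplings, 4L)
  expect_equal(topo$measured$jHz, c(4.5, 8.5, 3.2, 9.3))
  expect_equal(topo$couplings[[1]]@label, "H40a/H41")
  s <- topo$couplings[[1]]@substituents
  expect_setequal(s$deltaChi, c(0.76, 0, 1.33, 0.72))
})

test_that("ensembles are validated on construction", {
  expect_error(conformerEnsemble(c("C1", "C1"),
                                 array(0, dim = c(2, 3, 1))),
               "unique")
  expect_error(conformerEnsemble(c("C1", "H1"),
                                 array(c(0, Inf), dim = c(2, 3, 1))),
               "finite")
  expect_error(conformerEnsemble(c("C1", "H1"),
                                 array(0, dim = c(3, 3, 1))),
               "atoms")
})
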