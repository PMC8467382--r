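test_that("built conformers reproduce the requested torsions exactly", {
  bp <- fragmentBlueprint("R")
  for (tv in list(c(chi1 = 60, chi2 = 180), c(chi1 = -73.2, chi2 = 41.7),
                  c(chi1 = 179.99, chi2 = -179.99))) {
    fr <- buildConformer(bp, tv)
    xyz <- frameCoords(fr, 1)
    chi1 <- signedDihedral(xyz["C42", ], xyz["C41", ], xyz["C40", ],
                           xyz["C39", ])
    chi2 <- signedDihedral(xyz["C43", ], xyz["C42", ], xyz["C41", ],
                           xyz["C40", ])
    expect_lt(abs(wrapAngle(chi1 - tv[["chi1"]])), 1e-6)
    expect_lt(abs(wrapAngle(chi2 - tv[["chi2"]])), 1e-6)
  }
  expect_error(buildConformer(bp, c(chi1 = 60)),
               class = "vicinalJ_construction_error")
})

test_that("identical build inputs give bit-identical frames", {
  bp <- fragmentBlueprint("R")
  f1 <- buildConformer(bp, c(chi1 = 12.3, chi2 = -140))
  f2 <- buildConformer(bp, c(chi1 = 12.3, chi2 = -140))
  expect_identical(f1@coords, f2@coords)
})

test_that("R and S blueprints are exact mirror images at mirrored torsions", {
  # the builder's canonical frame lies in the z = 0 plane, so reflection
  # through the xy-plane maps anchor atoms onto themselves and per-atom
  # coordinates can be compared directly
  bpR <- fragmentBlueprint("R")
  bpS <- fragmentBlueprint("S")
  for (tv in list(c(chi1 = 47, chi2 = 163), c(chi1 = -60, chi2 = 60))) {
    frR <- buildConformer(bpR, tv)
    frS <- buildConformer(bpS, -tv)
    expect_lt(max(abs(reflectZ(frR)@coords - frS@coords)), 1e-6)
  }
})

test_that("ensemble generation is reproducible under a fixed seed", {
  bp <- fragmentBlueprint("R")
  g1 <- generateRotamerEnsemble(bp, nFrames = 2000, seed = 7)
  g2 <- generateRotamerEnsemble(bp, nFrames = 2000, seed = 7)
  expect_identical(g1$ensemble@coords, g2$ensemble@coords)
  expect_identical(g1$torsions, g2$torsions)
  g3 <- generateRotamerEnsemble(bp, nFrames = 2000, seed = 8)
  expect_false(identical(g1$ensemble@coords, g3$ensemble@coords))
  # truth record carries the generating conditions
  expect_equal(g1$truth$chirality, "R")
  expect_equal(g1$truth$seed, 7)
  expect_true(g1$truth$hbond_bias)
})

test_that("a concentrated single rotamer centers tightly on its state", {
  spec <- list(rotamerSpec("chi1", 180, 1, kappa = 1000),
               rotamerSpec("chi2", 60, 1, kappa = 1000))
  bp <- fragmentBlueprint("R", hbondBias = FALSE, sampledTorsions = spec)
  gen <- generateRotamerEnsemble(bp, nFrames = 50000, seed = 99)
  x <- gen$torsions[, "chi1"] * pi / 180
  circMean <- atan2(mean(sin(x)), mean(cos(x))) * 180 / pi
  expect_lt(abs(wrapAngle(circMean - 180)), 0.2)
  # kappa = 1000 corresponds to a circular SD near 1.8 degrees
  expect_lt(stats::sd(wrapAngle(gen$torsions[, "chi1"] - 180)), 2.5)
})

test_that("basin occupancies track the mixture weights", {
  spec <- list(rotamerSpec("chi1", c(60, 180), c(0.7, 0.3), kappa = 20),
               rotamerSpec("chi2", 180, 1, kappa = 60))
  bp <- fragmentBlueprint("R", hbondBias = FALSE, sampledTorsions = spec)
  gen <- generateRotamerEnsemble(bp, nFrames = 50000, seed = 123)
  chi1 <- gen$torsions[, "chi1"]
  # nearest-center rule on the circle
  d60 <- abs(wrapAngle(chi1 - 60)); d180 <- abs(wrapAngle(chi1 - 180))
  occ60 <- mean(d60 < d180)
  expect_lt(abs(occ60 - 0.7), 0.02)
})

test_that("sampled torsions match the specified mixture density", {
  spec <- rotamerSpec("chi1", c(60, 180, -60), c(0.65, 0.25, 0.10),
                      kappa = 20)
  bp <- fragmentBlueprint("R", hbondBias = FALSE,
                          sampledTorsions = list(
                            spec, rotamerSpec("chi2", 180, 1, kappa = 60)))
  gen <- generateRotamerEnsemble(bp, nFrames = 50000, seed = 246)
  x <- gen$torsions[, "chi1"]
  breaks <- seq(-180, 180, by = 10)
  obs <- table(cut(x, breaks))
  # expected bin probabilities by numerical integration of the mixture
  probs <- vapply(seq_len(length(breaks) - 1), function(i)
    stats::integrate(function(t) vicinalJ:::vonMisesMixtureDensity(t, spec),
                     breaks[i], breaks[i + 1], rel.tol = 1e-8)$value,
    numeric(1))
  keep <- probs * 50000 >= 5  # chi-squared validity
  chi2 <- sum((as.numeric(obs[keep]) - 50000 * probs[keep])^2 /
                (50000 * probs[keep]))
  p <- stats::pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("mirroring is an involution and negates torsions", {
  gen <- generateRotamerEnsemble(fragmentBlueprint("R"), nFrames = 30,
                                 seed = 17)
  mir <- mirrorEnsemble(gen$ensemble)
  expect_identical(mirrorEnsemble(mir)@coords, gen$ensemble@coords)
  expect_equal(nFrames(mir), 30L)
  cp <- readTopologyConfig(exampleTopologyPath())$couplings[[3]]
  phi <- torsionSeries(gen$ensemble, cp)$phiDeg
  phiM <- torsionSeries(mir, cp)$phiDeg
  expect_equal(wrapAngle(phi + phiM), rep(0, 30), tolerance = 1e-9)
})

test_that("mirrored ensembles predict identical couplings after xi re-assignment", {
  gen <- generateRotamerEnsemble(fragmentBlueprint("R"), nFrames = 500,
                                 seed = 404)
  mir <- mirrorEnsemble(gen$ensemble)
  topo <- readTopologyConfig(exampleTopologyPath())
  for (cp in topo$couplings) {
    jO <- jMean(ensembleAverageJ(gen$ensemble, cp))
    jM <- jMean(ensembleAverageJ(mir, cp))
    expect_lt(abs(jO - jM), 1e-9)
  }
})

test_that("default R-epimer couplings alternate small/large across the methylenes", {
  gen <- generateRotamerEnsemble(fragmentBlueprint("R"), nFrames = 2000,
                                 seed = 1001)
  topo <- readTopologyConfig(exampleTopologyPath())
  js <- vapply(topo$couplings, function(cp)
    jMean(ensembleAverageJ(gen$ensemble, cp)), numeric(1))
  names(js) <- vapply(topo$couplings, function(cp) cp@label, character(1))
  # qualitative pattern of the measured column: small, large, small, large
  expect_lt(js[["H40a/H41"]], 6)
  expect_gt(js[["H40b/H41"]], 7)
  expect_lt(js[["H41/H42a"]], 6)
  expect_gt(js[["H41/H42b"]], 7)
})

test_that("ensembles and truth sidecars roundtrip through files", {
  gen <- generateRotamerEnsemble(fragmentBlueprint("S"), nFrames = 10,
                                 seed = 3)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  truth <- withr::local_tempfile(fileext = ".json")
  writeEnsembleWithTruth(gen, pdb, truth)
  back <- readMultimodelPDB(pdb)
  expect_equal(nFrames(back), 10L)
  rec <- jsonlite::read_json(truth)
  expect_equal(rec$chirality, "S")
  expect_equal(rec$seed, 3)
})

test_that("rotamer specs validate their invariants", {
  expect_error(rotamerSpec("t", c(60, 180), c(0.5, 0.4)), "sum to 1")
  expect_error(rotamerSpec("t", 60, 1, kappa = -2), "positive")
  # centers are wrapped into (-180, 180] on construction
  expect_equal(rotamerSpec("t", 210, 1)@centers, -150)
})
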