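test_that("a one-frame ensemble average equals the single-conformer value", {
  fr <- buildConformer(fragmentBlueprint("R"), c(chi1 = 60, chi2 = 180))
  cp <- readTopologyConfig(exampleTopologyPath())$couplings[[1]]
  rep_ <- ensembleAverageJ(fr, cp)
  phi <- torsionSeries(fr, cp)$phiDeg
  xi <- assignXi(fr, cp)
  s <- cp@substituents
  direct <- predict3J(phi, data.frame(deltaChi = s$deltaChi,
                                      xi = unname(xi[s$atom])))
  expect_equal(jMean(rep_), direct)
  expect_equal(rep_@nFrames, 1L)
})

test_that("a two-state unsubstituted ensemble averages the two couplings", {
  # frames at phi = 60 and 180 built on the idealized fragment, no
  # substituents: J = (3.85 + 16.00) / 2
  f1 <- staggeredFragment(phi = 60)
  f2 <- staggeredFragment(phi = 180)
  co <- array(NA_real_, dim = c(6, 3, 2))
  co[, , 1] <- f1@coords[, , 1]
  co[, , 2] <- f2@coords[, , 1]
  ens <- conformerEnsemble(f1@atoms, co)
  rep_ <- ensembleAverageJ(ens, simpleCoupling(withSubs = FALSE))
  expect_equal(jMean(rep_), 9.925, tolerance = 1e-9)
  expect_equal(rep_@jPerFrame, c(3.85, 16.00), tolerance = 1e-9)
})

test_that("the pipeline average equals an oracle recomputation from exported torsions", {
  gen <- generateRotamerEnsemble(fragmentBlueprint("R"), nFrames = 2000,
                                 seed = 88)
  cp <- readTopologyConfig(exampleTopologyPath())$couplings[[4]]
  rep_ <- ensembleAverageJ(gen$ensemble, cp)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeTorsionTSV(torsionSeries(gen$ensemble, cp), tsv)
  phi <- utils::read.delim(tsv)$phi_deg
  xi <- assignXi(gen$ensemble, cp)
  s <- cp@substituents
  jOracle <- vapply(phi, function(p)
    oracleHLA(p, s$deltaChi, unname(xi[s$atom])), numeric(1))
  expect_lt(abs(jMean(rep_) - mean(jOracle)), 1e-9)
  expect_equal(rep_@nFrames, 2000L)
})

test_that("report invariants hold and permutation leaves the statistics unchanged", {
  gen <- generateRotamerEnsemble(fragmentBlueprint("R"), nFrames = 400,
                                 seed = 13)
  cp <- readTopologyConfig(exampleTopologyPath())$couplings[[2]]
  rep_ <- ensembleAverageJ(gen$ensemble, cp)
  expect_gte(jMean(rep_), min(rep_@jPerFrame))
  expect_lte(jMean(rep_), max(rep_@jPerFrame))
  expect_equal(rep_@convergence[rep_@nFrames], jMean(rep_))

  set.seed(9)
  perm <- sample(nFrames(gen$ensemble))
  shuffled <- conformerEnsemble(gen$ensemble@atoms,
                                gen$ensemble@coords[, , perm])
  rep2 <- ensembleAverageJ(shuffled, cp)
  expect_equal(jMean(rep2), jMean(rep_), tolerance = 1e-12)
  expect_equal(rep2@jSD, rep_@jSD, tolerance = 1e-12)
})

test_that("J is averaged over conformers, never the torsion", {
  # bimodal rotamer mixture at +/-60: <J(phi)> stays gauche-like while
  # J(<phi>) would be the eclipsed value - they must differ by > 3 Hz
  spec <- list(rotamerSpec("chi1", c(60, -60), c(0.5, 0.5), kappa = 200),
               rotamerSpec("chi2", 180, 1, kappa = 200))
  bp <- fragmentBlueprint("R", hbondBias = FALSE, sampledTorsions = spec)
  gen <- generateRotamerEnsemble(bp, nFrames = 2000, seed = 55)
  cp <- readTopologyConfig(exampleTopologyPath())$couplings[[1]]
  rep_ <- ensembleAverageJ(gen$ensemble, cp)
  phi <- torsionSeries(gen$ensemble, cp)$phiDeg
  xi <- assignXi(gen$ensemble, cp)
  s <- cp@substituents
  subs <- data.frame(deltaChi = s$deltaChi, xi = unname(xi[s$atom]))
  jOfMeanPhi <- predict3J(mean(phi), subs)
  expect_gt(abs(jMean(rep_) - jOfMeanPhi), 3)
})

test_that("the zero-fluctuation limit recovers the population-weighted couplings", {
  # two-state chi1 at kappa = 1000: the ensemble average must match the
  # population-weighted single-conformer couplings to < 0.05 Hz
  w <- c(0.7, 0.3)
  spec <- list(rotamerSpec("chi1", c(60, 180), w, kappa = 1000),
               rotamerSpec("chi2", 180, 1, kappa = 1000))
  bp <- fragmentBlueprint("R", hbondBias = FALSE, sampledTorsions = spec)
  gen <- generateRotamerEnsemble(bp, nFrames = 50000, seed = 2024)
  cp <- readTopologyConfig(exampleTopologyPath())$couplings[[1]]
  rep_ <- ensembleAverageJ(gen$ensemble, cp, maxFrames = 50000L)
  states <- vapply(c(60, 180), function(c1)
    jMean(ensembleAverageJ(buildConformer(bp, c(chi1 = c1, chi2 = 180)), cp)),
    numeric(1))
  expect_lt(abs(jMean(rep_) - sum(w * states)), 0.05)
})

test_that("convergence diagnostics pass stable series and fail drifting ones", {
  mk <- function(j) new("JPredictionReport", couplingLabel = "x",
                        jPerFrame = j, jMean = mean(j),
                        jSD = stats::sd(j),
                        jSE = c(naive = stats::sd(j) / sqrt(length(j)),
                                block = NA_real_),
                        nFrames = length(j),
                        convergence = cumsum(j) / seq_along(j),
                        xi = numeric(0))
  const <- mk(rep(7.5, 500))
  cv <- convergenceCheck(const, window = 100, tol = 0.2)
  expect_true(cv$pass)
  expect_equal(cv$drift, 0)

  drifting <- mk(seq(2, 12, length.out = 500))
  expect_false(convergenceCheck(drifting, window = 100, tol = 0.2)$pass)
  expect_error(convergenceCheck(const, window = 500),
               class = "vicinalJ_validation_error")
})

test_that("a 2000-frame bimodal rotamer ensemble converges at default mixing", {
  gen <- generateRotamerEnsemble(fragmentBlueprint("R"), nFrames = 2000,
                                 seed = 606)
  cp <- readTopologyConfig(exampleTopologyPath())$couplings[[1]]
  rep_ <- ensembleAverageJ(gen$ensemble, cp)
  cv <- convergenceCheck(rep_, window = 200, tol = 0.2)
  expect_true(cv$pass)
  # block SE is defined and larger series give both SE estimates
  expect_true(is.finite(rep_@jSE[["block"]]))
})

test_that("longer inputs are stride-subsampled to the frame budget", {
  gen <- generateRotamerEnsemble(fragmentBlueprint("R"), nFrames = 500,
                                 seed = 31)
  cp <- readTopologyConfig(exampleTopologyPath())$couplings[[1]]
  rep_ <- ensembleAverageJ(gen$ensemble, cp, maxFrames = 200L)
  expect_equal(rep_@nFrames, 200L)
})
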