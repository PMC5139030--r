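test_that("energy normalization hits formula endpoints and clamps", {
  # -P/(1.971 L) at P = -1.971*L gives 1 to machine precision
  expect_equal(unname(normalizeEnergyScores(list(dfire2 = -197.1),
                                            L = 100)["DFIRE2"]), 1,
               tolerance = 1e-12)
  expect_identical(unname(normalizeEnergyScores(list(rf_cb_srs_od = 700),
                                                L = 100)["RF_CB_SRS_OD"]), 0)
  # positive RWplus energy maps negative, clamps to 0
  expect_identical(unname(normalizeEnergyScores(list(rwplus = 500),
                                                L = 50)["RWPLUS"]), 0)
  # values over 1 clamp to 1
  expect_identical(unname(normalizeEnergyScores(list(dfire2 = -1e6),
                                                L = 10)["DFIRE2"]), 1)
  expect_error(normalizeEnergyScores(list(dfire2 = -1), L = 0), "L must be")
})

test_that("lower (better) energies give higher normalized scores", {
  L <- 120
  for (nm in c("dfire2", "rwplus", "rf_cb_srs_od", "dope", "goap", "opus")) {
    lo <- normalizeEnergyScores(setNames(list(-500), nm), L)
    hi <- normalizeEnergyScores(setNames(list(-100), nm), L)
    expect_gte(lo[[1]], hi[[1]])
  }
  # passthrough scores keep their value (clamped)
  expect_equal(unname(normalizeEnergyScores(list(qprob = 0.73), 50)["QPROB"]),
               0.73)
  expect_equal(unname(normalizeEnergyScores(list(proq2 = 1.3), 50)["PROQ2"]),
               1)
})

test_that("surface score is the exposed-nonpolar area fraction", {
  mLS <- caModel(matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE),
                 seqs = "LS")
  sasa <- list(absolute = c(80, 20), relative = c(0.5, 0.5),
               exposed = c(TRUE, TRUE))
  expect_equal(surfaceScore(sasa, mLS), 0.8)
  # all polar -> 0; all nonpolar exposed -> 1
  mSS <- caModel(matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE),
                 seqs = "SS")
  expect_equal(surfaceScore(sasa, mSS), 0)
  mLL <- caModel(matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE),
                 seqs = "LL")
  expect_equal(surfaceScore(sasa, mLL), 1)
  sasa0 <- list(absolute = c(0, 0), relative = c(0, 0),
                exposed = c(FALSE, FALSE))
  expect_equal(surfaceScore(sasa0, mLL), 0)
})

test_that("exposed mass score uses the residue mass table", {
  mGA <- caModel(matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE),
                 seqs = "GA")
  onlyG <- list(absolute = c(50, 10), relative = c(0.5, 0.1),
                exposed = c(TRUE, FALSE))
  expect_equal(exposedMassScore(onlyG, mGA), 57.05 / (57.05 + 71.08),
               tolerance = 1e-12)
  none <- list(absolute = c(0, 0), relative = c(0, 0),
               exposed = c(FALSE, FALSE))
  expect_equal(exposedMassScore(none, mGA), 0)
  all <- list(absolute = c(1, 1), relative = c(1, 1),
              exposed = c(TRUE, TRUE))
  expect_equal(exposedMassScore(all, mGA), 1)
})

test_that("exposed surface score is total area over reference, clamped", {
  m <- caModel(matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE),
               seqs = "GA")
  zero <- list(absolute = c(0, 0), relative = c(0, 0),
               exposed = c(FALSE, FALSE))
  expect_equal(exposedSurfaceScore(zero, m), 0)
  # ratio above 1 clamps
  big <- list(absolute = c(300, 300), relative = c(1, 1),
              exposed = c(TRUE, TRUE))
  expect_equal(exposedSurfaceScore(big, m), 1)
  # a fully extended peptide is mostly exposed
  ext <- generateNative(simConfig(L = 8, template = "strand", seed = 6))
  es <- exposedSurfaceScore(shrakeRupleySasa(ext, nPoints = 10000), ext)
  expect_gte(es, 0.3)
})

test_that("accessibility and secondary-structure agreement count matches", {
  sasa <- list(absolute = rep(1, 4), relative = rep(0.5, 4),
               exposed = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(saAgreementScore(sasa, "eebb"), 1)
  expect_equal(saAgreementScore(sasa, "bbee"), 0)
  expect_equal(saAgreementScore(sasa, "eebe"), 0.75)
  expect_error(saAgreementScore(sasa, "ee"), "length")

  expect_equal(ssSimilarityScore("HHCC", "HHCC"), 1)
  expect_equal(ssSimilarityScore("HHHH", "EEEE"), 0)
  expect_equal(ssSimilarityScore("HHCC", "HHCE"), 0.75)
  expect_error(ssSimilarityScore("HH", "HHC"), "length")

  expect_equal(ssPenaltyScore("HHHH", "HHHH"), 1)
  expect_equal(ssPenaltyScore("CCCC", "EEEE"), 0)
  # matches at 1 of the 2 predicted-H/E sites
  expect_equal(ssPenaltyScore("HCCC", "HECC"), 0.5)
  # neutral when nothing is predicted H/E
  expect_equal(ssPenaltyScore("HHHH", "CCCC"), 0.5)
})

test_that("compactness is mean pairwise distance over the extended span", {
  m2 <- caModel(matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(euclideanCompactScore(distanceMatrix(m2)), 1)
  coincident <- caModel(matrix(0, 3, 3))
  expect_equal(euclideanCompactScore(distanceMatrix(coincident)), 0)
  # fully extended chain: direct pair enumeration oracle
  L <- 6
  ext <- caModel(cbind(3.8 * (0:(L - 1)), 0, 0))
  dm <- distanceMatrix(ext)
  manual <- mean(dm[upper.tri(dm)]) / (3.8 * (L - 1))
  ec <- euclideanCompactScore(dm)
  expect_equal(ec, manual, tolerance = 1e-12)
  expect_gt(ec, 0); expect_lt(ec, 1)
  expect_error(euclideanCompactScore(matrix(0, 1, 1)), "at least 2")
})

test_that("assembly imputes missing inputs at 0.5 and orders keys", {
  d <- simDecoy(L = 12, noise = 1, seed = 51)
  fv <- assembleFeatureVector(d$decoy)
  expect_s4_class(fv, "FeatureVector")
  v <- featureValues(fv); pr <- featureProvenance(fv)
  expect_identical(names(v), featureSetKeys("full16"))
  # no external table, no predictions: 9 external + SA + SS + SP imputed
  expect_identical(unname(v[pr == "imputed"]),
                   rep(0.5, sum(pr == "imputed")))
  expect_equal(sum(pr == "imputed"), 12)
  expect_equal(sum(pr == "computed"), 4)
  expect_true(all(v >= 0 & v <= 1))

  fv9 <- assembleFeatureVector(d$decoy, featureSet = "deepqa9")
  expect_identical(names(featureValues(fv9)),
                   c("SU", "DOPE", "GOAP", "OPUS", "RWPLUS",
                     "MODELEVALUATOR", "SP", "EC", "QPROB"))

  # with predictions and scores, provenance shifts
  fv2 <- assembleFeatureVector(
    d$decoy, external = list(dfire2 = -500, qprob = 0.7),
    ssPred = d$pool@ssPred, saPred = d$pool@saPred)
  pr2 <- featureProvenance(fv2)
  expect_equal(unname(pr2[c("DFIRE2", "QPROB")]), rep("external", 2))
  expect_equal(unname(pr2[c("SA", "SS", "SP")]), rep("computed", 3))
  expect_equal(sum(pr2 == "imputed"), 7)
})

test_that("features stay in [0,1] and are rigid-invariant on random decoys", {
  set.seed(7)
  for (i in 1:5) {
    d <- simDecoy(L = 10 + 2 * i, noise = c(0.5, 2, 8)[1 + i %% 3],
                  template = c("mixed", "helix", "coil")[1 + i %% 3],
                  seed = 60 + i)
    v <- featureValues(assembleFeatureVector(
      d$decoy, ssPred = d$pool@ssPred, saPred = d$pool@saPred))
    expect_true(all(v >= 0 & v <= 1))
    copy <- rigidCopy(d$decoy)
    sasa1 <- shrakeRupleySasa(d$decoy); sasa2 <- shrakeRupleySasa(copy)
    expect_lt(abs(surfaceScore(sasa1, d$decoy) - surfaceScore(sasa2, copy)),
              1e-9)
    expect_lt(abs(exposedMassScore(sasa1, d$decoy) -
                    exposedMassScore(sasa2, copy)), 1e-9)
    expect_lt(abs(exposedSurfaceScore(sasa1, d$decoy) -
                    exposedSurfaceScore(sasa2, copy)), 1e-9)
    expect_lt(abs(euclideanCompactScore(distanceMatrix(d$decoy)) -
                    euclideanCompactScore(distanceMatrix(copy))), 1e-9)
  }
})
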