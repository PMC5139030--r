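test_that("GDT-TS is 1 for identical structures and rigid copies", {
  d <- simDecoy(L = 10, noise = 1, seed = 71)
  expect_equal(gdtTS(d$native, d$native), 1)
  set.seed(72)
  expect_equal(gdtTS(rigidCopy(d$native), d$native), 1, tolerance = 1e-9)
})

test_that("GDT-TS resolves a half-displaced toy to exactly 0.5", {
  set.seed(73)
  nat <- caModel(cbind(3.8 * (0:9), 0, 0) + matrix(rnorm(30, sd = 0.3),
                                                   10, 3))
  at <- atomTable(nat)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  # displace residues 6..10 far away in random directions
  for (i in 6:10) {
    dir <- rnorm(3); xyz[i, ] <- xyz[i, ] + 50 * dir / sqrt(sum(dir^2))
  }
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  dec <- proteinModel("half", modelSequence(nat), at)
  expect_equal(gdtTS(dec, nat), 0.5)
  expect_equal(gdtExhaustive(caCoords(dec), caCoords(nat)), 0.5)
})

test_that("heuristic GDT-TS stays within 0.05 of the exhaustive oracle", {
  set.seed(74)
  worst <- 0
  for (i in 1:20) {
    L <- sample(7:10, 1)
    tpl <- sample(c("helix", "mixed", "coil"), 1)
    nl <- sample(c(1, 2, 4), 1)
    d <- simDecoy(L = L, noise = nl, template = tpl, seed = 500 + i)
    gap <- gdtExhaustive(caCoords(d$decoy), caCoords(d$native)) -
      gdtTS(d$decoy, d$native)
    worst <- max(worst, gap)
  }
  expect_lte(worst, 0.05)
})

test_that("GDT-TS decreases with decoy noise, in expectation", {
  nat <- generateNative(simConfig(L = 20, template = "mixed", seed = 75))
  means <- vapply(c(0.5, 2, 8), function(s) {
    pool <- generateDecoys(nat, simConfig(L = 20, nDecoys = 10,
                                          noiseLevels = s, seed = 76))
    mean(poolTrueScores(pool, tm = FALSE, rmsd = FALSE)$gdtts)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("TM-score is 1 on self, rigid-invariant, and matches a
           restricted-superposition oracle for one displaced residue", {
  d <- simDecoy(L = 20, noise = 0.5, seed = 77)
  expect_equal(tmScore(d$native, d$native), 1)
  set.seed(78)
  expect_equal(tmScore(rigidCopy(d$decoy), d$native),
               tmScore(d$decoy, d$native), tolerance = 1e-6)

  nat <- generateNative(simConfig(L = 20, template = "mixed", seed = 79))
  at <- atomTable(nat)
  ca <- which(at$elety == "CA" & at$resno == 10)
  at[at$resno == 10, c("x", "y", "z")] <-
    at[at$resno == 10, c("x", "y", "z")] + 8
  dec <- proteinModel("disp", modelSequence(nat), at)
  # oracle: superpose on the 19 intact residues only, then score all 20
  mCA <- caCoords(dec); nCA <- caCoords(nat)
  keep <- setdiff(1:20, 10)
  sup <- kabschSuperpose(nCA[keep, ], mCA[keep, ])
  dev <- sqrt(rowSums((applySuperposition(mCA, sup) - nCA)^2))
  d0 <- max(0.5, 1.24 * (20 - 15)^(1 / 3) - 1.8)
  oracle <- mean(1 / (1 + (dev / d0)^2))
  expect_equal(tmScore(dec, nat), oracle, tolerance = 0.02)
})

test_that("RMSD is zero on rigid copies and matches the rotation oracle", {
  d <- simDecoy(L = 8, noise = 2, seed = 80)
  expect_lt(rmsdCA(d$native, d$native), 1e-12)
  set.seed(81)
  expect_lt(rmsdCA(rigidCopy(d$native), d$native), 1e-8)
  a <- matrix(c(0, 0, 0, 3.8, 0, 0, 3.8, 3.8, 0, 0, 3.8, 0), 4, 3,
              byrow = TRUE)
  b <- a; b[2, 3] <- b[2, 3] + 1.5
  expect_equal(rmsdCA(caModel(b), caModel(a)), rmsdRotationSearch(a, b),
               tolerance = 1e-4)
})

test_that("per-target correlation handles perfect, inverted and tiny pools", {
  x <- c(0.2, 0.5, 0.9, 0.4)
  expect_equal(perTargetCorrelation(x, x), 1)
  expect_equal(perTargetCorrelation(1 - x, x), -1)
  expect_equal(perTargetCorrelation(c(0, 0.5, 1), c(0, 1, 0.5)), 0.5)
  expect_true(is.na(perTargetCorrelation(c(1, 1), c(0, 1))))
  expect_true(is.na(perTargetCorrelation(rep(0.5, 5), runif(5))))
})

test_that("per-target loss rewards picking the pool best", {
  true <- c(m1 = 0.3, m2 = 0.5, m3 = 0.7)
  expect_equal(perTargetLoss(c(0.1, 0.2, 0.9), true, names(true)), 0)
  expect_equal(perTargetLoss(c(0.1, 0.9, 0.2), true, names(true)), 0.2)
  set.seed(82)
  for (i in 1:20)
    expect_gte(perTargetLoss(runif(6), runif(6)), 0)
  # prediction ties break lexicographically by id
  expect_equal(perTargetLoss(c(0.5, 0.5, 0.1), true, c("b", "a", "c")),
               0.7 - 0.5)
  expect_error(perTargetLoss(numeric(0), numeric(0)), "empty")
})

test_that("top-k selection reduces correctly at the boundaries", {
  pred <- c(0.9, 0.8, 0.1, 0.7, 0.5)
  tm <- c(0.3, 0.6, 0.9, 0.4, 0.5)
  rmsd <- c(8, 4, 1, 6, 5)
  top1 <- topKSelection(pred, tm, rmsd, k = 1)
  expect_equal(top1$tm, 0.3); expect_equal(top1$rmsd, 8)
  top5 <- topKSelection(pred, tm, rmsd, k = 5)
  expect_equal(top5$tm, max(tm)); expect_equal(top5$rmsd, min(rmsd))
  # perfect predictor: best-of-top-1 is the pool max
  expect_equal(topKSelection(tm, tm, k = 1)$tm, max(tm))
  expect_warning(big <- topKSelection(pred, tm, rmsd, k = 10), "pool")
  expect_equal(big$tm, max(tm))
})

test_that("Z-score sums use the population standard deviation", {
  pools <- list(c(0.2, 0.4, 0.6), c(0.1, 0.2, 0.3))
  expect_equal(zscoreSum(vapply(pools, mean, numeric(1)), pools), 0)
  expect_equal(zscoreSum(0.6, pools[1]), 0.2 / sqrt(mean((c(-.2, 0, .2))^2)),
               tolerance = 1e-9)
  expect_equal(zscoreSum(0.6, pools[1]), 1.2247, tolerance = 1e-4)
  # degenerate pool contributes zero
  expect_equal(zscoreSum(0.5, list(rep(0.5, 4))), 0)
  # random selector averages to zero over many targets
  set.seed(83)
  pools <- replicate(1000, runif(10), simplify = FALSE)
  sel <- vapply(pools, function(p) p[sample.int(10, 1)], numeric(1))
  expect_lt(abs(zscoreSum(sel, pools)) / 1000, 0.1)
})

test_that("Wilcoxon signed-rank: exact enumeration, degeneracy, approximation", {
  # n = 5, all differences positive: p = 2/32
  res <- wilcoxonSignedRank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(res$p, 0.0625)
  expect_equal(res$method, "exact enumeration")

  same <- wilcoxonSignedRank(1:5, 1:5)
  expect_true(same$degenerate)
  expect_equal(same$p, 1)

  # agreement with the reference implementation on tie-free data
  set.seed(84)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(wilcoxonSignedRank(a, b)$p,
               wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)

  # exact vs normal approximation close at n = 12
  set.seed(85)
  a <- rnorm(12, 0.3); b <- rnorm(12)
  pe <- wilcoxonSignedRank(a, b, exactLimit = 12)$p
  pn <- wilcoxonSignedRank(a, b, exactLimit = 5)$p
  expect_lt(abs(pe - pn), 0.02)
})

test_that("local error profiles convert to global quality by the 1/(1+(l/5)^2) mean", {
  expect_equal(localToGlobal(rep(0, 30)), 1)
  expect_equal(localToGlobal(rep(5, 7)), 0.5)
  expect_equal(localToGlobal(c(0, 5)), 0.75)
  expect_error(localToGlobal(c(1, -2)), "non-negative")
})

test_that("evaluateQA aggregates per-target statistics", {
  set.seed(86)
  tab <- do.call(rbind, lapply(c("t1", "t2"), function(tg) {
    true <- runif(8, 0.2, 0.9)
    data.frame(target = tg, model = sprintf("m%d", 1:8),
               predicted = true, gdtts = true,
               tm = true, rmsd = 10 * (1 - true))
  }))
  ev <- evaluateQA(tab, k = 5)
  expect_equal(nrow(ev$perTarget), 2)
  expect_equal(unname(ev$summary["meanCorrelation"]), 1)
  expect_equal(unname(ev$summary["meanLoss"]), 0)
  expect_gt(unname(ev$summary["zsumTMTop1"]), 0)
  expect_lt(unname(ev$summary["zsumRMSDTop1"]), 0)
})
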