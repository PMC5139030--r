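# Ideal backbone geometry (Angstrom / degrees) used by the native builder.
BOND_N_CA <- 1.458; BOND_CA_C <- 1.525; BOND_C_N <- 1.329; BOND_C_O <- 1.231
ANG_N_CA_C <- 111.2; ANG_CA_C_N <- 116.2; ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.8

#' Simulation configuration
#'
#' @param L chain length (>= 5).
#' @param nDecoys decoys generated per noise level.
#' @param noiseLevels coordinate noise standard deviations (Angstrom);
#'   the default grid spans near-native to essentially unfolded.
#' @param template backbone dihedral template: "helix" (phi -57, psi -47),
#'   "strand" (-120, 120), "coil" (random outside both windows) or
#'   "mixed" (helix / coil / strand thirds).
#' @param seed integer seed.
#' @return named list of class "simConfig".
#' @export
simConfig <- function(L = 30, nDecoys = 20,
                      noiseLevels = c(0.5, 1, 2, 4, 8),
                      template = c("mixed", "helix", "strand", "coil"),
                      seed = 1L) {
  template <- match.arg(template)
  stopifnot(L >= 5, nDecoys >= 1, all(noiseLevels >= 0))
  structure(list(L = L, nDecoys = nDecoys, noiseLevels = noiseLevels,
                 template = template, seed = as.integer(seed)),
            class = "simConfig")
}

# Natural extension reference frame: place atom D given A-B-C, bond
# length R (C-D), bond angle theta (B-C-D) and torsion phi (A-B-C-D),
# angles in degrees.
placeAtom <- function(a, b, c, R, theta, phi) {
  th <- theta * pi / 180
  ph <- -phi * pi / 180  # sign matches the IUPAC torsion read back by dihedralAngle()
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  c + R * (-cos(th) * bc + sin(th) * cos(ph) * m + sin(th) * sin(ph) * n)
}

templateDihedrals <- function(template, L) {
  switch(template,
         helix = list(phi = rep(-57, L), psi = rep(-47, L)),
         strand = list(phi = rep(-120, L), psi = rep(120, L)),
         coil = list(phi = stats::runif(L, 20, 160),
                     psi = stats::runif(L, -180, 180)),
         mixed = {
           k <- floor(L / 3)
           phi <- c(rep(-57, k), stats::runif(L - 2 * k, 20, 160),
                    rep(-120, k))
           psi <- c(rep(-47, k), stats::runif(L - 2 * k, -180, 180),
                    rep(120, k))
           list(phi = phi, psi = psi)
         })
}

#' Build an ideal-geometry native model
#'
#' Constructs an N/CA/C/O backbone from template dihedrals with standard
#' bond lengths and angles (trans peptide, omega = 180). The sequence is
#' drawn uniformly from the 20 amino acids. Deterministic given the
#' config seed.
#'
#' @param config a \code{simConfig()}.
#' @return a \linkS4class{ProteinModel} with id "native".
#' @export
generateNative <- function(config = simConfig()) {
  set.seed(config$seed)
  L <- config$L
  seqv <- sample(AA1, L, replace = TRUE)
  dih <- templateDihedrals(config$template, L)

  coords <- list()  # per residue: N, CA, C, O
  th <- ANG_N_CA_C * pi / 180
  N1 <- c(0, 0, 0); CA1 <- c(BOND_N_CA, 0, 0)
  C1 <- CA1 + BOND_CA_C * c(-cos(th), sin(th), 0)
  Ni <- N1; CAi <- CA1; Ci <- C1
  for (i in seq_len(L)) {
    if (i > 1) {
      Nnew <- placeAtom(Ni, CAi, Ci, BOND_C_N, ANG_CA_C_N, dih$psi[i - 1])
      CAnew <- placeAtom(CAi, Ci, Nnew, BOND_N_CA, ANG_C_N_CA, 180)
      Cnew <- placeAtom(Ci, Nnew, CAnew, BOND_CA_C, ANG_N_CA_C, dih$phi[i])
      coords[[i - 1]]$O <- placeAtom(Ni, CAi, Ci, BOND_C_O, ANG_CA_C_O,
                                     dih$psi[i - 1] + 180)
      Ni <- Nnew; CAi <- CAnew; Ci <- Cnew
    }
    coords[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  coords[[L]]$O <- placeAtom(Ni, CAi, Ci, BOND_C_O, ANG_CA_C_O,
                             dih$psi[L] + 180)

  atoms <- do.call(rbind, lapply(seq_len(L), function(i) {
    nm <- c("N", "CA", "C", "O")
    xyz <- do.call(rbind, coords[[i]][nm])
    data.frame(resno = i, elety = nm,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }))
  proteinModel("native", paste(seqv, collapse = ""), atoms)
}

randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a noise-graded decoy pool
#'
#' For every noise level sigma, \code{nDecoys} decoys are built by adding
#' i.i.d. Gaussian noise N(0, sigma^2) to each atom coordinate of the
#' native and re-orienting the copy with a random rigid transform (so
#' nothing downstream can rely on a shared frame). The pool carries the
#' native, plus "predicted" secondary-structure and accessibility strings
#' derived from the native, emulating accurate sequence-based predictors.
#'
#' @param native model from \code{generateNative()}.
#' @param config a \code{simConfig()}.
#' @return a \linkS4class{ModelPool}; decoy ids encode the noise level
#'   (e.g. "d_s2_05").
#' @export
generateDecoys <- function(native, config = simConfig()) {
  set.seed(config$seed + 1L)
  at <- atomTable(native)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  models <- list()
  for (s in config$noiseLevels) {
    for (j in seq_len(config$nDecoys)) {
      noisy <- xyz + matrix(stats::rnorm(length(xyz), sd = s), ncol = 3)
      moved <- noisy %*% randomRotation()
      moved <- sweep(moved, 2, stats::runif(3, -20, 20), "+")
      id <- sprintf("d_s%g_%02d", s, j)
      a2 <- at
      a2$x <- moved[, 1]; a2$y <- moved[, 2]; a2$z <- moved[, 3]
      models[[id]] <- proteinModel(id, modelSequence(native), a2,
                                   resno = native@resno)
    }
  }
  sasaN <- shrakeRupleySasa(native)
  modelPool("sim_target", models, native = native,
            ssPred = assignSecondaryStructure(native),
            saPred = paste(ifelse(sasaN$exposed, "e", "b"), collapse = ""))
}

#' True quality scores of a pool against its native
#'
#' @param pool a \linkS4class{ModelPool} with a native.
#' @param tm,rmsd also compute TM-score / RMSD (GDT-TS always computed).
#' @return data.frame: model, gdtts, and optionally tm, rmsd.
#' @export
poolTrueScores <- function(pool, tm = TRUE, rmsd = TRUE) {
  native <- poolNative(pool)
  if (is.null(native)) stop("pool has no native structure")
  models <- poolModels(pool)
  out <- data.frame(model = names(models),
                    gdtts = vapply(models, gdtTS, numeric(1),
                                   native = native),
                    stringsAsFactors = FALSE)
  if (tm) out$tm <- vapply(models, tmScore, numeric(1), native = native)
  if (rmsd) out$rmsd <- vapply(models, rmsdCA, numeric(1), native = native)
  rownames(out) <- NULL
  out
}

#' Synthetic external score table for a pool
#'
#' Emits raw scores on each tool's native scale such that, after
#' normalization, each tracks the given true quality up to Gaussian
#' noise. This exercises the external-score path (reading, length
#' normalization, imputation) without the external tools themselves;
#' it is labelled synthetic and carries no information beyond
#' \code{quality + noise}.
#'
#' @param pool a \linkS4class{ModelPool}.
#' @param quality true quality per model (named by model id, or in pool
#'   order).
#' @param noiseSd score noise on the [0,1] scale.
#' @param seed integer seed.
#' @param columns which score columns to emit.
#' @return data.frame suitable for \code{ModelPool@externalScores}.
#' @export
generateExternalScores <- function(pool, quality, noiseSd = 0.05, seed = 1L,
                                   columns = names(EXTERNAL_SCORE_KINDS)) {
  set.seed(seed)
  models <- poolModels(pool)
  ids <- names(models)
  if (!is.null(names(quality))) quality <- quality[ids]
  L <- nResidues(models[[1]])
  q <- function() pmin(1, pmax(0, quality + stats::rnorm(length(ids),
                                                         sd = noiseSd)))
  out <- data.frame(model = ids, stringsAsFactors = FALSE)
  for (cn in columns) {
    out[[cn]] <- switch(cn,
      dfire2 = -q() * 1.971 * L,
      rwplus = -q() * 232.6 * L,
      rf_cb_srs_od = 700 - q() * (1000 + 0.4823 * L),
      dope = -q() * LINEAR_SCALE_DEFAULTS[["dope"]] * L,
      goap = -q() * LINEAR_SCALE_DEFAULTS[["goap"]] * L,
      opus = -q() * LINEAR_SCALE_DEFAULTS[["opus"]] * L,
      q())
  }
  rownames(out) <- NULL
  out
}

#' Synthetic feature/target dataset with a known mapping
#'
#' Features are uniform on [0,1]; the target is a logistic ramp in the
#' sum of the two designated informative features plus Gaussian noise,
#' clamped to [0.01, 0.99] to keep the output sigmoid off its saturated
#' tails:
#' \deqn{y = clamp(\sigma(4 (x_1 + x_2 - 1)) + N(0, \sigma_y^2))}
#' The noiseless generating function is returned so tests can recompute
#' targets exactly.
#'
#' @param n rows (>= 10).
#' @param noiseSd target noise sigma_y.
#' @param seed integer seed.
#' @param nFeatures number of feature columns (16 matches the full
#'   feature set).
#' @return list: \code{features} (n x nFeatures matrix),
#'   \code{targets}, \code{trueFunction} (matrix -> noiseless target),
#'   \code{informative} (column indices 1:2).
#' @export
generateFeatureDataset <- function(n = 2000, noiseSd = 0.05, seed = 1L,
                                   nFeatures = 16) {
  stopifnot(n >= 10, nFeatures >= 2)
  set.seed(seed)
  X <- matrix(stats::runif(n * nFeatures), n, nFeatures)
  colnames(X) <- if (nFeatures <= 16) featureSetKeys("full16")[seq_len(nFeatures)]
                 else paste0("F", seq_len(nFeatures))
  trueFun <- function(M) stats::plogis(4 * (M[, 1] + M[, 2] - 1))
  y <- pmin(0.99, pmax(0.01, trueFun(X) + stats::rnorm(n, sd = noiseSd)))
  rownames(X) <- sprintf("m%04d", seq_len(n))
  names(y) <- rownames(X)
  list(features = X, targets = y, trueFunction = trueFun,
       informative = c(1L, 2L))
}

#' End-to-end benchmark on simulated decoy pools
#'
#' Builds training pools (several simulated targets with noise-graded
#' decoys and synthetic external scores), trains the network on their
#' feature matrices against true GDT-TS, then scores an independent test
#' pool and reports the ranking statistics. This is the package's fully
#' self-contained analogue of a decoy-ranking benchmark: every input is
#' simulated, so the result measures the pipeline, not any external
#' dataset.
#'
#' @param seed master seed; all stages derive their seeds from it.
#' @param L chain length of the simulated targets.
#' @param nTrainTargets number of training targets.
#' @param nDecoysTrain decoys per noise level per training target.
#' @param nDecoysTest decoys per noise level in the test pool.
#' @param noiseLevels coordinate noise grid (Angstrom).
#' @param trainConfig a \code{dbnTrainConfig()}; its seed is re-derived
#'   from \code{seed}.
#' @return list: \code{pearson} and \code{loss} on the test pool,
#'   \code{predictions}, \code{truth} (test-pool true scores),
#'   \code{model} (the trained \linkS4class{DBNModel}), \code{nTrain}.
#' @export
runSimulatedBenchmark <- function(seed = 1L, L = 30, nTrainTargets = 3,
                                  nDecoysTrain = 8, nDecoysTest = 20,
                                  noiseLevels = c(0.5, 1, 2, 4, 8),
                                  trainConfig = dbnTrainConfig()) {
  seed <- as.integer(seed)
  templates <- c("mixed", "helix", "strand")
  buildPool <- function(poolSeed, nDecoys, template) {
    cfg <- simConfig(L = L, nDecoys = nDecoys, noiseLevels = noiseLevels,
                     template = template, seed = poolSeed)
    native <- generateNative(cfg)
    pool <- generateDecoys(native, cfg)
    truth <- poolTrueScores(pool, tm = FALSE, rmsd = FALSE)
    pool@externalScores <- generateExternalScores(
      pool, stats::setNames(truth$gdtts, truth$model),
      seed = poolSeed + 7L)
    X <- poolFeatureMatrix(pool)
    list(X = X, y = truth$gdtts[match(rownames(X), truth$model)])
  }
  train <- lapply(seq_len(nTrainTargets), function(i)
    buildPool(seed + 10L * i, nDecoysTrain,
              templates[1 + (i - 1) %% length(templates)]))
  trainX <- do.call(rbind, lapply(train, `[[`, "X"))
  trainY <- unlist(lapply(train, `[[`, "y"))
  trainConfig$seed <- seed
  net <- trainDBN(trainX, trainY, trainConfig)

  test <- buildPool(seed + 1000L, nDecoysTest, "mixed")
  pred <- predictQuality(net, test$X)
  list(pearson = perTargetCorrelation(pred, test$y),
       loss = perTargetLoss(pred, test$y, rownames(test$X)),
       predictions = stats::setNames(pred, rownames(test$X)),
       truth = stats::setNames(test$y, rownames(test$X)),
       model = net, nTrain = nrow(trainX))
}
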