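sigmoid <- function(x) 1 / (1 + exp(-x))

#' Training configuration for the deep belief network
#'
#' Defaults follow the tuned architecture: 20 and 10 hidden nodes in the
#' two RBM layers, learning rate 1e-4, weight cost 0.007, momentum
#' schedule 0.5 rising to 0.9.
#'
#' @param N1,N2 hidden nodes in RBM layers 1 and 2.
#' @param learningRate contrastive-divergence learning rate (epsilon).
#' @param weightCost L2 weight decay (omega) applied to RBM weights.
#' @param momentumInitial,momentumFinal,momentumSwitch momentum (nu) is
#'   \code{momentumInitial} for the first \code{momentumSwitch} epochs,
#'   then \code{momentumFinal}.
#' @param pretrainEpochs CD-1 epochs per RBM layer.
#' @param batchSize minibatch size for CD-1.
#' @param bfgsMaxIter,bfgsTol BFGS fine-tuning iteration cap and relative
#'   improvement tolerance on the mean squared error.
#' @param seed integer seed making pretraining and fine-tuning
#'   deterministic.
#' @return named list of class "dbnTrainConfig".
#' @export
dbnTrainConfig <- function(N1 = 20, N2 = 10,
                           learningRate = 1e-4, weightCost = 0.007,
                           momentumInitial = 0.5, momentumFinal = 0.9,
                           momentumSwitch = 5,
                           pretrainEpochs = 100, batchSize = 100,
                           bfgsMaxIter = 1000, bfgsTol = 1e-9,
                           seed = 1L) {
  stopifnot(N1 >= 1, N2 >= 1, learningRate > 0, weightCost >= 0,
            momentumInitial >= 0, momentumInitial < 1,
            momentumFinal >= 0, momentumFinal < 1,
            pretrainEpochs >= 1, batchSize >= 1, bfgsMaxIter >= 1)
  structure(list(N1 = N1, N2 = N2, learningRate = learningRate,
                 weightCost = weightCost,
                 momentumInitial = momentumInitial,
                 momentumFinal = momentumFinal,
                 momentumSwitch = momentumSwitch,
                 pretrainEpochs = pretrainEpochs, batchSize = batchSize,
                 bfgsMaxIter = bfgsMaxIter, bfgsTol = bfgsTol,
                 seed = as.integer(seed)),
            class = "dbnTrainConfig")
}

newRbmLayer <- function(nVisible, nHidden) {
  list(W = matrix(stats::rnorm(nVisible * nHidden, sd = 0.01),
                  nVisible, nHidden),
       vbias = numeric(nVisible), hbias = numeric(nHidden))
}

zeroVelocity <- function(layer) {
  list(W = layer$W * 0, vbias = layer$vbias * 0, hbias = layer$hbias * 0)
}

#' One CD-1 update of an RBM layer
#'
#' Hidden probabilities are logistic in the visible input; hidden states
#' are Bernoulli samples; the visible reconstruction uses probabilities
#' (visible units are real-valued scores in [0,1]). The weight gradient is
#' the difference of data and reconstruction correlations, applied through
#' a momentum velocity with L2 weight cost on W:
#' \code{velocity <- nu * velocity + eps * (gradient - omega * W)}.
#'
#' @param layer list(W, vbias, hbias).
#' @param visible minibatch matrix (rows = cases) with entries in [0,1].
#' @param eps learning rate; \code{eps = 0} leaves weights unchanged.
#' @param omega weight cost.
#' @param nu momentum.
#' @param velocity previous velocity (same shapes as layer); NULL = zeros.
#' @return list(layer, velocity, reconError) where reconError is the mean
#'   squared difference between data and reconstruction.
#' @export
cd1Update <- function(layer, visible, eps, omega, nu, velocity = NULL) {
  visible <- as.matrix(visible)
  if (ncol(visible) != nrow(layer$W))
    stop("visible dimension ", ncol(visible),
         " != layer visible size ", nrow(layer$W))
  if (is.null(velocity)) velocity <- zeroVelocity(layer)
  n <- nrow(visible)

  hProb <- sigmoid(sweep(visible %*% layer$W, 2, layer$hbias, "+"))
  hState <- matrix(stats::rbinom(length(hProb), 1, hProb), nrow(hProb))
  vRecon <- sigmoid(sweep(hState %*% t(layer$W), 2, layer$vbias, "+"))
  hProb2 <- sigmoid(sweep(vRecon %*% layer$W, 2, layer$hbias, "+"))

  gW <- unname(crossprod(visible, hProb) - crossprod(vRecon, hProb2)) / n
  gV <- unname(colMeans(visible - vRecon))
  gH <- unname(colMeans(hProb - hProb2))

  velocity$W <- nu * velocity$W + eps * (gW - omega * layer$W)
  velocity$vbias <- nu * velocity$vbias + eps * gV
  velocity$hbias <- nu * velocity$hbias + eps * gH
  layer$W <- layer$W + velocity$W
  layer$vbias <- layer$vbias + velocity$vbias
  layer$hbias <- layer$hbias + velocity$hbias

  list(layer = layer, velocity = velocity,
       reconError = mean((visible - vRecon)^2))
}

trainRbm <- function(data, nHidden, config) {
  layer <- newRbmLayer(ncol(data), nHidden)
  velocity <- zeroVelocity(layer)
  n <- nrow(data)
  epochErr <- numeric(config$pretrainEpochs)
  for (epoch in seq_len(config$pretrainEpochs)) {
    nu <- if (epoch <= config$momentumSwitch) config$momentumInitial
          else config$momentumFinal
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$batchSize)
    errs <- numeric(length(starts))
    for (b in seq_along(starts)) {
      idx <- ord[starts[b]:min(starts[b] + config$batchSize - 1, n)]
      step <- cd1Update(layer, data[idx, , drop = FALSE],
                        config$learningRate, config$weightCost, nu, velocity)
      layer <- step$layer; velocity <- step$velocity
      errs[b] <- step$reconError
    }
    epochErr[epoch] <- mean(errs)
  }
  list(layer = layer, reconErrors = epochErr)
}

#' Greedy layer-wise pretraining of the network
#'
#' Trains the first RBM on the feature matrix and the second on the first
#' layer's hidden probabilities, both by CD-1; the logistic output layer
#' starts at zero. Deterministic for a fixed config seed.
#'
#' @param features matrix (rows = models) with entries in [0,1].
#' @param config a \code{dbnTrainConfig()}.
#' @param featureSet feature-set name recorded in the model.
#' @return a \linkS4class{DBNModel} (not yet fine-tuned).
#' @export
pretrainDBN <- function(features, config = dbnTrainConfig(),
                        featureSet = "full16") {
  features <- as.matrix(features)
  if (nrow(features) == 0L) stop("empty feature matrix")
  if (any(features < 0 | features > 1))
    stop("features must lie in [0,1]")
  set.seed(config$seed)
  r1 <- trainRbm(features, config$N1, config)
  h1 <- sigmoid(sweep(features %*% r1$layer$W, 2, r1$layer$hbias, "+"))
  r2 <- trainRbm(h1, config$N2, config)
  new("DBNModel", rbm1 = r1$layer, rbm2 = r2$layer,
      outW = numeric(config$N2), outB = 0,
      featureSet = featureSet, config = unclass(config),
      metadata = list(seed = config$seed,
                      pretrainEpochs = config$pretrainEpochs,
                      reconErrors1 = r1$reconErrors,
                      reconErrors2 = r2$reconErrors))
}

flattenParams <- function(model) {
  c(as.vector(model@rbm1$W), model@rbm1$hbias,
    as.vector(model@rbm2$W), model@rbm2$hbias,
    model@outW, model@outB)
}

unflattenParams <- function(theta, model) {
  nIn <- nrow(model@rbm1$W); N1 <- ncol(model@rbm1$W); N2 <- ncol(model@rbm2$W)
  i <- 0
  take <- function(k) { out <- theta[(i + 1):(i + k)]; i <<- i + k; out }
  model@rbm1$W <- matrix(take(nIn * N1), nIn, N1)
  model@rbm1$hbias <- take(N1)
  model@rbm2$W <- matrix(take(N1 * N2), N1, N2)
  model@rbm2$hbias <- take(N2)
  model@outW <- take(N2)
  model@outB <- take(1)
  model
}

dbnForward <- function(theta, X, dims) {
  nIn <- dims[1]; N1 <- dims[2]; N2 <- dims[3]
  i <- 0
  take <- function(k) { out <- theta[(i + 1):(i + k)]; i <<- i + k; out }
  W1 <- matrix(take(nIn * N1), nIn, N1); b1 <- take(N1)
  W2 <- matrix(take(N1 * N2), N1, N2); b2 <- take(N2)
  w3 <- take(N2); b3 <- take(1)
  h1 <- sigmoid(sweep(X %*% W1, 2, b1, "+"))
  h2 <- sigmoid(sweep(h1 %*% W2, 2, b2, "+"))
  yhat <- as.vector(sigmoid(h2 %*% w3 + b3))
  list(h1 = h1, h2 = h2, yhat = yhat, W2 = W2, w3 = w3)
}

dbnCost <- function(theta, X, y, dims) {
  mean((dbnForward(theta, X, dims)$yhat - y)^2)
}

dbnGradient <- function(theta, X, y, dims) {
  f <- dbnForward(theta, X, dims)
  n <- nrow(X)
  e <- 2 * (f$yhat - y) * f$yhat * (1 - f$yhat) / n
  gw3 <- as.vector(crossprod(f$h2, e))
  gb3 <- sum(e)
  d2 <- (e %o% f$w3) * f$h2 * (1 - f$h2)
  gW2 <- crossprod(f$h1, d2)
  gb2 <- colSums(d2)
  d1 <- (d2 %*% t(f$W2)) * f$h1 * (1 - f$h1)
  gW1 <- crossprod(X, d1)
  gb1 <- colSums(d1)
  c(as.vector(gW1), gb1, as.vector(gW2), gb2, gw3, gb3)
}

#' BFGS fine-tuning of all network weights
#'
#' Minimises the full-batch mean squared error of the logistic
#' feed-forward network (logistic units at both hidden layers and the
#' output) over all weights and biases, using BFGS with the analytic
#' backpropagation gradient. Optimisation runs in bounded chunks so the
#' objective can be monitored; the recorded objective trace is
#' non-increasing, and the run stops once the relative improvement falls
#' below \code{bfgsTol} or \code{bfgsMaxIter} iterations are spent.
#'
#' @param model a pretrained \linkS4class{DBNModel}.
#' @param features matrix of training inputs in [0,1].
#' @param targets numeric vector of true quality scores in [0,1].
#' @param config a \code{dbnTrainConfig()}; NULL = the model's own.
#' @return the fine-tuned \linkS4class{DBNModel}; metadata gains
#'   \code{mseTrace} (objective after each chunk, first entry = initial
#'   MSE) and \code{finalMSE}.
#' @export
finetuneBFGS <- function(model, features, targets, config = NULL) {
  if (is.null(config)) config <- do.call(dbnTrainConfig, model@config)
  X <- as.matrix(features)
  y <- as.numeric(targets)
  if (length(y) != nrow(X)) stop("targets length != feature rows")
  dims <- c(nrow(model@rbm1$W), ncol(model@rbm1$W), ncol(model@rbm2$W))
  if (ncol(X) != dims[1]) stop("feature dimension mismatch")

  theta <- flattenParams(model)
  f0 <- dbnCost(theta, X, y, dims)
  if (!is.finite(f0)) stop("non-finite objective at start of fine-tuning")
  trace <- f0
  chunk <- 50L
  spent <- 0L
  repeat {
    it <- min(chunk, config$bfgsMaxIter - spent)
    if (it <= 0L) break
    fit <- stats::optim(theta, dbnCost, dbnGradient, X = X, y = y,
                        dims = dims, method = "BFGS",
                        control = list(maxit = it, reltol = 1e-12))
    spent <- spent + it
    if (!is.finite(fit$value))
      stop("non-finite objective during fine-tuning")
    # keep the better iterate; optim can only improve or stay
    if (fit$value <= trace[length(trace)]) theta <- fit$par
    fNew <- min(fit$value, trace[length(trace)])
    improved <- (trace[length(trace)] - fNew) >
      config$bfgsTol * max(1e-12, trace[length(trace)])
    trace <- c(trace, fNew)
    if (!improved || fit$convergence == 0) break
  }
  out <- unflattenParams(theta, model)
  out@metadata$mseTrace <- trace
  out@metadata$finalMSE <- trace[length(trace)]
  out@metadata$bfgsIterations <- spent
  validObject(out)
  out
}

#' Train a quality regressor end to end
#'
#' Contrastive-divergence pretraining followed by BFGS fine-tuning.
#'
#' @inheritParams pretrainDBN
#' @param targets true quality scores in [0,1], one per feature row.
#' @return a fine-tuned \linkS4class{DBNModel}.
#' @export
trainDBN <- function(features, targets, config = dbnTrainConfig(),
                     featureSet = "full16") {
  model <- pretrainDBN(features, config, featureSet)
  finetuneBFGS(model, features, targets, config)
}

#' Predict model quality
#'
#' Deterministic feed-forward pass; the logistic output keeps every
#' prediction strictly inside (0,1).
#'
#' @param model a \linkS4class{DBNModel}.
#' @param features a \linkS4class{FeatureVector}, a numeric vector, or a
#'   matrix with one row per model.
#' @return numeric vector of predicted quality scores in (0,1).
#' @export
predictQuality <- function(model, features) {
  if (is(features, "FeatureVector")) {
    if (!identical(features@featureSet, model@featureSet))
      stop("feature set '", features@featureSet,
           "' does not match model feature set '", model@featureSet, "'")
    features <- featureValues(features)
  }
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(X) != nrow(model@rbm1$W))
    stop("feature dimension ", ncol(X), " != model input size ",
         nrow(model@rbm1$W))
  dims <- c(nrow(model@rbm1$W), ncol(model@rbm1$W), ncol(model@rbm2$W))
  dbnForward(flattenParams(model), X, dims)$yhat
}

#' k-fold cross-validation with mean absolute error
#'
#' Rows are shuffled with the config seed and split into k folds whose
#' sizes differ by at most one; each fold is held out once while the
#' network is trained on the rest.
#'
#' @param features matrix in [0,1].
#' @param targets true scores in [0,1].
#' @param config a \code{dbnTrainConfig()}.
#' @param k number of folds (>= 2).
#' @param featureSet feature-set name stored in fold models.
#' @return list: \code{perFoldMAE}, \code{meanMAE}, \code{heldOutPearson}
#'   (over all held-out predictions pooled), \code{predictions} (named by
#'   row), \code{folds} (fold index per row).
#' @export
crossValidateDBN <- function(features, targets, config = dbnTrainConfig(),
                             k = 5, featureSet = "full16") {
  X <- as.matrix(features)
  y <- as.numeric(targets)
  n <- nrow(X)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("need at least k samples")
  set.seed(config$seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  preds <- numeric(n)
  mae <- numeric(k)
  for (f in seq_len(k)) {
    hold <- fold == f
    cfg <- config
    cfg$seed <- config$seed + f
    m <- trainDBN(X[!hold, , drop = FALSE], y[!hold], cfg, featureSet)
    preds[hold] <- predictQuality(m, X[hold, , drop = FALSE])
    mae[f] <- mean(abs(preds[hold] - y[hold]))
  }
  names(preds) <- rownames(X)
  list(perFoldMAE = mae, meanMAE = mean(mae),
       heldOutPearson = perTargetCorrelation(preds, y),
       predictions = preds, folds = fold)
}

DBN_FILE_VERSION <- "1.0"

#' Save / load a trained network as JSON
#'
#' Lossless round-trip of all weights, the training config and the
#' feature-set name; a loaded model predicts identically.
#'
#' @param model a \linkS4class{DBNModel}.
#' @param path JSON file path.
#' @return \code{loadDBN} returns the \linkS4class{DBNModel};
#'   \code{saveDBN} the path, invisibly.
#' @export
saveDBN <- function(model, path) {
  packLayer <- function(l) list(W = as.vector(l$W), dim = dim(l$W),
                                vbias = l$vbias, hbias = l$hbias)
  payload <- list(
    format = "dbnQA-model", version = DBN_FILE_VERSION,
    featureSet = model@featureSet,
    rbm1 = packLayer(model@rbm1), rbm2 = packLayer(model@rbm2),
    outW = model@outW, outB = model@outB,
    config = model@config,
    metadata = model@metadata)
  # I(17) significant digits: doubles survive the round-trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname saveDBN
#' @export
loadDBN <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "dbnQA-model"))
    stop("not a saved network file: ", path)
  if (!identical(p$version, DBN_FILE_VERSION))
    stop("unsupported model file version: ", p$version)
  keys <- tryCatch(featureSetKeys(p$featureSet),
                   error = function(e) stop("unknown feature set in ", path))
  asLayer <- function(l) list(W = matrix(as.numeric(l$W), l$dim[1], l$dim[2]),
                              vbias = as.numeric(l$vbias),
                              hbias = as.numeric(l$hbias))
  model <- new("DBNModel", rbm1 = asLayer(p$rbm1), rbm2 = asLayer(p$rbm2),
               outW = as.numeric(p$outW), outB = as.numeric(p$outB),
               featureSet = p$featureSet,
               config = as.list(p$config), metadata = as.list(p$metadata))
  if (nrow(model@rbm1$W) != length(keys))
    stop("model input size ", nrow(model@rbm1$W),
         " does not match feature set '", p$featureSet, "' (",
         length(keys), " features)")
  validObject(model)
  model
}
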