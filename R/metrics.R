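caPair <- function(model, native) {
  if (nResidues(model) != nResidues(native))
    stop("model and native differ in length")
  list(m = caCoords(model), n = caCoords(native))
}

# Iterative seed-and-extend superposition search shared by GDT-TS and
# TM-score. Every seed subset is superposed (Kabsch), the per-residue
# deviations are scored, and the subset is re-selected as the residues
# within cutoff (times a relaxation factor) until a fixed point; a
# k-closest re-superposition sweep and a worst-residue trimming pass
# refine the result. Short chains (L <= 12) additionally seed from every
# residue triple, which in practice reaches the exhaustive-subset
# optimum; longer chains use consecutive windows only, trading a little
# optimality for speed on large decoy pools.
seedExtendSearch <- function(mCA, nCA, cutoff, score, maxIter = 20) {
  L <- nrow(mCA)
  deep <- L <= 12
  devOf <- function(S) {
    sup <- kabschSuperpose(nCA[S, , drop = FALSE], mCA[S, , drop = FALSE])
    sqrt(rowSums((applySuperposition(mCA, sup) - nCA)^2))
  }
  seeds <- list(list(S = seq_len(L), sf = c(1, 1.5, 2)))
  winLens <- if (deep) 3:7 else 3L
  for (w in winLens[winLens <= L])
    for (s in seq_len(L - w + 1))
      seeds[[length(seeds) + 1L]] <- list(S = s:(s + w - 1),
                                          sf = if (deep) c(1, 1.5, 2)
                                               else c(1, 2))
  if (deep && L >= 4) {
    cm <- utils::combn(L, 3)
    for (j in seq_len(ncol(cm)))
      seeds[[length(seeds) + 1L]] <- list(S = cm[, j], sf = 1)
  }
  best <- -Inf
  bestDev <- NULL
  for (sd in seeds) for (sf in sd$sf) {
    S <- sd$S
    for (iter in seq_len(maxIter)) {
      d <- devOf(S)
      sc <- score(d)
      if (sc > best) { best <- sc; bestDev <- d }
      Snew <- which(d <= cutoff * sf)
      if (length(Snew) < 3 || identical(Snew, S)) break
      S <- Snew
    }
    if (deep) {
      ord <- order(d)
      for (k in 3:L) {
        dk <- devOf(ord[1:k])
        sck <- score(dk)
        if (sck > best) { best <- sck; bestDev <- dk }
      }
    }
  }
  # trim: from the full chain, drop the worst residue and re-superpose
  S <- seq_len(L)
  while (length(S) >= 3) {
    d <- devOf(S)
    sc <- score(d)
    if (sc > best) { best <- sc; bestDev <- d }
    S <- S[-which.max(d[S])]
  }
  # k-closest sweep from the best superposition found
  ord <- order(bestDev)
  for (k in 3:L) best <- max(best, score(devOf(ord[1:k])))
  best
}

#' GDT-TS structural similarity
#'
#' Global Distance Test Total Score: for each threshold d in {1,2,4,8}
#' Angstrom, the largest fraction of CA atoms that can be superposed
#' within d of the native is sought with an iterative seed-and-extend
#' heuristic (full-chain and all 3-residue-window seeds; superpose, keep
#' residues within d, re-superpose to a fixed point; best over seeds).
#' GDT-TS is the mean of the four fractions. The heuristic tracks the
#' classic large-subset search closely but is not the LGA program.
#'
#' @param model,native \linkS4class{ProteinModel}s of equal length.
#' @return GDT-TS in [0,1].
#' @export
gdtTS <- function(model, native) {
  p <- caPair(model, native)
  L <- nrow(p$m)
  fr <- vapply(c(1, 2, 4, 8), function(d) {
    seedExtendSearch(p$m, p$n, cutoff = d,
                     score = function(dev) sum(dev <= d) / L)
  }, numeric(1))
  mean(fr)
}

#' TM-score structural similarity
#'
#' Length-normalised similarity \eqn{\max (1/L) \sum 1/(1+(d_i/d_0)^2)}
#' over superpositions from the same seed-and-extend search as GDT-TS,
#' with \eqn{d_0 = 1.24 (L-15)^{1/3} - 1.8}, floored at 0.5 Angstrom so
#' short toy chains stay defined.
#'
#' @param model,native \linkS4class{ProteinModel}s of equal length.
#' @return TM-score in (0,1].
#' @export
tmScore <- function(model, native) {
  p <- caPair(model, native)
  L <- nrow(p$m)
  d0 <- max(0.5, 1.24 * sign(L - 15) * abs(L - 15)^(1 / 3) - 1.8)
  cutoff <- max(d0, 4.5)
  seedExtendSearch(p$m, p$n, cutoff = cutoff,
                   score = function(dev) mean(1 / (1 + (dev / d0)^2)))
}

#' CA RMSD after optimal superposition
#'
#' @param model,native \linkS4class{ProteinModel}s of equal length.
#' @return RMSD in Angstrom.
#' @export
rmsdCA <- function(model, native) {
  p <- caPair(model, native)
  kabschSuperpose(p$n, p$m)$rmsd
}

#' Per-target Pearson correlation between predicted and true quality
#'
#' @param predicted,true numeric vectors over one target's models.
#' @return Pearson r, or NA when fewer than 3 pairs or either side has
#'   zero variance (degenerate pools are excluded from averages).
#' @export
perTargetCorrelation <- function(predicted, true) {
  ok <- is.finite(predicted) & is.finite(true)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(predicted[ok]) == 0 || stats::sd(true[ok]) == 0)
    return(NA_real_)
  stats::cor(predicted[ok], true[ok])
}

# Order models by descending prediction, ties broken by model id so
# selection is reproducible.
selectionOrder <- function(predicted, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(predicted))
  order(-predicted, ids)
}

#' Per-target loss
#'
#' True quality of the pool's best model minus the true quality of the
#' model ranked first by the predictor. Ties on the prediction are broken
#' lexicographically by model id.
#'
#' @param predicted,true numeric vectors over one target's models.
#' @param ids optional model ids (for tie-breaking).
#' @return loss >= 0.
#' @export
perTargetLoss <- function(predicted, true, ids = NULL) {
  if (!length(predicted)) stop("empty model pool")
  top <- selectionOrder(predicted, ids)[1]
  unname(max(true) - true[top])
}

#' Best-of-top-k selection
#'
#' Among the k highest-predicted models, the best true TM-score and the
#' lowest RMSD. k larger than the pool is truncated with a warning.
#'
#' @param predicted prediction per model.
#' @param tm,rmsd true per-model TM-scores and RMSDs (either may be NULL).
#' @param k selection depth (k = 1 gives top-1 metrics).
#' @param ids optional model ids for tie-breaking.
#' @return list(tm, rmsd) of the best values among the selected k.
#' @export
topKSelection <- function(predicted, tm = NULL, rmsd = NULL, k = 5,
                          ids = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (k > length(predicted)) {
    warning("k exceeds pool size; using the whole pool")
    k <- length(predicted)
  }
  sel <- selectionOrder(predicted, ids)[seq_len(k)]
  list(tm = if (is.null(tm)) NULL else max(tm[sel]),
       rmsd = if (is.null(rmsd)) NULL else min(rmsd[sel]))
}

#' Summed selection Z-scores across targets
#'
#' For each target, the selected model's value standardised by the pool
#' mean and population standard deviation; zero when the pool is
#' degenerate. Good selections give positive sums for TM-score and
#' negative sums for RMSD (the formula is identical; orientation comes
#' from the metric).
#'
#' @param selected numeric vector: the chosen model's value per target.
#' @param pools list of numeric vectors: each target's pool values.
#' @return sum of per-target Z-scores.
#' @export
zscoreSum <- function(selected, pools) {
  stopifnot(length(selected) == length(pools))
  z <- mapply(function(s, pool) {
    sdp <- sqrt(mean((pool - mean(pool))^2))
    if (sdp == 0) 0 else (s - mean(pool)) / sdp
  }, selected, pools)
  sum(z)
}

#' Wilcoxon signed-rank test (two-sided)
#'
#' Paired test on a - b. Zero differences are dropped; absolute
#' differences are mid-ranked under ties. For up to 12 non-zero pairs the
#' two-sided p-value is exact, by enumeration of all 2^n sign
#' assignments; beyond that a normal approximation with tie correction
#' and continuity correction is used. If every difference is zero the
#' test is degenerate and p = 1 with a flag.
#'
#' @param a,b paired numeric vectors.
#' @param exactLimit maximum n for exact enumeration.
#' @return list(p, statistic = W+ (sum of positive ranks), n = non-zero
#'   pairs, method, degenerate).
#' @export
wilcoxonSignedRank <- function(a, b, exactLimit = 12) {
  d <- a - b
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(p = 1, statistic = 0, n = 0, method = "degenerate",
                degenerate = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exactLimit) {
    # distribution of W+ over all 2^n equiprobable sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.vector(signs %*% r)
    pGe <- mean(Wall >= W)
    pLe <- mean(Wall <= W)
    p <- min(1, 2 * min(pGe, pLe))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5 * sign(W - mu)
    z <- (W - mu - cc) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(p = p, statistic = W, n = n, method = method, degenerate = FALSE)
}

#' Convert residue-level distance errors to a global score
#'
#' \deqn{Global = (1/L) \sum_i 1 / (1 + (l_i / 5)^2)}
#' where \eqn{l_i} is the predicted (or actual) local distance error of
#' residue i in Angstrom.
#'
#' @param localDist non-negative numeric vector of length L.
#' @return global quality in (0,1].
#' @export
localToGlobal <- function(localDist) {
  if (any(!is.finite(localDist)) || any(localDist < 0))
    stop("local distances must be finite and non-negative")
  mean(1 / (1 + (localDist / 5)^2))
}

#' Evaluate predictions over multiple targets
#'
#' Aggregates the standard decoy-ranking statistics for one prediction
#' table: per-target Pearson correlation and loss, best-of-top-1/top-5
#' true TM-score and RMSD, and Z-score sums.
#'
#' @param table data.frame with columns \code{target}, \code{model},
#'   \code{predicted}, \code{gdtts} (true), and optionally \code{tm},
#'   \code{rmsd}.
#' @param k selection depth for the best-of-top-k columns.
#' @return list with \code{perTarget} (data.frame) and \code{summary}
#'   (named numeric: meanCorrelation, meanLoss, sums and Z-sums where the
#'   inputs allow).
#' @export
evaluateQA <- function(table, k = 5) {
  need <- c("target", "model", "predicted", "gdtts")
  if (!all(need %in% names(table)))
    stop("evaluation table needs columns: ", paste(need, collapse = ", "))
  hasTM <- "tm" %in% names(table)
  hasRMSD <- "rmsd" %in% names(table)
  rows <- lapply(split(table, table$target), function(tt) {
    ids <- as.character(tt$model)
    topk <- topKSelection(tt$predicted,
                          tm = if (hasTM) tt$tm else NULL,
                          rmsd = if (hasRMSD) tt$rmsd else NULL,
                          k = min(k, nrow(tt)), ids = ids)
    top1 <- selectionOrder(tt$predicted, ids)[1]
    data.frame(
      target = tt$target[1],
      nModels = nrow(tt),
      correlation = perTargetCorrelation(tt$predicted, tt$gdtts),
      loss = perTargetLoss(tt$predicted, tt$gdtts, ids),
      tmTop1 = if (hasTM) tt$tm[top1] else NA_real_,
      rmsdTop1 = if (hasRMSD) tt$rmsd[top1] else NA_real_,
      tmTopK = if (hasTM) topk$tm else NA_real_,
      rmsdTopK = if (hasRMSD) topk$rmsd else NA_real_,
      stringsAsFactors = FALSE)
  })
  perTarget <- do.call(rbind, rows)
  rownames(perTarget) <- NULL
  summary <- c(meanCorrelation = mean(perTarget$correlation, na.rm = TRUE),
               meanLoss = mean(perTarget$loss))
  if (hasTM) {
    pools <- split(table$tm, table$target)
    summary <- c(summary,
                 sumTMTop1 = sum(perTarget$tmTop1),
                 sumTMTopK = sum(perTarget$tmTopK),
                 zsumTMTop1 = zscoreSum(perTarget$tmTop1, pools),
                 zsumTMTopK = zscoreSum(perTarget$tmTopK, pools))
  }
  if (hasRMSD) {
    pools <- split(table$rmsd, table$target)
    summary <- c(summary,
                 sumRMSDTop1 = sum(perTarget$rmsdTop1),
                 sumRMSDTopK = sum(perTarget$rmsdTopK),
                 zsumRMSDTop1 = zscoreSum(perTarget$rmsdTop1, pools),
                 zsumRMSDTopK = zscoreSum(perTarget$rmsdTopK, pools))
  }
  list(perTarget = perTarget, summary = summary)
}
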