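# Independent oracles: brute-force or dense-sampling reference
# implementations kept deliberately separate from the package's
# production code paths.

# Exhaustive GDT: for every residue subset of size >= 3, superpose on the
# subset and accept it for a threshold when all subset deviations fit.
gdtExhaustive <- function(mCA, nCA, thresholds = c(1, 2, 4, 8)) {
  L <- nrow(mCA)
  best <- rep(0, length(thresholds))
  for (k in 3:L) {
    cm <- utils::combn(L, k)
    for (j in seq_len(ncol(cm))) {
      S <- cm[, j]
      sup <- kabschSuperpose(nCA[S, , drop = FALSE], mCA[S, , drop = FALSE])
      dev <- sqrt(rowSums((applySuperposition(mCA[S, , drop = FALSE], sup) -
                             nCA[S, , drop = FALSE])^2))
      mx <- max(dev)
      for (t in seq_along(thresholds))
        if (mx <= thresholds[t]) best[t] <- max(best[t], k / L)
    }
  }
  mean(best)
}

# Minimum RMSD over rotations by grid search on Euler angles followed by
# Nelder-Mead refinement; independent of the SVD route.
rmsdRotationSearch <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  rotOf <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  }
  obj <- function(ang) sqrt(mean(rowSums((bc %*% t(rotOf(ang)) - ac)^2)))
  grid <- seq(0, 2 * pi, length.out = 9)[-9]
  bestVal <- Inf; bestAng <- c(0, 0, 0)
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < bestVal) { bestVal <- v; bestAng <- c(a1, a2, a3) }
  }
  fit <- optim(bestAng, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  fit$value
}

# Central finite differences of the fine-tuning objective.
numericGradient <- function(theta, X, y, dims, idx, h = 1e-4) {
  vapply(idx, function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    (dbnQA:::dbnCost(tp, X, y, dims) - dbnQA:::dbnCost(tm, X, y, dims)) /
      (2 * h)
  }, numeric(1))
}

# Expected CD-1 update direction for a single-visible/single-hidden RBM
# on one sample, by enumerating the two hidden states.
cd1Expected1x1 <- function(w, vb, hb, v) {
  sig <- function(x) 1 / (1 + exp(-x))
  ph <- sig(v * w + hb)
  grad <- matrix(0, 1, 1); gv <- 0; gh <- 0
  for (h in c(0, 1)) {
    pr <- if (h == 1) ph else 1 - ph
    vr <- sig(h * w + vb)
    ph2 <- sig(vr * w + hb)
    grad <- grad + pr * (v * ph - vr * ph2)
    gv <- gv + pr * (v - vr)
    gh <- gh + pr * (ph - ph2)
  }
  list(W = grad, vbias = gv, hbias = gh)
}
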