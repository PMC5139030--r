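#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares superposition of point set \code{b} onto \code{a} via the
#' SVD of the cross-covariance matrix, with the reflection excluded so the
#' returned matrix is a proper rotation (det = +1).
#'
#' @param a,b numeric n x 3 matrices (n >= 3, not collinear), matched rows.
#' @return list with \code{rotation} (3x3, applied on the right),
#'   \code{translation} (length-3), and \code{rmsd}: the transform
#'   \code{b \%*\% rotation + translation} minimises the RMSD to \code{a}.
#' @export
kabschSuperpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  if (nrow(a) < 3L) stop("need at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  s <- svd(crossprod(bc, ac))          # maximise tr(t(R) C), C = t(bc) ac
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tr <- ca - as.vector(cb %*% R)
  resid <- bc %*% R - ac
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums(resid^2))))
}

#' Apply a superposition to coordinates
#'
#' @param coords n x 3 matrix.
#' @param sup result of \code{kabschSuperpose()}.
#' @return transformed n x 3 matrix.
#' @export
applySuperposition <- function(coords, sup) {
  sweep(as.matrix(coords) %*% sup$rotation, 2, sup$translation, "+")
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci
# lattice), so SASA is bit-stable across runs.
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

atomRadius <- function(elety) {
  el <- substr(gsub("^[0-9]", "", toupper(elety)), 1, 1)
  r <- ATOM_RADII[el]
  ifelse(is.na(r), ATOM_RADII[["C"]], r)
}

# Body-fixed orthonormal frame from the principal axes of the atom
# cloud, signs fixed by the third moment along each axis, right-handed,
# with the dominant axis as the third (polar) column. Sphere points
# expressed in this frame co-rotate with the molecule, so SASA is
# exactly invariant under rigid transforms; putting the lattice pole on
# the dominant axis also aligns the point rings with typical occlusion
# boundaries, which reduces quantization error.
principalFrame <- function(xyz) {
  if (nrow(xyz) < 2L) return(diag(3))
  xc <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)$vectors
  for (k in 1:2) {
    s <- sum((xc %*% ev[, k])^3)
    if (s < 0) ev[, k] <- -ev[, k]
  }
  v3 <- c(ev[2, 1] * ev[3, 2] - ev[3, 1] * ev[2, 2],
          ev[3, 1] * ev[1, 2] - ev[1, 1] * ev[3, 2],
          ev[1, 1] * ev[2, 2] - ev[2, 1] * ev[1, 2])
  cbind(ev[, 2], v3, ev[, 1])
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Rolls a probe over sphere points placed on each heavy atom; a point is
#' accessible when no other atom's probe-expanded sphere covers it.
#' Per-atom areas are summed per residue; relative accessibility divides
#' by a fixed per-residue maximum-ASA reference and is clamped to [0,1].
#' A residue is flagged exposed at relative accessibility >= 0.25.
#'
#' Models that carry only CA atoms are handled with one 2.0-Angstrom
#' pseudo-atom per residue (approximate; a message is emitted).
#'
#' @param model a \linkS4class{ProteinModel}.
#' @param probeRadius solvent probe radius in Angstrom (water: 1.4).
#' @param nPoints sphere points per atom; 92 is the fast default, larger
#'   values converge to the same areas.
#' @return list with numeric vectors \code{absolute} (Angstrom^2 per
#'   residue), \code{relative} (in [0,1]) and logical \code{exposed},
#'   all of length L in residue order.
#' @export
shrakeRupleySasa <- function(model, probeRadius = 1.4, nPoints = 92) {
  at <- model@atoms
  if (nrow(at) == 0L) stop("model has no atoms")
  caOnly <- all(at$elety == "CA")
  if (caOnly) {
    message("CA-only model '", modelId(model),
            "': SASA uses 2.0 A pseudo-atoms (approximate)")
    radii <- rep(CA_ONLY_RADIUS, nrow(at))
  } else {
    radii <- atomRadius(at$elety)
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rp <- radii + probeRadius
  sphere <- fibonacciSphere(nPoints) %*% t(principalFrame(xyz))
  n <- nrow(xyz)
  areas <- numeric(n)
  maxReach <- max(rp)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ], "-")^2)
    nb <- which(d2 < (rp + rp[i])^2 & seq_len(n) != i)
    if (!length(nb)) {
      areas[i] <- 4 * pi * rp[i]^2
      next
    }
    pts <- sweep(sphere * rp[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- rowSums(sweep(pts[free, , drop = FALSE], 2, xyz[j, ], "-")^2)
      free[free] <- dj2 >= rp[j]^2
    }
    areas[i] <- 4 * pi * rp[i]^2 * sum(free) / nPoints
  }
  absRes <- vapply(model@resno, function(r) sum(areas[at$resno == r]),
                   numeric(1))
  seqv <- strsplit(model@sequence, "")[[1]]
  ref <- unname(MAX_ASA[seqv])
  rel <- pmin(1, pmax(0, absRes / ref))
  list(absolute = absRes, relative = rel,
       exposed = rel >= EXPOSED_THRESHOLD)
}

# Torsion angle (degrees, in (-180, 180]) for four points.
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi dihedral angles
#'
#' @param model a \linkS4class{ProteinModel} with backbone N, CA, C atoms.
#' @return list of numeric vectors \code{phi}, \code{psi} (degrees, NA at
#'   chain termini or where backbone atoms are missing).
#' @export
backboneDihedrals <- function(model) {
  at <- model@atoms
  getAtom <- function(r, name) {
    i <- which(at$resno == r & at$elety == name)
    if (length(i)) as.numeric(at[i[1], c("x", "y", "z")]) else NULL
  }
  L <- length(model@resno)
  phi <- psi <- rep(NA_real_, L)
  for (k in seq_len(L)) {
    r <- model@resno[k]
    Nk <- getAtom(r, "N"); CAk <- getAtom(r, "CA"); Ck <- getAtom(r, "C")
    if (is.null(Nk) || is.null(CAk) || is.null(Ck)) next
    if (k > 1) {
      Cprev <- getAtom(model@resno[k - 1], "C")
      if (!is.null(Cprev)) phi[k] <- dihedralAngle(Cprev, Nk, CAk, Ck)
    }
    if (k < L) {
      Nnext <- getAtom(model@resno[k + 1], "N")
      if (!is.null(Nnext)) psi[k] <- dihedralAngle(Nk, CAk, Ck, Nnext)
    }
  }
  list(phi = phi, psi = psi)
}

#' Assign 3-state secondary structure from backbone dihedrals
#'
#' Deterministic window rules on phi/psi: helix (H) for phi in (-100,-30)
#' and psi in (-80,-5) over runs of at least 4 residues; strand (E) for
#' phi in (-170,-50) and psi in (80,180] or (-180,-170) over runs of at
#' least 2; everything else, including termini with undefined dihedrals,
#' is coil (C). Models without full backbone N/CA/C yield an all-C string
#' with a warning.
#'
#' @param model a \linkS4class{ProteinModel}.
#' @return 3-state string over {H,E,C} of length L.
#' @export
assignSecondaryStructure <- function(model) {
  L <- length(model@resno)
  at <- model@atoms
  hasBB <- all(vapply(model@resno, function(r) {
    all(c("N", "CA", "C") %in% at$elety[at$resno == r])
  }, logical(1)))
  if (!hasBB) {
    warning("model '", modelId(model),
            "' lacks full backbone; secondary structure set to all-coil")
    return(paste(rep("C", L), collapse = ""))
  }
  dh <- backboneDihedrals(model)
  phi <- dh$phi; psi <- dh$psi
  isH <- !is.na(phi) & !is.na(psi) &
    phi > -100 & phi < -30 & psi > -80 & psi < -5
  isE <- !is.na(phi) & !is.na(psi) &
    phi > -170 & phi < -50 &
    ((psi > 80 & psi <= 180) | (psi >= -180 & psi < -170))
  ss <- rep("C", L)
  ss[enforceRuns(isH, 4)] <- "H"
  ss[enforceRuns(isE, 2)] <- "E"
  paste(ss, collapse = "")
}

# Keep TRUE only inside runs of at least minLen consecutive TRUEs.
enforceRuns <- function(flag, minLen) {
  r <- rle(flag)
  r$values <- r$values & r$lengths >= minLen
  inverse.rle(r)
}

#' CA-CA distance matrix
#'
#' @param model a \linkS4class{ProteinModel}.
#' @return symmetric L x L matrix of CA-CA Euclidean distances (Angstrom),
#'   zero diagonal.
#' @export
distanceMatrix <- function(model) {
  as.matrix(stats::dist(caCoords(model)))
}
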